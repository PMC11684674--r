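# Independent brute-force oracles for the segmentation operators. These
# re-derive each result from first principles (double loops, linear-scan
# priority selection) and stay independent of the package's compiled
# paths.

orOffsets <- function(connectivity, ndim) {
  if (ndim == 2L) {
    o <- expand.grid(dc = -1:1, dr = -1:1)[, c("dr", "dc")]
    o <- o[order(o$dr, o$dc), ]
    o <- o[!(o$dr == 0 & o$dc == 0), ]
    if (connectivity == 4) o <- o[abs(o$dr) + abs(o$dc) == 1, ]
    as.matrix(o)
  } else {
    o <- expand.grid(dz = -1:1, dc = -1:1, dr = -1:1)[, c("dr", "dc", "dz")]
    o <- o[order(o$dr, o$dc, o$dz), ]
    o <- o[!(o$dr == 0 & o$dc == 0 & o$dz == 0), ]
    if (connectivity == 6) o <- o[abs(o$dr) + abs(o$dc) + abs(o$dz) == 1, ]
    as.matrix(o)
  }
}

orMeanFilter <- function(img, k) {
  h <- (k - 1) %/% 2
  n <- nrow(img); m <- ncol(img)
  out <- img
  for (r in seq_len(n)) for (c in seq_len(m)) {
    rr <- pmin(pmax(r + (-h:h), 1), n)
    cc <- pmin(pmax(c + (-h:h), 1), m)
    out[r, c] <- mean(img[rr, cc])
  }
  out
}

orLocalMask <- function(img, k) {
  hlo <- k %/% 2; hhi <- k - 1 - hlo
  n <- nrow(img); m <- ncol(img)
  out <- matrix(FALSE, n, m)
  for (r in seq_len(n)) for (c in seq_len(m)) {
    rr <- pmin(pmax(r + (-hlo:hhi), 1), n)
    cc <- pmin(pmax(c + (-hlo:hhi), 1), m)
    out[r, c] <- img[r, c] > mean(img[rr, cc])
  }
  out
}

orOtsu <- function(img) {
  # exhaustive search over every candidate threshold, recomputing the
  # between-class variance from scratch per candidate
  v <- as.numeric(img)
  u <- sort(unique(v))
  best <- -Inf; thr <- u[1]
  for (t in u[-length(u)]) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    mu0 <- sum(lo) / length(lo); mu1 <- sum(hi) / length(hi)
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best) { best <- sb; thr <- t }
  }
  out <- img > thr
  attr(out, "threshold") <- thr
  out
}

# reading-order BFS labelling
orLabel <- function(mask, connectivity = 8) {
  d <- dim(mask)
  off <- orOffsets(connectivity, length(d))
  lab <- array(0L, d)
  nxt <- 0L
  ord <- expand.grid(c = seq_len(d[2]), r = seq_len(d[1]))[, c("r", "c")]
  ord <- ord[order(ord$r, ord$c), ]
  for (i in seq_len(nrow(ord))) {
    r0 <- ord$r[i]; c0 <- ord$c[i]
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (j in seq_len(nrow(off))) {
        rr <- p[1] + off[j, 1]; cc <- p[2] + off[j, 2]
        if (rr < 1 || rr > d[1] || cc < 1 || cc > d[2]) next
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

orFillHoles <- function(mask, connectivity = 4) {
  d <- dim(mask)
  bg <- !mask
  reached <- array(FALSE, d)
  off <- orOffsets(connectivity, 2L)
  queue <- list()
  for (r in seq_len(d[1])) for (c in seq_len(d[2]))
    if ((r == 1 || r == d[1] || c == 1 || c == d[2]) && bg[r, c] &&
        !reached[r, c]) {
      reached[r, c] <- TRUE
      queue[[length(queue) + 1]] <- c(r, c)
    }
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (j in seq_len(nrow(off))) {
      rr <- p[1] + off[j, 1]; cc <- p[2] + off[j, 2]
      if (rr < 1 || rr > d[1] || cc < 1 || cc > d[2]) next
      if (bg[rr, cc] && !reached[rr, cc]) {
        reached[rr, cc] <- TRUE
        queue[[length(queue) + 1]] <- c(rr, cc)
      }
    }
  }
  mask | (bg & !reached)
}

orLargest <- function(mask, connectivity = 8) {
  lab <- orLabel(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

orHullExtent <- function(mask) {
  rows <- which(mask, arr.ind = TRUE)[, 1]
  max(rows) - min(rows) + 1L
}

orApplyMask <- function(grid, mask) {
  g <- grid
  g[!mask] <- 0L
  u <- sort(unique(g[g > 0L]))
  out <- array(0L, dim(g))
  for (i in seq_along(u)) out[g == u[i]] <- i
  out
}

orRemoveBorder <- function(grid) {
  d <- dim(grid)
  border <- unique(c(grid[1, ], grid[d[1], ], grid[, 1], grid[, d[2]]))
  g <- grid
  g[g %in% border[border > 0]] <- 0L
  u <- sort(unique(g[g > 0L]))
  out <- array(0L, dim(g))
  for (i in seq_along(u)) out[g == u[i]] <- i
  out
}

# priority-flood watershed oracle: linear-scan selection of the queue
# entry with minimal (relief value, insertion order)
orWatershed <- function(relief, seeds, mask = NULL, connectivity = 8) {
  d <- dim(relief)
  if (is.null(mask)) mask <- array(TRUE, d)
  off <- orOffsets(connectivity, 2L)
  lab <- array(0L, d)
  qv <- numeric(); qo <- integer(); qr <- integer(); qc <- integer()
  ql <- integer()
  ord <- 0L
  for (i in seq_len(nrow(seeds))) {
    qv <- c(qv, relief[seeds[i, 1], seeds[i, 2]])
    qo <- c(qo, ord); ord <- ord + 1L
    qr <- c(qr, seeds[i, 1]); qc <- c(qc, seeds[i, 2])
    ql <- c(ql, i)
  }
  while (length(qv)) {
    cand <- which(qv == min(qv))
    pick <- cand[which.min(qo[cand])]
    r <- qr[pick]; c <- qc[pick]; l <- ql[pick]
    qv <- qv[-pick]; qo <- qo[-pick]; qr <- qr[-pick]; qc <- qc[-pick]
    ql <- ql[-pick]
    if (lab[r, c] > 0L) next
    lab[r, c] <- l
    for (j in seq_len(nrow(off))) {
      rr <- r + off[j, 1]; cc <- c + off[j, 2]
      if (rr < 1 || rr > d[1] || cc < 1 || cc > d[2]) next
      if (mask[rr, cc] && lab[rr, cc] == 0L) {
        qv <- c(qv, relief[rr, cc]); qo <- c(qo, ord); ord <- ord + 1L
        qr <- c(qr, rr); qc <- c(qc, cc); ql <- c(ql, l)
      }
    }
  }
  lab
}
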