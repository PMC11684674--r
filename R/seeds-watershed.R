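## Multi-scale Laplacian-of-Gaussian blob seeding and the deterministic
## seeded immersion watershed they initialise.

#' Scale-normalised Laplacian-of-Gaussian response
#'
#' Smooths with a Gaussian of standard deviation `sigma` and applies the
#' discrete Laplacian; the response is negated and multiplied by
#' `sigma^2` so that bright blobs of matching size produce positive peaks
#' comparable across scales.
#'
#' @inheritParams meanFilter
#' @param sigma Gaussian scale in pixels.
#' @return Numeric array of responses, same shape as `x`.
#' @export
logFilter <- function(x, sigma) {
  a <- .pix(x)
  d <- .dims(a)
  g <- .convolveSep(as.numeric(a), d, .gaussKernel(sigma))
  lap <- numeric(length(g))
  k2 <- c(1, -2, 1)
  for (axis in seq_along(d))
    lap <- lap + cpp_convolve_axis(g, d, k2, axis - 1L)
  out <- -sigma^2 * lap
  dim(out) <- d
  out
}

#' Multi-scale Laplacian-of-Gaussian seed detection
#'
#' Detects blob centres as local maxima of the scale-normalised negative
#' LoG response over a geometric progression of `nScales` scales between
#' `scaleMin` and `scaleMax`. Candidate maxima must be strict spatial
#' maxima at their scale and not exceeded at the same position by the
#' neighbouring scales. Non-maximum suppression then removes any
#' candidate lying within the detection scale (blob support) of a
#' stronger accepted seed, so no two seeds are closer than the detection
#' scale.
#'
#' The reference nuclei pipeline uses scale ranges (5, 15) for the earlier
#' two blastoderm time points and (1, 10) for the later one.
#'
#' @inheritParams meanFilter
#' @param scaleMin,scaleMax scale range (sigma, pixels), `0 < scaleMin <=
#'   scaleMax`.
#' @param nScales number of geometrically spaced scales.
#' @param threshold absolute response floor; candidates must exceed it.
#' @param relThreshold optional relative floor as a fraction of the
#'   maximum response over all scales (e.g. 0.1); applied in addition to
#'   `threshold` when not `NULL`.
#' @return A [SeedSet-class].
#' @export
logSeeds <- function(x, scaleMin = 5, scaleMax = 15, nScales = 10,
                     threshold = 0, relThreshold = NULL) {
  if (!(scaleMin > 0 && scaleMin <= scaleMax))
    stop("configuration error: need 0 < scaleMin <= scaleMax")
  a <- .pix(x)
  d <- .dims(a)
  scales <- if (scaleMin == scaleMax) scaleMin else
    exp(seq(log(scaleMin), log(scaleMax), length.out = nScales))
  resp <- lapply(scales, function(s) logFilter(a, s))
  floorVal <- threshold
  if (!is.null(relThreshold)) {
    gmax <- max(vapply(resp, max, numeric(1)))
    floorVal <- max(floorVal, relThreshold * gmax)
  }
  cand <- list()
  ## with >= 3 scales, only interior scale-space maxima qualify: a
  ## detection at a boundary scale is one-sided and typically an
  ## artefact of range truncation (cluster-scale or noise-scale blobs)
  sidx <- if (length(scales) >= 3L) 2:(length(scales) - 1L)
          else seq_along(scales)
  for (si in sidx) {
    r <- resp[[si]]
    ok <- .strictLocalMaxima(r) & (r > floorVal)
    if (si > 1L) ok <- ok & (r >= resp[[si - 1L]])
    if (si < length(scales)) ok <- ok & (r >= resp[[si + 1L]])
    idx <- which(ok)
    if (length(idx))
      cand[[length(cand) + 1L]] <-
        cbind(arrayInd(idx, d), scale = scales[si], value = r[idx])
  }
  nd <- length(d)
  if (!length(cand))
    return(SeedSet(matrix(integer(), 0, nd), numeric(), numeric()))
  cand <- do.call(rbind, cand)
  ## strongest first; ties resolved in reading order, then smaller scale
  o <- do.call(order, c(list(-cand[, "value"]),
                        lapply(seq_len(nd), function(j) cand[, j]),
                        list(cand[, "scale"])))
  cand <- cand[o, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    prev <- which(keep)
    dist2 <- rowSums((cand[prev, seq_len(nd), drop = FALSE] -
                      matrix(cand[i, seq_len(nd)], length(prev), nd,
                             byrow = TRUE))^2)
    ## no two seeds closer than the detection scale: the support of a
    ## LoG detection at scale sigma is a ball of radius sqrt(d)*sigma
    ## (its zero-crossing), so a blob whose support already contains an
    ## accepted seed is redundant (e.g. a group-of-nuclei detection)
    minSep <- sqrt(nd) * pmax(cand[prev, "scale"], cand[i, "scale"])
    if (all(dist2 >= minSep^2)) keep[i] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  ## drop exact duplicate positions surviving across scales (keep stronger)
  dup <- duplicated(cand[, seq_len(nd), drop = FALSE])
  cand <- cand[!dup, , drop = FALSE]
  SeedSet(cand[, seq_len(nd), drop = FALSE], cand[, "scale"],
          cand[, "value"])
}

## strict spatial local maxima (8/26-neighbourhood), borders compared
## against existing neighbours only
.strictLocalMaxima <- function(r) {
  d <- dim(r)
  nd <- length(d)
  offs <- expand.grid(rep(list(-1:1), nd))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  out <- array(TRUE, d)
  idxList <- lapply(d, seq_len)
  for (i in seq_len(nrow(offs))) {
    src <- dst <- idxList
    for (j in seq_len(nd)) {
      o <- offs[i, j]
      if (o == 1L) { dst[[j]] <- seq_len(d[j] - 1L); src[[j]] <- 2:d[j] }
      else if (o == -1L) { dst[[j]] <- 2:d[j]; src[[j]] <- seq_len(d[j] - 1L) }
    }
    cmp <- do.call(`[`, c(list(r), dst, list(drop = FALSE))) >
           do.call(`[`, c(list(r), src, list(drop = FALSE)))
    sub <- do.call(`[`, c(list(out), dst, list(drop = FALSE))) & cmp
    out <- do.call(`[<-`, c(list(out), dst, list(sub)))
  }
  out
}

#' Seeded immersion watershed
#'
#' Floods the relief from the seed pixels, lower relief values first, and
#' assigns every reachable masked pixel to exactly one seed label.
#' Flooding order is fully deterministic: ties on the relief value are
#' broken by insertion order into the flooding queue (seeds in list
#' order, then neighbours in the order they are reached, enumerated in
#' reading order), so repeated runs are bit-identical.
#'
#' The nuclei pipelines apply this to the *inverted* smoothed image so
#' that bright nucleus centres become basins.
#'
#' @param relief matrix/3D array, [ImageFrame-class] or
#'   [ImageStack-class]; lower values flood first.
#' @param seeds a [SeedSet-class] or integer coordinate matrix (one row
#'   per seed). Seeds outside `mask` are dropped with a warning.
#' @param mask optional logical mask restricting the flooded region
#'   (default: whole image).
#' @param connectivity 4/8 (2D) or 6/26 (3D).
#' @return A [LabelMap-class]; label `k` is the basin of the `k`-th
#'   retained seed (re-compacted if a seed captured no pixels).
#' @export
seededWatershed <- function(relief, seeds, mask = NULL,
                            connectivity = .defaultConnectivity(.pix(relief))) {
  a <- .pix(relief)
  d <- .dims(a)
  connectivity <- .checkConnectivity(connectivity, a)
  co <- if (is(seeds, "SeedSet")) seeds@coords else {
    if (is.null(dim(seeds))) seeds <- matrix(seeds, nrow = 1)
    seeds
  }
  if (ncol(co) == 2L && length(d) == 3L)
    stop("2D seeds supplied for a 3D relief")
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!identical(as.integer(dim(mask)), d))
    stop("shape mismatch between relief and mask")
  if (nrow(co) == 0L) stop("no markers: empty seed set")
  inMask <- vapply(seq_len(nrow(co)), function(i) {
    idx <- if (length(d) == 2L) co[i, 1:2] else co[i, 1:3]
    isTRUE(mask[matrix(idx, 1)])
  }, logical(1))
  if (!all(inMask)) {
    warning(sum(!inMask), " seed(s) outside the mask were dropped")
    co <- co[inMask, , drop = FALSE]
  }
  if (nrow(co) == 0L) stop("no markers: all seeds outside the mask")
  seeds0 <- cbind(co[, 1] - 1L, co[, 2] - 1L,
                  if (length(d) == 3L) co[, 3] - 1L else 0L)
  storage.mode(seeds0) <- "integer"
  g <- cpp_watershed(as.numeric(a), d, seeds0, as.logical(mask),
                     connectivity)
  dim(g) <- d
  LabelMap(.compactLabels(g))
}
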