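## Core image operators composing the length, nuclei and pole-cell
## pipelines. All operators are deterministic; the filtering/threshold
## workhorses live in src/operators.cpp.

.pix <- function(x) {
  if (is(x, "ImageFrame") || is(x, "ImageStack")) x@data else x
}

.rewrap <- function(x, data) {
  if (is(x, "ImageFrame")) {
    x@data <- data
    x
  } else if (is(x, "ImageStack")) {
    x@data <- data
    x
  } else data
}

.checkOddRange <- function(range, what) {
  if (length(range) != 1L || !is.finite(range) || range <= 0 ||
      range != round(range) || range %% 2 == 0)
    stop("configuration error: '", what,
         "' must be an odd positive integer, got ", range)
  as.integer(range)
}

.dims <- function(a) {
  d <- dim(a)
  if (is.null(d)) stop("input must be a matrix or array")
  if (!length(d) %in% c(2L, 3L)) stop("only 2D and 3D images supported")
  as.integer(d)
}

.defaultConnectivity <- function(a) if (length(dim(a)) == 3L) 26L else 8L

.checkConnectivity <- function(connectivity, a) {
  d <- length(dim(a))
  ok <- if (d == 3L) c(6L, 26L) else c(4L, 8L)
  if (!connectivity %in% ok)
    stop("configuration error: connectivity must be one of ",
         paste(ok, collapse = "/"), " for ", d, "D input")
  as.integer(connectivity)
}

## ---- smoothing ----------------------------------------------------------

#' Mean (box) filter
#'
#' Replaces each pixel by the mean of its `range` x `range` (x `range` for
#' stacks) neighbourhood; borders are handled by edge replication. A
#' `range` of 3 reproduces the reference smoothing step of the embryo
#' length pipeline.
#'
#' For integer-valued images (as camera data are) the window sums are
#' computed exactly, so e.g. a constant image is returned bit-identically.
#'
#' @param x matrix, 3D array, [ImageFrame-class] or [ImageStack-class].
#' @param range odd positive kernel edge length in pixels.
#' @return Smoothed image of the same class as `x`.
#' @examples
#' m <- matrix(0, 5, 5); m[3, 3] <- 9
#' meanFilter(m)[3, 3]  # 1
#' @export
setGeneric("meanFilter", function(x, range = 3) standardGeneric("meanFilter"))

#' @rdname meanFilter
setMethod("meanFilter", "ANY", function(x, range = 3) {
  range <- .checkOddRange(range, "range")
  a <- .pix(x)
  d <- .dims(a)
  out <- cpp_box_mean(as.numeric(a), d, range)
  dim(out) <- d
  .rewrap(x, out)
})

#' Gaussian filter
#'
#' Gaussian smoothing with standard deviation `range` pixels, applied
#' separably with edge replication. The kernel is truncated at
#' `ceiling(3 * range)` and renormalised to unit sum. The reference
#' nuclei pipeline uses `range = 2`.
#'
#' @inheritParams meanFilter
#' @param range Gaussian standard deviation in pixels (> 0).
#' @return Smoothed image of the same class as `x`.
#' @export
setGeneric("gaussianFilter",
           function(x, range = 2) standardGeneric("gaussianFilter"))

#' @rdname gaussianFilter
setMethod("gaussianFilter", "ANY", function(x, range = 2) {
  if (length(range) != 1L || !is.finite(range) || range <= 0)
    stop("configuration error: Gaussian 'range' (sigma) must be positive")
  a <- .pix(x)
  d <- .dims(a)
  out <- .convolveSep(as.numeric(a), d, .gaussKernel(range))
  dim(out) <- d
  .rewrap(x, out)
})

.gaussKernel <- function(sigma) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(-h:h)^2 / (2 * sigma^2))
  k / sum(k)
}

.convolveSep <- function(a, d, kernel) {
  for (axis in seq_along(d)) a <- cpp_convolve_axis(a, d, kernel, axis - 1L)
  a
}

## ---- thresholding -------------------------------------------------------

#' Local mean (adaptive) threshold
#'
#' A pixel is foreground iff its value strictly exceeds the mean intensity
#' of the `window` x `window` neighbourhood centred on it (edge
#' replicated). The reference length pipeline uses `window = 150`; the
#' nuclei pipeline uses 15 or 10. A window larger than the image reduces
#' towards a global-mean threshold.
#'
#' The comparison is exact for integer-valued images, and a constant image
#' always yields an all-`FALSE` mask (nothing is strictly above the mean).
#' For an even `window` the neighbourhood extends one pixel further
#' towards lower row/column indices than towards higher ones.
#'
#' @inheritParams meanFilter
#' @param window positive window edge length in pixels (may be even, and
#'   may exceed the image size).
#' @return Logical mask congruent with `x`.
#' @export
setGeneric("localMeanThreshold",
           function(x, window = 150) standardGeneric("localMeanThreshold"))

#' @rdname localMeanThreshold
setMethod("localMeanThreshold", "ANY", function(x, window = 150) {
  if (length(window) != 1L || !is.finite(window) || window <= 0 ||
      window != round(window))
    stop("configuration error: 'window' must be a positive integer")
  window <- as.integer(window)
  a <- .pix(x)
  d <- .dims(a)
  out <- cpp_box_mask(as.numeric(a), d, window)
  dim(out) <- d
  out
})

#' Otsu threshold
#'
#' Global threshold maximising the between-class variance over the
#' intensity histogram (exhaustive search over all distinct values; the
#' lowest maximising threshold is returned). Foreground is `x > threshold`.
#'
#' @inheritParams meanFilter
#' @return Logical mask with attribute `"threshold"`.
#' @export
setGeneric("otsuThreshold", function(x) standardGeneric("otsuThreshold"))

#' @rdname otsuThreshold
setMethod("otsuThreshold", "ANY", function(x) {
  a <- .pix(x)
  v <- as.numeric(a)
  u <- sort(unique(v))
  if (length(u) < 2L) stop("degenerate histogram: image is constant")
  cnt <- tabulate(match(v, u), nbins = length(u))
  n <- length(v)
  cumN <- cumsum(cnt)
  cumS <- cumsum(cnt * u)
  i <- seq_len(length(u) - 1L)           # threshold candidates u[i]
  w0 <- cumN[i] / n
  w1 <- 1 - w0
  mu0 <- cumS[i] / cumN[i]
  mu1 <- (cumS[length(u)] - cumS[i]) / (n - cumN[i])
  sb <- w0 * w1 * (mu0 - mu1)^2
  thr <- u[which.max(sb)]
  out <- a > thr
  dim(out) <- dim(a)
  attr(out, "threshold") <- thr
  out
})

## ---- morphology ---------------------------------------------------------

#' Label connected components
#'
#' Deterministic connected-component labelling; label 1 is the component
#' whose first pixel comes first in reading order (row, then column, then
#' slice).
#'
#' @param mask logical matrix or 3D array.
#' @param connectivity 4 or 8 (2D), 6 or 26 (3D); defaults to the maximal
#'   connectivity of the dimensionality.
#' @return A [LabelMap-class].
#' @export
labelComponents <- function(mask, connectivity = .defaultConnectivity(mask)) {
  d <- .dims(mask)
  connectivity <- .checkConnectivity(connectivity, mask)
  g <- cpp_label(as.logical(mask), d, connectivity)
  dim(g) <- d
  LabelMap(g)
}

#' Morphological hole filling
#'
#' Background components not connected to the image border are converted
#' to foreground; foreground pixels are never changed. Idempotent. The
#' background is traversed with the complementary connectivity of the
#' foreground default (4 in 2D, 6 in 3D).
#'
#' @param mask logical matrix or 3D array.
#' @param connectivity background connectivity; 4/8 (2D) or 6/26 (3D).
#' @return Logical mask of the same shape.
#' @export
fillHoles <- function(mask,
                      connectivity = if (length(dim(mask)) == 3L) 6L else 4L) {
  d <- .dims(mask)
  connectivity <- .checkConnectivity(connectivity, mask)
  bg <- !mask
  g <- cpp_label(as.logical(bg), d, connectivity)
  dim(g) <- d
  borderLabs <- unique(g[.borderIndices(d)])
  borderLabs <- borderLabs[borderLabs > 0L]
  out <- mask | (bg & !(g %in% borderLabs))
  dim(out) <- d
  out
}

.borderIndices <- function(d) {
  if (length(d) == 2L) {
    ai <- arrayInd(seq_len(prod(d)), d)
    which(ai[, 1] == 1L | ai[, 1] == d[1] | ai[, 2] == 1L | ai[, 2] == d[2])
  } else {
    ai <- arrayInd(seq_len(prod(d)), d)
    which(ai[, 1] == 1L | ai[, 1] == d[1] | ai[, 2] == 1L |
          ai[, 2] == d[2] | ai[, 3] == 1L | ai[, 3] == d[3])
  }
}

#' Keep only the largest connected component
#'
#' Retains the component with the most pixels; a tie is resolved in favour
#' of the component whose first pixel comes first in reading order.
#' Idempotent.
#'
#' @inheritParams labelComponents
#' @return Logical mask containing a single component.
#' @export
largestComponent <- function(mask,
                             connectivity = .defaultConnectivity(mask)) {
  d <- .dims(mask)
  connectivity <- .checkConnectivity(connectivity, mask)
  g <- cpp_label(as.logical(mask), d, connectivity)
  if (max(g) == 0L) stop("no object: mask is empty")
  sizes <- tabulate(g[g > 0L])
  keep <- which.max(sizes)  # first (reading-order) label among ties
  out <- g == keep
  dim(out) <- d
  out
}

#' Convex hull and its extent along the anterior-posterior axis
#'
#' Computes the convex hull of the foreground pixel centres and the hull's
#' extent along *y* (rows) as an inclusive pixel count,
#' `max(row) - min(row) + 1`. This is the embryo length readout of the
#' length pipeline.
#'
#' @param mask logical matrix with at least one foreground pixel, or an
#'   [ImageFrame-class] holding one.
#' @param pixelSize optional micrometres per pixel; when given, the extent
#'   is also reported in micrometres.
#' @return List with `hull` (matrix of hull vertices, columns row/col,
#'   counter-ordered as returned by [grDevices::chull()]), `extent_px`,
#'   and `extent_um` (`NA` when uncalibrated).
#' @export
convexHullExtent <- function(mask, pixelSize = NA_real_) {
  if (is(mask, "ImageFrame")) {
    if (is.na(pixelSize)) pixelSize <- mask@pixelSize
    mask <- mask@data > 0
  }
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0L) stop("no object: mask is empty")
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hull <- pts[h, , drop = FALSE]
  colnames(hull) <- c("row", "col")
  extent <- max(hull[, "row"]) - min(hull[, "row"]) + 1L
  list(hull = hull, extent_px = as.integer(extent),
       extent_um = if (is.na(pixelSize)) NA_real_ else extent * pixelSize)
}

#' Restrict a LabelMap to a mask
#'
#' Sets labels outside `mask` to background, removes objects reduced to
#' zero pixels, and re-compacts the remaining labels to `1..K` (ascending
#' original label order). This realises the final "multiply threshold and
#' watershed" step of the nuclei pipelines.
#'
#' @param labels a [LabelMap-class].
#' @param mask logical mask congruent with the label grid.
#' @return A [LabelMap-class].
#' @export
applyMask <- function(labels, mask) {
  stopifnot(is(labels, "LabelMap"))
  g <- labels@data
  if (!identical(dim(g), dim(mask)))
    stop("shape mismatch between labels (", paste(dim(g), collapse = "x"),
         ") and mask (", paste(dim(mask), collapse = "x"), ")")
  g[!mask] <- 0L
  LabelMap(.compactLabels(g))
}

#' Discard objects touching the image border
#'
#' Objects with any pixel on any image face are removed; remaining labels
#' are re-compacted to `1..K`.
#'
#' @param labels a [LabelMap-class].
#' @return A [LabelMap-class].
#' @export
removeBorderObjects <- function(labels) {
  stopifnot(is(labels, "LabelMap"))
  g <- labels@data
  d <- dim(g)
  drop <- unique(g[.borderIndices(as.integer(d))])
  drop <- drop[drop > 0L]
  g[g %in% drop] <- 0L
  LabelMap(.compactLabels(g))
}

.compactLabels <- function(g) {
  u <- sort(unique(g[g > 0L]))
  if (!length(u)) return(g)
  remap <- integer(max(u))
  remap[u] <- seq_along(u)
  g[g > 0L] <- remap[g[g > 0L]]
  g
}
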