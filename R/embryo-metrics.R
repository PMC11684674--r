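## Embryo length over developmental time and germband-tip kinematics.

#' Configuration of the embryo length pipeline
#'
#' The reference pipeline on an aligned z-maximum projection is: crop to
#' the region of interest, 3x3 mean filtering, local-mean thresholding
#' with a 150x150 window, retention of the largest binary object, and the
#' convex-hull extent along *y* as the embryo length.
#'
#' @param crop optional crop rectangle `c(rmin, rmax, cmin, cmax)`.
#' @param meanRange mean filter kernel edge (odd; reference value 3).
#' @param thresholdWindow local-mean threshold window (reference 150).
#' @param connectivity component connectivity (default 8).
#' @return A list of class `"lengthConfig"`.
#' @export
lengthConfig <- function(crop = NULL, meanRange = 3, thresholdWindow = 150,
                         connectivity = 8) {
  .checkOddRange(meanRange, "meanRange")
  if (thresholdWindow <= 0 || thresholdWindow != round(thresholdWindow))
    stop("configuration error: 'thresholdWindow' must be a positive integer")
  structure(list(crop = crop, meanRange = meanRange,
                 thresholdWindow = thresholdWindow,
                 connectivity = connectivity),
            class = "lengthConfig")
}

#' Measure the embryo length in a single frame
#'
#' Applies the length pipeline (see [lengthConfig()]) and returns the
#' convex-hull extent along *y* in pixels. The frame must already be
#' aligned so that the anterior-posterior axis runs along the rows.
#'
#' @param frame an [ImageFrame-class] or numeric matrix.
#' @param cfg a [lengthConfig()].
#' @return Length in pixels, with attribute `"length_um"` when the frame
#'   is calibrated.
#' @export
measureEmbryoLength <- function(frame, cfg = lengthConfig()) {
  px <- if (is(frame, "ImageFrame")) frame@pixelSize else NA_real_
  a <- .pix(frame)
  if (!is.null(cfg$crop)) {
    cr <- cfg$crop
    a <- a[cr[1]:cr[2], cr[3]:cr[4], drop = FALSE]
  }
  sm <- meanFilter(a, cfg$meanRange)
  mask <- localMeanThreshold(sm, cfg$thresholdWindow)
  if (!any(mask)) stop("embryo not found: empty segmentation")
  obj <- largestComponent(mask, cfg$connectivity)
  hull <- convexHullExtent(obj, pixelSize = px)
  structure(hull$extent_px, length_um = hull$extent_um)
}

#' Embryo length as a function of developmental time
#'
#' Measures every frame with [measureEmbryoLength()] and assembles a
#' length series with normalised length (fraction of the first frame's
#' length) and normalised time (fraction of the covered development
#' span). Frames whose measurement fails are recorded as missing with a
#' warning and interpolated linearly for aggregation (flagged in the
#' `interpolated` column).
#'
#' @param frames list of [ImageFrame-class] objects, or the output of
#'   [generateEmbryoMovie()].
#' @param times acquisition times in hours (default: frame times).
#' @param cfg a [lengthConfig()].
#' @param datasetId optional dataset identifier attached as an attribute.
#' @return data.frame (`LengthSeries`): time_h, length_px, length_um,
#'   norm_time, norm_length, interpolated.
#' @export
lengthTimeseries <- function(frames, times = NULL, cfg = lengthConfig(),
                             datasetId = NA_character_) {
  if (is.list(frames) && !is.null(frames$frames)) frames <- frames$frames
  n <- length(frames)
  if (n < 2L) stop("at least two frames are required for a length series")
  if (is.null(times))
    times <- vapply(frames, function(f)
      if (is(f, "ImageFrame")) f@time else NA_real_, numeric(1))
  if (any(is.na(times)) || any(diff(times) <= 0))
    stop("frame times must be known and strictly increasing")
  px <- vapply(frames, function(f)
    if (is(f, "ImageFrame")) f@pixelSize else NA_real_, numeric(1))
  len <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    len[i] <- tryCatch(as.numeric(measureEmbryoLength(frames[[i]], cfg)),
                       error = function(e) {
                         warning("frame ", i, " failed: ",
                                 conditionMessage(e), call. = FALSE)
                         NA_real_
                       })
  }
  interp <- is.na(len)
  if (all(interp)) stop("embryo not found in any frame")
  if (any(interp))
    len[interp] <- approx(times[!interp], len[!interp],
                          xout = times[interp], rule = 2)$y
  first <- len[1]
  data.frame(time_h = times, length_px = len,
             length_um = len * px,
             norm_time = (times - times[1]) / (times[n] - times[1]),
             norm_length = len / first,
             interpolated = interp) |>
    structure(datasetId = datasetId)
}

#' Aggregate normalised length series across datasets
#'
#' Linearly interpolates each series onto a common normalised-time grid
#' and computes the pointwise mean and sample standard deviation
#' (n - 1 denominator) of the normalised length, giving the
#' mean +/- SD length curve used to compare temporally aligned datasets.
#'
#' @param seriesList list of at least two `LengthSeries` data.frames.
#' @param nGrid number of grid points (default 1000).
#' @return data.frame (`AggregateCurve`): norm_time, mean, sd, n.
#' @export
aggregateCurves <- function(seriesList, nGrid = 1000) {
  if (length(seriesList) < 2L) stop("at least two series are required")
  lo <- max(vapply(seriesList, function(s) min(s$norm_time), numeric(1)))
  hi <- min(vapply(seriesList, function(s) max(s$norm_time), numeric(1)))
  if (lo >= hi) stop("series have non-overlapping time supports")
  grid <- seq(lo, hi, length.out = nGrid)
  vals <- vapply(seriesList, function(s)
    approx(s$norm_time, s$norm_length, xout = grid)$y, numeric(nGrid))
  data.frame(norm_time = grid,
             mean = rowMeans(vals),
             sd = apply(vals, 1, sd),
             n = rowSums(!is.na(vals)))
}

#' Germband-tip migration kinematics from manual annotations
#'
#' Converts manually annotated posterior germband-tip positions into the
#' cumulative migration distance (running sum of Euclidean steps between
#' successive annotations, scaled to micrometres) and per-interval
#' migration speed. The path is the straight-segment polyline through the
#' annotations, a lower bound on the true dorsal-surface arc length.
#'
#' @param annot data.frame with columns `time_h`, `row`, `col` (pixel
#'   coordinates in the z-maximum projection), times strictly increasing.
#' @param pixelSize micrometres per pixel.
#' @return data.frame (`TipKinematics`): time_h, step_um, distance_um,
#'   speed_um_h (speed of the interval ending at each time; first row
#'   `NA`).
#' @export
tipKinematics <- function(annot, pixelSize = 1) {
  stopifnot(all(c("time_h", "row", "col") %in% names(annot)))
  if (nrow(annot) < 2L) stop("at least two annotated timepoints required")
  o <- order(annot$time_h)
  annot <- annot[o, ]
  if (anyDuplicated(annot$time_h)) stop("duplicate timestamps in annotation")
  step <- c(NA, sqrt(diff(annot$row)^2 + diff(annot$col)^2) * pixelSize)
  dist <- cumsum(ifelse(is.na(step), 0, step))
  speed <- step / c(NA, diff(annot$time_h))
  data.frame(time_h = annot$time_h, step_um = step, distance_um = dist,
             speed_um_h = speed)
}

#' Detect deviational peaks in an aggregate curve
#'
#' Finds local maxima of the standard-deviation channel of an
#' [aggregateCurves()] result whose topographic prominence exceeds
#' `minProminence`, i.e. the time points at which the datasets deviate
#' most from one another. Peaks are reported in normalised time and, when
#' a staging table is supplied, mapped to the stage containing each peak.
#'
#' @param curve an `AggregateCurve` data.frame.
#' @param minProminence minimum prominence of a peak (same units as the
#'   SD channel).
#' @param stagingTable optional single-dataset staging table (columns
#'   stage, start_h, end_h) whose *normalised* boundaries are used for
#'   the mapping.
#' @return data.frame: norm_time, sd, prominence (ordered by time), plus
#'   `stage` when `stagingTable` is given.
#' @export
detectSdPeaks <- function(curve, minProminence = 0.005,
                          stagingTable = NULL) {
  s <- curve$sd
  n <- length(s)
  isMax <- which(vapply(seq_len(n), function(i) {
    l <- if (i > 1) s[i - 1] else -Inf
    r <- if (i < n) s[i + 1] else -Inf
    s[i] > l && s[i] >= r
  }, logical(1)))
  prom <- vapply(isMax, function(i) .prominence(s, i), numeric(1))
  keep <- prom >= minProminence
  out <- data.frame(norm_time = curve$norm_time[isMax[keep]],
                    sd = s[isMax[keep]], prominence = prom[keep])
  if (!is.null(stagingTable) && nrow(out)) {
    b <- c(stagingTable$start_h, stagingTable$end_h[nrow(stagingTable)])
    bn <- (b - b[1]) / (b[length(b)] - b[1])
    out$stage <- pmin(pmax(findInterval(out$norm_time, bn), 1L), 17L)
  }
  out[order(out$norm_time), , drop = FALSE]
}

## topographic prominence of the peak at index i
.prominence <- function(s, i) {
  n <- length(s)
  left <- if (i == 1) s[i] else {
    j <- i - 1; m <- s[i]
    while (j >= 1 && s[j] <= s[i]) { m <- min(m, s[j]); j <- j - 1 }
    if (j >= 1) m else min(s[1:i])
  }
  right <- if (i == n) s[i] else {
    j <- i + 1; m <- s[i]
    while (j <= n && s[j] <= s[i]) { m <- min(m, s[j]); j <- j + 1 }
    if (j <= n) m else min(s[i:n])
  }
  s[i] - max(left, right)
}
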