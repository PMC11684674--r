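## Blastoderm nuclei area/density in the posterior analysis window (2D)
## and pole-cell nucleus counting in aligned z-stacks (3D).

#' Extract the posterior analysis window
#'
#' Segments the embryo with Otsu's algorithm, locates the posterior end
#' of the embryo as the extreme foreground pixel along *y*, and extracts
#' a `size` x `size` window whose centre sits `offset` pixels interior to
#' the posterior end on the embryo midline (the centroid column of the
#' embryo mask). The reference pipeline uses an offset of 150 pixels and
#' a 150 x 150 window.
#'
#' @param frame an [ImageFrame-class] or numeric matrix.
#' @param offset distance of the window centre from the posterior end in
#'   pixels.
#' @param size window edge length in pixels.
#' @param posteriorEnd `"max_y"` if the posterior pole is at the highest
#'   row index, `"min_y"` otherwise.
#' @return An [ImageFrame-class] window with attributes `"rows"` and
#'   `"cols"` recording its position in the source frame.
#' @export
extractPosteriorWindow <- function(frame, offset = 150, size = 150,
                                   posteriorEnd = c("max_y", "min_y")) {
  posteriorEnd <- match.arg(posteriorEnd)
  a <- .pix(frame)
  mask <- otsuThreshold(a)
  if (!any(mask)) stop("empty embryo: Otsu segmentation found nothing")
  emb <- largestComponent(mask)
  pix <- which(emb, arr.ind = TRUE)
  if (posteriorEnd == "max_y") {
    r <- max(pix[, 1]); centerRow <- r - offset
  } else {
    r <- min(pix[, 1]); centerRow <- r + offset
  }
  centerCol <- round(mean(pix[, 2]))
  half <- size %/% 2
  rows <- (centerRow - half):(centerRow - half + size - 1L)
  cols <- (centerCol - half):(centerCol - half + size - 1L)
  if (min(rows) < 1L || max(rows) > nrow(a) ||
      min(cols) < 1L || max(cols) > ncol(a))
    stop("window exceeds image bounds (posterior end at row ", r, ")")
  out <- ImageFrame(a[rows, cols],
                    pixelSize = if (is(frame, "ImageFrame"))
                      frame@pixelSize else NA_real_)
  attr(out, "rows") <- range(rows)
  attr(out, "cols") <- range(cols)
  out
}

#' Configuration of the 2D nuclei segmentation
#'
#' Parameter block of [segmentNuclei2D()]. The reference settings are
#' `gaussRange = 2` throughout, `localRange = 15` with LoG scales
#' `c(5, 15)` for the first two blastoderm time points (larger, sparser
#' nuclei) and `localRange = 10` with scales `c(1, 10)` for the later
#' time point (smaller, denser nuclei).
#'
#' @param gaussRange Gaussian smoothing sigma (pixels).
#' @param localRange local-mean threshold window (pixels).
#' @param logScales LoG scale range `c(min, max)` (pixels).
#' @param nScales number of LoG scales.
#' @param relThreshold relative seed-response floor (fraction of the
#'   maximum response); at the typical shot/read noise of a
#'   well-exposed recording, noise-driven scale-space maxima stay below
#'   about 0.15 of a nucleus response, so 0.2 suppresses them while
#'   keeping any nucleus within a five-fold intensity range of the
#'   brightest.
#' @param connectivity component connectivity (default 8).
#' @param minArea resolution floor in pixels: final objects smaller than
#'   a 3 x 3 neighbourhood cannot be resolved nuclei and are discarded.
#' @return List of class `"nucleiConfig"`.
#' @export
nucleiConfig <- function(gaussRange = 2, localRange = 15,
                         logScales = c(5, 15), nScales = 10,
                         relThreshold = 0.2, connectivity = 8,
                         minArea = 9) {
  structure(list(gaussRange = gaussRange, localRange = localRange,
                 logScales = logScales, nScales = nScales,
                 relThreshold = relThreshold, connectivity = connectivity,
                 minArea = minArea),
            class = "nucleiConfig")
}

#' Segment blastoderm nuclei in a 2D window
#'
#' The five-step nuclei pipeline: Gaussian smoothing, local-mean
#' thresholding, morphological hole filling, multi-scale
#' Laplacian-of-Gaussian seed detection, and a seeded immersion watershed
#' on the inverted smoothed image; the final label map is the watershed
#' restricted to the threshold mask, with border-touching objects
#' discarded.
#'
#' @param window an [ImageFrame-class] or numeric matrix (typically from
#'   [extractPosteriorWindow()] or [generateNucleiWindow()]).
#' @param cfg a [nucleiConfig()].
#' @return A [LabelMap-class]; empty (with a warning) when no seeds are
#'   found.
#' @export
segmentNuclei2D <- function(window, cfg = nucleiConfig()) {
  a <- .pix(window)
  sm <- gaussianFilter(a, cfg$gaussRange)
  mask <- localMeanThreshold(sm, cfg$localRange)
  mask <- fillHoles(mask)
  seeds <- logSeeds(sm, cfg$logScales[1], cfg$logScales[2], cfg$nScales,
                    relThreshold = cfg$relThreshold)
  if (nrow(seedCoords(seeds)) == 0L) {
    warning("no seeds found: returning an empty segmentation")
    return(LabelMap(array(0L, dim(a))))
  }
  relief <- max(sm) - sm
  ws <- seededWatershed(relief, seeds, mask = NULL,
                        connectivity = cfg$connectivity)
  out <- .maskedSeedObjects(ws, mask, seeds, cfg$connectivity)
  out <- .dropSubresolution(out, cfg$minArea)
  removeBorderObjects(out)
}

## discard objects below the resolution floor (sub-resolution debris)
.dropSubresolution <- function(labels, minSize) {
  if (is.null(minSize) || minSize <= 1 || nObjects(labels) == 0L)
    return(labels)
  small <- labels@table$label[labels@table$area_px < minSize]
  if (!length(small)) return(labels)
  g <- labels@data
  g[g %in% small] <- 0L
  LabelMap(.compactLabels(g))
}

## Multiply the watershed with the threshold mask and keep, per basin,
## the connected piece containing the basin's own seed. A strict
## above-local-mean threshold marks about half of any flat noisy
## background, so each basin also contains speckle debris; the nucleus,
## however, is separated from it by the depressed-mean moat around every
## bright spot, and is exactly the piece its seed sits in. Basins whose
## seed falls outside the mask are spurious and dropped.
.maskedSeedObjects <- function(ws, mask, seeds, connectivity) {
  g <- labelData(ws)
  g[!mask] <- 0L
  if (max(g) == 0L) return(LabelMap(g))
  comp <- labelData(labelComponents(g > 0L, connectivity))
  co <- seedCoords(seeds)
  k <- max(g)
  seedComp <- integer(k)
  for (i in seq_len(min(nrow(co), k))) {
    cc <- comp[matrix(co[i, ], 1)]
    if (g[matrix(co[i, ], 1)] == i) seedComp[i] <- cc
  }
  keep <- g > 0L & seedComp[pmax(g, 1L)] > 0L &
    comp == seedComp[pmax(g, 1L)]
  g[!keep] <- 0L
  LabelMap(.compactLabels(g))
}

#' Summary statistics of a nuclei segmentation
#'
#' Count, per-nucleus projected area, mean area, and density (count per
#' analysis window and, when calibrated, per square micrometre).
#'
#' @param labels a [LabelMap-class] from [segmentNuclei2D()].
#' @param windowAreaPx analysis window area in pixels (default: the full
#'   label grid).
#' @param pixelSize micrometres per pixel (optional).
#' @return List of class `"NucleiStats"`: count, areas_px2, mean_area_px2,
#'   mean_area_um2, density_per_window, density_per_um2, window_area_px.
#' @export
nucleiStats <- function(labels, windowAreaPx = NULL, pixelSize = NA_real_) {
  stopifnot(is(labels, "LabelMap"))
  if (is.null(windowAreaPx)) windowAreaPx <- prod(dim(labels@data))
  areas <- labels@table$area_px
  count <- length(areas)
  structure(list(
    count = count,
    areas_px2 = areas,
    mean_area_px2 = if (count) mean(areas) else NA_real_,
    mean_area_um2 = if (count && !is.na(pixelSize))
      mean(areas) * pixelSize^2 else NA_real_,
    density_per_window = count,               # nuclei per analysis window
    density_per_px2 = count / windowAreaPx,
    density_per_um2 = if (!is.na(pixelSize))
      count / (windowAreaPx * pixelSize^2) else NA_real_,
    window_area_px = windowAreaPx), class = "NucleiStats")
}

#' Area and density ratios across a division event
#'
#' Ratios (after / before) of the mean projected nucleus area and of the
#' nucleus density between two [nucleiStats()] results, quantifying a
#' synchronous nuclear division wave. Across the 10th/11th divisions the
#' mean projected area drops to roughly one third while the density
#' increases roughly four-fold.
#'
#' @param before,after `"NucleiStats"` for the two time points.
#' @return List with `areaRatio` and `densityRatio`.
#' @export
divisionRatios <- function(before, after) {
  if (before$count == 0L || after$count == 0L)
    stop("empty input: both time points must contain nuclei")
  list(areaRatio = after$mean_area_px2 / before$mean_area_px2,
       densityRatio = after$density_per_px2 / before$density_per_px2)
}

#' Configuration of the 3D pole-cell counting pipeline
#'
#' Parameter block of [countPoleCells3D()]. The LoG "3 pixel range" is
#' read as a sigma of 3 by default (`logIsSigma = TRUE`); the
#' local-threshold window and seed scales default to the 2D nuclei
#' settings because the reference description does not state 3D-specific
#' values. Per-dataset alignment angles of the reference recordings:
#' DS0001 -40, DS0002 -7, DS0003 +41, DS0004 +13 degrees.
#'
#' @param logRange LoG filter range (pixels).
#' @param logIsSigma interpret `logRange` as sigma (`TRUE`) or as a
#'   kernel edge length whose sigma is `logRange / 3` (`FALSE`).
#' @param gaussRange sigma of the Gaussian-filtered image whose
#'   inversion serves as the watershed relief (default 2, mirroring the
#'   2D nuclei pipeline).
#' @param localRange local-mean threshold window (voxels).
#' @param logScales seed-detection scale range `c(min, max)`.
#' @param nScales number of seed scales.
#' @param relThreshold relative seed-response floor.
#' @param connectivity 3D connectivity (default 26).
#' @param crop optional crop list `list(rows =, cols =, slices =)`.
#' @param minVolume resolution floor in voxels: final objects smaller
#'   than a 3 x 3 x 3 neighbourhood cannot be resolved nuclei and are
#'   discarded.
#' @return List of class `"polecellConfig"`.
#' @export
polecellConfig <- function(logRange = 3, logIsSigma = TRUE, gaussRange = 2,
                           localRange = 15, logScales = c(1, 10),
                           nScales = 10, relThreshold = 0.2,
                           connectivity = 26, crop = NULL,
                           minVolume = 27) {
  structure(list(logRange = logRange, logIsSigma = logIsSigma,
                 gaussRange = gaussRange,
                 localRange = localRange, logScales = logScales,
                 nScales = nScales, relThreshold = relThreshold,
                 connectivity = connectivity, crop = crop,
                 minVolume = minVolume),
            class = "polecellConfig")
}

#' Count pole-cell nuclei in a 3D stack
#'
#' The 3D counting pipeline: optional crop, isotropic resampling,
#' rigid rotation about *y* to align the embryonic axes, LoG filtering,
#' local-mean thresholding with hole filling, multi-scale LoG seed
#' detection, and a seeded immersion watershed on the inverted smoothed
#' stack; the count is the number of objects of the watershed restricted
#' to the threshold mask.
#'
#' @param stack an [ImageStack-class] (or bare 3D array, assumed
#'   isotropic).
#' @param angle rotation angle about *y* in degrees applied before
#'   counting (the negative of the tilt of the recording).
#' @param cfg a [polecellConfig()].
#' @return List of class `"PoleCellCount"`: datasetId, timepointId,
#'   angle, count, labels (the final [LabelMap-class]).
#' @export
countPoleCells3D <- function(stack, angle = 0, cfg = polecellConfig()) {
  if (!is(stack, "ImageStack")) stack <- ImageStack(stack)
  if (!is.null(cfg$crop)) {
    a <- stack@data
    cr <- cfg$crop
    a <- a[cr$rows %||% seq_len(dim(a)[1]),
           cr$cols %||% seq_len(dim(a)[2]),
           cr$slices %||% seq_len(dim(a)[3]), drop = FALSE]
    stack@data <- a
  }
  if (!any(is.na(stack@voxelSize)) &&
      diff(range(stack@voxelSize)) > 1e-9 * min(stack@voxelSize))
    stack <- resampleIsotropic(stack)
  if (angle %% 360 != 0) stack <- rotateAboutY(stack, angle)
  a <- stack@data
  sigma <- if (cfg$logIsSigma) cfg$logRange else cfg$logRange / 3
  sm <- gaussianFilter(a, cfg$gaussRange)
  det <- logFilter(a, sigma)
  mask <- localMeanThreshold(det, cfg$localRange) & det > 0
  mask <- fillHoles(mask)
  seeds <- logSeeds(a, cfg$logScales[1], cfg$logScales[2], cfg$nScales,
                    relThreshold = cfg$relThreshold)
  count <- 0L
  labels <- LabelMap(array(0L, dim(a)))
  if (nrow(seedCoords(seeds)) == 0L || !any(mask)) {
    warning("empty segmentation: pole-cell count is 0")
  } else {
    relief <- max(sm) - sm
    ws <- seededWatershed(relief, seeds, mask = NULL,
                          connectivity = cfg$connectivity)
    labels <- .maskedSeedObjects(ws, mask, seeds, cfg$connectivity)
    labels <- .dropSubresolution(labels, cfg$minVolume)
    count <- nObjects(labels)
    if (count == 0L) warning("empty segmentation: pole-cell count is 0")
  }
  structure(list(datasetId = stack@datasetId,
                 timepointId = stack@timepointId,
                 angle = angle, count = count, labels = labels),
            class = "PoleCellCount")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise pole-cell counts across datasets
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of a
#' set of per-dataset pole-cell counts.
#'
#' @param counts numeric vector of counts, or a list of
#'   `"PoleCellCount"` results.
#' @return List with `mean` and `sd`.
#' @export
summarizeCounts <- function(counts) {
  if (is.list(counts))
    counts <- vapply(counts, function(x)
      if (inherits(x, "PoleCellCount")) x$count else as.numeric(x),
      numeric(1))
  if (length(counts) < 2L) stop("at least two counts are required")
  list(mean = mean(counts), sd = sd(counts))
}
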