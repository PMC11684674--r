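#' Calibrated 2D image frame
#'
#' A single fluorescence image (typically a z-maximum projection) on a
#' row/column grid. Rows run along the rotation axis *y* (the
#' anterior-posterior axis of an aligned embryo), columns along the
#' illumination axis *x*. Intensities must be finite and non-negative.
#'
#' @slot data numeric matrix of intensities.
#' @slot pixelSize physical pixel edge length in micrometres per pixel
#'   (`NA` when uncalibrated).
#' @slot time acquisition time in hours (`NA` when unknown).
#' @exportClass ImageFrame
setClass("ImageFrame",
  representation(data = "matrix", pixelSize = "numeric", time = "numeric"))

setValidity("ImageFrame", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("'data' must be a numeric matrix")
  if (any(!is.finite(d))) return("intensities must be finite")
  if (any(d < 0)) return("intensities must be non-negative")
  if (length(object@pixelSize) != 1L) return("'pixelSize' must be length 1")
  if (!is.na(object@pixelSize) && object@pixelSize <= 0)
    return("'pixelSize' must be positive")
  if (length(object@time) != 1L) return("'time' must be length 1")
  TRUE
})

#' Calibrated 3D image stack
#'
#' A z-stack stored as a 3D array indexed `[row (y), col (x), slice (z)]`
#' with a physical voxel size for each axis.
#'
#' @slot data numeric 3D array of intensities.
#' @slot voxelSize named numeric of length 3, micrometres per voxel along
#'   `c(z =, y =, x =)`.
#' @slot datasetId,timepointId character identifiers (e.g. `"DS0007"`,
#'   `"TP0009"`); may be `NA`.
#' @exportClass ImageStack
setClass("ImageStack",
  representation(data = "array", voxelSize = "numeric",
                 datasetId = "character", timepointId = "character"))

setValidity("ImageStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("'data' must be a 3D array")
  if (any(!is.finite(d))) return("intensities must be finite")
  if (any(d < 0)) return("intensities must be non-negative")
  if (length(object@voxelSize) != 3L) return("'voxelSize' must be length 3")
  if (any(!is.na(object@voxelSize) & object@voxelSize <= 0))
    return("voxel sizes must be positive")
  TRUE
})

#' Labelled segmentation map
#'
#' An integer grid (0 = background, objects labelled `1..K` consecutively)
#' together with a per-object geometry table that can always be recomputed
#' from the grid: label, pixel/voxel count, centroid, bounding box, and a
#' flag marking objects touching the image border.
#'
#' @slot data integer matrix or 3D array of labels.
#' @slot table data.frame with one row per object.
#' @exportClass LabelMap
setClass("LabelMap",
  representation(data = "array", table = "data.frame"))

setValidity("LabelMap", function(object) {
  g <- object@data
  if (any(g < 0)) return("labels must be non-negative")
  k <- max(g, 0L)
  u <- sort(unique(g[g > 0L]))
  if (length(u) && !identical(as.integer(u), seq_len(k)))
    return("labels must be consecutive 1..K")
  if (nrow(object@table) != k)
    return("object table must have one row per label")
  if (k > 0 && sum(object@table$area_px) != sum(g > 0L))
    return("object table inconsistent with label grid")
  TRUE
})

#' Seed points for marker-based segmentation
#'
#' Seed coordinates (1-based, one row per seed: row, col and, for stacks,
#' slice) with the Laplacian-of-Gaussian detection scale of each seed.
#'
#' @slot coords integer matrix of seed coordinates.
#' @slot scales numeric detection scale (sigma, pixels) per seed.
#' @slot response numeric detection response per seed.
#' @exportClass SeedSet
setClass("SeedSet",
  representation(coords = "matrix", scales = "numeric",
                 response = "numeric"))

setValidity("SeedSet", function(object) {
  co <- object@coords
  n <- nrow(co)
  if (n && any(co < 1)) return("seed coordinates must be >= 1")
  if (n && anyDuplicated(as.data.frame(co)))
    return("duplicate seed coordinates")
  if (length(object@scales) != n)
    return("one scale per seed required")
  if (n && any(object@scales <= 0)) return("scales must be positive")
  TRUE
})

## ---- constructors -------------------------------------------------------

#' Create an ImageFrame
#'
#' @param data numeric matrix of intensities.
#' @param pixelSize micrometres per pixel, or `NA`.
#' @param time acquisition time in hours, or `NA`.
#' @return An [ImageFrame-class] object.
#' @examples
#' f <- ImageFrame(matrix(0, 8, 8), pixelSize = 0.65)
#' dim(imageData(f))
#' @export
ImageFrame <- function(data, pixelSize = NA_real_, time = NA_real_) {
  storage.mode(data) <- "double"
  new("ImageFrame", data = data, pixelSize = as.numeric(pixelSize),
      time = as.numeric(time))
}

#' Create an ImageStack
#'
#' @param data numeric 3D array `[row, col, slice]`.
#' @param voxelSize micrometres per voxel along `c(z, y, x)`.
#' @param datasetId,timepointId optional identifiers.
#' @return An [ImageStack-class] object.
#' @export
ImageStack <- function(data, voxelSize = c(z = NA_real_, y = NA_real_,
                                           x = NA_real_),
                       datasetId = NA_character_,
                       timepointId = NA_character_) {
  storage.mode(data) <- "double"
  voxelSize <- as.numeric(voxelSize)
  names(voxelSize) <- c("z", "y", "x")
  new("ImageStack", data = data, voxelSize = voxelSize,
      datasetId = as.character(datasetId),
      timepointId = as.character(timepointId))
}

#' Create a LabelMap from a label grid
#'
#' The per-object table (area, centroid, bounding box, border flag) is
#' computed from the grid, so it is consistent by construction.
#'
#' @param grid integer matrix or 3D array; 0 is background.
#' @return A [LabelMap-class] object.
#' @export
LabelMap <- function(grid) {
  storage.mode(grid) <- "integer"
  new("LabelMap", data = grid, table = .objectTable(grid))
}

#' Create a SeedSet
#'
#' @param coords integer matrix of 1-based seed coordinates (row, col
#'   and optionally slice).
#' @param scales detection scale (pixels) per seed.
#' @param response optional detection response per seed.
#' @return A [SeedSet-class] object.
#' @export
SeedSet <- function(coords, scales, response = rep(NA_real_, nrow(coords))) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  storage.mode(coords) <- "integer"
  new("SeedSet", coords = coords, scales = as.numeric(scales),
      response = as.numeric(response))
}

## ---- internal geometry table -------------------------------------------

.objectTable <- function(grid) {
  dims <- dim(grid)
  k <- max(grid, 0L)
  if (k == 0L) {
    tab <- data.frame(label = integer(), area_px = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      rmin = integer(), rmax = integer(),
                      cmin = integer(), cmax = integer(),
                      border = logical())
    if (length(dims) == 3L) {
      tab$centroid_slice <- numeric()
      tab$zmin <- integer(); tab$zmax <- integer()
    }
    return(tab)
  }
  idx <- which(grid > 0L)
  lab <- grid[idx]
  ai <- arrayInd(idx, dims)
  area <- tabulate(lab, nbins = k)
  crow <- rowsum(as.numeric(ai[, 1]), lab)[, 1] / area
  ccol <- rowsum(as.numeric(ai[, 2]), lab)[, 1] / area
  rmin <- .byLabel(ai[, 1], lab, k, min)
  rmax <- .byLabel(ai[, 1], lab, k, max)
  cmin <- .byLabel(ai[, 2], lab, k, min)
  cmax <- .byLabel(ai[, 2], lab, k, max)
  border <- rmin == 1L | rmax == dims[1] | cmin == 1L | cmax == dims[2]
  tab <- data.frame(label = seq_len(k), area_px = area,
                    centroid_row = crow, centroid_col = ccol,
                    rmin = rmin, rmax = rmax, cmin = cmin, cmax = cmax,
                    border = border)
  if (length(dims) == 3L) {
    tab$centroid_slice <- rowsum(as.numeric(ai[, 3]), lab)[, 1] / area
    tab$zmin <- .byLabel(ai[, 3], lab, k, min)
    tab$zmax <- .byLabel(ai[, 3], lab, k, max)
    tab$border <- tab$border | tab$zmin == 1L | tab$zmax == dims[3]
  }
  rownames(tab) <- NULL
  tab
}

.byLabel <- function(v, lab, k, fun) {
  out <- vapply(split(v, factor(lab, levels = seq_len(k))), fun, numeric(1))
  as.integer(unname(out))
}

## ---- accessors ----------------------------------------------------------

#' @describeIn ImageFrame Extract the pixel matrix.
#' @param x an object.
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))
setMethod("imageData", "ImageFrame", function(x) x@data)
setMethod("imageData", "ImageStack", function(x) x@data)

#' @describeIn ImageFrame Physical pixel size (micrometres/pixel).
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
setMethod("pixelSize", "ImageFrame", function(x) x@pixelSize)

#' @describeIn ImageStack Physical voxel size (micrometres, `c(z, y, x)`).
#' @param x an object.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
setMethod("voxelSize", "ImageStack", function(x) x@voxelSize)

#' @describeIn ImageFrame Acquisition time in hours.
#' @export
setGeneric("frameTime", function(x) standardGeneric("frameTime"))
setMethod("frameTime", "ImageFrame", function(x) x@time)

#' @describeIn LabelMap Integer label grid.
#' @param x an object.
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))
setMethod("labelData", "LabelMap", function(x) x@data)

#' @describeIn LabelMap Per-object geometry table.
#' @export
setGeneric("objectTable", function(x) standardGeneric("objectTable"))
setMethod("objectTable", "LabelMap", function(x) x@table)

#' @describeIn LabelMap Number of labelled objects.
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))
setMethod("nObjects", "LabelMap", function(x) nrow(x@table))

#' @describeIn SeedSet Seed coordinate matrix (1-based).
#' @param x an object.
#' @export
setGeneric("seedCoords", function(x) standardGeneric("seedCoords"))
setMethod("seedCoords", "SeedSet", function(x) x@coords)

#' @describeIn SeedSet Detection scales (pixels).
#' @export
setGeneric("seedScales", function(x) standardGeneric("seedScales"))
setMethod("seedScales", "SeedSet", function(x) x@scales)

## ---- show ---------------------------------------------------------------

setMethod("show", "ImageFrame", function(object) {
  d <- object@data
  cat(sprintf("ImageFrame %d x %d px, range [%.4g, %.4g]\n",
              nrow(d), ncol(d), min(d), max(d)))
  if (!is.na(object@pixelSize))
    cat(sprintf("  pixel size: %g um/px\n", object@pixelSize))
  if (!is.na(object@time))
    cat(sprintf("  time: %g h\n", object@time))
  invisible(NULL)
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack %d x %d x %d voxels (row, col, slice)\n",
              d[1], d[2], d[3]))
  if (!any(is.na(object@voxelSize)))
    cat(sprintf("  voxel size (z,y,x): %s um\n",
                paste(signif(object@voxelSize, 4), collapse = " x ")))
  if (!is.na(object@datasetId))
    cat(sprintf("  dataset %s", object@datasetId))
  if (!is.na(object@timepointId)) cat(sprintf(" %s", object@timepointId))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelMap %s: %d object(s)\n",
              paste(d, collapse = " x "), nrow(object@table)))
  invisible(NULL)
})

setMethod("show", "SeedSet", function(object) {
  cat(sprintf("SeedSet with %d seed(s)\n", nrow(object@coords)))
  invisible(NULL)
})
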