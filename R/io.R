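## TIFF and CSV readers/writers binding the pipelines together.

#' Read a TIFF image as a frame or stack
#'
#' A single-page TIFF becomes an [ImageFrame-class]; a multi-page TIFF
#' becomes an [ImageStack-class] with one slice per page. Integer sample
#' values are returned as stored (no 0-1 rescaling).
#'
#' @param path path to a TIFF file.
#' @param pixelSize,voxelSize optional calibration overrides.
#' @param time optional acquisition time (hours) for frames.
#' @return An [ImageFrame-class] or [ImageStack-class].
#' @export
readImage <- function(path, pixelSize = NA_real_,
                      voxelSize = c(z = NA_real_, y = NA_real_,
                                    x = NA_real_),
                      time = NA_real_) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("unreadable TIFF '", path, "': ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    storage.mode(p) <- "double"
    p
  })
  if (length(pages) == 1L)
    return(ImageFrame(pages[[1]], pixelSize = pixelSize, time = time))
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  ImageStack(arr, voxelSize = voxelSize)
}

#' Write a frame or stack as TIFF
#'
#' Intensities are rounded, clamped to the 16-bit range and stored as
#' 16-bit samples, so integer-valued images round-trip exactly through
#' [readImage()].
#'
#' @param x [ImageFrame-class], [ImageStack-class], matrix or 3D array.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeImage <- function(x, path) {
  a <- .pix(x)
  a <- round(a)
  if (any(a > 65535)) {
    warning("intensities above 65535 clamped for 16-bit TIFF output")
    a <- pmin(a, 65535)
  }
  a <- pmax(a, 0) / 65535
  what <- if (length(dim(a)) == 3L)
    lapply(seq_len(dim(a)[3]), function(z) a[, , z]) else a
  tiff::writeTIFF(what, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read germband-tip annotations
#'
#' CSV with columns `time_h`, `row`, `col` (manually located posterior
#' tip of the germband in z-maximum projections).
#'
#' @param path CSV path.
#' @return data.frame suitable for [tipKinematics()].
#' @export
readTipAnnotations <- function(path) {
  a <- read.csv(path)
  stopifnot(all(c("time_h", "row", "col") %in% names(a)))
  a
}

#' Read / write staging tables
#'
#' Staging tables are CSV files with columns `dataset`, `stage`,
#' `start_h`, `end_h`, one row per dataset and stage.
#'
#' @param path CSV path.
#' @return data.frame of stage boundaries.
#' @export
readStagingTable <- function(path) {
  t <- read.csv(path)
  stopifnot(all(c("dataset", "stage", "start_h", "end_h") %in% names(t)))
  t
}

#' @rdname readStagingTable
#' @param table staging table to write.
#' @export
writeStagingTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a LabelMap as 16-bit TIFF plus a CSV object table
#'
#' The label grid is stored as a 16-bit TIFF (one page per slice for 3D
#' maps) and the per-object geometry table as CSV; with a pixel size the
#' table also carries areas in square micrometres.
#'
#' @param labels a [LabelMap-class].
#' @param pathTiff,pathCsv output paths.
#' @param pixelSize optional micrometres per pixel for `area_um2`.
#' @return `pathTiff`, invisibly.
#' @export
writeLabelMap <- function(labels, pathTiff, pathCsv, pixelSize = NA_real_) {
  stopifnot(is(labels, "LabelMap"))
  writeImage(labels@data, pathTiff)
  tab <- labels@table
  if (!is.na(pixelSize)) tab$area_um2 <- tab$area_px * pixelSize^2
  write.csv(tab, pathCsv, row.names = FALSE)
  invisible(pathTiff)
}

#' @rdname writeLabelMap
#' @param path TIFF path of a stored label grid.
#' @export
readLabelMap <- function(path) {
  img <- readImage(path)
  g <- imageData(img)
  storage.mode(g) <- "integer"
  LabelMap(g)
}
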