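## Configuration handling and the file-level pipeline driver with its
## reproducibility manifest.

#' Default pipeline configuration
#'
#' A nested list holding every tunable constant of the analysis
#' pipelines at its reference value: 3x3 mean filtering and a 150x150
#' local-threshold window for the length pipeline; Gaussian range 2,
#' local-threshold ranges 15/10 and LoG scale ranges (5, 15)/(1, 10) for
#' the early/late blastoderm time points; LoG range 3 and the per-dataset
#' alignment angles (DS0001 -40, DS0002 -7, DS0003 +41, DS0004 +13
#' degrees) for the pole-cell pipeline.
#'
#' @return Nested list of class `"embryostagerConfig"`.
#' @export
defaultConfig <- function() {
  structure(list(
    length = list(mean_range = 3, threshold_window = 150, crop = NULL,
                  connectivity = 8),
    nuclei = list(gauss_range = 2, local_range_early = 15,
                  local_range_late = 10, log_scales_early = c(5, 15),
                  log_scales_late = c(1, 10), n_scales = 10,
                  rel_threshold = 0.1, window_offset = 150,
                  window_size = 150, posterior_end = "max_y"),
    polecells = list(log_range = 3, log_is_sigma = TRUE, local_range = 15,
                     log_scales = c(1, 10), n_scales = 10,
                     rel_threshold = 0.1, connectivity = 26,
                     angles = list(DS0001 = -40, DS0002 = -7,
                                   DS0003 = 41, DS0004 = 13)),
    calibration = list(pixel_size = NA, voxel_size = c(NA, NA, NA)),
    synth = list(seed = 1)
  ), class = "embryostagerConfig")
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys and out-of-range parameters before any
#' computation starts.
#'
#' @param config nested list as returned by [defaultConfig()] (possibly
#'   modified) or read from YAML via [readConfig()].
#' @return The validated config, invisibly.
#' @export
validateConfig <- function(config) {
  ref <- defaultConfig()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown))
    stop("unknown configuration block(s): ", paste(unknown, collapse = ", "))
  for (blk in names(config)) {
    bad <- setdiff(names(config[[blk]]), names(ref[[blk]]))
    if (length(bad))
      stop("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", "))
  }
  len <- config$length
  if (!is.null(len)) {
    .checkOddRange(len$mean_range %||% 3, "length$mean_range")
    tw <- len$threshold_window %||% 150
    if (tw <= 0 || tw != round(tw))
      stop("configuration error: length$threshold_window must be a ",
           "positive integer")
  }
  nuc <- config$nuclei
  if (!is.null(nuc)) {
    for (k in c("gauss_range", "local_range_early", "local_range_late"))
      if (!is.null(nuc[[k]]) && nuc[[k]] <= 0)
        stop("configuration error: nuclei$", k, " must be positive")
    for (k in c("log_scales_early", "log_scales_late"))
      if (!is.null(nuc[[k]]) &&
          !(nuc[[k]][1] > 0 && nuc[[k]][1] <= nuc[[k]][2]))
        stop("configuration error: nuclei$", k,
             " must satisfy 0 < min <= max")
  }
  pc <- config$polecells
  if (!is.null(pc) && !is.null(pc$log_range) && pc$log_range <= 0)
    stop("configuration error: polecells$log_range must be positive")
  invisible(config)
}

#' Read / write a configuration as YAML
#'
#' @param path YAML path.
#' @return [readConfig()] returns a validated config list.
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "embryostagerConfig"
  validateConfig(cfg)
  cfg
}

#' @rdname readConfig
#' @param config configuration list to write.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.configHash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

.writeManifest <- function(outDir, pipeline, config, inputs, warnings) {
  manifest <- list(
    tool = "embryostager",
    version = as.character(packageVersion("embryostager")),
    pipeline = pipeline,
    config_hash = .configHash(config),
    inputs = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    warnings = as.list(warnings),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  manifest
}

#' Run a named analysis pipeline on files
#'
#' File-level driver tying the package's stages together. Available
#' pipelines:
#' \describe{
#'   \item{synth}{generate a synthetic embryo movie into `outDir`
#'     (frame TIFFs, `times.csv`, `truth.csv`, `spec.yaml`).}
#'   \item{length}{measure all `frame_*.tif` files in `inputDir` (times
#'     from `times.csv`) and write `lengths.csv`.}
#'   \item{tip}{convert `tip_annotations.csv` in `inputDir` into
#'     `kinematics.csv`.}
#'   \item{nuclei}{segment every `window_*.tif` in `inputDir` and write
#'     `nuclei.csv` (one row per window).}
#'   \item{polecells}{count every `stack_*.tif` in `inputDir` (angles
#'     from the config's `polecells$angles` by dataset id in the file
#'     name) and write `polecells.csv`.}
#'   \item{staging}{aggregate `staging.csv` in `inputDir` into
#'     `stage_durations.csv` and `boundaries.csv`.}
#' }
#' Every run validates the configuration first, writes its outputs plus
#' a `manifest.yaml` (tool version, config hash, input checksums,
#' warnings) into `outDir`, and is deterministic for a fixed config and
#' inputs.
#'
#' @param name pipeline name (see above).
#' @param config configuration list (default [defaultConfig()]).
#' @param inputDir directory of inputs (not needed for `synth`).
#' @param outDir output directory (created if missing).
#' @param seed seed for `synth`.
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(name = c("synth", "length", "tip", "nuclei",
                                 "polecells", "staging"),
                        config = defaultConfig(), inputDir = NULL,
                        outDir, seed = NULL) {
  name <- match.arg(name)
  validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character()
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  inputs <- character()
  if (name == "synth") {
    spec <- syntheticEmbryoSpec(seed = seed %||% config$synth$seed)
    mov <- generateEmbryoMovie(spec)
    for (i in seq_along(mov$frames))
      writeImage(mov$frames[[i]],
                 file.path(outDir, sprintf("frame_%04d.tif", i)))
    write.csv(data.frame(frame = seq_along(mov$frames),
                         time_h = mov$truth$time_h),
              file.path(outDir, "times.csv"), row.names = FALSE)
    write.csv(mov$truth, file.path(outDir, "truth.csv"),
              row.names = FALSE)
    yaml::write_yaml(list(frame_shape = spec$frameShape,
                          semi_axes = unname(spec$semiAxes),
                          n_frames = spec$nFrames,
                          frame_interval = spec$frameInterval,
                          pixel_size = spec$pixelSize, seed = spec$seed),
                     file.path(outDir, "spec.yaml"))
  } else if (name == "length") {
    files <- sort(list.files(inputDir, "^frame_.*\\.tif$",
                             full.names = TRUE))
    if (!length(files)) stop("no frame_*.tif files in ", inputDir)
    times <- read.csv(file.path(inputDir, "times.csv"))
    inputs <- c(files, file.path(inputDir, "times.csv"))
    frames <- lapply(seq_along(files), function(i)
      readImage(files[i], time = times$time_h[i]))
    cfgL <- lengthConfig(crop = config$length$crop,
                         meanRange = config$length$mean_range,
                         thresholdWindow = config$length$threshold_window,
                         connectivity = config$length$connectivity)
    series <- wh(lengthTimeseries(frames, cfg = cfgL))
    write.csv(series, file.path(outDir, "lengths.csv"), row.names = FALSE)
  } else if (name == "tip") {
    f <- file.path(inputDir, "tip_annotations.csv")
    inputs <- f
    kin <- tipKinematics(readTipAnnotations(f),
                         pixelSize = config$calibration$pixel_size %||% 1)
    write.csv(kin, file.path(outDir, "kinematics.csv"), row.names = FALSE)
  } else if (name == "nuclei") {
    files <- sort(list.files(inputDir, "^window_.*\\.tif$",
                             full.names = TRUE))
    if (!length(files)) stop("no window_*.tif files in ", inputDir)
    inputs <- files
    nc <- config$nuclei
    rows <- lapply(files, function(f) {
      w <- readImage(f)
      lab <- wh(segmentNuclei2D(w, nucleiConfig(
        gaussRange = nc$gauss_range, localRange = nc$local_range_early,
        logScales = nc$log_scales_early, nScales = nc$n_scales,
        relThreshold = nc$rel_threshold)))
      st <- nucleiStats(lab)
      data.frame(file = basename(f), count = st$count,
                 mean_area_px2 = st$mean_area_px2,
                 density_per_px2 = st$density_per_px2)
    })
    write.csv(do.call(rbind, rows), file.path(outDir, "nuclei.csv"),
              row.names = FALSE)
  } else if (name == "polecells") {
    files <- sort(list.files(inputDir, "^stack_.*\\.tif$",
                             full.names = TRUE))
    if (!length(files)) stop("no stack_*.tif files in ", inputDir)
    inputs <- files
    pc <- config$polecells
    rows <- lapply(files, function(f) {
      ds <- sub("^stack_([^.]*)\\.tif$", "\\1", basename(f))
      angle <- pc$angles[[ds]] %||% 0
      st <- readImage(f)
      res <- wh(countPoleCells3D(st, angle = angle, polecellConfig(
        logRange = pc$log_range, logIsSigma = pc$log_is_sigma,
        localRange = pc$local_range, logScales = pc$log_scales,
        nScales = pc$n_scales, relThreshold = pc$rel_threshold,
        connectivity = pc$connectivity)))
      data.frame(file = basename(f), dataset = ds, angle = angle,
                 count = res$count)
    })
    write.csv(do.call(rbind, rows), file.path(outDir, "polecells.csv"),
              row.names = FALSE)
  } else if (name == "staging") {
    f <- file.path(inputDir, "staging.csv")
    inputs <- f
    tables <- readStagingTable(f)
    agg <- aggregateStaging(tables)
    write.csv(agg$stages, file.path(outDir, "stage_durations.csv"),
              row.names = FALSE)
    write.csv(agg$boundaries, file.path(outDir, "boundaries.csv"),
              row.names = FALSE)
  }
  invisible(.writeManifest(outDir, name, config, inputs, warnings))
}
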