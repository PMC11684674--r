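## Synthetic-data generators with exact ground truth. Every generator is a
## pure function of its specification and seed; intensities are quantised
## to integer grey levels, as camera data are.

.withSeed <- function(seed, expr) {
  if (length(seed) != 1L || !is.finite(seed))
    stop("configuration error: a single finite 'seed' is required")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.applyNoise <- function(img, poisson = TRUE, gaussianSd = 4) {
  if (poisson) img[] <- rpois(length(img), lambda = pmax(img, 0))
  if (gaussianSd > 0) img[] <- img + rnorm(length(img), sd = gaussianSd)
  img[] <- pmax(round(img), 0)
  img
}

.addSpots2d <- function(img, centers, sigma, amplitude) {
  if (!nrow(centers)) return(img)
  h <- ceiling(4 * sigma)
  d <- dim(img)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    rr <- max(1, floor(r0 - h)):min(d[1], ceiling(r0 + h))
    cc <- max(1, floor(c0 - h)):min(d[2], ceiling(c0 + h))
    img[rr, cc] <- img[rr, cc] + amplitude *
      exp(-(outer((rr - r0)^2, (cc - c0)^2, `+`)) / (2 * sigma^2))
  }
  img
}

.addBlobs3d <- function(arr, centers, sigmaVox, amplitude) {
  if (!nrow(centers)) return(arr)
  d <- dim(arr)
  h <- ceiling(4 * sigmaVox)
  for (i in seq_len(nrow(centers))) {
    ct <- centers[i, ]
    rr <- max(1, floor(ct[1] - h[1])):min(d[1], ceiling(ct[1] + h[1]))
    cc <- max(1, floor(ct[2] - h[2])):min(d[2], ceiling(ct[2] + h[2]))
    zz <- max(1, floor(ct[3] - h[3])):min(d[3], ceiling(ct[3] + h[3]))
    gr <- exp(-(rr - ct[1])^2 / (2 * sigmaVox[1]^2))
    gc <- exp(-(cc - ct[2])^2 / (2 * sigmaVox[2]^2))
    gz <- exp(-(zz - ct[3])^2 / (2 * sigmaVox[3]^2))
    arr[rr, cc, zz] <- arr[rr, cc, zz] +
      amplitude * (gr %o% gc %o% gz)
  }
  arr
}

## rejection-sample n points with pairwise separation >= minSep inside a
## sampler()'s support; error after bounded attempts
.placePoints <- function(n, sampler, minSep, maxAttempts = 500L * max(n, 1L),
                         what = "points") {
  pts <- matrix(numeric(), 0, length(sampler()))
  attempts <- 0L
  while (nrow(pts) < n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("placement infeasible for ", n, " ", what,
           " at separation ", signif(minSep, 3),
           "; reduce the count or the spot size")
    p <- sampler()
    if (nrow(pts) == 0L ||
        min(rowSums((pts - matrix(p, nrow(pts), length(p),
                                  byrow = TRUE))^2)) >= minSep^2)
      pts <- rbind(pts, p)
  }
  pts
}

#' The default relative-length trajectory of the synthetic embryo
#'
#' A smooth curve over normalised developmental time emulating the
#' characteristic anterior-posterior length dynamics of the medfly embryo:
#' near-constant length through blastoderm and gastrulation, a mild
#' maximum during germband elongation, withdrawal to a minimum of 90% of
#' the initial extent during dorsal closure (normalised time 0.75), and
#' partial reversal before hatching.
#'
#' @param u normalised developmental time in `[0, 1]`.
#' @return Relative length (1 = initial extent).
#' @examples
#' medflyLengthTrajectory(c(0, 0.75, 1))
#' @export
medflyLengthTrajectory <- function(u) {
  knots <- c(0, 0.15, 0.3, 0.45, 0.6, 0.7, 0.75, 0.85, 1)
  vals <- c(1, 1.0, 1.02, 1.02, 0.98, 0.94, 0.90, 0.96, 0.98)
  f <- splinefun(knots, vals, method = "monoH.FC")
  f(pmin(pmax(u, 0), 1))
}

#' Specification of a synthetic embryo movie
#'
#' Bundles and validates all parameters of [generateEmbryoMovie()]. The
#' synthetic embryo is an ellipse (semi-axis `a` along *y* = rows, `b`
#' along *x* = columns) whose extent along *y* is scaled over time by
#' `lengthTrajectory`, filled with a uniform body intensity and decorated
#' with Gaussian-spot nuclei on the rim; frames are corrupted by Poisson
#' shot noise followed by additive Gaussian read noise and quantised to
#' integer grey levels.
#'
#' @param frameShape frame size `c(rows, cols)` in pixels.
#' @param semiAxes ellipse semi-axes `c(a, b)` in pixels (`a` along y).
#' @param lengthTrajectory function of normalised time `u` in `[0, 1]`
#'   returning the relative length (must stay in `(0, 1.2]`).
#' @param nFrames number of frames.
#' @param frameInterval time between frames in hours.
#' @param nSurfaceNuclei number of rim nuclei.
#' @param nucleusSigma Gaussian spot sigma in pixels.
#' @param intensityEmbryo,intensityNucleus,backgroundLevel fluorescence
#'   levels in arbitrary units (grey values).
#' @param noisePoisson enable Poisson shot noise.
#' @param noiseGaussianSd additive Gaussian read noise sigma (0 = off).
#' @param pixelSize micrometres per pixel.
#' @param seed mandatory RNG seed.
#' @return A validated list of class `"SyntheticEmbryoSpec"`.
#' @export
syntheticEmbryoSpec <- function(frameShape = c(460, 220),
                                semiAxes = c(a = 200, b = 85),
                                lengthTrajectory = medflyLengthTrajectory,
                                nFrames = 25, frameInterval = 0.5,
                                nSurfaceNuclei = 80, nucleusSigma = 3,
                                intensityEmbryo = 40,
                                intensityNucleus = 160,
                                backgroundLevel = 10,
                                noisePoisson = TRUE, noiseGaussianSd = 4,
                                pixelSize = 1, seed) {
  spec <- list(frameShape = as.integer(frameShape),
               semiAxes = setNames(as.numeric(semiAxes), c("a", "b")),
               lengthTrajectory = lengthTrajectory,
               nFrames = as.integer(nFrames),
               frameInterval = frameInterval,
               nSurfaceNuclei = as.integer(nSurfaceNuclei),
               nucleusSigma = nucleusSigma,
               intensityEmbryo = intensityEmbryo,
               intensityNucleus = intensityNucleus,
               backgroundLevel = backgroundLevel,
               noisePoisson = isTRUE(noisePoisson),
               noiseGaussianSd = noiseGaussianSd,
               pixelSize = pixelSize, seed = seed)
  uu <- seq(0, 1, length.out = max(spec$nFrames, 2L))
  L <- spec$lengthTrajectory(uu)
  if (any(!is.finite(L)) || any(L <= 0) || any(L > 1.2))
    stop("configuration error: lengthTrajectory values must lie in (0, 1.2]")
  if (2 * spec$semiAxes["a"] * max(L) >= spec$frameShape[1])
    stop("configuration error: embryo does not fit inside the frame ",
         "(2*a*max(lengthTrajectory) must be < rows)")
  if (2 * spec$semiAxes["b"] >= spec$frameShape[2])
    stop("configuration error: embryo does not fit inside the frame ",
         "(2*b must be < cols)")
  if (spec$nucleusSigma <= 0)
    stop("configuration error: nucleusSigma must be > 0")
  if (spec$nSurfaceNuclei < 0 || spec$nFrames < 1)
    stop("configuration error: counts must be >= 0")
  if (missing(seed)) stop("configuration error: 'seed' is mandatory")
  class(spec) <- "SyntheticEmbryoSpec"
  spec
}

#' Generate a synthetic embryo movie with exact ground truth
#'
#' Renders the movie described by a [syntheticEmbryoSpec()]. The ground
#' truth records, per frame, the exact true length `2 * a *
#' lengthTrajectory(u)` in pixels and micrometres along with the nucleus
#' centres, providing the oracle for length-recovery tests. Deterministic
#' for a fixed seed.
#'
#' @param spec a `"SyntheticEmbryoSpec"`.
#' @return List with `frames` (list of [ImageFrame-class]), `truth`
#'   (data.frame: frame, time_h, norm_time, rel_length, length_px,
#'   length_um), `nucleusCenters` (list of per-frame center matrices) and
#'   `spec`.
#' @export
generateEmbryoMovie <- function(spec) {
  stopifnot(inherits(spec, "SyntheticEmbryoSpec"))
  .withSeed(spec$seed, {
    nr <- spec$frameShape[1]; nc <- spec$frameShape[2]
    a <- spec$semiAxes["a"]; b <- spec$semiAxes["b"]
    cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
    u <- if (spec$nFrames == 1L) 0 else
      (seq_len(spec$nFrames) - 1) / (spec$nFrames - 1)
    L <- spec$lengthTrajectory(u)
    theta <- sort(runif(spec$nSurfaceNuclei, 0, 2 * pi))
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    frames <- vector("list", spec$nFrames)
    centersList <- vector("list", spec$nFrames)
    for (i in seq_len(spec$nFrames)) {
      inside <- ((rows - cr) / (a * L[i]))^2 + ((cols - cc) / b)^2 <= 1
      img <- matrix(spec$backgroundLevel, nr, nc)
      img[inside] <- img[inside] + spec$intensityEmbryo
      centers <- cbind(row = cr + 0.92 * a * L[i] * cos(theta),
                       col = cc + 0.92 * b * sin(theta))
      img <- .addSpots2d(img, centers, spec$nucleusSigma,
                         spec$intensityNucleus)
      img <- round(img)
      if (spec$noisePoisson || spec$noiseGaussianSd > 0)
        img <- .applyNoise(img, spec$noisePoisson, spec$noiseGaussianSd)
      frames[[i]] <- ImageFrame(img, pixelSize = spec$pixelSize,
                                time = (i - 1) * spec$frameInterval)
      centersList[[i]] <- centers
    }
    truth <- data.frame(frame = seq_len(spec$nFrames),
                        time_h = (seq_len(spec$nFrames) - 1) *
                          spec$frameInterval,
                        norm_time = u, rel_length = L,
                        length_px = 2 * a * L,
                        length_um = 2 * a * L * spec$pixelSize)
    list(frames = frames, truth = truth, nucleusCenters = centersList,
         spec = spec)
  })
}

#' Generate a synthetic nuclei window with exact ground truth
#'
#' Renders `n` isotropic Gaussian-spot nuclei at rejection-sampled
#' positions (pairwise separation at least `4 * sigma`, kept clear of the
#' window border) on a uniform background, with the standard noise model.
#' The ground truth reports the centres and, per nucleus, the projected
#' area that the noise-free segmentation response defines (see
#' [spotReferenceArea()]).
#'
#' @param n number of nuclei (>= 0).
#' @param sigma spot sigma in pixels.
#' @param window window edge length in pixels (reference pipelines use
#'   150).
#' @param intensityNucleus,backgroundLevel grey levels.
#' @param noisePoisson,noiseGaussianSd noise model (see
#'   [syntheticEmbryoSpec()]).
#' @param seed mandatory RNG seed.
#' @param minSepFactor minimum centre separation in units of `sigma`.
#' @param localRange local-threshold window used for the reference area
#'   (15 for large early-blastoderm nuclei, 10 for the later time point).
#' @return List with `window` ([ImageFrame-class]), `truth` (list:
#'   `count`, `centers`, `trueArea_px2`) and the parameters.
#' @export
generateNucleiWindow <- function(n, sigma = 3, window = 150,
                                 intensityNucleus = 160,
                                 backgroundLevel = 10,
                                 noisePoisson = TRUE, noiseGaussianSd = 4,
                                 seed, minSepFactor = 4, localRange = 15) {
  if (n < 0) stop("configuration error: n must be >= 0")
  if (sigma <= 0) stop("configuration error: sigma must be > 0")
  .withSeed(seed, {
    margin <- max(4 * sigma, 8)
    if (n > 0 && window - 2 * margin <= 0)
      stop("placement infeasible: window too small for spots of sigma ",
           sigma, "; reduce n or sigma")
    sampler <- function() runif(2, min = margin, max = window - margin)
    centers <- .placePoints(n, sampler, minSep = minSepFactor * sigma,
                            what = "nuclei")
    img <- matrix(backgroundLevel, window, window)
    img <- .addSpots2d(img, centers, sigma, intensityNucleus)
    img <- round(img)
    if (noisePoisson || noiseGaussianSd > 0)
      img <- .applyNoise(img, noisePoisson, noiseGaussianSd)
    area <- if (n > 0)
      rep(spotReferenceArea(sigma, intensityNucleus, backgroundLevel,
                            localRange = localRange), n) else numeric()
    list(window = ImageFrame(img),
         truth = list(count = n, centers = centers, trueArea_px2 = area),
         sigma = sigma, localRange = localRange, seed = seed)
  })
}

## memoised reference areas
.areaCache <- new.env(parent = emptyenv())

#' Reference projected area of an ideal nucleus spot
#'
#' The projected area a Gaussian-spot nucleus occupies after the
#' deterministic noise-free segmentation response: the spot is rendered
#' alone, smoothed with the pipeline's Gaussian (`gaussRange`), and the
#' pixels strictly above the local window mean (`localRange`) are
#' counted. This operational definition is what the generators report as
#' ground-truth area; it scales approximately with `sigma^2 +
#' gaussRange^2`.
#'
#' @param sigma spot sigma in pixels.
#' @param amplitude,background grey levels.
#' @param gaussRange smoothing sigma of the nuclei pipeline (default 2).
#' @param localRange local-threshold window (default 15).
#' @return Area in pixels squared (a count of pixels).
#' @export
spotReferenceArea <- function(sigma, amplitude = 160, background = 10,
                              gaussRange = 2, localRange = 15) {
  key <- paste(signif(sigma, 8), amplitude, background, gaussRange,
               localRange, sep = "_")
  if (!is.null(.areaCache[[key]])) return(.areaCache[[key]])
  side <- 2L * as.integer(ceiling(4 * sigma + 2 * localRange)) + 21L
  ctr <- (side + 1) / 2
  img <- .addSpots2d(matrix(background, side, side),
                     matrix(c(ctr, ctr), 1), sigma, amplitude)
  sm <- gaussianFilter(img, gaussRange)
  mask <- localMeanThreshold(sm, localRange)
  ## count only the blob at the centre (ignore faint replication artefacts)
  lab <- labelComponents(mask)
  g <- labelData(lab)
  centerLab <- g[round(ctr), round(ctr)]
  area <- if (centerLab > 0) sum(g == centerLab) else 0
  .areaCache[[key]] <- area
  area
}

#' Generate a matched pre/post-division pair of nuclei windows
#'
#' Emulates a synchronous nuclear division wave in the posterior analysis
#' window: the post-division window holds `ratioCount` times as many
#' nuclei, and the post-division spot width is chosen by numerically
#' inverting [spotReferenceArea()] so that the reference projected area
#' is `areaRatio` times the pre-division area. With the defaults this
#' reconstructs the "area drops to one third, density rises four-fold"
#' configuration of the 10th/11th division waves.
#'
#' @param nBefore pre-division nucleus count.
#' @param sigmaBefore pre-division spot sigma (pixels).
#' @param ratioCount post/pre count ratio (default 4).
#' @param areaRatio target post/pre reference-area ratio (default 1/3).
#' @param seed mandatory RNG seed (two sub-seeds are derived).
#' @param ... further arguments passed to [generateNucleiWindow()].
#' @return List with `before`, `after` (outputs of
#'   [generateNucleiWindow()]) and `sigmaAfter`.
#' @export
generateDivisionPair <- function(nBefore = 12, sigmaBefore = 6,
                                 ratioCount = 4, areaRatio = 1 / 3,
                                 seed, ...) {
  targetArea <- areaRatio * spotReferenceArea(sigmaBefore, localRange = 15)
  sig <- seq(1.2, sigmaBefore, by = 0.2)
  areas <- vapply(sig, function(s)
    spotReferenceArea(s, localRange = 10), numeric(1))
  sigmaAfter <- approx(areas, sig, xout = targetArea, rule = 2)$y
  before <- generateNucleiWindow(nBefore, sigmaBefore, seed = seed + 1L,
                                 localRange = 15, ...)
  after <- generateNucleiWindow(nBefore * ratioCount, sigmaAfter,
                                seed = seed + 2L, localRange = 10, ...)
  list(before = before, after = after, sigmaAfter = sigmaAfter)
}

#' Generate a synthetic pole-cell stack with exact ground truth
#'
#' Places `n` Gaussian blobs (pairwise separation at least `minSep`)
#' inside a sphere of radius `clusterRadius` micrometres, tilts the whole
#' cluster about the *y* axis by `tiltAngle` degrees, and renders it into
#' an anisotropic voxel grid with the standard noise model, so that the
#' 3D counting pipeline's isotropic resampling and de-rotation steps are
#' exercised.
#'
#' @param n number of pole-cell nuclei (>= 0).
#' @param clusterRadius cluster radius in micrometres.
#' @param voxelSize micrometres per voxel `c(z, y, x)`.
#' @param tiltAngle tilt about y in degrees (de-rotate with the opposite
#'   angle when counting).
#' @param nucleusSigma blob sigma in micrometres.
#' @param extent physical edge length of the (cubic) stack in
#'   micrometres.
#' @param intensityNucleus,backgroundLevel grey levels.
#' @param noisePoisson,noiseGaussianSd noise model.
#' @param minSep minimum centre separation in micrometres.
#' @param seed mandatory RNG seed.
#' @return List with `stack` ([ImageStack-class]) and `truth` (list:
#'   `count`, `centersUm` tilted, `centersUntiltedUm`, and `roi`, the
#'   region of interest implied by the cluster geometry, suitable as the
#'   `crop` of [polecellConfig()]).
#' @export
generatePoleCellStack <- function(n = 27, clusterRadius = 22,
                                  voxelSize = c(z = 2, y = 1, x = 1),
                                  tiltAngle = 0, nucleusSigma = 2.5,
                                  extent = 76, intensityNucleus = 160,
                                  backgroundLevel = 10,
                                  noisePoisson = TRUE, noiseGaussianSd = 4,
                                  minSep = 8, seed) {
  if (n < 0) stop("configuration error: n must be >= 0")
  vs <- setNames(as.numeric(voxelSize), c("z", "y", "x"))
  half <- extent / 2
  if (clusterRadius + 4 * nucleusSigma >= half)
    stop("configuration error: cluster too large for stack extent ",
         extent, " um")
  .withSeed(seed, {
    sampler <- function() {
      repeat {
        p <- runif(3, -clusterRadius, clusterRadius)
        if (sum(p^2) <= clusterRadius^2) return(p)
      }
    }
    pts <- .placePoints(n, sampler, minSep = minSep, what = "pole cells")
    ## tilt about y: (z, x) plane rotation, y untouched; pts cols are
    ## (y, x, z) offsets in um about the stack centre
    if (n > 0) {
      th <- tiltAngle * pi / 180
      zt <- cos(th) * pts[, 3] - sin(th) * pts[, 2]
      xt <- sin(th) * pts[, 3] + cos(th) * pts[, 2]
      tilted <- cbind(pts[, 1], xt, zt)
    } else tilted <- pts
    if (n > 0 && any(abs(tilted) + 4 * nucleusSigma > half))
      stop("configuration error: tilted cluster exceeds the stack; ",
           "reduce clusterRadius or tiltAngle")
    dims <- c(ceiling(extent / vs["y"]), ceiling(extent / vs["x"]),
              ceiling(extent / vs["z"]))
    arr <- array(backgroundLevel, dims)
    ctrVox <- (dims + 1) / 2
    sigVox <- nucleusSigma / c(vs["y"], vs["x"], vs["z"])
    if (n > 0) {
      centersVox <- cbind(ctrVox[1] + tilted[, 1] / vs["y"],
                          ctrVox[2] + tilted[, 2] / vs["x"],
                          ctrVox[3] + tilted[, 3] / vs["z"])
      arr <- .addBlobs3d(arr, centersVox, sigVox, intensityNucleus)
    }
    arr <- round(arr)
    if (noisePoisson || noiseGaussianSd > 0)
      arr <- .applyNoise(arr, noisePoisson, noiseGaussianSd)
    ## region of interest implied by the cluster geometry, for the
    ## counting pipeline's crop step (one voxel-rounded pad beyond the
    ## outermost possible blob support)
    hUm <- min(clusterRadius + 4 * nucleusSigma + 2, half)
    roi <- list(
      rows = max(1, floor(ctrVox[1] - hUm / vs["y"])):
        min(dims[1], ceiling(ctrVox[1] + hUm / vs["y"])),
      cols = max(1, floor(ctrVox[2] - hUm / vs["x"])):
        min(dims[2], ceiling(ctrVox[2] + hUm / vs["x"])),
      slices = max(1, floor(ctrVox[3] - hUm / vs["z"])):
        min(dims[3], ceiling(ctrVox[3] + hUm / vs["z"])))
    list(stack = ImageStack(arr, voxelSize = vs, datasetId = "SYNTH"),
         truth = list(count = n, centersUm = tilted,
                      centersUntiltedUm = pts, roi = roi))
  })
}

#' Generate synthetic per-dataset staging tables
#'
#' Draws `nDatasets` staging tables around a mean 17-stage boundary
#' vector with per-boundary Gaussian jitter (re-sorted to stay monotone),
#' emulating the between-embryo variability of temporally aligned
#' recordings. The default timetable spans 62 hours of embryonic
#' development.
#'
#' @param nDatasets number of datasets (tables) to draw.
#' @param meanBoundaries strictly increasing vector of the 18 stage
#'   boundaries (start of stage 1 ... end of stage 17) in hours.
#' @param boundarySd per-boundary jitter SD in hours (recycled).
#' @param seed mandatory RNG seed.
#' @return List with `tables` (data.frame: dataset, stage, start_h,
#'   end_h) and `truth` (list: meanBoundaries, boundarySd).
#' @export
generateStageTables <- function(nDatasets = 5,
                                meanBoundaries = medflyStageBoundaries(),
                                boundarySd = 0.5, seed) {
  if (length(meanBoundaries) != 18L)
    stop("configuration error: 18 boundaries (17 stages) required")
  if (any(diff(meanBoundaries) <= 0))
    stop("configuration error: mean boundaries must be strictly increasing")
  boundarySd <- rep_len(boundarySd, 18L)
  if (any(boundarySd < 0))
    stop("configuration error: boundary SDs must be >= 0")
  .withSeed(seed, {
    rows <- lapply(seq_len(nDatasets), function(i) {
      b <- sort(meanBoundaries + rnorm(18L, sd = boundarySd))
      data.frame(dataset = sprintf("DS%04d", i), stage = 1:17,
                 start_h = b[1:17], end_h = b[2:18])
    })
    list(tables = do.call(rbind, rows),
         truth = list(meanBoundaries = meanBoundaries,
                      boundarySd = boundarySd))
  })
}

#' Default mean stage boundaries of the synthetic staging tables
#'
#' An 18-element boundary vector (hours) for stages 1-17 spanning 62 h of
#' embryonic development, consistent with the reported process durations
#' (about four hours of blastoderm quiescence in stage 5, about two hours
#' of fast germband-tip migration in stage 8, about five and a half hours
#' for the slow migration phase across stages 9-10, and about seven and a
#' half hours of germband retraction in stage 12).
#'
#' @return Numeric vector of length 18.
#' @export
medflyStageBoundaries <- function() {
  durations <- c(1, 3, 2, 2.5, 4,      # event I: stages 1-5
                 1.5, 2,               # event II: stages 6-7
                 2, 2.5, 3, 2,         # event III: stages 8-11
                 7.5,                  # event IV: stage 12
                 4, 4, 4.5,            # event V: stages 13-15
                 8, 8.5)               # event VI: stages 16-17
  c(0, cumsum(durations))
}
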