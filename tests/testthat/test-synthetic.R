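# Synthetic-data generators: exact ground truth, determinism, validation.

test_that("embryo movie ground truth is exact by construction", {
  spec <- syntheticEmbryoSpec(frameShape = c(200, 100),
                              semiAxes = c(a = 80, b = 35),
                              lengthTrajectory = function(u) 1 - 0.1 * u,
                              nFrames = 3, nSurfaceNuclei = 20,
                              noisePoisson = FALSE, noiseGaussianSd = 0,
                              seed = 4)
  mov <- generateEmbryoMovie(spec)
  expect_equal(mov$truth$length_px, 2 * 80 * c(1, 0.95, 0.9))
  expect_identical(length(mov$frames), 3L)
  expect_true(all(vapply(mov$frames, function(f)
    all(imageData(f) == round(imageData(f))), logical(1))))
})

test_that("generators are bit-identical for a fixed seed", {
  spec <- syntheticEmbryoSpec(frameShape = c(120, 70),
                              semiAxes = c(a = 45, b = 25),
                              nFrames = 2, nSurfaceNuclei = 10, seed = 9)
  m1 <- generateEmbryoMovie(spec)
  m2 <- generateEmbryoMovie(spec)
  expect_identical(imageData(m1$frames[[2]]), imageData(m2$frames[[2]]))
  w1 <- generateNucleiWindow(8, seed = 5)
  w2 <- generateNucleiWindow(8, seed = 5)
  expect_identical(imageData(w1$window), imageData(w2$window))
  s1 <- generatePoleCellStack(n = 5, clusterRadius = 12, extent = 50,
                              seed = 2)
  s2 <- generatePoleCellStack(n = 5, clusterRadius = 12, extent = 50,
                              seed = 2)
  expect_identical(imageData(s1$stack), imageData(s2$stack))
})

test_that("invalid embryo specs name the violated invariant", {
  expect_error(syntheticEmbryoSpec(frameShape = c(100, 60),
                                   semiAxes = c(a = 60, b = 20), seed = 1),
               "fit inside the frame")
  expect_error(syntheticEmbryoSpec(lengthTrajectory = function(u) 1.5,
                                   seed = 1),
               "\\(0, 1.2\\]")
  expect_error(syntheticEmbryoSpec(nucleusSigma = 0, seed = 1),
               "nucleusSigma")
  expect_error(syntheticEmbryoSpec(), "seed")
})

test_that("nuclei windows respect counts, separation and feasibility", {
  w0 <- generateNucleiWindow(0, seed = 1)
  expect_identical(w0$truth$count, 0)
  expect_identical(dim(imageData(w0$window)), c(150L, 150L))
  w <- generateNucleiWindow(25, sigma = 3, seed = 7)
  expect_identical(nrow(w$truth$centers), 25L)
  d <- as.matrix(dist(w$truth$centers)); diag(d) <- Inf
  expect_true(min(d) >= 4 * 3)
  expect_error(generateNucleiWindow(500, sigma = 6, seed = 1),
               "placement infeasible")
})

test_that("the reference spot area grows monotonically with sigma", {
  a1 <- spotReferenceArea(6)
  a2 <- spotReferenceArea(3)
  # the adaptive threshold adds a log-correction to the sigma^2 law, so
  # halving sigma shrinks the area by a factor between 2 and 4 (the
  # generator's division construction inverts this curve numerically
  # rather than assuming the naive quadratic scaling)
  expect_gt(a1 / a2, 2)
  expect_lt(a1 / a2, 4)
  as_ <- vapply(c(2, 3, 4, 6), spotReferenceArea, numeric(1))
  expect_true(all(diff(as_) > 0))
})

test_that("pole-cell stacks validate geometry and honour the tilt", {
  empty <- generatePoleCellStack(n = 0, seed = 3)
  expect_identical(empty$truth$count, 0)
  expect_error(generatePoleCellStack(n = 5, clusterRadius = 60,
                                     extent = 76, seed = 1),
               "cluster too large")
  g <- generatePoleCellStack(n = 8, tiltAngle = -40, seed = 6)
  th <- -40 * pi / 180
  u <- g$truth$centersUntiltedUm
  expect_equal(g$truth$centersUm[, 3],
               cos(th) * u[, 3] - sin(th) * u[, 2], tolerance = 1e-12)
  expect_equal(g$truth$centersUm[, 1], u[, 1], tolerance = 1e-12)  # y fixed
})

test_that("stage tables jitter around the mean and stay monotone", {
  zero <- generateStageTables(3, boundarySd = 0, seed = 11)
  byds <- split(zero$tables, zero$tables$dataset)
  expect_equal(byds[[1]]$start_h, byds[[2]]$start_h)
  expect_equal(byds[[1]]$start_h, medflyStageBoundaries()[1:17])
  g <- generateStageTables(5, boundarySd = 0.5, seed = 12)
  expect_identical(nrow(g$tables), 5L * 17L)
  for (t in split(g$tables, g$tables$dataset)) {
    expect_true(all(diff(t$start_h) > 0))
    expect_true(all(t$end_h >= t$start_h))
  }
  expect_error(generateStageTables(2, meanBoundaries = rep(1, 18), seed = 1),
               "strictly increasing")
  expect_error(generateStageTables(2, meanBoundaries = 1:10, seed = 1),
               "18 boundaries")
})

test_that("de-rotating a tilted cluster restores the untilted geometry", {
  gt <- generatePoleCellStack(n = 6, clusterRadius = 12, extent = 56,
                              tiltAngle = -40, noisePoisson = FALSE,
                              noiseGaussianSd = 0, seed = 8)
  g0 <- generatePoleCellStack(n = 6, clusterRadius = 12, extent = 56,
                              tiltAngle = 0, noisePoisson = FALSE,
                              noiseGaussianSd = 0, seed = 8)
  iso <- resampleIsotropic(gt$stack)
  back <- rotateAboutY(iso, 40)
  iso0 <- resampleIsotropic(g0$stack)
  a <- imageData(back); b <- imageData(iso0)
  # compare centred crops of the two volumes (canvas sizes differ)
  ctrA <- (dim(a) + 1) / 2; ctrB <- (dim(b) + 1) / 2
  h <- 15
  cropA <- a[ctrA[1] + (-h:h), ctrA[2] + (-h:h), ctrA[3] + (-h:h)]
  cropB <- b[ctrB[1] + (-h:h), ctrB[2] + (-h:h), ctrB[3] + (-h:h)]
  # interpolation tolerance: bright blobs agree to a few grey levels
  expect_lt(mean(abs(cropA - cropB)), 3)
  expect_gt(cor(as.numeric(cropA), as.numeric(cropB)), 0.95)
})
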