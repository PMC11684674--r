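# Embryo length measurement, aggregation and tip kinematics.

smallSpec <- function(seed, trajectory = function(u) rep(1, length(u)),
                      nFrames = 2, noise = TRUE) {
  syntheticEmbryoSpec(frameShape = c(360, 160),
                      semiAxes = c(a = 150, b = 60),
                      lengthTrajectory = trajectory, nFrames = nFrames,
                      nSurfaceNuclei = 40,
                      noisePoisson = noise,
                      noiseGaussianSd = if (noise) 4 else 0,
                      seed = seed)
}

test_that("embryo length is recovered from single frames", {
  mov <- generateEmbryoMovie(smallSpec(1, noise = FALSE))
  len <- as.numeric(measureEmbryoLength(mov$frames[[1]]))
  expect_lte(abs(len - 300), 2)
  expect_error(measureEmbryoLength(matrix(5, 50, 50)), "embryo not found")
})

test_that("length is invariant to intensity offset and 180-degree turn", {
  mov <- generateEmbryoMovie(smallSpec(2, noise = FALSE))
  a <- imageData(mov$frames[[1]])
  l0 <- as.numeric(measureEmbryoLength(a))
  expect_identical(as.numeric(measureEmbryoLength(a + 50)), l0)
  flipped <- a[rev(seq_len(nrow(a))), rev(seq_len(ncol(a)))]
  expect_identical(as.numeric(measureEmbryoLength(flipped)), l0)
})

test_that("length series normalisation and missing-frame handling", {
  mov <- generateEmbryoMovie(smallSpec(3, nFrames = 4))
  ser <- lengthTimeseries(mov)
  expect_identical(nrow(ser), 4L)
  expect_identical(ser$norm_length[1], 1)
  expect_equal(ser$norm_time, c(0, 1/3, 2/3, 1))
  expect_true(all(abs(ser$norm_length - 1) < 0.02))
  expect_error(lengthTimeseries(mov$frames[1]), "at least two")
  # a blank frame is interpolated with a warning, not a crash
  frames <- mov$frames
  frames[[2]] <- ImageFrame(matrix(5, 360, 160), time = frameTime(frames[[2]]))
  expect_warning(ser2 <- lengthTimeseries(frames), "frame 2 failed")
  expect_true(ser2$interpolated[2])
  expect_false(any(is.na(ser2$length_px)))
})

test_that("aggregate curves compute the n-1 sample SD (closed form)", {
  base <- data.frame(norm_time = seq(0, 1, length.out = 11))
  delta <- 0.04
  s1 <- transform(base, norm_length = 1 - delta)
  s2 <- transform(base, norm_length = 1 + delta)
  agg <- aggregateCurves(list(s1, s2), nGrid = 21)
  expect_equal(unique(round(agg$mean, 12)), 1)
  # sample SD of {m - d, m + d} is sqrt(2) * d
  expect_equal(unique(round(agg$sd, 12)), round(sqrt(2) * delta, 12))
  ident <- aggregateCurves(list(s1, s1), nGrid = 21)
  expect_true(all(ident$sd == 0))
  expect_error(aggregateCurves(list(s1)), "at least two")
  s3 <- data.frame(norm_time = 2:3, norm_length = 1)
  expect_error(aggregateCurves(list(s1, s3)), "non-overlapping")
})

test_that("tip kinematics integrate steps and scale to physical units", {
  still <- data.frame(time_h = 0:3, row = 10, col = 10)
  k0 <- tipKinematics(still, pixelSize = 1)
  expect_true(all(k0$distance_um == 0))
  expect_true(all(k0$speed_um_h[-1] == 0))
  # 10 px per 0.5 h at 1 um/px -> 20 um/h
  mv <- data.frame(time_h = seq(0, 2, 0.5), row = seq(0, 40, 10), col = 5)
  k <- tipKinematics(mv, pixelSize = 1)
  expect_equal(k$speed_um_h[-1], rep(20, 4))
  expect_equal(k$distance_um[5], 40)
  # rigid translation of all annotations leaves the path length unchanged
  k2 <- tipKinematics(transform(mv, row = row + 7, col = col - 3), 1)
  expect_equal(k2$distance_um, k$distance_um)
  expect_error(tipKinematics(data.frame(time_h = c(0, 0), row = 1:2,
                                        col = 1:2), 1),
               "duplicate timestamps")
  expect_error(tipKinematics(mv[1, ], 1), "at least two")
})

test_that("SD peaks are detected with their prominence and mapped to stages", {
  grid <- seq(0, 1, length.out = 201)
  flat <- data.frame(norm_time = grid, mean = 1, sd = 0)
  expect_identical(nrow(detectSdPeaks(flat, 0.001)), 0L)
  sd <- 0.004 +
    0.03 * exp(-(grid - 0.3)^2 / 0.001) +
    0.05 * exp(-(grid - 0.8)^2 / 0.001)
  curve <- data.frame(norm_time = grid, mean = 1, sd = sd)
  pk <- detectSdPeaks(curve, minProminence = 0.01)
  expect_identical(nrow(pk), 2L)
  expect_equal(pk$norm_time, c(0.3, 0.8), tolerance = 0.01)
  tab <- generateStageTables(1, boundarySd = 0, seed = 1)$tables
  pk2 <- detectSdPeaks(curve, 0.01, stagingTable = tab)
  expect_true(all(pk2$stage %in% 1:17))
})
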