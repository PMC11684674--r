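# Posterior-window extraction, 2D nuclei statistics and 3D pole-cell
# counting.

test_that("posterior window sits at the stated offset on the midline", {
  # bright ellipse on dark background, posterior at high row indices
  nr <- 460; nc <- 200
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  emb <- ((rows - 230) / 190)^2 + ((cols - 100) / 70)^2 <= 1
  img <- matrix(10, nr, nc); img[emb] <- 80
  w <- extractPosteriorWindow(img, offset = 150, size = 150)
  posterior <- max(which(emb, arr.ind = TRUE)[, 1])  # row 420
  expect_identical(attr(w, "rows")[1], posterior - 150L - 75L)
  expect_identical(attr(w, "rows")[2], posterior - 150L + 74L)
  expect_identical(dim(imageData(w)), c(150L, 150L))
  # mirrored frame with the opposite posterior convention gives the
  # same window content (odd window, where the centring is symmetric)
  wo <- extractPosteriorWindow(img, offset = 150, size = 151)
  wm <- extractPosteriorWindow(img[rev(seq_len(nr)), ], offset = 150,
                               size = 151, posteriorEnd = "min_y")
  expect_equal(imageData(wm)[rev(seq_len(151)), ], imageData(wo))
  expect_error(extractPosteriorWindow(img, offset = 400, size = 150),
               "exceeds image bounds")
  expect_error(extractPosteriorWindow(matrix(7, 50, 50)),
               "degenerate histogram")
})

test_that("nuclei segmentation recovers counts and splits touching spots", {
  g <- generateNucleiWindow(25, sigma = 3, seed = 42, localRange = 10)
  lab <- segmentNuclei2D(g$window,
                         nucleiConfig(localRange = 10, logScales = c(1, 10)))
  expect_identical(nObjects(lab), 25L)
  # empty window -> empty map with a warning
  flat <- generateNucleiWindow(0, seed = 1, noisePoisson = FALSE,
                               noiseGaussianSd = 0)
  expect_warning(empty <- segmentNuclei2D(flat$window), "no seeds")
  expect_identical(nObjects(empty), 0L)
  # two spots two sigma apart are still divided at the ridge
  img <- matrix(10, 61, 61)
  img <- embryostager:::.addSpots2d(img, rbind(c(31, 24), c(31, 38)), 3, 160)
  lab2 <- segmentNuclei2D(round(img),
                          nucleiConfig(localRange = 10,
                                       logScales = c(1, 10)))
  expect_identical(nObjects(lab2), 2L)
})

test_that("nuclei statistics and density scale as expected", {
  g <- generateNucleiWindow(20, sigma = 3, seed = 8, localRange = 10)
  lab <- segmentNuclei2D(g$window,
                         nucleiConfig(localRange = 10, logScales = c(1, 10)))
  st <- nucleiStats(lab, pixelSize = 0.5)
  expect_identical(st$count, 20L)
  expect_identical(length(st$areas_px2), 20L)
  expect_equal(st$density_per_px2, 20 / 150^2)
  expect_equal(st$density_per_um2, 20 / (150^2 * 0.25))
  expect_equal(st$mean_area_um2, st$mean_area_px2 * 0.25)
  # measured mean area within 10% of the generator's reference area
  expect_lt(abs(st$mean_area_px2 - g$truth$trueArea_px2[1]) /
              g$truth$trueArea_px2[1], 0.1)
  e <- nucleiStats(LabelMap(matrix(0L, 10, 10)))
  expect_identical(e$count, 0L)
  expect_true(is.na(e$mean_area_px2))
  expect_identical(e$density_per_px2, 0)
})

test_that("division ratios are exact for identical inputs and track a
          constructed division", {
  g <- generateNucleiWindow(15, sigma = 4, seed = 3, localRange = 15)
  lab <- segmentNuclei2D(g$window, nucleiConfig(localRange = 15,
                                                logScales = c(1, 10)))
  st <- nucleiStats(lab)
  same <- divisionRatios(st, st)
  expect_equal(same$areaRatio, 1)
  expect_equal(same$densityRatio, 1)
  expect_error(divisionRatios(st, nucleiStats(LabelMap(matrix(0L, 5, 5)))),
               "empty input")
  # doubling the count in the same window doubles the density exactly
  g2 <- generateNucleiWindow(30, sigma = 4, seed = 4, localRange = 15)
  lab2 <- segmentNuclei2D(g2$window, nucleiConfig(localRange = 15,
                                                  logScales = c(1, 10)))
  st2 <- nucleiStats(lab2)
  expect_identical(st2$count, 30L)
  expect_equal(divisionRatios(st, st2)$densityRatio, 2)
})

test_that("pole-cell counting handles empty stacks and recovers clusters", {
  blank <- array(10, c(20, 20, 20))
  expect_warning(r0 <- countPoleCells3D(blank), "empty segmentation")
  expect_identical(r0$count, 0L)
  g <- generatePoleCellStack(n = 12, clusterRadius = 16, extent = 60,
                             tiltAngle = -40, seed = 5)
  r <- countPoleCells3D(g$stack, angle = 40,
                        polecellConfig(crop = g$truth$roi))
  expect_lte(abs(r$count - 12L), 1L)
  expect_identical(r$angle, 40)
})

test_that("count summaries use the sample standard deviation", {
  expect_equal(summarizeCounts(c(27, 27, 27)), list(mean = 27, sd = 0))
  s <- summarizeCounts(c(25, 30))
  expect_equal(s$mean, 27.5)
  expect_equal(s$sd, sqrt(2) * 2.5)  # sample SD of {25, 30} = 3.5355
  expect_equal(round(s$sd, 3), 3.536)
  expect_error(summarizeCounts(27), "at least two")
})
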