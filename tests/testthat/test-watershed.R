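# Seeded immersion watershed and LoG seed detection.

test_that("a single seed floods the whole mask", {
  set.seed(3)
  relief <- matrix(runif(36), 6, 6)
  lm <- seededWatershed(relief, matrix(c(3, 3), 1))
  expect_identical(unname(sum(labelData(lm) == 1L)), 36L)
})

test_that("two basins split at the ridge of a 1D profile", {
  # basins at positions 3 and 10, ridge at position 6
  prof <- matrix(c(5, 3, 1, 2, 4, 9, 4, 3, 2, 1, 2, 3), 1, 12)
  lm <- seededWatershed(prof, rbind(c(1, 3), c(1, 10)), connectivity = 4)
  g <- labelData(lm)
  expect_identical(as.integer(g[1, 1:5]), rep(1L, 5))
  expect_identical(as.integer(g[1, 7:12]), rep(2L, 6))
  # the ridge pixel floods last and joins the basin that reaches it first
  expect_true(g[1, 6] %in% c(1L, 2L))
})

test_that("watershed partitions the mask and requires markers", {
  set.seed(21)
  relief <- matrix(sample(0:50, 64, TRUE), 8, 8)
  mask <- matrix(TRUE, 8, 8); mask[1, ] <- FALSE
  lm <- seededWatershed(relief, rbind(c(3, 2), c(7, 7)), mask)
  g <- labelData(lm)
  expect_identical(unname(sum(g > 0)), unname(sum(mask)))
  expect_error(seededWatershed(relief, matrix(numeric(), 0, 2)),
               "no markers")
  expect_warning(
    seededWatershed(relief, rbind(c(1, 1), c(5, 5)), mask),
    "dropped")
})

test_that("LoG seeding finds isolated spots and nothing in empty images", {
  img <- matrix(0, 41, 41)
  img <- embryostager:::.addSpots2d(img, matrix(c(21, 21), 1), 3, 100)
  s <- logSeeds(img, 1.5, 6, 8)
  co <- seedCoords(s)
  expect_identical(nrow(co), 1L)
  expect_true(max(abs(co - c(21, 21))) <= 1)
  expect_identical(nrow(seedCoords(logSeeds(matrix(0, 20, 20), 1, 5))), 0L)
  two <- embryostager:::.addSpots2d(img, matrix(c(10, 31), 1), 3, 100)
  s2 <- logSeeds(two, 1.5, 6, 8)
  expect_identical(nrow(seedCoords(s2)), 2L)
  expect_error(logSeeds(img, 5, 2), "scaleMin")
})

test_that("watershed splits touching spots at the ridge between them", {
  img <- matrix(0, 31, 31)
  img <- embryostager:::.addSpots2d(img, rbind(c(16, 10), c(16, 22)), 3, 100)
  seeds <- SeedSet(rbind(c(16, 10), c(16, 22)), c(3, 3))
  lm <- seededWatershed(max(img) - img, seeds)
  g <- labelData(lm)
  expect_identical(g[16, 10], 1L)
  expect_identical(g[16, 22], 2L)
  # boundary between the two labels falls at the midline +/- 1 px
  boundary <- max(which(g[16, ] == 1L))
  expect_true(abs(boundary - 16) <= 1)
})
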