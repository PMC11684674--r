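# Contracts of the elementary image operators.

test_that("mean filter smooths as specified and validates its range", {
  m <- matrix(0, 5, 5); m[3, 3] <- 9
  out <- meanFilter(m, 3)
  expect_identical(out[3, 3], 1)
  expect_identical(meanFilter(matrix(7, 4, 4), 3), matrix(7, 4, 4))
  expect_error(meanFilter(m, 4), "odd")
  expect_error(meanFilter(m, -3), "odd")
})

test_that("local mean threshold is strict, offset-invariant and handles
          oversized windows", {
  expect_false(any(localMeanThreshold(matrix(5, 6, 6), 3)))
  expect_false(any(localMeanThreshold(matrix(0.3, 6, 6), 3)))
  one <- matrix(0, 7, 7); one[4, 4] <- 10
  mk <- localMeanThreshold(one, 3)
  expect_true(mk[4, 4]); expect_identical(sum(mk), 1L)
  # window larger than the image behaves like a global mean
  big <- localMeanThreshold(one, 99)
  expect_true(big[4, 4])
  # adding a constant offset changes nothing (integer-exact path)
  set.seed(11)
  img <- matrix(sample(0:60, 100, TRUE), 10, 10)
  expect_identical(localMeanThreshold(img, 5),
                   localMeanThreshold(img + 17, 5))
  expect_error(localMeanThreshold(img, 0), "positive")
})

test_that("Gaussian filter preserves constants, mass and superposition", {
  expect_equal(gaussianFilter(matrix(3, 8, 8), 2), matrix(3, 8, 8),
               tolerance = 1e-12)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  g <- gaussianFilter(imp, 1.5)
  expect_equal(which.max(g), which.max(imp))  # peak stays at the impulse
  expect_equal(sum(g), 1, tolerance = 1e-9)   # interior impulse keeps mass
  two <- matrix(0, 21, 21); two[6, 6] <- 1; two[16, 16] <- 1
  g2 <- gaussianFilter(two, 1.5)
  one1 <- matrix(0, 21, 21); one1[6, 6] <- 1
  one2 <- matrix(0, 21, 21); one2[16, 16] <- 1
  expect_equal(g2, gaussianFilter(one1, 1.5) + gaussianFilter(one2, 1.5),
               tolerance = 1e-12)
  expect_error(gaussianFilter(imp, 0), "positive")
})

test_that("Otsu threshold separates a bimodal image and rejects constants", {
  img <- matrix(c(rep(10, 100), rep(200, 100)), 20, 10)
  mk <- otsuThreshold(img)
  expect_identical(unname(sum(mk)), 100L)
  expect_true(attr(mk, "threshold") >= 10 && attr(mk, "threshold") < 200)
  expect_error(otsuThreshold(matrix(4, 5, 5)), "degenerate histogram")
})

test_that("hole filling closes interior background only and is idempotent", {
  sq <- matrix(FALSE, 7, 7); sq[2:6, 2:6] <- TRUE
  expect_identical(fillHoles(sq), sq)
  ring <- sq; ring[3:5, 3:5] <- FALSE
  expect_identical(fillHoles(ring), sq)
  expect_identical(fillHoles(fillHoles(ring)), fillHoles(ring))
  # background touching the border is never filled
  open_ <- ring; open_[2, 4] <- FALSE; open_[1, 4] <- FALSE
  filled <- fillHoles(open_)
  expect_false(filled[4, 4])
})

test_that("largest component selection obeys size and the reading-order
          tie rule", {
  m <- matrix(FALSE, 12, 12)
  m[2:6, 2:6] <- TRUE            # 25 px
  m[9:11, 9:11] <- TRUE          # 9 px
  out <- largestComponent(m)
  expect_true(out[3, 3]); expect_false(out[10, 10])
  expect_identical(largestComponent(out), out)  # idempotent
  # exact tie: keep the component whose first pixel is first in reading order
  t2 <- matrix(FALSE, 8, 8)
  t2[5, 1:3] <- TRUE             # starts at (5,1)
  t2[2, 5:7] <- TRUE             # starts at (2,5) - earlier row
  out2 <- largestComponent(t2)
  expect_true(out2[2, 5]); expect_false(out2[5, 1])
  expect_error(largestComponent(matrix(FALSE, 3, 3)), "no object")
})

test_that("convex hull extent equals the anterior-posterior point extent", {
  rect <- matrix(FALSE, 15, 8); rect[3:12, 2:5] <- TRUE
  expect_identical(convexHullExtent(rect)$extent_px, 10L)
  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  expect_identical(convexHullExtent(px)$extent_px, 1L)
  expect_error(convexHullExtent(matrix(FALSE, 4, 4)), "empty")
  expect_equal(convexHullExtent(rect, pixelSize = 0.5)$extent_um, 5)
})

test_that("label maps stay consistent under masking and border removal", {
  m <- matrix(FALSE, 9, 9)
  m[1:2, 1:2] <- TRUE    # touches the border
  m[4:5, 4:6] <- TRUE    # interior
  m[8, 8] <- TRUE        # interior single pixel
  lm <- labelComponents(m)
  expect_identical(nObjects(lm), 3L)
  # all-ones mask keeps everything (up to compaction)
  expect_identical(labelData(applyMask(lm, array(TRUE, dim(m)))),
                   labelData(lm))
  # all-zero mask empties the map
  expect_identical(nObjects(applyMask(lm, array(FALSE, dim(m)))), 0L)
  expect_error(applyMask(lm, matrix(TRUE, 3, 3)), "shape mismatch")
  nb <- removeBorderObjects(lm)
  expect_identical(nObjects(nb), 2L)
  expect_identical(unname(sum(labelData(nb) > 0)), 7L)
  centred <- labelComponents(matrix(c(rep(FALSE, 12),
                                      FALSE, TRUE, FALSE,
                                      rep(FALSE, 12)), 9, 3))
  expect_identical(nObjects(removeBorderObjects(centred)), 1L)
})

test_that("operators are deterministic on re-run", {
  set.seed(99)
  img <- matrix(sample(0:255, 15 * 15, TRUE), 15, 15)
  expect_identical(meanFilter(img, 3), meanFilter(img, 3))
  expect_identical(localMeanThreshold(img, 5), localMeanThreshold(img, 5))
  mk <- img > 128
  expect_identical(labelData(labelComponents(mk)),
                   labelData(labelComponents(mk)))
})
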