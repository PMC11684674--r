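# The two-level staging model.

test_that("the catalogue partitions stages 1-17 into the six events", {
  cat_ <- stageCatalog()
  expect_identical(cat_$stage, 1:17)
  expect_identical(unique(cat_$event), c("I", "II", "III", "IV", "V", "VI"))
  counts <- table(cat_$event)[c("I", "II", "III", "IV", "V", "VI")]
  expect_identical(unname(as.integer(counts)), c(5L, 2L, 4L, 1L, 3L, 2L))
  expect_identical(eventOf(1), "I")
  expect_identical(eventOf(12), "IV")
  expect_identical(eventOf(17), "VI")
  expect_identical(eventOf(c(6, 7)), c("II", "II"))
  expect_error(eventOf(18), "out of range")
  expect_error(eventOf(0), "out of range")
})

test_that("stage durations are exact and normalised durations sum to one", {
  uniform <- data.frame(stage = 1:17, start_h = (0:16) * 4,
                        end_h = (1:17) * 4)
  d <- stageDurations(uniform)
  expect_equal(unname(d), rep(4, 17))
  dn <- stageDurations(uniform, normalized = TRUE)
  expect_equal(unname(dn), rep(1 / 17, 17))
  expect_lt(abs(sum(dn) - 1), 1e-12)
  g <- generateStageTables(4, boundarySd = 0.4, seed = 20)
  for (t in split(g$tables, g$tables$dataset)) {
    expect_lt(abs(sum(stageDurations(t, normalized = TRUE)) - 1), 1e-12)
  }
  broken <- uniform
  broken$start_h[5] <- broken$start_h[5] + 1  # gap against stage 4 end
  expect_error(stageDurations(broken), "stage 4 -> 5")
})

test_that("aggregation reproduces closed-form SDs and locates shifts", {
  t1 <- data.frame(dataset = "A", stage = 1:17, start_h = (0:16) * 2,
                   end_h = (1:17) * 2)
  agg0 <- aggregateStaging(rbind(t1, transform(t1, dataset = "B")))
  expect_true(all(agg0$stages$sd_h == 0))
  expect_true(all(agg0$boundaries$sd_h == 0))
  # shift one interior boundary of B by delta: boundary SD = delta/sqrt(2)
  delta <- 0.6
  t2 <- transform(t1, dataset = "B")
  t2$end_h[9] <- t2$end_h[9] + delta
  t2$start_h[10] <- t2$start_h[10] + delta
  agg <- aggregateStaging(rbind(t1, t2))
  expect_equal(agg$boundaries$sd_h[10], delta / sqrt(2))
  expect_identical(which.max(agg$boundaries$sd_h), 10L)
  # permutation invariance over datasets
  agg2 <- aggregateStaging(rbind(t2, t1))
  expect_equal(agg$boundaries$mean_h, agg2$boundaries$mean_h)
  expect_equal(agg$stages$sd_norm, agg2$stages$sd_norm)
  expect_error(aggregateStaging(t1), "at least two")
})

test_that("time classification respects half-open stage intervals", {
  tab <- generateStageTables(1, boundarySd = 0, seed = 1)$tables
  s7 <- tab$start_h[tab$stage == 7]
  expect_identical(classifyTime(s7, tab)$stage, 7L)
  expect_identical(classifyTime(s7, tab)$event, "II")
  expect_identical(classifyTime(s7 - 1e-9, tab)$stage, 6L)
  # terminal boundary is closed so the whole span is covered
  expect_identical(classifyTime(max(tab$end_h), tab)$stage, 17L)
  expect_error(classifyTime(max(tab$end_h) + 0.1, tab), "outside")
  expect_error(classifyTime(min(tab$start_h) - 0.1, tab), "outside")
})

test_that("classification matches a linear-scan oracle on random queries", {
  set.seed(33)
  tab <- generateStageTables(1, boundarySd = 0.7, seed = 14)$tables
  b <- c(tab$start_h, tab$end_h[17])
  t <- runif(200, min(b), max(b))
  got <- classifyTime(t, tab)$stage
  want <- vapply(t, function(x) {
    for (s in 1:17) if (x >= b[s] && (x < b[s + 1] || s == 17L)) return(s)
    NA_integer_
  }, integer(1))
  expect_identical(got, as.integer(want))
})
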