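test_that("cvPercent follows the n-1 definition and flags degenerate input", {
  expect_equal(cvPercent(c(5, 5, 5)), 0)
  expect_equal(cvPercent(c(1, 2, 3)), 50)   # sd = 1, mean = 2
  expect_true(is.na(cvPercent(c(0, 0))))
  expect_true(is.na(cvPercent(7)))          # a single replicate
  expect_true(is.na(cvPercent(c(8, 0, 0)))) # one detected value only
  ## scale invariance
  set.seed(41)
  v <- runif(6, 1, 9)
  expect_equal(cvPercent(v * 1e3), cvPercent(v))
})

test_that("bucket boundaries assign 10 and 30 to the middle bucket", {
  x <- toyTable(rbind(c(100, 110.2), c(100, 75), c(100, 20)), replicate = 1:2)
  ## CVs approximately 6.9, 20.2, 94.3: one per bucket
  prof <- cvProfile(x)
  expect_equal(unname(unlist(prof$buckets[, c("cv_lt_10", "cv_10_30", "cv_gt_30")])),
               rep(100 / 3, 3))
  expect_equal(sum(unlist(prof$buckets[, c("cv_lt_10", "cv_10_30", "cv_gt_30")])), 100)

  ## exact boundary CVs: mean 100 with sd exactly 10 and 30
  xb <- toyTable(rbind(c(90, 100, 110), c(70, 100, 130)))
  pb <- cvProfile(xb)
  expect_equal(pb$buckets$cv_10_30, 100)
})

test_that("undefined-CV features are excluded but counted", {
  x <- toyTable(rbind(c(10, 12, 14), c(0, 0, 0)))
  prof <- cvProfile(x)
  expect_equal(prof$buckets$n_features_used, 1L)
  expect_equal(prof$buckets$n_undefined, 1L)
  expect_false(prof$cv$defined[prof$cv$feature_id == "f2"])
})

test_that("an all-undefined condition is an error", {
  expect_error(cvProfile(toyTable(matrix(0, 2, 3))), "no feature has a defined CV")
})

test_that("variation to baseline is zero at day 0 and tracks forced arithmetic", {
  ## identical days: variation 0, all stable
  m <- matrix(rep(c(100, 200), 6), nrow = 2)
  x <- toyTable(m, replicate = rep(1:2, 3), day = rep(c(0L, 1L, 2L), each = 2))
  v <- variationToBaseline(x)
  expect_equal(v$variation$variation_pct, rep(0, 3))
  expect_true(all(v$variation$stable))

  ## day 3 at 70% of baseline: -30%, unstable at the +/-20 band
  m2 <- cbind(c(100, 50), c(100, 50), c(70, 35), c(70, 35))
  x2 <- toyTable(m2, replicate = c(1, 2, 1, 2), day = c(0L, 0L, 3L, 3L))
  v2 <- variationToBaseline(x2)
  d3 <- v2$variation[v2$variation$day == 3, ]
  expect_equal(d3$variation_pct, -30)
  expect_false(d3$stable)
  expect_equal(v2$classSummary$first_unstable_day, 3L)
})

test_that("first unstable day matches the closed form of geometric decay", {
  for (r in c(0.08, 0.1, 0.2)) {
    cfg <- syntheticConfig(noiseCv = 0, decayRate = r, devices = "Capitainer",
                           nFeaturesPerClass = 2, seed = 43)
    sim <- simulateStabilitySeries(cfg, days = 0:5)
    v <- variationToBaseline(sim$table, band = 20)
    ## smallest integer day with (1-r)^t - 1 strictly below -band:
    ## a class sitting exactly on the band edge is still stable
    analytic <- floor(log(1 - 20 / 100) / log(1 - r) + 1e-9) + 1
    expect_true(all(v$classSummary$first_unstable_day ==
                    ifelse(analytic <= 5, analytic, NA)))
  }
})

test_that("day-0 variation is exactly zero even under noise", {
  sim <- simulateStabilitySeries(
    syntheticConfig(noiseCv = 0.3, devices = "Whatman",
                    nFeaturesPerClass = 3, seed = 44), days = 0:2)
  v <- variationToBaseline(sim$table)
  expect_true(all(v$variation$variation_pct[v$variation$day == 0] == 0))
})

test_that("features missing at baseline are excluded and reported", {
  m <- cbind(c(100, 0), c(100, 0), c(50, 80), c(50, 80))
  x <- toyTable(m, compound_class = "sugars",
                replicate = c(1, 2, 1, 2), day = c(0L, 0L, 1L, 1L))
  v <- variationToBaseline(x)
  expect_equal(v$variation$n_features[1], 1L)
  expect_equal(v$variation$n_excluded[1], 1L)
  expect_equal(v$variation$variation_pct[v$variation$day == 1], -50)
})

test_that("stability requires a single device and a day-0 baseline", {
  sim <- simulateStabilitySeries(syntheticConfig(nFeaturesPerClass = 2, seed = 45),
                                 days = 0:1)
  expect_error(variationToBaseline(sim$table), "one device")
  one <- sim$table[, colData(sim$table)$device == "Capitainer"]
  expect_error(variationToBaseline(one[, colData(one)$day > 0]), "day 0")
})
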