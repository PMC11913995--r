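test_that("the vectorised Welch test matches stats::t.test", {
  set.seed(51)
  a <- matrix(rnorm(60, 5, 1), 10, 6)
  b <- matrix(rnorm(40, 5.5, 2), 10, 4)
  w <- spotEval:::.rowWelch(a, b)
  for (i in seq_len(10)) {
    ref <- stats::t.test(b[i, ], a[i, ], var.equal = FALSE)
    expect_equal(w$pvalue[i], ref$p.value, tolerance = 1e-12)
    expect_equal(w$statistic[i], unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("identical groups give fold change 1 and p 1", {
  m <- matrix(runif(12, 1, 10), 3, 4)
  a <- toyTable(m[, 1:2], replicate = 1:2)
  b <- toyTable(m[, 1:2], replicate = 1:2, mode = "consecutive")
  res <- volcanoCompare(a, b)
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$pvalue, rep(1, 3))
  expect_false(any(res$significant))
})

test_that("swapping the groups flips the fold change and keeps p", {
  set.seed(52)
  a <- toyTable(matrix(runif(9, 1, 10), 3, 3))
  b <- toyTable(matrix(runif(9, 1, 10), 3, 3), mode = "consecutive")
  ab <- volcanoCompare(a, b)
  ba <- volcanoCompare(b, a)
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$pvalue, ba$pvalue)
})

test_that("volcano recovers a planted fold change on pre-normalized tables", {
  set.seed(53)
  base <- runif(20, 0.01, 0.1)
  mk <- function(fc, mode) {
    m <- replicate(3, base * exp(rnorm(20, 0, 0.02)))
    m[1:5, ] <- m[1:5, ] * fc
    toyTable(m, compound_class = c(rep("phosphorylated compounds", 5),
                                   rep("sugars", 15)),
             mode = mode, normalized = TRUE)
  }
  res <- volcanoCompare(mk(1, "single"), mk(4, "consecutive"))
  boosted <- res$compound_class == "phosphorylated compounds"
  expect_true(all(res$significant[boosted]))
  expect_equal(mean(2^res$log2fc[boosted]), 4, tolerance = 0.05)
  expect_false(any(res$significant[!boosted]))
})

test_that("features detected in neither group are excluded and counted", {
  m <- rbind(c(5, 6, 7), c(0, 0, 0))
  a <- toyTable(m)
  b <- toyTable(m, mode = "consecutive")
  res <- volcanoCompare(a, b)
  expect_equal(nrow(res), 1L)
  expect_equal(attr(res, "n_excluded"), 1L)
})

test_that("PCA reports variance fractions that sum to 100 and finds rank-1 data", {
  ## rank-1: one latent direction, no noise
  latent <- c(1, 2, 3, 4, 5, 6)
  m <- outer(runif(10, 1, 2), latent)
  p <- pcaOverview(toyTable(m, normalized = TRUE, logTransformed = TRUE))
  expect_equal(p$varianceExplained[1], 100, tolerance = 1e-8)
  expect_equal(sum(p$varianceExplained), 100)

  set.seed(54)
  m2 <- matrix(rnorm(60), 10, 6)
  p2 <- pcaOverview(toyTable(m2, logTransformed = TRUE))
  expect_equal(sum(p2$varianceExplained), 100)
  expect_equal(p2$pc12Sum, sum(p2$varianceExplained[1:2]))

  ## sample order does not change the variance profile
  perm <- c(3, 1, 6, 2, 5, 4)
  p3 <- pcaOverview(toyTable(m2[, perm], logTransformed = TRUE))
  expect_equal(p2$varianceExplained, p3$varianceExplained, tolerance = 1e-9)

  expect_error(pcaOverview(toyTable(matrix(1, 3, 3), logTransformed = TRUE)),
               "constant")
})

test_that("two solvent groups with distinct class profiles split on PC1", {
  ## sum normalization removes overall yield, so separation must come from
  ## the class composition: pure organics extract only the sugars here
  yld <- uniformYield(c(1, 1, 1, 1, 1))
  org <- yld$solvent %in% c("ISO", "BuMe")
  yld$yield[org] <- ifelse(yld$compound_class[org] == "sugars", 1, 0.05)
  cfg <- syntheticConfig(noiseCv = 0.1, classYield = yld,
                         devices = "Capitainer", nFeaturesPerClass = 5,
                         detectionLimit = 0, seed = 55)
  sim <- simulateExtractionExperiment(cfg)
  p <- pcaOverview(log10Transform(normalizeSum(sim$table)))
  grp <- colData(sim$table)$solvent %in% c("ISO", "BuMe")
  pc1 <- p$scores[, 1]
  ## group separation along PC1 exceeds the within-group spread
  expect_gt(abs(mean(pc1[grp]) - mean(pc1[!grp])),
            stats::sd(pc1[grp]) + stats::sd(pc1[!grp]))
})

test_that("BCA calibration inverts exactly on linear standards", {
  conc <- c(0, 25, 125, 250, 500, 750, 1000, 1500, 2000)
  std <- data.frame(concentration_ug_ml = conc, absorbance = 0.05 + 0.001 * conc)
  fit <- bcaFit(std)
  expect_equal(fit@rSquared, 1)
  got <- bcaConcentration(fit, 0.05 + 0.001 * conc)
  expect_true(all(abs(got$concentration_ug_ml - conc) < 1e-9))
  expect_false(any(got$extrapolated))

  ## dilution scales linearly
  expect_equal(bcaConcentration(fit, 0.55, 2)$concentration_ug_ml, 1000)

  ## above the top standard: flagged extrapolation
  high <- bcaConcentration(fit, 0.05 + 0.001 * 2500)
  expect_true(high$extrapolated)
  expect_equal(high$concentration_ug_ml, 2500)
})

test_that("BCA failure modes are rejected", {
  expect_error(bcaFit(data.frame(concentration_ug_ml = c(100, 100),
                                 absorbance = c(0.1, 0.2))), "distinct")
  expect_error(bcaFit(data.frame(concentration_ug_ml = c(0, 100),
                                 absorbance = c(0.2, 0.1))), "slope")
  fit <- bcaFit(data.frame(concentration_ug_ml = c(0, 100, 200),
                           absorbance = c(0, 0.1, 0.2)))
  expect_error(bcaConcentration(fit, 0.1, dilutionFactor = 0.5), ">= 1")
})

test_that("quadratic calibration recovers a curved standard series", {
  conc <- c(0, 25, 125, 250, 500, 750, 1000, 1500, 2000)
  absb <- 0.02 + 0.001 * conc - 8e-8 * conc^2   # mild top-of-range flattening
  fit <- bcaFit(data.frame(concentration_ug_ml = conc, absorbance = absb),
                degree = 2)
  got <- bcaConcentration(fit, absb)
  expect_true(all(abs(got$concentration_ug_ml - conc) < 1e-6))
})
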