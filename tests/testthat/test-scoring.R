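test_that("relative intensity anchors each feature to its in-scope maximum", {
  x <- toyTable(matrix(c(100, 0, 3, 50, 0, 6, 25, 0, 4, 10, 0, 1), 3, 4))
  rel <- relativeIntensity(x)
  expect_equal(rel[1, ], c(s1 = 100, s2 = 50, s3 = 25, s4 = 10))
  expect_equal(unname(rel[2, ]), rep(0, 4))          # all-zero row, no NaN
  expect_equal(unname(rel[3, ]), c(50, 100, 200 / 3, 100 / 6))
  expect_error(relativeIntensity(x[, 0]), "no samples")
  expect_error(relativeIntensity(normalizeSum(x)), "raw")
})

test_that("score bins follow the printed quartile boundaries", {
  expect_identical(scoreBin(c(10, 24.9, 25, 49.9, 50, 74.9, 75, 100)),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_identical(scoreBin(0, detected = FALSE), 0L)
  ## detected-but-tiny signal scores 1, not 0
  expect_identical(scoreBin(0.001, detected = TRUE), 1L)
  expect_error(scoreBin(101), "\\[0, 100\\]")
  expect_error(scoreBin(-1), "\\[0, 100\\]")
})

test_that("scoring matches the brute-force oracle on random small matrices", {
  set.seed(31)
  for (k in 1:40) {
    m <- randomScoreMatrix()
    x <- toyTable(m)
    expect_identical(unname(scoreFeatures(x, scope = "all")),
                     unname(bruteScoreMatrix(m)))
  }
})

test_that("every detected feature has at least one score-4 sample in scope", {
  set.seed(32)
  sim <- simulateExtractionExperiment(syntheticConfig(seed = 32))
  s <- scoreFeatures(sim$table)
  cd <- colData(sim$table)
  for (d in unique(cd$device)) {
    sub <- s[, cd$device == d, drop = FALSE]
    detected <- rowSums(assay(sim$table, "intensity")[, cd$device == d]) > 0
    expect_true(all(apply(sub[detected, ], 1, max) == 4L))
  }
})

test_that("scores are invariant to scaling a feature row", {
  set.seed(33)
  m <- matrix(runif(40, 0, 50), 5, 8)
  m2 <- m
  m2[3, ] <- m2[3, ] * 1e4
  expect_identical(scoreFeatures(toyTable(m), scope = "all"),
                   scoreFeatures(toyTable(m2), scope = "all"),
                   ignore_attr = TRUE)
  expect_identical(unname(scoreFeatures(toyTable(m), scope = "all")),
                   unname(scoreFeatures(toyTable(m2), scope = "all")))
})

test_that("raising one intensity never lowers its own score (brute force)", {
  set.seed(34)
  for (k in 1:15) {
    m <- randomScoreMatrix(5, 6)
    i <- sample(nrow(m), 1); j <- sample(ncol(m), 1)
    m2 <- m
    m2[i, j] <- m2[i, j] + runif(1, 0.1, 50)
    expect_gte(bruteScoreMatrix(m2)[i, j], bruteScoreMatrix(m)[i, j])
    ## other samples of that feature may only drop via re-anchored maxima
    expect_true(all(bruteScoreMatrix(m2)[i, -j] <= bruteScoreMatrix(m)[i, -j]))
  }
})

test_that("condition totals average replicate sums with n-1 SD", {
  ## three replicates engineered to total 10, 12, 14
  m <- rbind(c(100, 100, 100),    # 4 4 4
             c(40, 100, 60),      # 2 4 3
             c(60, 100, 74),      # 3 4 3
             c(20, 0, 100))       # 1 0 4
  tot <- totalScores(toyTable(m))
  expect_equal(tot$mean_score, 12)
  expect_equal(tot$sd_score, 2)
  expect_equal(unname(colSums(scoreFeatures(toyTable(m)))), c(10, 12, 14))

  ## constant case: 2 features always at the max
  tot2 <- totalScores(toyTable(matrix(100, 2, 3)))
  expect_equal(tot2$mean_score, 8)
  expect_equal(tot2$sd_score, 0)

  ## single replicate: sd 0 with a warning flag
  expect_warning(tot3 <- totalScores(toyTable(matrix(c(50, 60), 2, 1))),
                 "single replicate")
  expect_true(tot3$single_replicate)
  expect_equal(tot3$sd_score, 0)
})

test_that("class heatmap averages scores per class and flags empty classes", {
  m <- rbind(c(100, 100), c(40, 100))
  x <- toyTable(m, compound_class = c("sugars", "sugars"),
                solvent = "CH3OH100", replicate = 1:2)
  hm <- classScoreHeatmap(x)
  ## scores: f1 = 4,4; f2 = 2,4 -> class mean 3.5
  expect_equal(unname(hm$Capitainer["sugars", "CH3OH100"]), 3.5)
  expect_true(is.na(hm$Capitainer["carnitines", "CH3OH100"]))
})

test_that("zero-noise totals rank solvents by configured class yields", {
  yld <- uniformYield(c(1, 0.6, 0.4, 0, 0.2))   # 100 > 80 > 50 > BuMe > ISO
  cfg <- syntheticConfig(noiseCv = 0, classYield = yld,
                         devices = "Capitainer", nFeaturesPerClass = 4,
                         seed = 35)
  sim <- simulateExtractionExperiment(cfg)
  tot <- totalScores(sim$table)
  ranking <- tot$solvent[order(-tot$mean_score)]
  expect_identical(ranking, c("CH3OH100", "CH3OH80", "CH3OH50", "BuMe", "ISO"))
})
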