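test_that("mid-rank percentiles follow the counting definition", {
  expect_equal(percentileRank(c(1, 2, 3, 4)), c(12.5, 37.5, 62.5, 87.5))
  expect_equal(percentileRank(rep(7, 5)), rep(50, 5))

  set.seed(11)
  v <- c(rnorm(171), NA, NA)
  p <- percentileRank(v)
  expect_equal(p, brutePercentile(v))
  expect_true(all(is.na(p[is.na(v)])))
  expect_equal(order(p[!is.na(p)]), order(v[!is.na(v)]))
  expect_equal(mean(p, na.rm = TRUE), 50)

  expect_error(percentileRank(c(NA_real_, NA_real_)), "missing")
})

test_that("percentile brackets are closed at 25 and 70, open above", {
  expect_equal(percentileBracket(c(25, 25.0001, 70, 70.0001)),
               c("low", "intermediate", "intermediate", "high"))
  expect_equal(percentileBracket(c(0, 100)), c("low", "high"))
})

test_that("density score reproduces the hand-computed worked example", {
  ex <- workedExample()
  ds <- densityScore(ex$values[[1]], ex$values[[2]],
                     ex$values[[3]], ex$values[[4]])
  expect_equal(ds$mean_percentile, ex$mean_percentile)
  expect_equal(ds$score, ex$score)
  expect_equal(ds$n_components, rep(4L, 10))
})

test_that("missing components propagate; partial tumors still score", {
  ex <- workedExample()
  v <- ex$values
  v[[1]][1] <- NA; v[[2]][1] <- NA; v[[3]][1] <- NA; v[[4]][1] <- NA
  v[[4]][2] <- NA  # tumor 2 keeps three components
  ds <- densityScore(v[[1]], v[[2]], v[[3]], v[[4]])
  expect_true(is.na(ds$score[1]))
  expect_equal(ds$n_components[1], 0L)
  expect_false(is.na(ds$score[2]))
  expect_equal(ds$n_components[2], 3L)
})

test_that("cohort-maximum components always score high", {
  set.seed(21)
  m <- as.data.frame(matrix(runif(4 * 30), ncol = 4))
  m[7, ] <- 2  # above every other value in all four components
  ds <- densityScore(m[[1]], m[[2]], m[[3]], m[[4]])
  expect_equal(ds$score[7], "high")
})

test_that("proximity and density scores share one machinery", {
  set.seed(31)
  m <- as.data.frame(matrix(runif(4 * 40), ncol = 4))
  expect_equal(proximityScore(m[[1]], m[[2]], m[[3]], m[[4]]),
               densityScore(m[[1]], m[[2]], m[[3]], m[[4]]))
  # zero G-cross everywhere in a positive cohort: low
  g <- as.data.frame(matrix(runif(4 * 20, 0.2, 0.9), ncol = 4))
  g[5, ] <- 0
  ps <- proximityScore(g[[1]], g[[2]], g[[3]], g[[4]])
  expect_equal(ps$score[5], "low")
})

test_that("scores are invariant under monotone transforms and ordering", {
  set.seed(41)
  m <- as.data.frame(matrix(rlnorm(4 * 35), ncol = 4))
  base <- densityScore(m[[1]], m[[2]], m[[3]], m[[4]])$score
  trans <- densityScore(log(m[[1]]), sqrt(m[[2]]), 3 * m[[3]] + 1,
                        exp(m[[4]] / 10))$score
  expect_equal(trans, base)

  perm <- sample(nrow(m))
  shuffled <- densityScore(m[[1]][perm], m[[2]][perm], m[[3]][perm],
                           m[[4]][perm])$score
  expect_equal(shuffled[order(perm)], base)
})

test_that("score category proportions match percentile arithmetic", {
  set.seed(51)
  m <- as.data.frame(matrix(rnorm(4 * 100), ncol = 4))
  ds <- densityScore(m[[1]], m[[2]], m[[3]], m[[4]])
  # direct oracle: mean of counting-based percentiles, bracketed
  pct <- sapply(m, brutePercentile)
  expect_equal(ds$mean_percentile, rowMeans(pct))
  expect_equal(ds$score, percentileBracket(rowMeans(pct)))

  # when the four components rank tumors identically (strongly coupled
  # infiltration), the mean percentile is uniform and tie-free data split
  # exactly 25 / 45 / 30 per the bracket widths
  z <- rnorm(100)
  ds2 <- densityScore(z, exp(z), z^3, 5 * z + 2)
  tab <- table(factor(ds2$score, c("low", "intermediate", "high")))
  expect_equal(as.integer(tab), c(25, 45, 30))
})

test_that("CLR density is count over margin length", {
  expect_equal(clrDensity(21, 50), 0.42)
  expect_equal(clrDensity(0, 37.5), 0)
  set.seed(61)
  k <- rpois(50, 20); L <- runif(50, 10, 80)
  expect_equal(clrDensity(k, L), k / L)
  expect_error(clrDensity(5, 0), "positive")
  expect_error(clrDensity(-1, 10), "non-negative")
})

test_that("CLR categorization is inclusive at the cut-off", {
  expect_equal(clrCategorize(c(0.42, 0.419, 0.421, NA)),
               c("high", "low", "high", NA))
  set.seed(71)
  dens <- runif(60, 0, 1)
  expect_equal(clrCategorize(dens, 0.42),
               ifelse(dens >= 0.42, "high", "low"))
})

test_that("ROC cutoff maximizes Youden's J, ties to smallest threshold", {
  res <- rocOptimalCutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(res$cutoff, 2.5)
  expect_equal(res$J, 1)

  # duplicated optimum: the smaller threshold wins
  res2 <- rocOptimalCutoff(c(1, 1, 2, 2, 3, 3), c(0, 0, 1, 1, 1, 1))
  expect_equal(res2$cutoff, 1.5)

  expect_error(rocOptimalCutoff(1:4, c(1, 1, 1, 1)), "both outcome")
})

test_that("ROC cutoff equals the exhaustive-scan oracle", {
  set.seed(81)
  for (i in 1:10) {
    v <- round(rnorm(30), 1)
    y <- rbinom(30, 1, plogis(v))
    if (length(unique(y)) < 2) next
    got <- rocOptimalCutoff(v, y)
    want <- bruteRocCutoff(v, y)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$J, want$J)
  }
})

test_that("ROC Youden J agrees with pROC on a reference sample", {
  set.seed(91)
  v <- rnorm(200)
  y <- rbinom(200, 1, plogis(2 * v))
  got <- rocOptimalCutoff(v, y)
  roc <- pROC::roc(y, v, direction = "<", quiet = TRUE)
  best <- pROC::coords(roc, "best", best.method = "youden",
                       transpose = FALSE)
  expect_equal(got$J, max(roc$sensitivities + roc$specificities - 1),
               tolerance = 1e-10)
  expect_equal(got$cutoff, best$threshold[1], tolerance = 1e-10)
})

test_that("null ROC: permuted labels give J near zero on average", {
  set.seed(95)
  v <- rnorm(60)
  y <- rep(c(0, 1), 30)
  Js <- replicate(100, rocOptimalCutoff(v, sample(y))$J)
  # optimum of a null scan is positively biased but small
  expect_lt(mean(Js), 0.45)
  expect_gt(mean(Js), 0)
})

test_that("tertiles split the cohort with boundary-to-lower ties", {
  expect_equal(tertileClassify(1:9),
               rep(c("low", "moderate", "high"), each = 3))
  # heavy ties share one group
  v <- c(1, 2, rep(5, 6), 9, 10)
  tc <- tertileClassify(v)
  expect_length(unique(tc[v == 5]), 1)
  # continuous data: group sizes within 1 of n/3
  set.seed(105)
  sizes <- table(tertileClassify(rnorm(99)))
  expect_true(all(abs(sizes - 33) <= 1))
  # NA stays NA
  expect_true(is.na(tertileClassify(c(1:9, NA))[10]))
})

test_that("PD-L1 histoscore brackets follow <1, 1-<5, >=5", {
  expect_equal(pdl1TumorCategorize(c(0, 0.9, 1, 4.99, 5, 80, NA)),
               c("negative", "negative", "1-<5", "1-<5", ">=5", ">=5", NA))
})

test_that("scoreCohort assembles all categories and respects missingness", {
  ex <- workedExample()
  profiles <- data.frame(
    tumor_id = sprintf("t%02d", 1:10),
    cd3_ct = ex$values[[1]], cd3_im = ex$values[[2]],
    cd8_ct = ex$values[[3]], cd8_im = ex$values[[4]],
    g_cd3_ct = ex$values[[1]] / 100, g_cd3_im = ex$values[[2]] / 100,
    g_cd8_ct = ex$values[[3]] / 100, g_cd8_im = ex$values[[4]] / 100,
    clr_count = c(21, 0, 5, 30, NA, 8, 12, 40, 2, 7),
    margin_length_mm = c(50, 20, 25, 40, 30, 10, 35, 45, 15, 12),
    pdl1_tumor_histoscore = c(0, 0.5, 1, 2, 4.9, 5, 7, NA, 0.2, 3))
  sc <- scoreCohort(profiles)
  expect_equal(sc$density_score, ex$score)
  expect_equal(sc$proximity_score, ex$score)  # same values, same machinery
  expect_equal(sc$clr_density_per_mm[1], 0.42)
  expect_equal(sc$clr_category[1], "high")
  expect_true(is.na(sc$clr_category[5]))
  expect_true(is.na(sc$pdl1_tumor_category[8]))
  expect_true(all(sc$density_score %in%
                    c("low", "intermediate", "high", NA)))
  expect_true(all(sc$clr_category %in% c("low", "high", NA)))

  # auto cut-off route goes through the ROC scan
  ev <- c(1, 1, 0, 0, 0, 1, 0, 0, 1, 1)
  sc2 <- scoreCohort(profiles, clrCutoff = "auto", dssEvent = ev)
  expect_equal(attr(sc2, "clr_cutoff"),
               rocOptimalCutoff(sc$clr_density_per_mm, ev)$cutoff)
  expect_error(scoreCohort(profiles, clrCutoff = "auto"), "dssEvent")
})
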