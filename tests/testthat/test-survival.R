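test_that("30-day postoperative deaths are excluded with a count", {
  rc <- emulateReferenceCohort(seed = 2)
  filt <- excludePostoperative(rc)
  expect_equal(filt$nExcluded, 9)
  expect_equal(nrow(filt$cohort), 162)

  none <- data.frame(postoperative_death = rep(FALSE, 5),
                     os_time = runif(5, 1, 10))
  expect_identical(excludePostoperative(none)$cohort, none)

  sim <- simulateCohort(cohortParams(n = 400, postopProb = 0.06), seed = 5)
  expect_equal(excludePostoperative(sim$cohort)$nExcluded,
               sim$truth$nPostoperative)

  # internal consistency: a flagged death with a long clock is an error
  bad <- data.frame(postoperative_death = TRUE, os_time = 2)
  expect_error(excludePostoperative(bad), "30 days")
})

test_that("Kaplan-Meier matches hand computation and edge cases", {
  # hand-computed 5-point example: times 1..5, events 1,1,0,1,0
  km <- kmEstimate(1:5, c(1, 1, 0, 1, 0))
  expect_equal(km$survivalAt(c(1, 2, 3, 4, 5)),
               c(4 / 5, 3 / 5, 3 / 5, 3 / 10, 3 / 10))
  expect_equal(km$survivalAt(0.5), 1)

  # no censoring: empirical survival fraction at every event time
  set.seed(12)
  t <- sort(runif(40, 0, 10))
  km2 <- kmEstimate(t, rep(1, 40))
  expect_equal(km2$survivalAt(t), 1 - seq_len(40) / 40)

  # all censored: flat at 1
  km3 <- kmEstimate(t, rep(0, 40))
  expect_true(all(km3$steps$surv == 1))

  # stratified fit exports labelled step groups
  km4 <- kmEstimate(c(t, t + 1), rep(c(1, 0), each = 40),
                    groups = rep(c("a", "b"), each = 40))
  expect_setequal(unique(km4$steps$group), c("a", "b"))
})

test_that("reverse KM swaps event roles and finds follow-up medians", {
  # no deaths: reversed curve is an ordinary KM of the censor times,
  # median equals the sample median
  t <- c(2, 4, 6, 8, 10)
  rk <- reverseKmMedianFollowup(t, rep(0, 5))
  expect_true(rk$defined)
  expect_equal(rk$median, 6)

  # all deaths: the reversed curve never drops, median undefined
  rk2 <- reverseKmMedianFollowup(t, rep(1, 5))
  expect_false(rk2$defined)
  expect_true(is.na(rk2$median))

  # administrative censoring at T = 10: median follow-up ~ 10
  set.seed(22)
  death <- 14 * (-log(runif(300)))^(1 / 1.2)
  ot <- pmin(death, 10)
  oe <- as.numeric(death <= 10)
  rk3 <- reverseKmMedianFollowup(ot, oe)
  expect_equal(rk3$median, 10, tolerance = 1e-8)

  # identity: reverse KM is KM with flags flipped, both orientations
  ev <- rbinom(300, 1, 0.4)
  fit_rev <- survival::survfit(
    survival::Surv(ot, 1 - ev) ~ 1, conf.type = "log-log")
  expect_equal(reverseKmMedianFollowup(ot, ev)$median,
               unname(summary(fit_rev)$table["median"]))
  expect_equal(kmEstimate(ot, 1 - ev)$steps$surv[
    kmEstimate(ot, 1 - ev)$steps$n_event > 0],
    fit_rev$surv[fit_rev$n.event > 0])
})

test_that("log-rank test needs two groups and detects real separation", {
  t <- runif(30, 1, 5)
  expect_error(logrankTest(rep("a", 30), t, rbinom(30, 1, 0.5)),
               "two groups")

  # power at HR 3, n = 200 (30 simulations to stay light)
  set.seed(32)
  hits <- replicate(30, {
    d <- simTwoGroup(200, hr = 3)
    logrankTest(d$x, d$os_time, d$os_event)$p < 0.05
  })
  expect_gt(mean(hits), 0.8)

  # null: p-values over label permutations are roughly uniform
  set.seed(42)
  d <- simTwoGroup(80, hr = 1)
  ps <- replicate(200, {
    logrankTest(sample(d$x), d$os_time, d$os_event)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("coxFit recovers a known hazard ratio and reports Wald CIs", {
  set.seed(52)
  sim <- simulateCohort(cohortParams(
    n = 2000, marginals = list(x = c("0" = 0.5, "1" = 0.5)),
    logHR = list(x = c("0" = 0, "1" = log(2))), postopProb = 0),
    seed = 52)
  fit <- coxFit(list(x = "0"), sim$cohort, outcome = "OS")
  row <- resultTable(fit)[2, ]
  expect_gt(row$hr, 1.8)
  expect_lt(row$hr, 2.2)
  expect_true(row$ci_low < row$hr && row$hr < row$ci_high)
  ref <- resultTable(fit)[1, ]
  expect_equal(ref$hr, 1)
  expect_equal(ref$note, "reference")
  expect_equal(fit@n, 2000L)
})

test_that("coxFit agrees with a direct coxph call (Efron ties)", {
  set.seed(62)
  d <- simTwoGroup(150, hr = 2)
  d$os_time <- round(d$os_time)  # coarse times force ties
  d$os_time[d$os_time == 0] <- 0.5
  fit <- coxFit(list(x = "0"), d, outcome = "OS")
  direct <- survival::coxph(
    survival::Surv(os_time, os_event) ~ x, data = d, ties = "efron")
  expect_equal(log(resultTable(fit)$hr[2]), unname(coef(direct)),
               tolerance = 1e-10)
})

test_that("degenerate covariates and separation raise diagnostics", {
  d <- simTwoGroup(50, hr = 1)
  d$z <- "same"
  expect_error(coxFit(list(z = "same"), d, outcome = "OS"), "degenerate")

  dn <- d; dn$w <- 1
  expect_error(coxFit(list(w = NULL), dn, outcome = "OS"), "constant")

  expect_no_error(coxFit(list(x = "0"), d, outcome = "DSS", label = "m"))
  expect_error(coxFit(list(missing_col = "0"), d, outcome = "OS"),
               "lacks column")
})

test_that("zero-event levels are reported as No event, not fitted", {
  set.seed(72)
  d <- simTwoGroup(300, hr = 2)
  d$stage <- sample(c("1", "3", "4"), 300, replace = TRUE,
                    prob = c(0.1, 0.6, 0.3))
  d$os_event[d$stage == "1"] <- 0  # no events in stage 1
  fit <- coxFit(list(stage = "1"), d, outcome = "OS")
  tab <- resultTable(fit)
  r1 <- tab[tab$level == "1", ]
  expect_equal(r1$note, "No event")
  expect_equal(r1$events, 0L)
  expect_true(is.na(r1$hr))
  # reference moved to the first remaining level; model excludes stage 1
  expect_equal(tab$note[tab$level == "3"], "reference")
  expect_equal(fit@n, sum(d$stage != "1"))
})

test_that("estimates are invariant to covariate level reordering", {
  set.seed(82)
  d <- simTwoGroup(400, hr = 2)
  d$g <- sample(c("a", "b", "c"), 400, replace = TRUE)
  f1 <- resultTable(coxFit(list(g = "b"), d, outcome = "OS"))
  d2 <- d[order(d$g, decreasing = TRUE), ]
  f2 <- resultTable(coxFit(list(g = "b"), d2, outcome = "OS"))
  f2 <- f2[match(f1$level, f2$level), ]
  expect_equal(f1$hr, f2$hr)
  expect_equal(f1$p, f2$p)
})

test_that("KM ordering and Cox log-HR sign agree under PH", {
  set.seed(92)
  d <- simTwoGroup(600, hr = 2.5)
  fit <- coxFit(list(x = "0"), d, outcome = "OS")
  hr <- resultTable(fit)$hr[2]
  km <- kmEstimate(d$os_time, d$os_event, groups = d$x)
  s5 <- vapply(c("0", "1"), function(g) {
    st <- km$steps[km$steps$group == g & km$steps$time <= 5, ]
    st$surv[nrow(st)]
  }, numeric(1))
  expect_gt(hr, 1)           # group 1 has higher hazard...
  expect_lt(s5[["1"]], s5[["0"]])  # ...and the lower survival curve
})

test_that("Wald CI coverage is near nominal in small simulations", {
  set.seed(103)
  cover <- replicate(100, {
    d <- simTwoGroup(300, hr = 2)
    tab <- resultTable(coxFit(list(x = "0"), d, outcome = "OS"))
    log(2) >= log(tab$ci_low[2]) && log(2) <= log(tab$ci_high[2])
  })
  expect_gte(mean(cover), 0.88)
  expect_lte(mean(cover), 1.0)
})

test_that("the standard model battery runs on the reference cohort", {
  rc <- emulateReferenceCohort(seed = 7)
  fits <- runStandardModels(rc)
  expect_equal(fits$nExcluded, 9)
  # univariable sex fit has the Table-layout rows and n = 162 minus NA
  uni <- fits$uni_sex_DSS
  expect_s4_class(uni, "SurvivalFit")
  tab <- resultTable(uni)
  expect_setequal(tab$level, c("male", "female"))
  expect_equal(sum(tab$n), 162)
  expect_equal(tab$hr[tab$level == "female"], 1)
  # multivariable CLR model: 4 adjusters + immune factor
  multi <- fits$multi_clr_category_DSS
  expect_s4_class(multi, "SurvivalFit")
  expect_setequal(unique(resultTable(multi)$variable),
                  c("clr_category", "cci_group", "tnm_group",
                    "necrosis_group", "stroma_group"))
  # protective high-CLR generator effect: low vs high HR above 1
  expect_gt(resultTable(multi)$hr[
    resultTable(multi)$variable == "clr_category" &
      resultTable(multi)$level == "low"], 1)
  # both outcomes fitted
  expect_s4_class(fits$multi_clr_category_OS, "SurvivalFit")
  expect_s4_class(fits$uni_tnm_group_OS, "SurvivalFit")
})
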