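# Independent oracles and fixture builders shared across the suite.
# These deliberately avoid the package's own code paths: distances by
# explicit loops, percentiles by counting, ROC by exhaustive scan.

# Uniform random pattern on a disc with given per-phenotype counts.
randomPattern <- function(counts, radius = 500, center = c(0, 0),
                          coreId = "c1", tumorId = "t1", ...) {
  n <- sum(counts)
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  CorePattern(coreId, data.frame(
    x = center[1] + r * cos(th), y = center[2] + r * sin(th),
    phenotype = rep(names(counts), counts)),
    tumorId = tumorId, center = center, radius = radius, ...)
}

# Brute-force G-cross: explicit all-pairs loop over the raw cell table.
bruteGcross <- function(pattern, fromType, toType, r,
                        edgeCorrection = TRUE) {
  d <- cellData(pattern)
  from <- d[d$phenotype == fromType, , drop = FALSE]
  to <- d[d$phenotype == toType, , drop = FALSE]
  ctr <- coreCenter(pattern)
  R <- coreRadius(pattern)
  hits <- 0L; elig <- 0L
  for (i in seq_len(nrow(from))) {
    if (edgeCorrection) {
      b <- R - sqrt((from$x[i] - ctr[1])^2 + (from$y[i] - ctr[2])^2)
      if (b < r) next
    }
    elig <- elig + 1L
    best <- Inf
    for (j in seq_len(nrow(to))) {
      dd <- sqrt((from$x[i] - to$x[j])^2 + (from$y[i] - to$y[j])^2)
      if (dd < best) best <- dd
    }
    if (best <= r) hits <- hits + 1L
  }
  list(value = if (elig == 0L) NA_real_ else hits / elig,
       nReference = elig)
}

# Counting-based mid-rank percentile, independent of rank().
brutePercentile <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  out <- rep(NA_real_, length(values))
  for (i in which(ok)) {
    out[i] <- 100 * (sum(values[ok] < values[i]) +
                       0.5 * sum(values[ok] == values[i])) / n
  }
  out
}

# Exhaustive ROC scan over every candidate threshold.
bruteRocCutoff <- function(values, outcome) {
  outcome <- as.logical(outcome)
  u <- sort(unique(values))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (t in cand) {
    J <- sum(values >= t & outcome) / sum(outcome) +
      sum(values < t & !outcome) / sum(!outcome) - 1
    if (is.null(best) || J > best$J + 1e-12) best <- list(cutoff = t, J = J)
  }
  best
}

# The frozen 10-tumor worked example: four components, each a
# permutation of 10, 20, ..., 100, so the mid-rank percentile of the
# value 10k is exactly 10k - 5. Hand-computed mean percentiles and
# categories (boundaries at 25 and 70 hit exactly by tumors 1 and 3).
workedExample <- function() {
  rank_mat <- rbind(
    c(2, 2, 4, 4),     # mean pct 25.0  -> low (boundary)
    c(3, 3, 3, 5),     # mean pct 30.0  -> intermediate
    c(7, 7, 8, 8),     # mean pct 70.0  -> intermediate (boundary)
    c(8, 8, 9, 9),     # mean pct 80.0  -> high
    c(1, 1, 1, 1),     # mean pct 5.0   -> low
    c(10, 10, 10, 10), # mean pct 95.0  -> high (cohort maximum)
    c(4, 5, 2, 2),     # mean pct 27.5  -> intermediate
    c(5, 4, 5, 6),     # mean pct 45.0  -> intermediate
    c(6, 9, 6, 3),     # mean pct 55.0  -> intermediate
    c(9, 6, 7, 7))     # mean pct 67.5  -> intermediate
  stopifnot(apply(rank_mat, 2, function(cc) all(sort(cc) == 1:10)))
  list(values = as.data.frame(rank_mat * 10),
       mean_percentile = c(25, 30, 70, 80, 5, 95, 27.5, 45, 55, 67.5),
       score = c("low", "intermediate", "intermediate", "high", "low",
                 "high", "intermediate", "intermediate", "intermediate",
                 "intermediate"))
}

# Small two-group cohort with known proportional hazards for recovery
# tests: binary covariate, exponential baseline, administrative censoring.
simTwoGroup <- function(n, hr, censor = 15, scale = 12) {
  x <- rep(0:1, length.out = n)
  t <- scale * (-log(runif(n)) / exp(log(hr) * x))
  data.frame(x = as.character(x),
             os_time = pmin(t, censor), os_event = as.numeric(t <= censor),
             dss_time = pmin(t, censor), dss_event = as.numeric(t <= censor),
             postoperative_death = FALSE)
}
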