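#' Mid-rank cohort percentiles
#'
#' Converts a cohort of values into percentiles on \[0, 100\] using the
#' mid-rank convention: the percentile of v is
#' 100 * (#\{values < v\} + 0.5 * #\{values = v\}) / n, so ties are treated
#' symmetrically and the mean percentile of a tie-free cohort is exactly
#' 50. Missing values receive missing percentiles and are excluded from n.
#'
#' @param values Numeric vector (one entry per tumor), `NA` allowed.
#' @return Numeric vector of percentiles, same length and order.
#' @examples
#' percentileRank(c(1, 2, 3, 4))  # 12.5 37.5 62.5 87.5
#' @export
percentileRank <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n == 0L) stop("all values are missing", call. = FALSE)
  if (n < 2L) stop("need at least 2 non-missing values", call. = FALSE)
  out <- rep(NA_real_, length(values))
  ## mid-rank: rank(ties = "average") equals count(<v) + (count(=v)+1)/2
  out[ok] <- 100 * (rank(values[ok], ties.method = "average") - 0.5) / n
  out
}

## Shared machinery of the density and proximity scores: mean of the
## available component percentiles, cut into low/intermediate/high.
.percentileMeanScore <- function(components, breaks = c(25, 70)) {
  stopifnot(is.data.frame(components) || is.matrix(components))
  components <- as.data.frame(components)
  if (any(diff(breaks) <= 0) || length(breaks) != 2L) {
    stop("'breaks' must be two increasing percentile cut points",
         call. = FALSE)
  }
  colPct <- function(v) {
    if (all(is.na(v))) rep(NA_real_, length(v)) else percentileRank(v)
  }
  pct <- vapply(components, colPct, numeric(nrow(components)))
  if (!is.matrix(pct)) pct <- matrix(pct, nrow = 1L)
  meanPct <- rowMeans(pct, na.rm = TRUE)
  meanPct[rowSums(!is.na(pct)) == 0L] <- NA_real_
  data.frame(mean_percentile = meanPct,
             score = percentileBracket(meanPct, breaks),
             n_components = rowSums(!is.na(pct)))
}

#' Three-group percentile bracket
#'
#' Maps a (mean) percentile to the low / intermediate / high brackets
#' used by the density and proximity scores: low is 0 to `breaks[1]`
#' inclusive, intermediate is above `breaks[1]` up to `breaks[2]`
#' inclusive, high is above `breaks[2]` — i.e. closed at 25, open above,
#' matching the 0–25 / >25–70 / >70–100 convention.
#'
#' @param meanPercentile Numeric percentiles in \[0, 100\], `NA` allowed.
#' @param breaks Two increasing cut points (default `c(25, 70)`).
#' @return Character vector of `"low"`, `"intermediate"`, `"high"`.
#' @examples
#' percentileBracket(c(25, 25.0001, 70, 70.0001))
#' @export
percentileBracket <- function(meanPercentile, breaks = c(25, 70)) {
  as.character(cut(meanPercentile, breaks = c(-Inf, breaks, Inf),
                   labels = c("low", "intermediate", "high"), right = TRUE))
}

#' T-cell density score
#'
#' Immunoscore-style categorization: the four cohort-wide T-cell density
#' components (CD3 and CD8, tumor center and invasive margin) are
#' converted to mid-rank percentiles and each tumor is scored by the mean
#' of its available component percentiles, cut at 25 and 70 — low
#' (0–25\], intermediate (25–70\], high (70–100\]. A tumor with all four
#' components missing gets a missing score; partially measured tumors are
#' scored from the components they have.
#'
#' @param cd3_ct,cd3_im,cd8_ct,cd8_im Numeric cohort vectors of densities
#'   (cells per mm-squared), aligned by tumor; `NA` allowed.
#' @param breaks Two percentile cut points (default `c(25, 70)`).
#' @return `data.frame` with `mean_percentile`, `score` (one of `"low"`,
#'   `"intermediate"`, `"high"` or `NA`) and `n_components`.
#' @seealso [proximityScore()], [percentileRank()]
#' @export
densityScore <- function(cd3_ct, cd3_im, cd8_ct, cd8_im,
                         breaks = c(25, 70)) {
  .percentileMeanScore(
    data.frame(cd3_ct = cd3_ct, cd3_im = cd3_im,
               cd8_ct = cd8_ct, cd8_im = cd8_im),
    breaks = breaks)
}

#' T-cell proximity score
#'
#' The same percentile machinery as [densityScore()], applied to the four
#' tumor-cell-to-T-cell G-cross values at a 20-micrometre radius (CD3 and
#' CD8, tumor center and invasive margin) instead of densities: values
#' are converted to cohort percentiles, averaged over available
#' components, and cut at 25 and 70.
#'
#' @param g_cd3_ct,g_cd3_im,g_cd8_ct,g_cd8_im Numeric cohort vectors of
#'   G-cross values in \[0, 1\], aligned by tumor; `NA` allowed.
#' @inheritParams densityScore
#' @return As [densityScore()].
#' @export
proximityScore <- function(g_cd3_ct, g_cd3_im, g_cd8_ct, g_cd8_im,
                           breaks = c(25, 70)) {
  .percentileMeanScore(
    data.frame(g_cd3_ct = g_cd3_ct, g_cd3_im = g_cd3_im,
               g_cd8_ct = g_cd8_ct, g_cd8_im = g_cd8_im),
    breaks = breaks)
}

#' Crohn's-like reaction density
#'
#' The number of Crohn's-like lymphoid aggregates at the tumor invasive
#' margin divided by the margin length, in aggregates per millimetre.
#'
#' @param clrCount Non-negative integer count(s) of aggregates.
#' @param marginLengthMm Positive margin length(s), millimetres.
#' @return Numeric density per mm.
#' @examples
#' clrDensity(21, 50)  # 0.42/mm
#' @export
clrDensity <- function(clrCount, marginLengthMm) {
  if (any(!is.na(marginLengthMm) & marginLengthMm <= 0)) {
    stop("'marginLengthMm' must be positive", call. = FALSE)
  }
  if (any(!is.na(clrCount) & clrCount < 0)) {
    stop("'clrCount' must be non-negative", call. = FALSE)
  }
  clrCount / marginLengthMm
}

#' Categorize CLR density
#'
#' Dichotomizes Crohn's-like reaction density at a cut-off (default
#' 0.42/mm, derived from ROC analysis against disease-specific survival).
#' The boundary is inclusive into `"high"`: ROC thresholds conventionally
#' classify values at or above the cut-off as positive.
#'
#' @param density Numeric densities per mm.
#' @param cutoff Cut-off per mm (default 0.42).
#' @return Character vector `"low"`/`"high"` (`NA` preserved).
#' @export
clrCategorize <- function(density, cutoff = 0.42) {
  ifelse(is.na(density), NA_character_,
         ifelse(density >= cutoff, "high", "low"))
}

#' ROC-optimal cut-off by Youden's J
#'
#' Scans every candidate threshold (midpoints between consecutive sorted
#' unique values, plus minus/plus infinity) and returns the one
#' maximizing Youden's J = sensitivity + specificity - 1, where a value
#' at or above the threshold predicts the event. Ties are broken toward
#' the smallest threshold.
#'
#' @param values Numeric marker values.
#' @param outcome Logical/0-1 event indicator, same length.
#' @return List with `cutoff`, `J`, `sensitivity`, `specificity`.
#' @examples
#' rocOptimalCutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))  # cutoff 2.5, J = 1
#' @export
rocOptimalCutoff <- function(values, outcome) {
  ok <- !is.na(values) & !is.na(outcome)
  values <- values[ok]
  outcome <- as.logical(outcome[ok])
  if (length(unique(outcome)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  u <- sort(unique(values))
  cand <- c(-Inf, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, Inf)
  nPos <- sum(outcome)
  nNeg <- sum(!outcome)
  J <- vapply(cand, function(t) {
    sens <- sum(values >= t & outcome) / nPos
    spec <- sum(values < t & !outcome) / nNeg
    sens + spec - 1
  }, numeric(1))
  best <- which.max(J)  # which.max takes the first maximum: smallest threshold
  list(cutoff = cand[best], J = J[best],
       sensitivity = sum(values >= cand[best] & outcome) / nPos,
       specificity = sum(values < cand[best] & !outcome) / nNeg)
}

#' Tertile classification of immune densities
#'
#' Distributes a cohort of densities into low / moderate / high groups at
#' the 33.33rd and 66.67th mid-rank percentiles of the full-cohort
#' distribution. Boundary values go to the lower group, and tied values
#' always share a group (so group sizes can be unequal under heavy ties).
#'
#' @param values Numeric cohort vector, `NA` allowed.
#' @return Character vector of `"low"`, `"moderate"`, `"high"` (`NA`
#'   preserved).
#' @export
tertileClassify <- function(values) {
  pct <- percentileRank(values)
  out <- ifelse(pct <= 100 / 3, "low",
                ifelse(pct <= 200 / 3, "moderate", "high"))
  out[is.na(pct)] <- NA_character_
  out
}

#' Categorize tumor-cell PD-L1 histoscore
#'
#' Brackets the PD-L1 tumor-cell histoscore into negative (< 1),
#' 1 to < 5, and >= 5.
#'
#' @param histoscore Non-negative numeric histoscores.
#' @return Character vector of `"negative"`, `"1-<5"`, `">=5"` (`NA`
#'   preserved).
#' @export
pdl1TumorCategorize <- function(histoscore) {
  ifelse(is.na(histoscore), NA_character_,
         ifelse(histoscore < 1, "negative",
                ifelse(histoscore < 5, "1-<5", ">=5")))
}

#' Score a cohort of tumor immune profiles
#'
#' Applies the full categorical scoring battery to a per-tumor profile
#' table: T-cell density score, T-cell proximity score, CLR density and
#' category (fixed cut-off or ROC-derived when `clrCutoff = "auto"`), and
#' the PD-L1 tumor-cell category. Optionally adds tertile classifications
#' for named density columns.
#'
#' @param profiles `data.frame` with columns `tumor_id`, the four density
#'   columns `cd3_ct`, `cd3_im`, `cd8_ct`, `cd8_im`, the four G-cross
#'   columns `g_cd3_ct`, `g_cd3_im`, `g_cd8_ct`, `g_cd8_im`, and
#'   optionally `clr_count`, `margin_length_mm`, `pdl1_tumor_histoscore`.
#' @param clrCutoff Numeric cut-off per mm (default 0.42) or `"auto"` to
#'   derive it by [rocOptimalCutoff()] against `dssEvent`.
#' @param dssEvent Event indicator aligned with `profiles`, required when
#'   `clrCutoff = "auto"`.
#' @param breaks Percentile cut points for the density/proximity scores.
#' @param tertileColumns Character vector of density column names to also
#'   classify into tertiles (suffix `_tertile` appended).
#' @return `data.frame`, one row per tumor: `tumor_id`, `density_score`,
#'   `proximity_score`, `clr_density_per_mm`, `clr_category`,
#'   `pdl1_tumor_category`, plus any tertile columns.
#' @export
scoreCohort <- function(profiles, clrCutoff = 0.42, dssEvent = NULL,
                        breaks = c(25, 70), tertileColumns = character(0)) {
  stopifnot(is.data.frame(profiles), "tumor_id" %in% names(profiles))
  get <- function(col) {
    if (col %in% names(profiles)) profiles[[col]]
    else rep(NA_real_, nrow(profiles))
  }
  ds <- densityScore(get("cd3_ct"), get("cd3_im"),
                     get("cd8_ct"), get("cd8_im"), breaks = breaks)
  ps <- proximityScore(get("g_cd3_ct"), get("g_cd3_im"),
                       get("g_cd8_ct"), get("g_cd8_im"), breaks = breaks)
  out <- data.frame(tumor_id = profiles$tumor_id,
                    density_score = ds$score,
                    proximity_score = ps$score)
  clrc <- get("clr_count")
  mlen <- get("margin_length_mm")
  dens <- ifelse(is.na(clrc) | is.na(mlen), NA_real_, clrDensity(clrc, mlen))
  if (identical(clrCutoff, "auto")) {
    if (is.null(dssEvent)) {
      stop("clrCutoff = \"auto\" requires 'dssEvent'", call. = FALSE)
    }
    clrCutoff <- rocOptimalCutoff(dens, dssEvent)$cutoff
  }
  out$clr_density_per_mm <- dens
  out$clr_category <- clrCategorize(dens, cutoff = clrCutoff)
  out$pdl1_tumor_category <- pdl1TumorCategorize(get("pdl1_tumor_histoscore"))
  for (col in tertileColumns) {
    out[[paste0(col, "_tertile")]] <- tertileClassify(get(col))
  }
  attr(out, "clr_cutoff") <- clrCutoff
  out
}
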