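#' Exclude postoperative deaths from a cohort
#'
#' Deaths within 30 days of surgery are considered postoperative and are
#' excluded from all survival analyses. The flag is expected in the
#' `postoperative_death` column; consistency with the overall-survival
#' clock (`os_time` at most 30/365.25 years when flagged) is checked.
#'
#' @param cohort Patient `data.frame` with a logical
#'   `postoperative_death` column.
#' @return List with `cohort` (filtered) and `nExcluded`.
#' @export
excludePostoperative <- function(cohort) {
  stopifnot(is.data.frame(cohort), "postoperative_death" %in% names(cohort))
  flag <- cohort$postoperative_death
  flag[is.na(flag)] <- FALSE
  if ("os_time" %in% names(cohort)) {
    bad <- flag & !is.na(cohort$os_time) & cohort$os_time > 30 / 365.25 + 1e-9
    if (any(bad)) {
      stop(sprintf(
        "%d record(s) flagged postoperative but os_time exceeds 30 days",
        sum(bad)), call. = FALSE)
    }
  }
  list(cohort = cohort[!flag, , drop = FALSE], nExcluded = sum(flag))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survival function, with step
#' coordinates exported for plotting and a risk table.
#'
#' @param times Follow-up times (years).
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Optional grouping factor for stratified curves.
#' @param confType Confidence-interval transform passed to
#'   [survival::survfit()] (default `"log"`).
#' @return List with `fit` (the `survfit` object), `steps` (a
#'   `data.frame` of `time`, `n_risk`, `n_event`, `surv`, `lower`,
#'   `upper`, and `group` when stratified), and `survivalAt(t)`, a
#'   function evaluating the step curve at arbitrary times.
#' @export
kmEstimate <- function(times, events, groups = NULL, confType = "log") {
  stopifnot(length(times) == length(events))
  df <- data.frame(time = times, event = as.numeric(events))
  if (is.null(groups)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df,
                             conf.type = confType)
    grp <- NULL
  } else {
    df$group <- as.factor(groups)
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df,
                             conf.type = confType)
    grp <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  steps <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv,
                      lower = fit$lower, upper = fit$upper)
  if (!is.null(grp)) steps$group <- grp
  survivalAt <- function(t) {
    if (!is.null(grp)) {
      stop("survivalAt() supports unstratified fits only", call. = FALSE)
    }
    vapply(t, function(ti) {
      idx <- which(fit$time <= ti)
      if (!length(idx)) 1 else fit$surv[max(idx)]
    }, numeric(1))
  }
  list(fit = fit, steps = steps, survivalAt = survivalAt)
}

#' Median follow-up by the reverse Kaplan-Meier technique
#'
#' Applies the Kaplan-Meier estimator with the roles of death and
#' censoring swapped (deaths become censorings), so the resulting curve
#' estimates the follow-up-time distribution; the median follow-up is the
#' first time this curve drops to 0.5 or below, with a log-log 95%
#' confidence interval.
#'
#' @param times Follow-up times (years).
#' @param osEvents Overall-survival event indicators (deaths).
#' @return List with `median`, `ciLow`, `ciHigh` (years; `NA` with
#'   `defined = FALSE` when the reversed curve never reaches 0.5, e.g.
#'   when every patient dies).
#' @export
reverseKmMedianFollowup <- function(times, osEvents) {
  df <- data.frame(time = times, cens = 1 - as.numeric(osEvents))
  fit <- survival::survfit(survival::Surv(time, cens) ~ 1, data = df,
                           conf.type = "log-log")
  tab <- summary(fit)$table
  med <- unname(tab["median"])
  list(median = med,
       ciLow = unname(tab["0.95LCL"]), ciHigh = unname(tab["0.95UCL"]),
       defined = !is.na(med))
}

#' Log-rank test between survival curves
#'
#' @param groups Grouping factor (at least two observed levels).
#' @param times Follow-up times (years).
#' @param events Event indicators.
#' @return List with `chisq`, `df`, `p`.
#' @export
logrankTest <- function(groups, times, events) {
  g <- as.factor(groups)
  if (nlevels(droplevels(g[!is.na(g)])) < 2L) {
    stop("log-rank test requires at least two groups", call. = FALSE)
  }
  df <- data.frame(time = times, event = as.numeric(events), group = g)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = dfree,
       p = pchisq(sd$chisq, dfree, lower.tail = FALSE))
}

## Resolve the outcome columns for DSS or OS.
.outcomeColumns <- function(outcome) {
  outcome <- match.arg(outcome, c("DSS", "OS"))
  if (outcome == "DSS") c(time = "dss_time", event = "dss_event")
  else c(time = "os_time", event = "os_event")
}

#' Cox proportional-hazards fit with reference-coded covariates
#'
#' Fits a Cox model by partial likelihood with Efron tie handling and
#' reports, per covariate level: n, events, hazard ratio, Wald 95%
#' confidence interval and p-value. Categorical covariates are
#' dummy-coded against the stated reference level. Levels observed with
#' zero events are reported as "No event" and their records are excluded
#' from the likelihood instead of being fitted to a divergent
#' coefficient; if that removes the reference, the first remaining level
#' becomes the reference. Non-convergence or separation raises an
#' explicit error rather than returning unstable coefficients.
#'
#' @param covariates Named list: names are cohort column names; each
#'   value is the reference level for a categorical covariate, or `NULL`
#'   for a numeric covariate.
#' @param cohort Patient `data.frame`; postoperative exclusion is assumed
#'   to have been applied already (see [excludePostoperative()]). Records
#'   missing any model variable are dropped (complete-case).
#' @param outcome `"DSS"` or `"OS"`; uses columns
#'   `dss_time`/`dss_event` or `os_time`/`os_event` (times in years).
#' @param label Model name carried into the result.
#' @return A [SurvivalFit-class] object.
#' @examples
#' \dontrun{coxFit(list(sex = "female"), cohort, outcome = "OS")}
#' @export
coxFit <- function(covariates, cohort, outcome = c("DSS", "OS"),
                   label = NULL) {
  stopifnot(is.list(covariates), length(covariates) >= 1L,
            !is.null(names(covariates)), is.data.frame(cohort))
  outcome <- match.arg(outcome)
  cols <- .outcomeColumns(outcome)
  vars <- names(covariates)
  missing_cols <- setdiff(c(vars, unname(cols)), names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(label)) label <- paste(vars, collapse = " + ")

  df <- cohort[, c(vars, unname(cols)), drop = FALSE]
  names(df)[names(df) == cols["time"]] <- ".time"
  names(df)[names(df) == cols["event"]] <- ".event"
  df$.event <- as.numeric(df$.event)
  df <- df[complete.cases(df), , drop = FALSE]

  noEvent <- list()
  for (v in vars) {
    ref <- covariates[[v]]
    if (is.null(ref)) next  # numeric covariate
    f <- factor(df[[v]])
    ev <- tapply(df$.event, f, sum)
    nn <- tapply(rep(1, nrow(df)), f, sum)
    dead_levels <- names(ev)[!is.na(ev) & ev == 0]
    if (length(dead_levels)) {
      noEvent[[v]] <- data.frame(
        variable = v, level = dead_levels,
        n = as.integer(nn[dead_levels]), events = 0L,
        hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p = NA_real_, note = "No event")
      df <- df[!df[[v]] %in% dead_levels, , drop = FALSE]
      f <- factor(df[[v]])
    }
    lev <- levels(droplevels(factor(df[[v]])))
    if (length(lev) < 2L) {
      stop(sprintf(
        "covariate '%s' is degenerate (fewer than two informative levels)",
        v), call. = FALSE)
    }
    if (!ref %in% lev) ref <- lev[1]
    df[[v]] <- stats::relevel(factor(df[[v]], levels = lev), ref = ref)
  }
  for (v in vars) {
    if (is.null(covariates[[v]]) && length(unique(df[[v]])) < 2L) {
      stop(sprintf("covariate '%s' is constant", v), call. = FALSE)
    }
  }

  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~", paste(vars, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|Loglik", conditionMessage(w))) {
        stop("Cox model did not converge (possible separation): ",
             conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    stop("Cox model shows divergent coefficients (separation suspected)",
         call. = FALSE)
  }

  sm <- summary(fit)
  coefTab <- sm$coefficients
  ciTab <- sm$conf.int
  rows <- list()
  for (v in vars) {
    if (is.null(covariates[[v]])) {  # numeric covariate: one row
      rn <- v
      rows[[v]] <- data.frame(
        variable = v, level = "(per unit)",
        n = nrow(df), events = as.integer(sum(df$.event)),
        hr = unname(ciTab[rn, "exp(coef)"]),
        ci_low = unname(ciTab[rn, "lower .95"]),
        ci_high = unname(ciTab[rn, "upper .95"]),
        p = unname(coefTab[rn, "Pr(>|z|)"]), note = "")
      next
    }
    f <- df[[v]]
    ev <- tapply(df$.event, f, sum)
    nn <- tapply(rep(1, nrow(df)), f, sum)
    lev <- levels(f)
    block <- lapply(lev, function(l) {
      if (l == lev[1]) {
        data.frame(variable = v, level = l, n = as.integer(nn[l]),
                   events = as.integer(ev[l]), hr = 1,
                   ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                   note = "reference")
      } else {
        rn <- paste0(v, l)
        data.frame(variable = v, level = l, n = as.integer(nn[l]),
                   events = as.integer(ev[l]),
                   hr = unname(ciTab[rn, "exp(coef)"]),
                   ci_low = unname(ciTab[rn, "lower .95"]),
                   ci_high = unname(ciTab[rn, "upper .95"]),
                   p = unname(coefTab[rn, "Pr(>|z|)"]), note = "")
      }
    })
    block <- do.call(rbind, block)
    if (!is.null(noEvent[[v]])) block <- rbind(block, noEvent[[v]])
    rows[[v]] <- block
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("SurvivalFit", label = label, outcome = outcome, table = tab,
      n = nrow(df), nEvents = as.integer(sum(df$.event)), fit = fit)
}

#' @rdname resultTable
setMethod("resultTable", "SurvivalFit", function(object) object@table)

setMethod("show", "SurvivalFit", function(object) {
  cat(sprintf("SurvivalFit '%s' (%s): n = %d, events = %d\n",
              object@label, object@outcome, object@n, object@nEvents))
  tab <- object@table
  tab$hr <- ifelse(tab$note == "No event", "No event",
                   ifelse(tab$note == "reference", "1 (ref)",
                          sprintf("%.2f", tab$hr)))
  tab$ci <- ifelse(is.na(tab$ci_low), "",
                   sprintf("%.2f-%.2f", tab$ci_low, tab$ci_high))
  tab$p <- ifelse(is.na(tab$p), "", format.pval(tab$p, digits = 3))
  print(tab[, c("variable", "level", "n", "events", "hr", "ci", "p")],
        row.names = FALSE)
})

#' Fit the standard prognostic model battery
#'
#' Runs the univariable Cox battery over the clinicopathological and
#' immune covariates, and four multivariable models — one per immune
#' factor (CLR category, T-cell proximity score, PD-L1+ macrophage
#' tertiles at the tumor center and invasive margin), each adjusted for
#' Charlson comorbidity index, TNM stage (I–II as reference), tumor
#' necrosis and intratumoral stroma — for both disease-specific and
#' overall survival. The cohort must already contain the score columns
#' (merge [scoreCohort()] output by `tumor_id`/`patient_id` first) and
#' postoperative deaths are excluded here.
#'
#' @param cohort Merged patient + score `data.frame`.
#' @param univariable Named list of univariable covariate specs (name ->
#'   reference level); a default battery is used when `NULL`, restricted
#'   to columns present in `cohort`.
#' @param immuneFactors Named list of immune-factor specs for the
#'   multivariable models; defaults to the four factors above.
#' @return Named list of [SurvivalFit-class] objects (one per model and
#'   outcome), plus `nExcluded`.
#' @export
runStandardModels <- function(cohort, univariable = NULL,
                              immuneFactors = NULL) {
  filt <- excludePostoperative(cohort)
  cohort <- filt$cohort
  if (is.null(univariable)) {
    univariable <- list(
      sex = "female", cci_group = "1-2", location = "left",
      t_stage = "1", n_stage = "0", tnm_group = "I-II",
      adjuvant = "no", lvi = "no", budding_group = "0-4",
      grade = "low", braf = "no", necrosis_group = "<10%",
      stroma_group = "<50%", clr_category = "high",
      proximity_score = "high", density_score = "high")
    univariable <- univariable[names(univariable) %in% names(cohort)]
  }
  adjusters <- list(cci_group = "1-2", tnm_group = "I-II",
                    necrosis_group = "<10%", stroma_group = "<50%")
  if (is.null(immuneFactors)) {
    immuneFactors <- list(
      clr_category = "high", proximity_score = "high",
      pdl1_mac_ct_tertile = "high", pdl1_mac_im_tertile = "high")
    immuneFactors <- immuneFactors[names(immuneFactors) %in% names(cohort)]
  }
  fits <- list()
  for (oc in c("DSS", "OS")) {
    for (v in names(univariable)) {
      key <- sprintf("uni_%s_%s", v, oc)
      fits[[key]] <- tryCatch(
        coxFit(univariable[v], cohort, outcome = oc,
               label = sprintf("univariable %s", v)),
        error = function(e) e)
    }
    for (v in names(immuneFactors)) {
      spec <- c(immuneFactors[v], adjusters)
      key <- sprintf("multi_%s_%s", v, oc)
      fits[[key]] <- tryCatch(
        coxFit(spec, cohort, outcome = oc,
               label = sprintf("multivariable %s", v)),
        error = function(e) e)
    }
  }
  fits$nExcluded <- filt$nExcluded
  fits
}
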