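## Named RNG sub-streams: one global seed drives a deterministic derived
## seed per stream name, so adding a generator never perturbs the draws of
## another. The derivation is a plain polynomial hash kept below 2^31.
.streamSeed <- function(seed, name) {
  s <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(name)) s <- (s * 31 + ch) %% 2147483647
  as.integer(s)
}

withStream <- function(seed, name, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    })
  }
  set.seed(.streamSeed(seed, name))
  force(expr)
}

#' Parameters for synthetic TMA-core point patterns
#'
#' Bundles the generator settings for one core's cell map. Tumor cells
#' follow a Thomas cluster process (Poisson parents, Poisson-count
#' Gaussian offspring) thinned to the core disc, emulating the clustered
#' growth of tumor epithelium. Immune cells are a mixture: a fraction
#' `rho` is placed as Gaussian offspring of randomly chosen tumor cells
#' (attraction, spread `tau`), the rest is homogeneous Poisson over the
#' disc. Marker positivity is Bernoulli per phenotype.
#'
#' Default intensities give roughly 600 tumor cells, 470 CD3+ and 240
#' CD8+ T cells per mm-squared — the order of magnitude seen in highly
#' infiltrated mismatch-repair-deficient colorectal tumors.
#'
#' @param radius Disc radius, micrometres (500 = 1-mm core).
#' @param tumorParentIntensity Cluster parents per mm-squared.
#' @param tumorOffspringMean Mean offspring per parent.
#' @param tumorSigma Offspring spread, micrometres.
#' @param immuneIntensity Named numeric vector, cells per mm-squared for
#'   the non-tumor phenotypes.
#' @param rho Attraction: fraction of immune cells placed as offspring of
#'   tumor cells, in \[0, 1\].
#' @param tau Attraction spread, micrometres.
#' @param pd1Prob PD-1 positivity probability on T cells.
#' @param pdl1ProbMacrophage,pdl1ProbTumor PD-L1 positivity probabilities.
#' @return Named list of validated parameters.
#' @export
patternParams <- function(radius = 500,
                          tumorParentIntensity = 30,
                          tumorOffspringMean = 20,
                          tumorSigma = 25,
                          immuneIntensity = c(T_CD3 = 470, T_CD8 = 240,
                                              macrophage = 180,
                                              other = 1200),
                          rho = 0, tau = 15,
                          pd1Prob = 0.3,
                          pdl1ProbMacrophage = 0.25,
                          pdl1ProbTumor = 0.1) {
  stopifnot(radius > 0, tumorParentIntensity >= 0, tumorOffspringMean >= 0,
            tumorSigma > 0, all(immuneIntensity >= 0),
            rho >= 0, rho <= 1, tau > 0)
  .checkPhenotype(names(immuneIntensity))
  list(radius = radius, tumorParentIntensity = tumorParentIntensity,
       tumorOffspringMean = tumorOffspringMean, tumorSigma = tumorSigma,
       immuneIntensity = immuneIntensity, rho = rho, tau = tau,
       pd1Prob = pd1Prob, pdl1ProbMacrophage = pdl1ProbMacrophage,
       pdl1ProbTumor = pdl1ProbTumor)
}

## Uniform points on a disc (area-correct inverse transform).
.runifDisc <- function(n, center, radius) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

#' Simulate one TMA-core cell map
#'
#' Draws a synthetic [CorePattern-class] under the model of
#' [patternParams()]: Thomas-cluster tumor cells thinned to the disc,
#' immune cells as a `rho` : (1 - `rho`) mixture of tumor-cell-attracted
#' Gaussian offspring and homogeneous Poisson points, and Bernoulli
#' marker flags. Fully deterministic given `seed`.
#'
#' @param params A [patternParams()] list.
#' @param coreId,tumorId,region,markerPanel Metadata for the resulting
#'   [CorePattern-class].
#' @param center Disc center, micrometres.
#' @param seed Integer seed (a named sub-stream of it drives each
#'   component), or `NULL` to use the current RNG state.
#' @return A [CorePattern-class].
#' @export
simulateCorePattern <- function(params = patternParams(), coreId = "core1",
                                tumorId = "tumor1", region = "CT",
                                markerPanel = "multiplex",
                                center = c(0, 0), seed = NULL) {
  gen <- function() .simulatePatternImpl(params, center)
  cells <- if (is.null(seed)) gen() else {
    withStream(seed, paste0("pattern:", tumorId, ":", coreId), gen())
  }
  CorePattern(coreId, cells, tumorId = tumorId, region = region,
              markerPanel = markerPanel, center = center,
              radius = params$radius)
}

.simulatePatternImpl <- function(params, center) {
  R <- params$radius
  areaMm2 <- pi * R^2 / 1e6
  ## Tumor cells: Thomas process. Parents live on an extended disc so
  ## clusters centred just outside still contribute; offspring are
  ## thinned to the core disc.
  extR <- R + 4 * params$tumorSigma
  extAreaMm2 <- pi * extR^2 / 1e6
  nPar <- rpois(1, params$tumorParentIntensity * extAreaMm2)
  tum <- matrix(numeric(0), ncol = 2)
  if (nPar > 0) {
    par <- .runifDisc(nPar, center, extR)
    nOff <- rpois(nPar, params$tumorOffspringMean)
    if (sum(nOff) > 0) {
      px <- rep(par[, 1], nOff)
      py <- rep(par[, 2], nOff)
      tum <- cbind(px + rnorm(sum(nOff), 0, params$tumorSigma),
                   py + rnorm(sum(nOff), 0, params$tumorSigma))
      keep <- sqrt((tum[, 1] - center[1])^2 +
                   (tum[, 2] - center[2])^2) <= R
      tum <- tum[keep, , drop = FALSE]
    }
  }
  cells <- data.frame(x = tum[, 1], y = tum[, 2],
                      phenotype = rep("tumor", nrow(tum)))
  ## Immune phenotypes: attracted fraction rho, CSR remainder.
  for (ph in names(params$immuneIntensity)) {
    lam <- params$immuneIntensity[[ph]]
    n <- rpois(1, lam * areaMm2)
    if (n == 0) next
    attracted <- if (nrow(tum) > 0) runif(n) < params$rho else rep(FALSE, n)
    pts <- matrix(NA_real_, n, 2)
    nA <- sum(attracted)
    if (nA > 0) {
      idx <- sample.int(nrow(tum), nA, replace = TRUE)
      px <- tum[idx, 1]; py <- tum[idx, 2]
      ## resample offsets falling outside the disc so realized counts
      ## keep their Poisson expectation
      ax <- px + rnorm(nA, 0, params$tau)
      ay <- py + rnorm(nA, 0, params$tau)
      for (tries in 1:100) {
        bad <- sqrt((ax - center[1])^2 + (ay - center[2])^2) > R
        if (!any(bad)) break
        ax[bad] <- px[bad] + rnorm(sum(bad), 0, params$tau)
        ay[bad] <- py[bad] + rnorm(sum(bad), 0, params$tau)
      }
      still <- sqrt((ax - center[1])^2 + (ay - center[2])^2) > R
      if (any(still)) {
        u <- .runifDisc(sum(still), center, R)
        ax[still] <- u[, 1]; ay[still] <- u[, 2]
      }
      pts[attracted, ] <- cbind(ax, ay)
    }
    if (any(!attracted)) {
      pts[!attracted, ] <- .runifDisc(sum(!attracted), center, R)
    }
    cells <- rbind(cells, data.frame(x = pts[, 1], y = pts[, 2],
                                     phenotype = rep(ph, n)))
  }
  n <- nrow(cells)
  cells$pd1 <- cells$phenotype %in% .PD1_PHENOTYPES &
    runif(n) < params$pd1Prob
  cells$pdl1 <- (cells$phenotype == "macrophage" &
                   runif(n) < params$pdl1ProbMacrophage) |
    (cells$phenotype == "tumor" & runif(n) < params$pdl1ProbTumor)
  cells
}

#' Parameters for synthetic patient cohorts
#'
#' Settings for [simulateCohort()]: cohort size, categorical covariate
#' marginals, true log hazard ratios, a Weibull baseline hazard,
#' administrative censoring, the cancer-death thinning probability that
#' turns overall-survival events into disease-specific events, a
#' postoperative-death probability, and a logistic model linking
#' covariates to metastatic status.
#'
#' Default covariate marginals follow the composition of a
#' population-based mismatch-repair-deficient colorectal cancer series:
#' elderly, two-thirds female, right-sided, mostly stage II–III.
#'
#' @param n Number of patients.
#' @param marginals Named list; each element is a named probability
#'   vector over the levels of one categorical covariate.
#' @param logHR Named list; each element is a named vector of true
#'   log hazard ratios per level (reference level 0).
#' @param weibullShape,weibullScale Baseline Weibull shape and scale
#'   (scale in years; shape 1 recovers the exponential).
#' @param censorTime Administrative censoring time, years.
#' @param cancerDeathProb Probability a death is cancer-related (thins
#'   OS events into DSS events; thinning preserves hazard ratios on the
#'   cause-specific scale).
#' @param postopProb Probability of postoperative death (within 30
#'   days of surgery).
#' @param metastasisIntercept,metastasisCoef Logistic intercept and named
#'   list of per-level coefficients for metastatic status.
#' @return Named list of validated parameters.
#' @export
cohortParams <- function(n = 171,
                         marginals = list(
                           sex = c(male = 0.32, female = 0.68),
                           tnm_group = c("I-II" = 0.65, "III" = 0.29,
                                         "IV" = 0.06),
                           cci_group = c("1-2" = 0.23, "3-4" = 0.45,
                                         ">=5" = 0.32)),
                         logHR = list(
                           tnm_group = c("I-II" = 0, "III" = log(2.5),
                                         "IV" = log(8)),
                           cci_group = c("1-2" = 0, "3-4" = log(1.8),
                                         ">=5" = log(2.5))),
                         weibullShape = 1.2, weibullScale = 14,
                         censorTime = 15,
                         cancerDeathProb = 0.4,
                         postopProb = 0.05,
                         metastasisIntercept = -1.4,
                         metastasisCoef = list()) {
  stopifnot(n >= 2, weibullShape > 0, weibullScale > 0, censorTime > 0,
            cancerDeathProb >= 0, cancerDeathProb <= 1,
            postopProb >= 0, postopProb <= 1)
  for (v in names(logHR)) {
    if (!v %in% names(marginals)) {
      stop("logHR names must be covariates present in 'marginals'",
           call. = FALSE)
    }
  }
  list(n = n, marginals = marginals, logHR = logHR,
       weibullShape = weibullShape, weibullScale = weibullScale,
       censorTime = censorTime, cancerDeathProb = cancerDeathProb,
       postopProb = postopProb,
       metastasisIntercept = metastasisIntercept,
       metastasisCoef = metastasisCoef)
}

#' Simulate a patient cohort with known ground truth
#'
#' Draws categorical covariates from their marginal distributions
#' (independently across covariates), overall-survival times from a
#' Weibull proportional-hazards model by inverse transform under the
#' specified true log hazard ratios, applies administrative censoring,
#' thins deaths into cancer-related (DSS) events by a fixed cause
#' probability, assigns metastatic status from a logistic model on the
#' covariates, and marks postoperative deaths (uniform within 30 days of
#' surgery). Deterministic given `seed`, with one named RNG sub-stream
#' per component.
#'
#' @param params A [cohortParams()] list.
#' @param seed Integer seed, or `NULL` for the current RNG state.
#' @return List with `cohort` (a `data.frame` of covariates plus
#'   `patient_id`, `metastatic`, `os_time`, `os_event`, `dss_time`,
#'   `dss_event`, `postoperative_death`; times in years) and `truth`
#'   (the generating parameters, including the true log hazard ratios).
#' @export
simulateCohort <- function(params = cohortParams(), seed = NULL) {
  run <- function(name, expr) {
    if (is.null(seed)) expr else withStream(seed, name, expr)
  }
  n <- params$n
  cov <- run("covariates", {
    out <- lapply(params$marginals, function(p) {
      sample(names(p), n, replace = TRUE, prob = p)
    })
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  lp <- rep(0, n)
  for (v in names(params$logHR)) {
    lp <- lp + unname(params$logHR[[v]][cov[[v]]])
  }
  times <- run("survival", {
    u <- runif(n)
    params$weibullScale * (-log(u) / exp(lp))^(1 / params$weibullShape)
  })
  osEvent <- as.integer(times <= params$censorTime)
  osTime <- pmin(times, params$censorTime)
  cancer <- run("cause", runif(n) < params$cancerDeathProb)
  dssEvent <- as.integer(osEvent == 1L & cancer)
  met <- run("metastasis", {
    lpm <- rep(params$metastasisIntercept, n)
    for (v in names(params$metastasisCoef)) {
      lpm <- lpm + unname(params$metastasisCoef[[v]][cov[[v]]])
    }
    runif(n) < plogis(lpm)
  })
  postop <- run("postop", runif(n) < params$postopProb)
  if (any(postop)) {
    tpo <- run("postop_time", runif(sum(postop), 0, 30 / 365.25))
    osTime[postop] <- tpo
    osEvent[postop] <- 1L
    dssEvent[postop] <- 0L  # excluded downstream by the 30-day rule anyway
  }
  cohort <- cbind(
    data.frame(patient_id = sprintf("P%04d", seq_len(n))),
    cov,
    data.frame(metastatic = ifelse(met, "yes", "no"),
               os_time = osTime, os_event = osEvent,
               dss_time = osTime, dss_event = dssEvent,
               postoperative_death = postop))
  list(cohort = cohort,
       truth = list(logHR = params$logHR, params = params,
                    nPostoperative = sum(postop)))
}

## Table-style fixed label multisets for the reference-shaped cohort.
.refMultiset <- function(counts) {
  rep(names(counts), unname(counts))
}

#' Emulate the reference dMMR cohort shape
#'
#' Produces a fixed-size cohort of 171 patients whose categorical
#' marginal counts exactly match a published population-based
#' mismatch-repair-deficient colorectal cancer series (for example 35
#' metastatic patients, 116 women, and one missing comorbidity index),
#' by permuting fixed label multisets independently across variables.
#' The Crohn's-like-reaction category and the postoperative-death flag
#' are pinned jointly with metastatic status, matching their published
#' cross-tabulations. Survival times are synthetic (Weibull with modest
#' stage effects, staggered administrative censoring): the cohort is
#' intended for pipeline smoke tests and report-shape checks, not for
#' reproducing patient-level hazard ratios — the joint covariate
#' distribution is not the real one.
#'
#' @param seed Integer seed; the same seed is bit-reproducible.
#' @return A patient `data.frame` of 171 rows with the standard
#'   clinical, score and survival columns.
#' @export
emulateReferenceCohort <- function(seed = 1) {
  n <- 171L
  marg <- list(
    age_group = c("<60" = 21, "60-80" = 95, ">80" = 55),
    sex = c(male = 55, female = 116),
    cci_group = c("1-2" = 39, "3-4" = 76, ">=5" = 55, "NA" = 1),
    location = c(right = 146, left = 25),
    t_stage = c("1" = 10, "2" = 20, "3" = 112, "4" = 29),
    n_stage = c("0" = 115, "1" = 29, "2" = 27),
    m_stage = c("0" = 160, "1" = 11),
    tnm_stage = c(I = 26, II = 85, III = 49, IV = 11),
    lvi = c(no = 149, yes = 22),
    budding_group = c("0-4" = 130, "5-9" = 22, ">=10" = 19),
    grade = c(low = 87, high = 84),
    braf = c(no = 54, yes = 117),
    necrosis_group = c("<10%" = 91, "10-<40%" = 58, ">=40%" = 22),
    stroma_group = c("<50%" = 95, ">=50%" = 76),
    density_score = c(low = 13, intermediate = 81, high = 65, "NA" = 12),
    proximity_score = c(low = 10, intermediate = 64, high = 84, "NA" = 13),
    pdl1_tumor_category = c(negative = 84, "1-<5" = 32, ">=5" = 41,
                            "NA" = 14),
    lynch = c(no = 164, yes = 7),
    adjuvant = c(no = 113, yes = 58))
  stopifnot(all(vapply(marg, sum, numeric(1)) == n))
  cohort <- data.frame(patient_id = sprintf("P%04d", seq_len(n)))
  ## metastatic status first; CLR and postoperative death are pinned
  ## within its strata
  cohort$metastatic <- withStream(seed, "ref:metastatic", {
    sample(.refMultiset(c(no = 136, yes = 35)))
  })
  for (v in names(marg)) {
    lab <- withStream(seed, paste0("ref:", v), sample(.refMultiset(marg[[v]])))
    lab[lab == "NA"] <- NA_character_
    cohort[[v]] <- lab
  }
  cohort$tnm_group <- ifelse(cohort$tnm_stage %in% c("I", "II"), "I-II",
                             cohort$tnm_stage)
  clr <- character(n)
  clr[cohort$metastatic == "no"] <- withStream(seed, "ref:clr_no", {
    sample(.refMultiset(c(low = 34, high = 102)))
  })
  clr[cohort$metastatic == "yes"] <- withStream(seed, "ref:clr_yes", {
    sample(.refMultiset(c(low = 21, high = 14)))
  })
  cohort$clr_category <- clr
  po <- logical(n)
  po[cohort$metastatic == "no"] <- withStream(seed, "ref:po_no", {
    sample(rep(c(FALSE, TRUE), c(129, 7)))
  })
  po[cohort$metastatic == "yes"] <- withStream(seed, "ref:po_yes", {
    sample(rep(c(FALSE, TRUE), c(33, 2)))
  })
  cohort$postoperative_death <- po
  ## synthetic survival: Weibull baseline with stage and CLR effects,
  ## staggered administrative censoring emulating 2000-2015 accrual with
  ## follow-up to about 2023
  surv <- withStream(seed, "ref:survival", {
    lp <- ifelse(cohort$tnm_group == "III", log(2.5),
                 ifelse(cohort$tnm_group == "IV", log(8), 0)) +
      ifelse(cohort$clr_category == "low", log(1.8), 0)
    t <- 14 * (-log(runif(n)) / exp(lp))^(1 / 1.2)
    cens <- runif(n, 8, 23)
    cancer <- runif(n) < 0.35
    list(t = t, cens = cens, cancer = cancer)
  })
  osEvent <- as.integer(surv$t <= surv$cens)
  osTime <- pmin(surv$t, surv$cens)
  osTime[po] <- withStream(seed, "ref:po_time", runif(sum(po), 0, 30 / 365.25))
  osEvent[po] <- 1L
  cohort$os_time <- osTime
  cohort$os_event <- osEvent
  cohort$dss_time <- osTime
  cohort$dss_event <- as.integer(osEvent == 1L & surv$cancer & !po)
  cohort
}
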