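#' @import methods
#' @importFrom stats chisq.test complete.cases pchisq plogis rnorm rpois
#'   runif setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

## Controlled vocabularies used throughout the package.
.PHENOTYPES <- c("tumor", "T_CD3", "T_CD8", "macrophage", "other")
.PD1_PHENOTYPES <- c("T_CD3", "T_CD8")
.PDL1_PHENOTYPES <- c("macrophage", "tumor")
.REGIONS <- c("CT", "IM")
.MARKER_PANELS <- c("CD3", "CD8", "multiplex")

#' Phenotype and region vocabularies
#'
#' Controlled label sets for cell phenotypes (exclusive classes assigned by
#' the upstream image-analysis step), tissue regions (tumor center `CT`,
#' invasive margin `IM`) and staining panels.
#'
#' @return Character vector of allowed labels.
#' @examples
#' cellPhenotypes()
#' @export
cellPhenotypes <- function() .PHENOTYPES

#' @rdname cellPhenotypes
#' @export
tissueRegions <- function() .REGIONS

#' @rdname cellPhenotypes
#' @export
markerPanels <- function() .MARKER_PANELS

#' CorePattern: the cell map of one TMA core
#'
#' An S4 container for the cell point pattern of a single 1-mm-diameter
#' tissue-microarray core: planar cell coordinates in micrometres, an
#' exclusive phenotype per cell, PD-1/PD-L1 marker flags, and the disc
#' geometry of the core. All distances computed from a `CorePattern` are
#' planar Euclidean distances in micrometres.
#'
#' @slot coreId Character scalar, unique core identifier within a tumor.
#' @slot tumorId Character scalar, identifier of the parent tumor.
#' @slot region Character scalar, `"CT"` (tumor center) or `"IM"`
#'   (invasive margin).
#' @slot markerPanel Character scalar, the stained section the core comes
#'   from: `"CD3"`, `"CD8"` or `"multiplex"`. CD3 and CD8 are separate
#'   sections, so their patterns are never merged within one geometry.
#' @slot center Numeric length-2, disc center (x, y) in micrometres.
#' @slot radius Positive numeric scalar, disc radius in micrometres
#'   (default 500, a 1-mm-diameter core).
#' @slot cells `data.frame` with columns `x`, `y` (micrometres),
#'   `phenotype` (one of [cellPhenotypes()]), `pd1`, `pdl1` (logical).
#'
#' @details Validity requires every cell to lie inside the disc (tolerance
#'   1e-6 micrometres), phenotypes to come from the controlled vocabulary,
#'   and marker flags to be `FALSE` except where biologically meaningful:
#'   PD-1 on T cells, PD-L1 on macrophages and tumor cells.
#'
#' @seealso [CorePattern()] for construction, [gcrossAtRadius()],
#'   [simulateCorePattern()]
#' @name CorePattern-class
#' @aliases CorePattern-class
#' @exportClass CorePattern
setClass("CorePattern",
  slots = c(
    coreId = "character",
    tumorId = "character",
    region = "character",
    markerPanel = "character",
    center = "numeric",
    radius = "numeric",
    cells = "data.frame"
  ),
  prototype = prototype(
    coreId = "core1", tumorId = "tumor1", region = "CT",
    markerPanel = "multiplex", center = c(0, 0), radius = 500,
    cells = data.frame(
      x = numeric(0), y = numeric(0),
      phenotype = character(0), pd1 = logical(0), pdl1 = logical(0)
    )
  )
)

setValidity("CorePattern", function(object) {
  msg <- character(0)
  if (length(object@coreId) != 1L || is.na(object@coreId)) {
    msg <- c(msg, "'coreId' must be a single non-missing string")
  }
  if (length(object@region) != 1L || !object@region %in% .REGIONS) {
    msg <- c(msg, sprintf("'region' must be one of %s",
                          paste(.REGIONS, collapse = ", ")))
  }
  if (length(object@markerPanel) != 1L ||
      !object@markerPanel %in% .MARKER_PANELS) {
    msg <- c(msg, sprintf("'markerPanel' must be one of %s",
                          paste(.MARKER_PANELS, collapse = ", ")))
  }
  if (length(object@center) != 2L || anyNA(object@center)) {
    msg <- c(msg, "'center' must be a numeric (x, y) pair")
  }
  if (length(object@radius) != 1L || is.na(object@radius) ||
      object@radius <= 0) {
    msg <- c(msg, "'radius' must be a single positive number")
  }
  cells <- object@cells
  need <- c("x", "y", "phenotype", "pd1", "pdl1")
  if (!all(need %in% names(cells))) {
    msg <- c(msg, sprintf("'cells' must have columns %s",
                          paste(need, collapse = ", ")))
    return(if (length(msg)) msg else TRUE)
  }
  bad_ph <- setdiff(unique(as.character(cells$phenotype)), .PHENOTYPES)
  if (length(bad_ph)) {
    msg <- c(msg, sprintf("unknown phenotype label(s): %s",
                          paste(bad_ph, collapse = ", ")))
  }
  if (nrow(cells)) {
    d <- sqrt((cells$x - object@center[1])^2 + (cells$y - object@center[2])^2)
    out <- which(d > object@radius + 1e-6)
    if (length(out)) {
      msg <- c(msg, sprintf(
        "%d cell(s) lie outside the core disc (first at row %d, distance %.3f > radius %.3f)",
        length(out), out[1], d[out[1]], object@radius))
    }
    if (any(cells$pd1 & !cells$phenotype %in% .PD1_PHENOTYPES)) {
      msg <- c(msg, "pd1 flag set on a phenotype other than T_CD3/T_CD8")
    }
    if (any(cells$pdl1 & !cells$phenotype %in% .PDL1_PHENOTYPES)) {
      msg <- c(msg, "pdl1 flag set on a phenotype other than macrophage/tumor")
    }
  }
  if (length(msg)) msg else TRUE
})

#' GCrossValue: a cross-type nearest-neighbour proportion
#'
#' The G-cross statistic evaluated at one radius: the proportion of
#' reference ("from") cells whose nearest cell of the target ("to")
#' phenotype lies within distance `radius`. `value` is `NA` when no
#' eligible reference cells exist (missing, never silently zero).
#'
#' @slot fromType,toType Character scalars, phenotypes.
#' @slot radius Positive numeric scalar, micrometres.
#' @slot value Numeric scalar in \[0, 1\] or `NA`.
#' @slot nReference Integer, number of eligible reference cells.
#' @seealso [gcrossAtRadius()]
#' @name GCrossValue-class
#' @aliases GCrossValue-class
#' @exportClass GCrossValue
setClass("GCrossValue",
  slots = c(
    fromType = "character", toType = "character",
    radius = "numeric", value = "numeric", nReference = "integer"
  )
)

setValidity("GCrossValue", function(object) {
  msg <- character(0)
  if (length(object@radius) != 1L || object@radius <= 0) {
    msg <- c(msg, "'radius' must be a single positive number")
  }
  v <- object@value
  if (length(v) != 1L || (!is.na(v) && (v < 0 || v > 1))) {
    msg <- c(msg, "'value' must be a single number in [0, 1] or NA")
  }
  if (length(object@nReference) != 1L || is.na(object@nReference) ||
      object@nReference < 0L) {
    msg <- c(msg, "'nReference' must be a single non-negative integer")
  }
  if (length(msg)) msg else TRUE
})

#' ContingencyResult: a cross-tabulation with a Pearson chi-square test
#'
#' Counts, column percentages (rounded half away from zero to integers)
#' and the Pearson chi-square test (no continuity correction) for a pair
#' of categorical variables; missing values are excluded pairwise and
#' counted in `nMissing`.
#'
#' @slot rowVar,colVar Character scalars, variable names.
#' @slot counts Integer matrix of cross-tabulated counts.
#' @slot colPercent Numeric matrix, per-column percentages.
#' @slot statistic,df,p.value Chi-square statistic, degrees of freedom
#'   and asymptotic p-value (`NA` when undefined, e.g. one observed level).
#' @slot nMissing Integer, observations dropped for missingness.
#' @slot warning Character, non-empty when expected counts are small.
#' @seealso [crosstab()]
#' @name ContingencyResult-class
#' @aliases ContingencyResult-class
#' @exportClass ContingencyResult
setClass("ContingencyResult",
  slots = c(
    rowVar = "character", colVar = "character",
    counts = "matrix", colPercent = "matrix",
    statistic = "numeric", df = "numeric", p.value = "numeric",
    nMissing = "integer", warning = "character"
  )
)

#' SurvivalFit: a fitted Cox proportional-hazards model
#'
#' Hazard ratios with Wald 95% confidence intervals and p-values for a
#' named model specification, one row per covariate level. Reference
#' levels carry HR 1 with no interval; levels observed with zero events
#' are reported as "No event" and excluded from the partial likelihood
#' rather than fitted to an infinite coefficient.
#'
#' @slot label Character scalar, model name.
#' @slot outcome Character scalar, `"DSS"` or `"OS"`.
#' @slot table `data.frame` with columns `variable`, `level`, `n`,
#'   `events`, `hr`, `ci_low`, `ci_high`, `p`, `note`.
#' @slot n,nEvents Cohort size and event count after filtering.
#' @slot fit The underlying [survival::coxph()] fit (or `NULL`).
#' @seealso [coxFit()]
#' @name SurvivalFit-class
#' @aliases SurvivalFit-class
#' @exportClass SurvivalFit
setClass("SurvivalFit",
  slots = c(
    label = "character", outcome = "character",
    table = "data.frame", n = "integer", nEvents = "integer",
    fit = "ANY"
  )
)
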