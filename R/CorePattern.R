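#' Construct a CorePattern
#'
#' Builds the validated cell map of one TMA core from per-cell coordinates
#' and phenotype labels.
#'
#' @param coreId Core identifier (unique within a tumor).
#' @param cells `data.frame` with columns `x`, `y` (micrometres),
#'   `phenotype`, and optionally `pd1`, `pdl1` (logical; default `FALSE`).
#' @param tumorId Parent tumor identifier.
#' @param region `"CT"` (tumor center) or `"IM"` (invasive margin).
#' @param markerPanel `"CD3"`, `"CD8"` or `"multiplex"` — the stained
#'   section the core image comes from.
#' @param center Disc center (x, y), micrometres.
#' @param radius Disc radius, micrometres; the default 500 corresponds to
#'   the standard 1-mm-diameter core.
#' @return A [CorePattern-class] object.
#' @examples
#' cp <- CorePattern("c1", data.frame(
#'   x = c(0, 3), y = c(0, 4),
#'   phenotype = c("tumor", "T_CD3")))
#' nCells(cp, "tumor")
#' @export
CorePattern <- function(coreId, cells, tumorId = "tumor1", region = "CT",
                        markerPanel = "multiplex", center = c(0, 0),
                        radius = 500) {
  cells <- as.data.frame(cells)
  if (is.null(cells$pd1)) cells$pd1 <- FALSE
  if (is.null(cells$pdl1)) cells$pdl1 <- FALSE
  cells$phenotype <- as.character(cells$phenotype)
  cells$pd1 <- as.logical(cells$pd1)
  cells$pdl1 <- as.logical(cells$pdl1)
  rownames(cells) <- NULL
  new("CorePattern",
      coreId = as.character(coreId), tumorId = as.character(tumorId),
      region = region, markerPanel = markerPanel,
      center = as.numeric(center), radius = as.numeric(radius),
      cells = cells[, c("x", "y", "phenotype", "pd1", "pdl1")])
}

#' @rdname accessors
setMethod("coreId", "CorePattern", function(object) object@coreId)

#' @rdname accessors
setMethod("tumorId", "CorePattern", function(object) object@tumorId)

#' @rdname accessors
setMethod("coreRegion", "CorePattern", function(object) object@region)

#' @rdname accessors
setMethod("markerPanel", "CorePattern", function(object) object@markerPanel)

#' @rdname accessors
setMethod("coreCenter", "CorePattern", function(object) object@center)

#' @rdname accessors
setMethod("coreRadius", "CorePattern", function(object) object@radius)

#' @rdname accessors
setMethod("cellData", "CorePattern", function(object) object@cells)

#' @rdname accessors
setMethod("nCells", "CorePattern", function(object, phenotype = NULL) {
  if (is.null(phenotype)) return(nrow(object@cells))
  .checkPhenotype(phenotype)
  sum(object@cells$phenotype == phenotype)
})

#' @rdname accessors
setMethod("gcrossValue", "GCrossValue", function(object) object@value)

#' @rdname accessors
setMethod("nReference", "GCrossValue", function(object) object@nReference)

setMethod("show", "CorePattern", function(object) {
  tab <- table(factor(object@cells$phenotype, levels = .PHENOTYPES))
  cat(sprintf(
    "CorePattern '%s' (tumor %s, %s, %s panel)\n  disc r = %g um at (%g, %g); %d cells\n",
    object@coreId, object@tumorId, object@region, object@markerPanel,
    object@radius, object@center[1], object@center[2], nrow(object@cells)))
  cat("  ", paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                  collapse = ", "), "\n", sep = "")
})

setMethod("show", "GCrossValue", function(object) {
  cat(sprintf("G-cross %s -> %s at r = %g um: %s (n_ref = %d)\n",
              object@fromType, object@toType, object@radius,
              ifelse(is.na(object@value), "NA (no eligible reference cells)",
                     sprintf("%.4f", object@value)),
              object@nReference))
})

.checkPhenotype <- function(x) {
  bad <- setdiff(as.character(x), .PHENOTYPES)
  if (length(bad)) {
    stop("unknown phenotype label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(.PHENOTYPES, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}
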