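#' Accessors for CorePattern and GCrossValue objects
#'
#' Slot accessors for the spatial containers: core/tumor identifiers,
#' disc geometry, the per-cell table, cell counts per phenotype, and the
#' components of a [GCrossValue-class] result.
#'
#' @param object A [CorePattern-class] or [GCrossValue-class] object.
#' @param phenotype Optional phenotype label to count.
#' @return The corresponding slot value; `nCells()` returns an integer
#'   count, `cellData()` the per-cell `data.frame`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("coreId", function(object) standardGeneric("coreId"))

#' @rdname accessors
#' @export
setGeneric("tumorId", function(object) standardGeneric("tumorId"))

#' @rdname accessors
#' @export
setGeneric("coreRegion", function(object) standardGeneric("coreRegion"))

#' @rdname accessors
#' @export
setGeneric("markerPanel", function(object) standardGeneric("markerPanel"))

#' @rdname accessors
#' @export
setGeneric("coreCenter", function(object) standardGeneric("coreCenter"))

#' @rdname accessors
#' @export
setGeneric("coreRadius", function(object) standardGeneric("coreRadius"))

#' @rdname accessors
#' @export
setGeneric("cellData", function(object) standardGeneric("cellData"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(object, phenotype = NULL) {
  standardGeneric("nCells")
})

#' @rdname accessors
#' @export
setGeneric("gcrossValue", function(object) standardGeneric("gcrossValue"))

#' @rdname accessors
#' @export
setGeneric("nReference", function(object) standardGeneric("nReference"))

#' Tidy extraction of result tables
#'
#' @param object A [SurvivalFit-class] or [ContingencyResult-class] object.
#' @return A `data.frame` representation of the fitted model or table.
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))
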