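## Round half away from zero to integers (printed-table style).
.roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Cross-tabulate two categorical variables with a Pearson chi-square test
#'
#' Builds the contingency table of `rowVar` by `colVar`, computes column
#' percentages rounded half away from zero to integers, and tests
#' association with Pearson's chi-square statistic without continuity
#' correction and an asymptotic p-value (no exact-test fallback; small
#' expected counts produce a warning note instead of a method switch).
#' Records missing either variable are excluded pairwise and counted.
#'
#' @param cohort `data.frame`.
#' @param rowVar,colVar Column names of categorical variables.
#' @param rowLevels,colLevels Optional level orders.
#' @return A [ContingencyResult-class].
#' @examples
#' d <- data.frame(clr = rep(c("low", "high"), c(55, 116)),
#'                 met = c(rep(c("no", "yes"), c(34, 21)),
#'                         rep(c("no", "yes"), c(102, 14))))
#' crosstab(d, "clr", "met")
#' @export
crosstab <- function(cohort, rowVar, colVar,
                     rowLevels = NULL, colLevels = NULL) {
  stopifnot(is.data.frame(cohort),
            all(c(rowVar, colVar) %in% names(cohort)))
  r <- cohort[[rowVar]]
  cc <- cohort[[colVar]]
  keep <- !is.na(r) & !is.na(cc)
  nMissing <- sum(!keep)
  r <- if (is.null(rowLevels)) factor(r[keep]) else {
    factor(r[keep], levels = rowLevels)
  }
  cc <- if (is.null(colLevels)) factor(cc[keep]) else {
    factor(cc[keep], levels = colLevels)
  }
  counts <- table(r, cc)
  counts <- unclass(counts)
  names(dimnames(counts)) <- NULL
  pct <- sweep(counts, 2, colSums(counts), "/") * 100
  pct[, colSums(counts) == 0] <- NA_real_
  pct <- .roundHalfUp(pct)
  warn <- character(0)
  if (nrow(counts) < 2L || ncol(counts) < 2L ||
      any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stat <- NA_real_; dfree <- NA_real_; p <- NA_real_
    warn <- "chi-square undefined: a variable has fewer than two observed levels"
  } else {
    ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
    stat <- unname(ct$statistic)
    dfree <- unname(ct$parameter)
    p <- unname(ct$p.value)
    if (any(ct$expected < 5)) {
      warn <- "some expected counts are below 5; asymptotic p-value may be inaccurate"
    }
  }
  new("ContingencyResult", rowVar = rowVar, colVar = colVar,
      counts = counts, colPercent = pct,
      statistic = stat, df = as.numeric(dfree), p.value = p,
      nMissing = as.integer(nMissing),
      warning = if (length(warn)) warn else character(0))
}

#' @rdname resultTable
setMethod("resultTable", "ContingencyResult", function(object) {
  out <- data.frame(variable = object@rowVar,
                    level = rownames(object@counts),
                    stringsAsFactors = FALSE)
  for (j in colnames(object@counts)) {
    out[[paste0(j, "_n")]] <- object@counts[, j]
    out[[paste0(j, "_pct")]] <- object@colPercent[, j]
  }
  out$p <- c(object@p.value, rep(NA_real_, nrow(out) - 1L))
  rownames(out) <- NULL
  out
})

setMethod("show", "ContingencyResult", function(object) {
  cat(sprintf("ContingencyResult: %s x %s (n = %d, missing = %d)\n",
              object@rowVar, object@colVar, sum(object@counts),
              object@nMissing))
  disp <- matrix(sprintf("%d (%s)", object@counts,
                         ifelse(is.na(object@colPercent), "-",
                                object@colPercent)),
                 nrow = nrow(object@counts),
                 dimnames = dimnames(object@counts))
  print(disp, quote = FALSE)
  if (!is.na(object@statistic)) {
    cat(sprintf("Pearson chi-square = %.3f, df = %d, p = %s\n",
                object@statistic, as.integer(object@df),
                format.pval(object@p.value, digits = 3)))
  } else {
    cat("chi-square undefined\n")
  }
  if (length(object@warning)) cat("note:", object@warning, "\n")
})

#' Multi-variable association report
#'
#' Stacks [crosstab()] results for a list of row variables against one
#' column variable (e.g. clinicopathological variables by metastatic
#' status), in the given order, with per-variable chi-square p-values and
#' a significance flag at p < 0.05.
#'
#' @param cohort `data.frame`.
#' @param variables Character vector of row-variable column names, or a
#'   named list mapping names to level orders.
#' @param colVar Column variable name.
#' @param colLevels Optional level order for `colVar`.
#' @return List with `table` (stacked tidy `data.frame` adding
#'   `significant` and per-variable `n_missing`) and `results` (the
#'   underlying [ContingencyResult-class] objects, in order).
#' @export
associationReport <- function(cohort, variables, colVar,
                              colLevels = NULL) {
  if (!is.list(variables)) {
    variables <- setNames(vector("list", length(variables)), variables)
  }
  results <- lapply(names(variables), function(v) {
    crosstab(cohort, v, colVar, rowLevels = variables[[v]],
             colLevels = colLevels)
  })
  names(results) <- names(variables)
  tabs <- lapply(results, function(res) {
    tt <- resultTable(res)
    tt$n_missing <- res@nMissing
    tt$significant <- !is.na(res@p.value) & res@p.value < 0.05
    tt
  })
  list(table = do.call(rbind, c(tabs, make.row.names = FALSE)),
       results = results)
}
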