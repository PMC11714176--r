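#' Nearest cross-type distances within a core
#'
#' For every cell of phenotype `fromType`, the planar Euclidean distance
#' (micrometres) to its nearest cell of phenotype `toType`. This is the
#' elementary quantity behind the G-cross statistic.
#'
#' @param pattern A [CorePattern-class].
#' @param fromType,toType Distinct phenotype labels.
#' @return Numeric vector, one distance per `fromType` cell (in the order
#'   the cells appear in [cellData()]). When no `toType` cell exists all
#'   distances are `Inf`. An empty pattern yields `numeric(0)`.
#' @examples
#' cp <- CorePattern("c1", data.frame(
#'   x = c(0, 3), y = c(0, 4), phenotype = c("tumor", "T_CD3")))
#' nearestCrossDistances(cp, "tumor", "T_CD3")  # 3-4-5 triangle: 5
#' @export
nearestCrossDistances <- function(pattern, fromType, toType) {
  stopifnot(is(pattern, "CorePattern"))
  .checkPhenotype(c(fromType, toType))
  if (fromType == toType) {
    stop("'fromType' and 'toType' must differ", call. = FALSE)
  }
  cells <- pattern@cells
  from <- cells[cells$phenotype == fromType, c("x", "y"), drop = FALSE]
  to <- cells[cells$phenotype == toType, c("x", "y"), drop = FALSE]
  nf <- nrow(from)
  if (nf == 0L) return(numeric(0))
  if (nrow(to) == 0L) return(rep(Inf, nf))
  ## all-pairs squared distances, vectorized; cores hold O(10^3) cells
  dx <- outer(from$x, to$x, "-")
  dy <- outer(from$y, to$y, "-")
  sqrt(.rowMins(dx * dx + dy * dy))
}

.rowMins <- function(m) {
  if (ncol(m) == 1L) return(as.numeric(m))
  do.call(pmin, as.data.frame(m))
}

#' G-cross value at a fixed radius
#'
#' The proportion of reference-phenotype cells having at least one cell of
#' the target phenotype within radius `r` — the cross-type
#' nearest-neighbour distance distribution function G evaluated at `r`.
#' With `edgeCorrection = TRUE` (minus-sampling, the default), only
#' reference cells at least `r` away from the disc boundary are eligible,
#' which makes the estimator unbiased for a stationary target process;
#' the uncorrected mode uses every reference cell and is provided for
#' sensitivity checks.
#'
#' @inheritParams nearestCrossDistances
#' @param r Radius in micrometres (default 20).
#' @param edgeCorrection Logical; apply minus-sampling (default `TRUE`).
#' @return A [GCrossValue-class]. When zero reference cells are eligible
#'   the value is `NA` (missing propagates into downstream scores). When
#'   reference cells exist but the target phenotype is absent the value is
#'   0: a tumor without T cells is a minimal-proximity tumor, not a
#'   missing one.
#' @examples
#' cp <- CorePattern("c1", data.frame(
#'   x = c(0, 10), y = c(0, 0), phenotype = c("tumor", "T_CD3")))
#' gcrossAtRadius(cp, "tumor", "T_CD3", r = 20)
#' @export
gcrossAtRadius <- function(pattern, fromType = "tumor", toType = "T_CD3",
                           r = 20, edgeCorrection = TRUE) {
  stopifnot(is(pattern, "CorePattern"))
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0) {
    stop("'r' must be a single positive radius in micrometres",
         call. = FALSE)
  }
  d <- nearestCrossDistances(pattern, fromType, toType)
  eligible <- rep(TRUE, length(d))
  if (edgeCorrection && length(d)) {
    cells <- pattern@cells
    from <- cells[cells$phenotype == fromType, c("x", "y"), drop = FALSE]
    dcent <- sqrt((from$x - pattern@center[1])^2 +
                  (from$y - pattern@center[2])^2)
    eligible <- (pattern@radius - dcent) >= r
  }
  n <- sum(eligible)
  val <- if (n == 0L) NA_real_ else sum(d[eligible] <= r) / n
  new("GCrossValue", fromType = fromType, toType = toType,
      radius = as.numeric(r), value = val, nReference = as.integer(n))
}

#' Pooled G-cross profile of one tumor
#'
#' Computes the tumor-cell-to-T-cell G-cross value at radius `r` for each
#' marker (CD3, CD8) and region (CT, IM), pooling a tumor's replicate
#' cores. Distances are never computed across cores: each core is
#' evaluated within its own geometry and the region value is the
#' reference-cell-count-weighted mean of the per-core values, so larger
#' tumor-cell populations contribute proportionally. Cores whose value is
#' missing (zero eligible reference cells) reduce the weight; when every
#' core of a combination is missing or absent the entry is `NA`.
#'
#' @param patterns List of [CorePattern-class] objects belonging to one
#'   tumor; CD3 and CD8 are separate stained sections, so cores are
#'   matched by `markerPanel`.
#' @param r Radius in micrometres (default 20).
#' @param edgeCorrection Passed to [gcrossAtRadius()].
#' @return `data.frame` with columns `marker`, `region`, `value`,
#'   `n_reference`, `n_cores`.
#' @export
tumorGcrossProfile <- function(patterns, r = 20, edgeCorrection = TRUE) {
  stopifnot(all(vapply(patterns, is, logical(1), "CorePattern")))
  grid <- expand.grid(marker = c("CD3", "CD8"), region = .REGIONS,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    marker <- grid$marker[i]
    region <- grid$region[i]
    toType <- if (marker == "CD3") "T_CD3" else "T_CD8"
    sel <- Filter(function(p) p@markerPanel == marker && p@region == region,
                  patterns)
    vals <- lapply(sel, gcrossAtRadius, fromType = "tumor", toType = toType,
                   r = r, edgeCorrection = edgeCorrection)
    v <- vapply(vals, gcrossValue, numeric(1))
    w <- vapply(vals, nReference, integer(1))
    ok <- !is.na(v) & w > 0L
    data.frame(
      marker = marker, region = region,
      value = if (any(ok)) sum(v[ok] * w[ok]) / sum(w[ok]) else NA_real_,
      n_reference = sum(w[ok]), n_cores = length(sel))
  })
  do.call(rbind, out)
}

#' Per-tumor density and proximity profiles from cell maps
#'
#' Summarizes a collection of core patterns into one row per tumor:
#' CD3+/CD8+ T-cell densities (cells per mm-squared of core area) at the
#' tumor center and invasive margin, and the pooled G-cross values at
#' radius `r` for the same four marker-by-region combinations. Densities
#' pool a region's cores as total cells over total core area; G-cross
#' values pool as in [tumorGcrossProfile()].
#'
#' @param patterns List of [CorePattern-class] objects, possibly spanning
#'   many tumors.
#' @param r G-cross radius in micrometres (default 20).
#' @param edgeCorrection Passed to [gcrossAtRadius()].
#' @return `data.frame` with columns `tumor_id`, `cd3_ct`, `cd3_im`,
#'   `cd8_ct`, `cd8_im` (densities), `g_cd3_ct`, `g_cd3_im`, `g_cd8_ct`,
#'   `g_cd8_im` (G-cross values, `NA` when not measurable).
#' @export
tumorProfiles <- function(patterns, r = 20, edgeCorrection = TRUE) {
  stopifnot(all(vapply(patterns, is, logical(1), "CorePattern")))
  ids <- vapply(patterns, tumorId, character(1))
  out <- lapply(split(patterns, ids), function(pats) {
    dens <- vapply(c(CD3 = "CD3", CD8 = "CD8"), function(marker) {
      toType <- if (marker == "CD3") "T_CD3" else "T_CD8"
      vapply(.REGIONS, function(region) {
        sel <- Filter(function(p) {
          p@markerPanel == marker && p@region == region
        }, pats)
        if (!length(sel)) return(NA_real_)
        ncell <- sum(vapply(sel, nCells, integer(1), phenotype = toType))
        area <- sum(vapply(sel, function(p) pi * p@radius^2, numeric(1)))
        ncell / (area / 1e6)  # um^2 -> mm^2
      }, numeric(1))
    }, numeric(2))
    gx <- tumorGcrossProfile(pats, r = r, edgeCorrection = edgeCorrection)
    gval <- function(m, reg) gx$value[gx$marker == m & gx$region == reg]
    data.frame(
      tumor_id = tumorId(pats[[1]]),
      cd3_ct = dens["CT", "CD3"], cd3_im = dens["IM", "CD3"],
      cd8_ct = dens["CT", "CD8"], cd8_im = dens["IM", "CD8"],
      g_cd3_ct = gval("CD3", "CT"), g_cd3_im = gval("CD3", "IM"),
      g_cd8_ct = gval("CD8", "CT"), g_cd8_im = gval("CD8", "IM"))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
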