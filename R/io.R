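.CELL_COLUMNS <- c("core_id", "tumor_id", "region", "marker_panel",
                   "x_um", "y_um", "phenotype", "pd1", "pdl1")
.GEOM_COLUMNS <- c("core_id", "center_x_um", "center_y_um", "radius_um")

#' Read a cell table into CorePattern objects
#'
#' Reads the tab-delimited per-cell export (one row per cell: core and
#' tumor identifiers, region, marker panel, coordinates in micrometres,
#' phenotype, PD-1/PD-L1 flags) together with a core-geometry table, and
#' assembles one validated [CorePattern-class] per core. Schema
#' violations — missing columns, unknown phenotype or region labels,
#' cells outside their core disc — raise errors naming the offending row.
#'
#' @param path Cell-table file (tab-delimited, header mandatory).
#' @param geometryPath Core-geometry file with columns `core_id`,
#'   `center_x_um`, `center_y_um`, `radius_um`; when `NULL`, every core
#'   gets the default 500-micrometre disc centred at the origin.
#' @return Named list of [CorePattern-class] objects (by `core_id`).
#' @seealso [writeCellTable()]
#' @export
readCellTable <- function(path, geometryPath = NULL) {
  if (!file.exists(path)) stop("cell table not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(.CELL_COLUMNS, names(tab))
  if (length(miss)) {
    stop("cell table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  badPh <- which(!tab$phenotype %in% .PHENOTYPES)
  if (length(badPh)) {
    stop(sprintf("unknown phenotype '%s' at row %d of %s",
                 tab$phenotype[badPh[1]], badPh[1], path), call. = FALSE)
  }
  badRg <- which(!tab$region %in% .REGIONS)
  if (length(badRg)) {
    stop(sprintf("unknown region '%s' at row %d of %s",
                 tab$region[badRg[1]], badRg[1], path), call. = FALSE)
  }
  geom <- NULL
  if (!is.null(geometryPath)) {
    geom <- read.delim(geometryPath, stringsAsFactors = FALSE)
    miss <- setdiff(.GEOM_COLUMNS, names(geom))
    if (length(miss)) {
      stop("geometry table lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  tab$.row <- seq_len(nrow(tab))
  out <- lapply(split(tab, tab$core_id), function(d) {
    cid <- d$core_id[1]
    center <- c(0, 0); radius <- 500
    if (!is.null(geom)) {
      g <- geom[geom$core_id == cid, , drop = FALSE]
      if (nrow(g) != 1L) {
        stop("geometry table must have exactly one row for core ", cid,
             call. = FALSE)
      }
      center <- c(g$center_x_um, g$center_y_um)
      radius <- g$radius_um
    }
    dcent <- sqrt((d$x_um - center[1])^2 + (d$y_um - center[2])^2)
    bad <- which(dcent > radius + 1e-6)
    if (length(bad)) {
      stop(sprintf(
        "cell at row %d of %s lies outside core '%s' (distance %.3f um > radius %.3f um)",
        d$.row[bad[1]], path, cid, dcent[bad[1]], radius), call. = FALSE)
    }
    CorePattern(cid,
                data.frame(x = d$x_um, y = d$y_um, phenotype = d$phenotype,
                           pd1 = as.logical(d$pd1),
                           pdl1 = as.logical(d$pdl1)),
                tumorId = d$tumor_id[1], region = d$region[1],
                markerPanel = d$marker_panel[1], center = center,
                radius = radius)
  })
  out[order(names(out))]
}

#' Write CorePattern objects to a cell table
#'
#' Inverse of [readCellTable()]: serializes a list of patterns to the
#' tab-delimited cell-table format and, optionally, the matching
#' core-geometry table. A write-then-read round trip reproduces all
#' fields.
#'
#' @param patterns List of [CorePattern-class] objects.
#' @param path Output cell-table file.
#' @param geometryPath Optional output geometry file.
#' @return Invisibly, the cell `data.frame` written.
#' @export
writeCellTable <- function(patterns, path, geometryPath = NULL) {
  stopifnot(all(vapply(patterns, is, logical(1), "CorePattern")))
  rows <- lapply(patterns, function(p) {
    d <- cellData(p)
    if (!nrow(d)) return(NULL)
    data.frame(core_id = coreId(p), tumor_id = tumorId(p),
               region = coreRegion(p), marker_panel = markerPanel(p),
               x_um = d$x, y_um = d$y, phenotype = d$phenotype,
               pd1 = d$pd1, pdl1 = d$pdl1)
  })
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(geometryPath)) {
    geom <- do.call(rbind, lapply(patterns, function(p) {
      data.frame(core_id = coreId(p), center_x_um = coreCenter(p)[1],
                 center_y_um = coreCenter(p)[2], radius_um = coreRadius(p))
    }))
    write.table(geom, geometryPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(tab)
}

.PATIENT_VOCAB <- list(
  sex = c("male", "female"),
  region = .REGIONS,
  tnm_stage = c("I", "II", "III", "IV"),
  metastatic = c("no", "yes"),
  density_score = c("low", "intermediate", "high"),
  proximity_score = c("low", "intermediate", "high"),
  clr_category = c("low", "high"))

#' Read and write patient tables
#'
#' Tab-delimited clinical tables, one row per patient: demographics,
#' comorbidity and stage groups, histology, score columns, survival
#' times (years) and event flags. Reading validates the controlled
#' vocabularies of any score/stage columns present (errors name the row)
#' and coerces flags; the 30-day postoperative rule is applied by the
#' analysis functions, never at read time.
#'
#' @param path File path.
#' @param cohort Patient `data.frame` (for writing).
#' @return `readPatientTable()`: a patient `data.frame`;
#'   `writePatientTable()`: the path, invisibly.
#' @export
readPatientTable <- function(path) {
  if (!file.exists(path)) {
    stop("patient table not found: ", path, call. = FALSE)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"patient_id" %in% names(tab)) {
    stop("patient table lacks a 'patient_id' column", call. = FALSE)
  }
  for (v in intersect(names(.PATIENT_VOCAB), names(tab))) {
    bad <- which(!is.na(tab[[v]]) & !tab[[v]] %in% .PATIENT_VOCAB[[v]])
    if (length(bad)) {
      stop(sprintf("unknown level '%s' in column '%s' at row %d of %s",
                   tab[[v]][bad[1]], v, bad[1], path), call. = FALSE)
    }
  }
  for (v in intersect(c("os_time", "dss_time"), names(tab))) {
    if (any(!is.na(tab[[v]]) & tab[[v]] < 0)) {
      stop("negative survival time in column ", v, call. = FALSE)
    }
  }
  if ("postoperative_death" %in% names(tab)) {
    tab$postoperative_death <- as.logical(tab$postoperative_death)
  }
  tab
}

#' @rdname readPatientTable
#' @export
writePatientTable <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects the settings of a full simulate/score/analyze run. Percentile
#' breaks must be strictly increasing inside (0, 100); the CLR cut-off is
#' a density per mm or `"auto"` to re-derive it from the cohort by ROC.
#'
#' @param cellTable,coreGeometry,patientTable Input paths.
#' @param outputDir Output directory (created if needed).
#' @param gcrossRadius G-cross radius, micrometres.
#' @param percentileBreaks Two increasing percentile cut points.
#' @param clrCutoff Numeric per-mm cut-off or `"auto"`.
#' @param tertileColumns Density columns to tertile-classify.
#' @param seed Integer seed recorded in the manifest.
#' @param verbose Log stage counts to the console.
#' @return Validated config list.
#' @export
pipelineConfig <- function(cellTable, patientTable, coreGeometry = NULL,
                           outputDir = "tme-output", gcrossRadius = 20,
                           percentileBreaks = c(25, 70), clrCutoff = 0.42,
                           tertileColumns = character(0), seed = 1L,
                           verbose = TRUE) {
  if (gcrossRadius <= 0) stop("'gcrossRadius' must be positive",
                              call. = FALSE)
  if (length(percentileBreaks) != 2L || any(diff(percentileBreaks) <= 0) ||
      any(percentileBreaks <= 0) || any(percentileBreaks >= 100)) {
    stop("'percentileBreaks' must be two increasing values inside (0, 100)",
         call. = FALSE)
  }
  if (!identical(clrCutoff, "auto") &&
      (!is.numeric(clrCutoff) || clrCutoff < 0)) {
    stop("'clrCutoff' must be a non-negative number or \"auto\"",
         call. = FALSE)
  }
  list(cellTable = cellTable, patientTable = patientTable,
       coreGeometry = coreGeometry, outputDir = outputDir,
       gcrossRadius = gcrossRadius, percentileBreaks = percentileBreaks,
       clrCutoff = clrCutoff, tertileColumns = tertileColumns,
       seed = as.integer(seed), verbose = isTRUE(verbose))
}

#' Run the full scoring and analysis pipeline
#'
#' Orchestrates the end-to-end analysis: read the cell and patient
#' tables, compute per-tumor density and G-cross profiles, derive the
#' categorical scores, build the association report against metastatic
#' status, fit the univariable and multivariable Cox batteries, export
#' Kaplan-Meier step coordinates for the immune factors, and write a run
#' manifest. Every output is regenerated deterministically from
#' (inputs, config, seed).
#'
#' @param config A [pipelineConfig()] list.
#' @return Invisibly, a list with `scores`, `cohort`, `report`, `fits`
#'   and the output file paths.
#' @export
runPipeline <- function(config) {
  say <- function(...) if (config$verbose) message(sprintf(...))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  patterns <- readCellTable(config$cellTable, config$coreGeometry)
  say("read %d cores (%d cells)", length(patterns),
      sum(vapply(patterns, nCells, integer(1))))
  patients <- readPatientTable(config$patientTable)
  say("read %d patients", nrow(patients))

  profiles <- tumorProfiles(patterns, r = config$gcrossRadius)
  clin <- intersect(c("clr_count", "margin_length_mm",
                      "pdl1_tumor_histoscore"), names(patients))
  if (length(clin)) {
    profiles <- merge(profiles,
                      patients[, c("patient_id", clin)],
                      by.x = "tumor_id", by.y = "patient_id",
                      all.x = TRUE, sort = TRUE)
  }
  scores <- scoreCohort(profiles, clrCutoff = config$clrCutoff,
                        dssEvent = if (identical(config$clrCutoff, "auto")) {
                          patients$dss_event[match(profiles$tumor_id,
                                                   patients$patient_id)]
                        },
                        breaks = config$percentileBreaks,
                        tertileColumns = config$tertileColumns)
  say("scored %d tumors (CLR cutoff %.3g/mm)", nrow(scores),
      attr(scores, "clr_cutoff"))
  scorePath <- file.path(config$outputDir, "scores.tsv")
  write.table(scores, scorePath, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")

  cohort <- merge(patients, scores, by.x = "patient_id", by.y = "tumor_id",
                  all.x = TRUE, sort = TRUE,
                  suffixes = c(".clinical", ""))
  paths <- list(scores = scorePath)

  report <- NULL
  if ("metastatic" %in% names(cohort)) {
    vars <- intersect(
      c("age_group", "sex", "cci_group", "location", "tnm_stage",
        "necrosis_group", "stroma_group", "density_score",
        "proximity_score", "clr_category", "pdl1_tumor_category"),
      names(cohort))
    report <- associationReport(cohort, vars, "metastatic",
                                colLevels = c("no", "yes"))
    reportPath <- file.path(config$outputDir, "association_report.tsv")
    write.table(report$table, reportPath, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
    paths$report <- reportPath
    say("association report: %d variables", length(report$results))
  }

  fits <- NULL
  if (all(c("os_time", "os_event", "dss_time", "dss_event",
            "postoperative_death") %in% names(cohort))) {
    fits <- runStandardModels(cohort)
    say("survival models: excluded %d postoperative deaths",
        fits$nExcluded)
    modelDir <- file.path(config$outputDir, "models")
    dir.create(modelDir, showWarnings = FALSE)
    for (nm in setdiff(names(fits), "nExcluded")) {
      if (inherits(fits[[nm]], "error")) next
      write.table(resultTable(fits[[nm]]),
                  file.path(modelDir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    }
    paths$models <- modelDir
    surv <- excludePostoperative(cohort)$cohort
    for (v in intersect(c("clr_category", "proximity_score"),
                        names(surv))) {
      ok <- !is.na(surv[[v]])
      km <- kmEstimate(surv$dss_time[ok], surv$dss_event[ok],
                       groups = surv[[v]][ok])
      kmPath <- file.path(config$outputDir, paste0("km_dss_", v, ".tsv"))
      write.table(km$steps, kmPath, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      paths[[paste0("km_", v)]] <- kmPath
    }
  }

  manifestPath <- file.path(config$outputDir, "manifest.txt")
  cfgTxt <- vapply(names(config), function(k) {
    sprintf("%s: %s", k, paste(format(config[[k]]), collapse = ", "))
  }, character(1))
  writeLines(c(
    "dmmrTME run manifest",
    sprintf("package_version: %s", as.character(packageVersion("dmmrTME"))),
    sprintf("config_hash: %d", .streamSeed(0L, paste(cfgTxt, collapse = ";"))),
    cfgTxt), manifestPath)
  paths$manifest <- manifestPath

  invisible(list(scores = scores, cohort = cohort, report = report,
                 fits = fits, paths = paths))
}

#' Write a small synthetic fixture bundle
#'
#' Generates a 6-tumor, 8-cores-per-tumor synthetic dataset (2 cores per
#' region for each of the CD3 and CD8 sections, plus clinical covariates,
#' CLR counts and survival times) and writes it in the cell-table,
#' geometry and patient-table formats. Deterministic given `seed`; used
#' for tests and examples.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param nTumors Number of tumors (default 6).
#' @return Named list of the written file paths.
#' @export
writeFixtureBundle <- function(dir, seed = 1, nTumors = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  patterns <- list()
  rhos <- rep(c(0.1, 0.4, 0.7), length.out = nTumors)
  for (i in seq_len(nTumors)) {
    tid <- sprintf("P%04d", i)
    pars <- patternParams(
      tumorParentIntensity = 12, tumorOffspringMean = 12,
      immuneIntensity = c(T_CD3 = 150, T_CD8 = 80, macrophage = 60,
                          other = 300),
      rho = rhos[i])
    k <- 0L
    for (panel in c("CD3", "CD8")) {
      for (region in .REGIONS) {
        for (rep_i in 1:2) {
          k <- k + 1L
          cid <- sprintf("%s_c%d", tid, k)
          patterns[[cid]] <- simulateCorePattern(
            pars, coreId = cid, tumorId = tid, region = region,
            markerPanel = panel, seed = seed + i)
        }
      }
    }
  }
  cellPath <- file.path(dir, "cells.tsv")
  geomPath <- file.path(dir, "geometry.tsv")
  writeCellTable(patterns, cellPath, geomPath)
  sim <- simulateCohort(cohortParams(n = nTumors), seed = seed)
  cohort <- sim$cohort
  extras <- withStream(seed, "fixtures:clinical", {
    data.frame(clr_count = rpois(nTumors, 15),
               margin_length_mm = runif(nTumors, 30, 60),
               pdl1_tumor_histoscore = round(runif(nTumors, 0, 10), 1))
  })
  cohort <- cbind(cohort, extras)
  patientPath <- file.path(dir, "patients.tsv")
  writePatientTable(cohort, patientPath)
  list(cells = cellPath, geometry = geomPath, patients = patientPath)
}
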