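# Ingest of long-format transition reports and assembly of the
# transition x run matrices.

#' Default column mapping for transition reports
#'
#' Maps canonical field names to the column headers expected in the input
#' file.  Override entries to ingest Skyline- or MultiQuant-style exports
#' without editing them.  \code{sample_id}, \code{group_id}, \code{replicate}
#' and \code{noise} are optional; when \code{sample_id} is absent every run
#' is its own sample.
#'
#' @return named character vector (canonical name -> file column header)
#' @export
#' @examples
#' defaultColumnMap()
defaultColumnMap <- function() {
  c(protein_id = "protein_id", peptide_id = "peptide_id",
    transition_id = "transition_id", run_id = "run_id",
    sample_id = "sample_id", group_id = "group_id", replicate = "replicate",
    peak_area = "peak_area", retention_time = "retention_time",
    noise = "noise")
}

.REQUIRED_FIELDS <- c("protein_id", "peptide_id", "transition_id", "run_id",
                      "peak_area", "retention_time")

#' Validate a long-format peak record table
#'
#' Checks the contracts of the ingest form: unique
#' (peptide, transition, run) keys, a single peptide per transition and a
#' single protein per peptide, and strictly positive peak areas wherever
#' present.  Non-positive areas are converted to missing under the default
#' policy, or rejected with \code{zeroAreaPolicy = "error"}.
#'
#' @param records data.frame with canonical columns (see
#'   [defaultColumnMap()])
#' @param zeroAreaPolicy \code{"missing"} (default) or \code{"error"}
#' @return the validated (possibly modified) data.frame
#' @export
validatePeakRecords <- function(records,
                                zeroAreaPolicy = c("missing", "error")) {
  zeroAreaPolicy <- match.arg(zeroAreaPolicy)
  missingCols <- setdiff(.REQUIRED_FIELDS, names(records))
  if (length(missingCols))
    mrmConfigError(paste("missing required column(s):",
                         paste(missingCols, collapse = ", ")))
  if (!"sample_id" %in% names(records))
    records$sample_id <- records$run_id
  if (!"group_id" %in% names(records)) records$group_id <- NA_character_
  if (!"replicate" %in% names(records)) records$replicate <- NA_integer_

  key <- paste(records$peptide_id, records$transition_id, records$run_id,
               sep = "||")
  dup <- duplicated(key)
  if (any(dup))
    mrmDataError(paste0("duplicate (peptide, transition, run) key: ",
                        key[which(dup)[1L]]))
  # one peptide per transition, one protein per peptide
  tp <- unique(records[, c("peptide_id", "transition_id")])
  ppt <- paste(tp$peptide_id, tp$transition_id)  # a transition id may recur
  pp <- unique(records[, c("protein_id", "peptide_id")])
  if (anyDuplicated(pp$peptide_id))
    mrmDataError("a peptide_id maps to more than one protein_id")

  bad <- !is.na(records$peak_area) & records$peak_area <= 0
  if (any(bad)) {
    if (zeroAreaPolicy == "error")
      mrmDataError(paste("non-positive peak_area in", sum(bad), "row(s)"))
    records$peak_area[bad] <- NA_real_
  }
  records
}

#' Read a long-format transition report
#'
#' Reads a delimited text file (comma- or tab-separated, chosen from the
#' file extension unless \code{sep} is given), renames columns through
#' \code{columnMap} and validates the result with [validatePeakRecords()].
#'
#' @param path file path
#' @param columnMap named character vector, canonical name -> file header;
#'   see [defaultColumnMap()]
#' @param sep field separator; default inferred (".tsv"/".txt" -> tab)
#' @param zeroAreaPolicy passed to [validatePeakRecords()]
#' @return validated data.frame of peak records
#' @export
readTransitionReport <- function(path, columnMap = defaultColumnMap(),
                                 sep = NULL,
                                 zeroAreaPolicy = c("missing", "error")) {
  if (!file.exists(path)) mrmConfigError(paste("input file not found:", path))
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  need <- columnMap[intersect(.REQUIRED_FIELDS, names(columnMap))]
  absent <- need[!need %in% names(raw)]
  if (length(absent))
    mrmConfigError(paste0("mapped column(s) not present in file: ",
                          paste(absent, collapse = ", ")))
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    matrix(nrow = nrow(raw), ncol = 0))
  for (canon in names(columnMap)) {
    col <- columnMap[[canon]]
    if (col %in% names(raw)) out[[canon]] <- raw[[col]]
  }
  validatePeakRecords(out, zeroAreaPolicy = match.arg(zeroAreaPolicy))
}

#' Write peak records as a delimited file
#'
#' @param records validated peak record data.frame
#' @param path output path; ".tsv" writes tab-separated, otherwise CSV
#' @return invisibly, \code{path}
#' @export
writeTransitionReport <- function(records, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  write.table(records, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble the transition x run matrices from peak records
#'
#' Builds an [MRMExperiment-class] whose \code{log2area} assay holds
#' log2(peak area) and whose \code{rt} assay holds retention times in
#' minutes.  Cells absent from the records are missing.  Rows are ordered by
#' (protein, peptide, transition) so peptide blocks are contiguous; columns
#' by (sample, replicate, run).
#'
#' @param records validated peak record data.frame
#' @return an \code{MRMExperiment}
#' @export
#' @examples
#' sim <- simulateMRM(simConfig(nProteins = 2, seed = 1))
#' mse <- buildMRMExperiment(sim$records)
#' mse
buildMRMExperiment <- function(records) {
  records <- validatePeakRecords(records)
  rowKey <- unique(records[, c("protein_id", "peptide_id", "transition_id")])
  rowKey <- rowKey[order(rowKey$protein_id, rowKey$peptide_id,
                         rowKey$transition_id), , drop = FALSE]
  colKey <- unique(records[, c("run_id", "sample_id", "group_id", "replicate")])
  if (anyDuplicated(colKey$run_id))
    mrmDataError("a run_id carries inconsistent sample/group annotation")
  colKey <- colKey[order(colKey$sample_id, colKey$replicate, colKey$run_id),
                   , drop = FALSE]

  rid <- paste(rowKey$peptide_id, rowKey$transition_id, sep = "|")
  ri <- match(paste(records$peptide_id, records$transition_id, sep = "|"), rid)
  ci <- match(records$run_id, colKey$run_id)
  n <- nrow(rowKey); m <- nrow(colKey)
  area <- matrix(NA_real_, n, m, dimnames = list(rid, colKey$run_id))
  rt <- matrix(NA_real_, n, m, dimnames = list(rid, colKey$run_id))
  idx <- cbind(ri, ci)
  area[idx] <- log2(records$peak_area)
  rt[idx] <- records$retention_time

  se <- SummarizedExperiment(
    assays = list(log2area = area, rt = rt),
    rowData = DataFrame(rowKey, row.names = rid),
    colData = DataFrame(colKey, row.names = colKey$run_id))
  new("MRMExperiment", se)
}

#' Flatten an MRMExperiment back to long-format records
#'
#' Inverse of [buildMRMExperiment()] up to row ordering: emits one row per
#' non-missing cell with \code{peak_area = 2^log2area}.
#'
#' @param x an \code{MRMExperiment}
#' @return peak record data.frame
#' @export
asPeakRecords <- function(x) {
  area <- log2Area(x)
  rt <- if ("rt" %in% assayNames(x)) retentionTime(x) else
    matrix(NA_real_, nrow(area), ncol(area))
  obs <- which(!is.na(area), arr.ind = TRUE)
  rd <- rowData(x); cd <- colData(x)
  data.frame(
    protein_id = as.character(rd$protein_id)[obs[, 1L]],
    peptide_id = as.character(rd$peptide_id)[obs[, 1L]],
    transition_id = as.character(rd$transition_id)[obs[, 1L]],
    run_id = as.character(cd$run_id)[obs[, 2L]],
    sample_id = as.character(cd$sample_id)[obs[, 2L]],
    group_id = as.character(cd$group_id)[obs[, 2L]],
    replicate = cd$replicate[obs[, 2L]],
    peak_area = 2^area[obs],
    retention_time = rt[obs],
    stringsAsFactors = FALSE)
}

#' Drop transitions detected in too few runs
#'
#' Removes rows whose \code{log2area} is observed in fewer than
#' \code{minRuns} runs (default 2, the usual "detected and quantified in at
#' least two runs" screen).  The paired retention-time assay is filtered
#' identically.  Idempotent.
#'
#' @param x an \code{MRMExperiment}
#' @param minRuns minimum number of non-missing runs per transition
#' @return filtered \code{MRMExperiment}
#' @export
filterMinDetected <- function(x, minRuns = 2L) {
  if (minRuns < 1L) mrmConfigError("minRuns must be >= 1")
  if (minRuns > ncol(x))
    mrmConfigError(sprintf("minRuns (%d) exceeds the number of runs (%d)",
                           minRuns, ncol(x)))
  keep <- rowSums(!is.na(log2Area(x))) >= minRuns
  x[keep, ]
}

#' Serialize / read an MRMExperiment as delimited text
#'
#' Writes three CSVs into \code{dir}: \code{quant.csv} and \code{rt.csv}
#' (annotation columns followed by one column per run) and \code{runs.csv}
#' (run annotation).  \code{readMRMExperiment} is the inverse.
#'
#' @param x an \code{MRMExperiment}
#' @param dir directory (created if needed)
#' @return invisibly, \code{dir} / the \code{MRMExperiment}
#' @export
writeMRMExperiment <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rd <- as.data.frame(rowData(x))[, c("protein_id", "peptide_id",
                                      "transition_id")]
  qdf <- cbind(rd, as.data.frame(log2Area(x), check.names = FALSE))
  write.csv(qdf, file.path(dir, "quant.csv"), row.names = FALSE)
  if ("rt" %in% assayNames(x)) {
    rdf <- cbind(rd, as.data.frame(retentionTime(x), check.names = FALSE))
    write.csv(rdf, file.path(dir, "rt.csv"), row.names = FALSE)
  }
  write.csv(as.data.frame(colData(x)), file.path(dir, "runs.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname writeMRMExperiment
#' @export
readMRMExperiment <- function(dir) {
  qp <- file.path(dir, "quant.csv")
  if (!file.exists(qp)) mrmConfigError(paste("no quant.csv under", dir))
  qdf <- read.csv(qp, check.names = FALSE, stringsAsFactors = FALSE)
  ann <- c("protein_id", "peptide_id", "transition_id")
  runs <- setdiff(names(qdf), ann)
  area <- as.matrix(qdf[, runs, drop = FALSE])
  rid <- paste(qdf$peptide_id, qdf$transition_id, sep = "|")
  dimnames(area) <- list(rid, runs)
  assays <- list(log2area = area)
  rp <- file.path(dir, "rt.csv")
  if (file.exists(rp)) {
    rdf <- read.csv(rp, check.names = FALSE, stringsAsFactors = FALSE)
    rt <- as.matrix(rdf[, runs, drop = FALSE])
    dimnames(rt) <- dimnames(area)
    assays$rt <- rt
  }
  cd <- read.csv(file.path(dir, "runs.csv"), stringsAsFactors = FALSE)
  cd <- cd[match(runs, cd$run_id), , drop = FALSE]
  if (!"group_id" %in% names(cd)) cd$group_id <- NA_character_
  if (!"replicate" %in% names(cd)) cd$replicate <- NA_integer_
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(qdf[, ann], row.names = rid),
    colData = DataFrame(cd, row.names = cd$run_id))
  new("MRMExperiment", se)
}
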