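#' MRMExperiment: annotated transition-by-run matrices
#'
#' An \code{MRMExperiment} extends
#' \link[SummarizedExperiment]{SummarizedExperiment} and holds the two
#' matrices an MRM pre-processing pipeline works on: \code{log2area}
#' (log2-transformed peak areas, transitions in rows, LC-MS runs in columns;
#' \code{NA} marks undetected peaks) and, optionally, \code{rt} (retention
#' times in minutes on the raw scale, same shape).  Row annotation carries
#' \code{protein_id}, \code{peptide_id} and \code{transition_id}; column
#' annotation carries \code{run_id}, \code{sample_id}, \code{group_id} and
#' \code{replicate}.  Rows are kept contiguous by peptide so per-peptide
#' model fitting can recover the grouping.
#'
#' @slot .. see \link[SummarizedExperiment]{SummarizedExperiment}; no extra
#'   slots are added, only validity constraints.
#'
#' @seealso [buildMRMExperiment()], [readTransitionReport()]
#' @export
setClass("MRMExperiment", contains = "SummarizedExperiment")

.validMRMExperiment <- function(object) {
  msg <- character()
  if (!("log2area" %in% assayNames(object)))
    msg <- c(msg, "assay 'log2area' is required")
  rd <- rowData(object)
  need <- c("protein_id", "peptide_id", "transition_id")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain", paste(need, collapse = ", ")))
  cd <- colData(object)
  if (!all(c("run_id", "sample_id") %in% colnames(cd)))
    msg <- c(msg, "colData must contain run_id and sample_id")
  if (length(msg) == 0L) {
    key <- paste(rd$peptide_id, rd$transition_id)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated (peptide_id, transition_id) rows")
    # peptide blocks must be contiguous
    pep <- as.character(rd$peptide_id)
    if (length(pep) > 1L) {
      blocks <- rle(pep)$values
      if (anyDuplicated(blocks))
        msg <- c(msg, "rows of the same peptide must be contiguous")
    }
    if ("rt" %in% assayNames(object)) {
      if (!identical(dim(assay(object, "rt")), dim(assay(object, "log2area"))))
        msg <- c(msg, "'rt' assay must match 'log2area' in shape")
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("MRMExperiment", .validMRMExperiment)

#' @describeIn MRMExperiment-class compact display
#' @param object an \code{MRMExperiment}
#' @export
setMethod("show", "MRMExperiment", function(object) {
  rd <- rowData(object)
  cat("MRMExperiment:", nrow(object), "transitions x", ncol(object), "runs\n")
  cat("  proteins:", length(unique(rd$protein_id)),
      " peptides:", length(unique(rd$peptide_id)), "\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  g <- colData(object)$group_id
  if (!is.null(g))
    cat("  groups:", paste(unique(as.character(g)), collapse = ", "), "\n")
  nmiss <- sum(is.na(assay(object, "log2area")))
  cat("  missing cells:", nmiss,
      sprintf("(%.1f%%)\n", 100 * nmiss / prod(dim(object))))
  invisible(NULL)
})

#' Accessors for MRMExperiment annotation and assays
#'
#' \code{log2Area} and \code{retentionTime} return the two assay matrices
#' (transitions x runs); \code{peptideIds}, \code{transitionIds},
#' \code{proteinIds} the row annotation vectors; \code{runIds},
#' \code{sampleIds}, \code{groupIds} the column annotation vectors.
#'
#' @param x an \code{MRMExperiment}
#' @return matrix or character vector as described
#' @name mrm-accessors
NULL

#' @rdname mrm-accessors
#' @export
log2Area <- function(x) assay(x, "log2area")

#' @rdname mrm-accessors
#' @export
retentionTime <- function(x) {
  if (!"rt" %in% assayNames(x))
    mrmDataError("this MRMExperiment carries no retention-time assay")
  assay(x, "rt")
}

#' @rdname mrm-accessors
#' @export
peptideIds <- function(x) as.character(rowData(x)$peptide_id)

#' @rdname mrm-accessors
#' @export
transitionIds <- function(x) as.character(rowData(x)$transition_id)

#' @rdname mrm-accessors
#' @export
proteinIds <- function(x) as.character(rowData(x)$protein_id)

#' @rdname mrm-accessors
#' @export
runIds <- function(x) as.character(colData(x)$run_id)

#' @rdname mrm-accessors
#' @export
sampleIds <- function(x) as.character(colData(x)$sample_id)

#' @rdname mrm-accessors
#' @export
groupIds <- function(x) {
  g <- colData(x)$group_id
  if (is.null(g)) NULL else as.character(g)
}

#' PeptideFit: robust two-way fit for one peptide
#'
#' Result of fitting the additive model \eqn{y_{ij} = \mu + \alpha_i +
#' \beta_j + \epsilon_{ij}} (log2 peak area of transition i in run j) by
#' iteratively reweighted least squares.  \code{alpha} (transition effects)
#' and \code{beta} (run effects) are sum-to-zero; \code{mu} is the overall
#' log2 level, so the run-level signal is \code{mu + beta}.  \code{weights}
#' holds the per-peak concordance weights in [0, 1] (\code{NA} at missing
#' cells); \code{sigma} is the robust residual scale (MAD/0.6745).
#'
#' @slot peptide character, the peptide id
#' @slot mu numeric(1)
#' @slot alpha named numeric, per transition, sums to zero
#' @slot beta named numeric, per run, sums to zero
#' @slot sigma numeric(1)
#' @slot weights numeric matrix, transitions x runs
#' @slot converged logical(1)
#' @slot nIterations integer(1)
#' @export
setClass("PeptideFit",
  representation(peptide = "character", mu = "numeric", alpha = "numeric",
                 beta = "numeric", sigma = "numeric", weights = "matrix",
                 converged = "logical", nIterations = "integer"))

setValidity("PeptideFit", function(object) {
  msg <- character()
  if (abs(sum(object@alpha)) > 1e-9)
    msg <- c(msg, "transition effects must sum to zero")
  w <- object@weights[!is.na(object@weights)]
  if (length(w) && (min(w) < -1e-12 || max(w) > 1 + 1e-12))
    msg <- c(msg, "weights must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn PeptideFit-class compact display
#' @param object a \code{PeptideFit}
#' @export
setMethod("show", "PeptideFit", function(object) {
  cat("PeptideFit for", object@peptide, ":",
      length(object@alpha), "transitions x", length(object@beta), "runs\n")
  cat(sprintf("  mu = %.3f, sigma = %.4f, %s in %d iterations\n",
              object@mu, object@sigma,
              if (object@converged) "converged" else "NOT converged",
              object@nIterations))
  invisible(NULL)
})

#' @rdname PeptideFit-class
#' @param object a \code{PeptideFit}
#' @export
setGeneric("peakWeights", function(object) standardGeneric("peakWeights"))

#' @rdname PeptideFit-class
#' @export
setMethod("peakWeights", "PeptideFit", function(object) object@weights)

#' @rdname PeptideFit-class
#' @export
setGeneric("fittedMatrix", function(object) standardGeneric("fittedMatrix"))

#' @describeIn PeptideFit-class fitted values mu + alpha_i + beta_j as a
#'   transitions x runs matrix
#' @export
setMethod("fittedMatrix", "PeptideFit", function(object) {
  outer(object@alpha, object@beta, "+") + object@mu
})

#' NormalizationResult: a normalized matrix plus method diagnostics
#'
#' @slot normalized the normalized object, same class and shape as the input
#'   (matrix or \code{MRMExperiment}); missing cells stay missing
#' @slot method one of \code{global_median}, \code{quantile},
#'   \code{cyclic_loess}, \code{subset_median}, \code{invariant_set}
#' @slot diagnostics method-specific list (per-run scaling factors,
#'   invariant-set membership, loess cycle summaries, ...)
#' @export
setClass("NormalizationResult",
  representation(normalized = "ANY", method = "character",
                 diagnostics = "list"))

#' @describeIn NormalizationResult-class compact display
#' @param object a \code{NormalizationResult}
#' @export
setMethod("show", "NormalizationResult", function(object) {
  d <- dim(if (is(object@normalized, "MRMExperiment"))
    log2Area(object@normalized) else object@normalized)
  cat("NormalizationResult (", object@method, "): ",
      d[1L], " x ", d[2L], "\n", sep = "")
  cat("  diagnostics:", paste(names(object@diagnostics), collapse = ", "), "\n")
  invisible(NULL)
})

#' @rdname NormalizationResult-class
#' @param object a \code{NormalizationResult}
#' @export
setGeneric("normalizedData", function(object) standardGeneric("normalizedData"))

#' @rdname NormalizationResult-class
#' @export
setMethod("normalizedData", "NormalizationResult",
          function(object) object@normalized)
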