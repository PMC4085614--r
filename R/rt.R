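# Retention-time drift correction and adjusted-CV transition screening.
#
# Chromatographic drift shifts whole runs earlier or later; comparing each
# run's deviation from the transition-specific median RT and removing the
# run-level median deviation ("offset") separates instrument drift from
# genuinely inconsistent transitions (mis-picked peaks).

#' Per-run retention-time offsets
#'
#' For each transition the reference is its median RT across runs; the run
#' offset is the median, over transitions observed in that run, of the
#' deviation from this reference.  Missing cells are excluded pairwise.
#'
#' @param rt retention-time matrix (transitions x runs, minutes) or an
#'   \code{MRMExperiment}
#' @return named numeric vector of offsets (minutes), one per run
#' @export
computeRunOffsets <- function(rt) {
  if (is(rt, "MRMExperiment")) rt <- retentionTime(rt)
  nObs <- colSums(!is.na(rt))
  if (any(nObs == 0L))
    mrmDataError(paste("run(s) with no observed retention times:",
                       paste(colnames(rt)[nObs == 0L], collapse = ", ")))
  dev <- rt - .rowMedians(rt)
  .colMedians(dev)
}

#' Subtract run offsets from a retention-time matrix
#'
#' @param rt retention-time matrix or \code{MRMExperiment}
#' @param offsets named per-run offsets covering every run (minutes)
#' @return object of the same class with adjusted RTs; missing cells stay
#'   missing
#' @export
adjustRetentionTime <- function(rt, offsets) {
  if (is(rt, "MRMExperiment")) {
    assay(rt, "rt") <- adjustRetentionTime(retentionTime(rt), offsets)
    return(rt)
  }
  if (!is.null(colnames(rt)) && !is.null(names(offsets))) {
    if (!all(colnames(rt) %in% names(offsets)))
      mrmConfigError("offsets do not cover all runs")
    offsets <- offsets[colnames(rt)]
  } else if (length(offsets) != ncol(rt)) {
    mrmConfigError("offsets do not cover all runs")
  }
  sweep(rt, 2L, offsets, "-")
}

#' Per-transition retention-time CV (percent)
#'
#' 100 * sd / mean on raw minutes, sample (n - 1) standard deviation,
#' computed over non-missing runs.  Transitions with fewer than two
#' observations get \code{NA}.
#'
#' @param rt retention-time matrix or \code{MRMExperiment}
#' @return numeric vector of CV percentages, one per transition
#' @export
rtCV <- function(rt) {
  if (is(rt, "MRMExperiment")) rt <- retentionTime(rt)
  apply(rt, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    100 * sd(v) / mean(v)
  })
}

#' Flag transitions with inconsistent retention-time behaviour
#'
#' Two rules are reported.  The two-sided rule flags transitions whose
#' original CV is small (\code{< lowThresh}) but whose adjusted CV is large
#' (\code{> highThresh}) — i.e. their RT ordering across runs contradicts
#' the global drift pattern.  The simple rule flags adjusted CV
#' \code{> singleThresh}.  Transitions with a missing CV are not evaluable
#' and are left unflagged.
#'
#' @param cvOriginal,cvAdjusted aligned CV vectors (percent)
#' @param lowThresh,highThresh two-sided rule thresholds (default 4 and 7)
#' @param singleThresh simple rule threshold (default 5)
#' @return data.frame with columns \code{cv_original}, \code{cv_adjusted},
#'   \code{flag_two_sided}, \code{flag_single}, \code{evaluable}
#' @export
flagRTInconsistent <- function(cvOriginal, cvAdjusted, lowThresh = 4,
                               highThresh = 7, singleThresh = 5) {
  if (length(cvOriginal) != length(cvAdjusted))
    mrmConfigError("CV vectors must be aligned")
  evaluable <- !is.na(cvOriginal) & !is.na(cvAdjusted)
  two <- evaluable & cvOriginal < lowThresh & cvAdjusted > highThresh
  one <- evaluable & cvAdjusted > singleThresh
  data.frame(cv_original = cvOriginal, cv_adjusted = cvAdjusted,
             flag_two_sided = two, flag_single = one, evaluable = evaluable)
}

#' Retention-time quality report
#'
#' Runs the full RT QC chain: compute per-run offsets, adjust, compute
#' original and adjusted CVs and apply both flagging rules.
#'
#' @param x an \code{MRMExperiment} with an \code{rt} assay
#' @inheritParams flagRTInconsistent
#' @return list with \code{offsets} (named numeric), \code{adjusted}
#'   (RT matrix) and \code{report} (data.frame: transition, peptide,
#'   median_rt, CVs and flags)
#' @export
#' @examples
#' fx <- makeFixture("rt_shifted")
#' mse <- buildMRMExperiment(fx$records)
#' head(rtQuality(mse)$report)
rtQuality <- function(x, lowThresh = 4, highThresh = 7, singleThresh = 5) {
  rt <- retentionTime(x)
  offsets <- computeRunOffsets(rt)
  adj <- adjustRetentionTime(rt, offsets)
  cvO <- rtCV(rt)
  cvA <- rtCV(adj)
  flags <- flagRTInconsistent(cvO, cvA, lowThresh, highThresh, singleThresh)
  report <- cbind(
    data.frame(protein_id = proteinIds(x), peptide_id = peptideIds(x),
               transition_id = transitionIds(x),
               median_rt = .rowMedians(rt), stringsAsFactors = FALSE),
    flags)
  rownames(report) <- rownames(rt)
  list(offsets = offsets, adjusted = adj, report = report)
}
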