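# Between-run normalization of log2 intensity matrices.
#
# All five methods operate on the log2 scale, preserve the missingness
# pattern and shape, and add back a grand-level term where applicable so the
# output stays on the original log2 scale (CV denominators downstream remain
# comparable).  Rows are opaque to the algorithms: they may be transitions
# or peptide-level summaries.

.checkRuns <- function(m) {
  nObs <- colSums(!is.na(m))
  if (any(nObs == 0L))
    mrmDataError(paste("run(s) with no observed cells:",
                       paste(colnames(m)[nObs == 0L], collapse = ", ")))
}

.normGlobalMedian <- function(m) {
  .checkRuns(m)
  f <- .colMedians(m)
  grand <- median(f)
  out <- sweep(m, 2L, f - grand, "-")
  list(normalized = out,
       diagnostics = list(run_medians = f, grand_median = grand,
                          factors = f - grand))
}

# empirical quantile function of one run's observed values, evaluated at
# probabilities p: knots at (i - 0.5)/n, linear in between, flat outside
.runQuantile <- function(sortedVals, p) {
  n <- length(sortedVals)
  if (n == 1L) return(rep(sortedVals, length(p)))
  probs <- (seq_len(n) - 0.5) / n
  approx(probs, sortedVals, xout = p, rule = 2)$y
}

.normQuantile <- function(m) {
  if (ncol(m) < 2L) mrmConfigError("quantile normalization needs >= 2 runs")
  .checkRuns(m)
  sortedCols <- lapply(seq_len(ncol(m)), function(j) sort(m[, j]))
  refQ <- function(p) {
    acc <- 0
    for (s in sortedCols) acc <- acc + .runQuantile(s, p)
    acc / length(sortedCols)
  }
  out <- m
  for (j in seq_len(ncol(m))) {
    oi <- which(!is.na(m[, j]))
    v <- m[oi, j]
    n <- length(v)
    ref <- refQ((seq_len(n) - 0.5) / n)   # reference at this run's ranks
    repl <- numeric(n)
    repl[order(v)] <- ref
    # tied input values share the mean of their assigned reference values
    repl <- ave(repl, match(v, v), FUN = mean)
    out[oi, j] <- repl
  }
  list(normalized = out, diagnostics = list(n_obs_per_run = colSums(!is.na(m))))
}

.normCyclicLoess <- function(m, span = 0.7, maxCycles = 3L, tol = 1e-3,
                             minPairObs = 20L) {
  if (ncol(m) < 2L) mrmConfigError("cyclic loess needs >= 2 runs")
  out <- m
  J <- ncol(m)
  cycleMax <- numeric(0)
  prevOut <- NULL
  for (cycle in seq_len(maxCycles)) {
    prevOut <- out
    maxAdj <- 0
    for (j in seq_len(J - 1L)) for (kk in (j + 1L):J) {
      ok <- which(!is.na(out[, j]) & !is.na(out[, kk]))
      if (length(ok) < minPairObs) {
        warning("cyclic loess: runs ", j, " and ", kk, " share only ",
                length(ok), " cells; pair skipped", call. = FALSE)
        next
      }
      M <- out[ok, j] - out[ok, kk]
      A <- (out[ok, j] + out[ok, kk]) / 2
      fit <- loess(M ~ A, span = span, degree = 1,
                   family = "gaussian",
                   control = loess.control(surface = "direct"))
      Mhat <- fitted(fit)
      out[ok, j] <- out[ok, j] - Mhat / 2
      out[ok, kk] <- out[ok, kk] + Mhat / 2
      maxAdj <- max(maxAdj, max(abs(Mhat / 2)))
    }
    # in noisy many-run panels the pairwise corrections stop contracting
    # once the systematic trend is gone and begin chasing noise; a cycle
    # whose largest adjustment grows is discarded and cycling stops
    if (length(cycleMax) && maxAdj > cycleMax[length(cycleMax)]) {
      out <- prevOut
      break
    }
    cycleMax <- c(cycleMax, maxAdj)
    if (maxAdj < tol) break
  }
  list(normalized = out,
       diagnostics = list(cycles = length(cycleMax),
                          max_adjustment_per_cycle = cycleMax,
                          span = span))
}

.normSubsetMedian <- function(m, control, rowIds = rownames(m),
                              center = c("median", "mean")) {
  center <- match.arg(center)
  if (is.logical(control)) {
    sel <- which(control)
  } else {
    sel <- which(rowIds %in% control)
    missing <- setdiff(control, rowIds)
    if (length(missing))
      mrmConfigError(paste("control id(s) not present:",
                           paste(missing, collapse = ", ")))
  }
  if (length(sel) == 0L) mrmConfigError("empty control set")
  ctrl <- m[sel, , drop = FALSE]
  nObs <- colSums(!is.na(ctrl))
  if (any(nObs == 0L))
    mrmDataError(paste("run(s) with no observed control cells:",
                       paste(colnames(m)[nObs == 0L], collapse = ", ")))
  stat <- if (center == "median") .colMedians(ctrl) else
    colMeans(ctrl, na.rm = TRUE)
  grand <- median(stat)
  factors <- stat - grand
  list(normalized = sweep(m, 2L, factors, "-"),
       diagnostics = list(factors = factors, control_rows = sel,
                          center = center))
}

# map run values through the inverse of a fitted run-vs-reference trend;
# slope-1 linear extension outside the fitted range
.invertTrend <- function(fittedVals, refVals, yout) {
  o <- order(refVals)
  fx <- cummax(fittedVals[o])   # enforce a nondecreasing curve
  rx <- refVals[o]
  keep <- !duplicated(fx)
  fx <- fx[keep]; rx <- rx[keep]
  res <- approx(fx, rx, xout = yout, rule = 2, ties = "ordered")$y
  lo <- !is.na(yout) & yout < fx[1L]
  hi <- !is.na(yout) & yout > fx[length(fx)]
  res[lo] <- rx[1L] + (yout[lo] - fx[1L])
  res[hi] <- rx[length(rx)] + (yout[hi] - fx[length(fx)])
  res
}

.rankInvariantSet <- function(runVals, refVals, rankTol, maxIter) {
  S <- seq_along(runVals)
  for (it in seq_len(maxIter)) {
    r1 <- rank(runVals[S])
    r2 <- rank(refVals[S])
    keep <- abs(r1 - r2) / length(S) < rankTol
    if (all(keep)) break
    S <- S[keep]
    if (length(S) == 0L) break
  }
  S
}

.normInvariantSet <- function(m, rankTol = 0.05, maxIter = 30L,
                              minSize = 10L, span = 0.7) {
  if (ncol(m) < 2L) mrmConfigError("invariant-set normalization needs >= 2 runs")
  ref <- .rowMedians(m)
  out <- m
  members <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  flagged <- character(0)
  for (j in seq_len(ncol(m))) {
    ok <- which(!is.na(m[, j]) & !is.na(ref))
    if (length(ok) < minSize) {
      warning("invariant set: run ", colnames(m)[j] %||% j,
              " has too few cells; left unnormalized", call. = FALSE)
      flagged <- c(flagged, colnames(m)[j] %||% as.character(j))
      next
    }
    S <- .rankInvariantSet(m[ok, j], ref[ok], rankTol, maxIter)
    if (length(S) < minSize) {
      warning("invariant set for run ", colnames(m)[j] %||% j,
              " smaller than ", minSize, "; run left unnormalized",
              call. = FALSE)
      flagged <- c(flagged, colnames(m)[j] %||% as.character(j))
      next
    }
    inv <- ok[S]
    members[inv, j] <- TRUE
    x <- ref[inv]; y <- m[inv, j]
    if (length(unique(x)) < 4L) {
      # degenerate reference spread: fall back to a constant shift
      out[ok, j] <- m[ok, j] - median(y - x)
      next
    }
    fit <- loess(y ~ x, span = span, degree = 1,
                 control = loess.control(surface = "direct"))
    out[ok, j] <- .invertTrend(fitted(fit), x, m[ok, j])
  }
  list(normalized = out,
       diagnostics = list(reference = ref, invariant_members = members,
                          set_sizes = colSums(members),
                          skipped_runs = flagged, rank_tol = rankTol))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.NORM_METHODS <- c("global_median", "quantile", "cyclic_loess",
                   "subset_median", "invariant_set")

#' Normalize log2 intensities between runs
#'
#' Dispatches one of five between-run normalization methods on a log2
#' intensity matrix (rows = transitions or peptides, columns = runs) or on
#' the \code{log2area} assay of an \code{MRMExperiment}:
#' \describe{
#'   \item{global_median}{per-run median matched to the grand median of the
#'     run medians.}
#'   \item{quantile}{each run's order statistics replaced by the cross-run
#'     mean quantile function; with complete equal-count data all run
#'     distributions become identical.  With missing cells, ranks are taken
#'     on observed values and the reference is interpolated at
#'     \eqn{(rank - 0.5)/n}; ties share the mean of their reference values.}
#'   \item{cyclic_loess}{for every unordered run pair, a degree-1 loess of M
#'     on A is subtracted symmetrically (half from each run); cycles repeat
#'     until the largest adjustment falls below \code{tol} or
#'     \code{maxCycles}.}
#'   \item{subset_median}{per-run median (or mean) over a declared control
#'     feature set, applied as a constant shift to all features of the run.}
#'   \item{invariant_set}{rank-invariant features against the per-row median
#'     reference are found iteratively (rank difference below
#'     \code{rankTol} of the current set size); a loess trend of run versus
#'     reference fitted on that set is inverted by interpolation and applied
#'     to every feature.}
#' }
#'
#' @param x log2 matrix or \code{MRMExperiment}
#' @param method one of \code{"global_median"}, \code{"quantile"},
#'   \code{"cyclic_loess"}, \code{"subset_median"}, \code{"invariant_set"}
#' @param controls control feature ids (rownames, or for an
#'   \code{MRMExperiment} peptide or transition ids) or a logical row mask;
#'   required for \code{subset_median}
#' @param span loess span for \code{cyclic_loess}/\code{invariant_set}
#'   (default 0.7)
#' @param maxCycles,tol,minPairObs cyclic-loess controls
#' @param rankTol,maxIter,minSize invariant-set controls
#' @param center \code{"median"} (default) or \code{"mean"} control summary
#'   for \code{subset_median}
#' @return a [NormalizationResult-class]; \code{normalizedData()} returns an
#'   object of the same class as \code{x}
#' @export
#' @examples
#' m <- matrix(rnorm(300, 18), 50, 6)
#' res <- normalizeRuns(m, "quantile")
#' apply(normalizedData(res), 2, median)
normalizeRuns <- function(x, method = .NORM_METHODS, controls = NULL,
                          span = 0.7, maxCycles = 3L, tol = 1e-3,
                          minPairObs = 20L, rankTol = 0.05, maxIter = 30L,
                          minSize = 10L, center = c("median", "mean")) {
  method <- match.arg(method)
  isExp <- is(x, "MRMExperiment")
  m <- if (isExp) log2Area(x) else as.matrix(x)
  res <- switch(method,
    global_median = .normGlobalMedian(m),
    quantile = .normQuantile(m),
    cyclic_loess = .normCyclicLoess(m, span = span, maxCycles = maxCycles,
                                    tol = tol, minPairObs = minPairObs),
    subset_median = {
      if (is.null(controls))
        mrmConfigError("subset_median requires a control feature set")
      ctl <- controls
      if (isExp && !is.logical(ctl)) {
        hit <- rownames(m) %in% ctl | peptideIds(x) %in% ctl |
          transitionIds(x) %in% ctl
        if (!any(hit))
          mrmConfigError("no control ids matched peptide or transition ids")
        unmatched <- ctl[!(ctl %in% c(rownames(m), peptideIds(x),
                                      transitionIds(x)))]
        if (length(unmatched))
          mrmConfigError(paste("control id(s) not present:",
                               paste(unmatched, collapse = ", ")))
        ctl <- hit
      }
      .normSubsetMedian(m, ctl, center = match.arg(center))
    },
    invariant_set = .normInvariantSet(m, rankTol = rankTol,
                                      maxIter = maxIter, minSize = minSize,
                                      span = span))
  normalized <- res$normalized
  if (isExp) {
    assay(x, "log2area") <- normalized
    normalized <- x
  }
  new("NormalizationResult", normalized = normalized, method = method,
      diagnostics = res$diagnostics)
}
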