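# Robust per-peptide two-way model.
#
# Transitions of one peptide are proportional fragments of the same analyte,
# so on the log2 scale their areas are additive in a transition effect and a
# run effect.  Peaks that break this parallel pattern (interference,
# mis-picked integration windows) show up as large residuals; IRLS with a
# bounded weight function turns them into per-peak quality weights in [0, 1].

.psiWeight <- function(u, k, psi) {
  au <- abs(u)
  if (psi == "huber") {
    ifelse(au <= k, 1, k / au)
  } else {                             # Tukey bisquare
    ifelse(au <= k, (1 - (u / k)^2)^2, 0)
  }
}

#' Fit the robust two-way model for one peptide
#'
#' Fits \eqn{y_{ij} = \mu + \alpha_i + \beta_j + \epsilon_{ij}} on the
#' observed cells of a transitions x runs log2-area matrix by iteratively
#' reweighted least squares.  Both effect vectors are sum-to-zero
#' (\eqn{\mu} carries the overall level; \eqn{\mu + \beta_j} is the run
#' level).  Each iteration solves the weighted normal equations, re-estimates
#' the residual scale as MAD/0.6745 (floored at 1e-8) and updates the
#' weights \eqn{w = 1} for \eqn{|r| \le k\hat\sigma}, else
#' \eqn{k\hat\sigma/|r|} (Huber; Tukey bisquare available).  Iteration stops
#' when the largest coefficient change falls below \code{tol} or after
#' \code{maxIter} passes; weights are recomputed from the final residuals.
#'
#' @param y numeric matrix, transitions x runs, \code{NA} = missing
#' @param k robust tuning constant (default 1.345, Huber 95\% efficiency)
#' @param psi weight function, \code{"huber"} (default) or
#'   \code{"bisquare"}
#' @param tol convergence tolerance on coefficients (default 1e-6)
#' @param maxIter iteration cap (default 100)
#' @param peptide peptide id used in messages
#' @return a [PeptideFit-class]
#' @export
#' @examples
#' y <- outer(c(1, -1), c(0, 0.5, -0.5), "+") + 20
#' fit <- fitPeptide(y)
#' fit@alpha
fitPeptide <- function(y, k = 1.345, psi = c("huber", "bisquare"),
                       tol = 1e-6, maxIter = 100L, peptide = "peptide") {
  psi <- match.arg(psi)
  y <- as.matrix(y)
  I <- nrow(y); J <- ncol(y)
  if (I < 2L)
    mrmFitError(paste0("peptide '", peptide, "' has fewer than 2 transitions"))
  obs <- which(!is.na(y), arr.ind = TRUE)
  runObs <- tabulate(obs[, 2L], nbins = J)
  if (sum(runObs > 0L) < 2L)
    mrmFitError(paste0("peptide '", peptide,
                       "' observed in fewer than 2 runs"))
  if (!.incidenceConnected(obs, I, J) ||
      any(tabulate(obs[, 1L], nbins = I) == 0L) || any(runObs == 0L))
    mrmFitError(paste0("peptide '", peptide,
                       "' has an unidentifiable transition-run layout"))

  yv <- y[obs]
  CT <- .contrSum(I); CR <- .contrSum(J)
  X <- cbind(1, CT[obs[, 1L], , drop = FALSE], CR[obs[, 2L], , drop = FALSE])
  p <- ncol(X)
  w <- rep(1, length(yv))
  coefOld <- rep(Inf, p)
  converged <- FALSE
  sigma <- NA_real_
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    # zero weights (bisquare) would drop cells from the solve entirely and
    # can make the layout singular; a tiny floor keeps the system full rank
    fit <- stats::lm.wfit(X, yv, pmax(w, 1e-8))
    cf <- fit$coefficients
    if (anyNA(cf))
      mrmFitError(paste0("peptide '", peptide, "' gives a singular fit"))
    r <- yv - drop(X %*% cf)
    sigma <- max(mad(r), 1e-8)
    w <- .psiWeight(r / sigma, k, psi)
    if (max(abs(cf - coefOld)) < tol) { converged <- TRUE; break }
    coefOld <- cf
  }
  alpha <- drop(CT %*% cf[2:I])
  beta <- drop(CR %*% cf[(I + 1):p])
  tn <- rownames(y); if (is.null(tn)) tn <- paste0("t", seq_len(I))
  rn <- colnames(y); if (is.null(rn)) rn <- paste0("r", seq_len(J))
  W <- matrix(NA_real_, I, J, dimnames = list(tn, rn))
  W[obs] <- w
  new("PeptideFit", peptide = peptide, mu = unname(cf[1L]),
      alpha = setNames(alpha, tn), beta = setNames(beta, rn),
      sigma = sigma, weights = W, converged = converged,
      nIterations = iter)
}

#' Fit the robust model for every peptide of an experiment
#'
#' Splits the log2-area matrix into contiguous peptide blocks, fits each with
#' [fitPeptide()] and assembles a full weight matrix aligned to the input
#' rows and columns.  Peptides that cannot be fitted (a single transition,
#' too few runs, disconnected layout) are skipped with a warning and listed
#' in the skip log, never aborting the run.
#'
#' @param x an \code{MRMExperiment} or a log2-area matrix plus
#'   \code{peptides}, a per-row peptide id vector
#' @param peptides per-row peptide ids (ignored when \code{x} is an
#'   \code{MRMExperiment})
#' @inheritParams fitPeptide
#' @return list with \code{fits} (named list of \code{PeptideFit}),
#'   \code{weights} (matrix aligned to the input; \code{NA} for missing
#'   cells and skipped peptides) and \code{skipped} (data.frame peptide /
#'   reason)
#' @export
fitAllPeptides <- function(x, peptides = NULL, k = 1.345,
                           psi = c("huber", "bisquare"), tol = 1e-6,
                           maxIter = 100L) {
  psi <- match.arg(psi)
  if (is(x, "MRMExperiment")) {
    peptides <- peptideIds(x)
    mat <- log2Area(x)
  } else {
    mat <- as.matrix(x)
    if (is.null(peptides) || length(peptides) != nrow(mat))
      mrmConfigError("per-row peptide ids are required for a plain matrix")
  }
  idx <- split(seq_len(nrow(mat)), factor(peptides, levels = unique(peptides)))
  fits <- list()
  skipped <- data.frame(peptide = character(), reason = character(),
                        stringsAsFactors = FALSE)
  W <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (pep in names(idx)) {
    rows <- idx[[pep]]
    res <- tryCatch(
      fitPeptide(mat[rows, , drop = FALSE], k = k, psi = psi, tol = tol,
                 maxIter = maxIter, peptide = pep),
      mrm_fit_error = function(e) e)
    if (is(res, "PeptideFit")) {
      fits[[pep]] <- res
      W[rows, ] <- res@weights
    } else {
      warning("skipping peptide '", pep, "': ", conditionMessage(res),
              call. = FALSE)
      skipped <- rbind(skipped,
                       data.frame(peptide = pep,
                                  reason = conditionMessage(res),
                                  stringsAsFactors = FALSE))
    }
  }
  list(fits = fits, weights = W, skipped = skipped)
}

#' Transition-level quality from peak weights
#'
#' Summarizes each transition's weights across runs by their median and
#' inter-quartile range.  Qualified transitions have a high median weight
#' and a small IQR; the pass flag is \code{median_weight > threshold}
#' (strict, default 0.9).
#'
#' @param weights weight matrix from [fitAllPeptides()] (rows = transitions)
#' @param threshold pass threshold on the median weight (default 0.9)
#' @return data.frame: \code{transition} (rowname), \code{median_weight},
#'   \code{weight_iqr}, \code{n_weights}, \code{pass}
#' @export
transitionQC <- function(weights, threshold = 0.9) {
  med <- .rowMedians(weights)
  iqr <- apply(weights, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else IQR(v)
  })
  n <- rowSums(!is.na(weights))
  data.frame(transition = rownames(weights), median_weight = med,
             weight_iqr = iqr, n_weights = n,
             pass = !is.na(med) & med > threshold,
             stringsAsFactors = FALSE)
}

#' Normalized unscaled standard error (NUSE) run quality
#'
#' For peptide p in run j the total transition weight is
#' \eqn{W_{pj} = \sum_i w_{ij}}; the unscaled standard error is
#' \eqn{1/\sqrt{W_{pj}}}, and NUSE divides it by its median across runs so
#' each peptide's NUSE is centred at 1 by construction.  Runs are then
#' summarized by the median and IQR of NUSE over peptides; a run fails when
#' its median NUSE exceeds \code{threshold} (default 1.05, i.e. a 5\%
#' standard-error inflation).
#'
#' @param fits list of \code{PeptideFit} (e.g. \code{fitAllPeptides()$fits})
#' @param threshold run flag threshold on the median NUSE (default 1.05)
#' @return list with \code{nuse} (peptides x runs matrix) and \code{runs}
#'   (data.frame: run, median_nuse, nuse_iqr, n_peptides, pass)
#' @export
nuseTable <- function(fits, threshold = 1.05) {
  if (is.list(fits) && !is.null(fits$fits)) fits <- fits$fits
  if (length(fits) == 0L) mrmConfigError("no peptide fits supplied")
  runs <- names(fits[[1L]]@beta)
  nuse <- matrix(NA_real_, length(fits), length(runs),
                 dimnames = list(names(fits), runs))
  for (p in seq_along(fits)) {
    W <- colSums(peakWeights(fits[[p]]), na.rm = TRUE)
    W <- W[runs]
    zero <- !is.na(W) & W == 0
    if (any(zero)) {
      warning("peptide '", names(fits)[p], "' has zero total weight in ",
              sum(zero), " run(s); NUSE set to NA there", call. = FALSE)
      W[zero] <- NA_real_
    }
    se <- 1 / sqrt(W)
    nuse[p, ] <- se / median(se, na.rm = TRUE)
  }
  medRun <- .colMedians(nuse)
  iqrRun <- apply(nuse, 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else IQR(v)
  })
  runsDf <- data.frame(run = runs, median_nuse = medRun, nuse_iqr = iqrRun,
                       n_peptides = colSums(!is.na(nuse)),
                       pass = !is.na(medRun) & medRun <= threshold,
                       stringsAsFactors = FALSE)
  rownames(runsDf) <- NULL
  list(nuse = nuse, runs = runsDf)
}
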