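# Group-aware evaluation of normalization performance and the Welch screen.
#
# Within-group variance is the yardstick: for each feature a one-factor
# model with the group variable is fitted, the mean squared error estimates
# the experimental noise, and CV = 100 * rootMSE / mean(log2 area).  Note
# the denominator is the log2-scale mean, which makes the CV directly
# comparable across normalizations that preserve the overall log2 level.

#' Per-feature group-model MSE and CV
#'
#' For each feature (row), residuals are taken about the group means of the
#' observed cells; \code{MSE = SSR / (n - K)} where K is the number of
#' groups with at least one observation, and
#' \code{cv_percent = 100 * sqrt(MSE) / mean(log2 area)}.  With a single
#' group this degenerates to the within-replicate variance about the mean.
#' Features with zero residual degrees of freedom are flagged, not errored.
#'
#' @param x log2 matrix or \code{MRMExperiment}
#' @param groups per-run group labels; defaults to the experiment's
#'   \code{group_id} (falling back to \code{sample_id} for single-condition
#'   designs, where biological samples play the role of groups)
#' @return data.frame per feature: \code{n_obs}, \code{n_groups}, \code{df},
#'   \code{SSR}, \code{MSE}, \code{mean_log2}, \code{cv_percent},
#'   \code{evaluable}
#' @export
#' @examples
#' m <- rbind(f1 = c(10, 12, 14, 16))
#' groupMSE(m, groups = c("a", "a", "b", "b"))
groupMSE <- function(x, groups = NULL) {
  if (is(x, "MRMExperiment")) {
    if (is.null(groups)) {
      groups <- groupIds(x)
      if (is.null(groups) || all(is.na(groups))) groups <- sampleIds(x)
    }
    x <- log2Area(x)
  }
  m <- as.matrix(x)
  if (length(groups) != ncol(m))
    mrmConfigError("groups must have one label per run")
  g <- factor(groups)
  res <- t(apply(m, 1L, function(v) {
    ok <- !is.na(v)
    n <- sum(ok)
    gg <- droplevels(g[ok])
    K <- nlevels(gg)
    if (n == 0L || n - K < 1L)
      return(c(n, K, NA, NA, NA, if (n) mean(v[ok]) else NA, NA))
    mu <- ave(v[ok], gg)
    ssr <- sum((v[ok] - mu)^2)
    df <- n - K
    mse <- ssr / df
    ml <- mean(v[ok])
    c(n, K, df, ssr, mse, ml, 100 * sqrt(mse) / ml)
  }))
  out <- data.frame(res)
  names(out) <- c("n_obs", "n_groups", "df", "SSR", "MSE", "mean_log2",
                  "cv_percent")
  out$evaluable <- !is.na(out$MSE)
  rownames(out) <- rownames(m)
  out
}

#' Compare normalization methods by group-aware MSE and CV
#'
#' Evaluates [groupMSE()] on the original matrix and on each normalized
#' matrix, and reports (a) a per-method summary — median CV, median absolute
#' deviation of CV, and whether the median CV improved — and (b) per-feature
#' MSE ratios (normalized / original) and log2 CV ratios.
#'
#' @param original log2 matrix or \code{MRMExperiment}
#' @param normalized named list of [NormalizationResult-class] objects (or
#'   matrices); names identify methods in the output
#' @param groups per-run group labels (see [groupMSE()])
#' @return list with \code{summary} (one row per method, original first,
#'   then alphabetical) and \code{perFeature} (long data.frame of ratios)
#' @export
compareNormalizations <- function(original, normalized, groups = NULL) {
  if (is(original, "MRMExperiment") && is.null(groups)) {
    groups <- groupIds(original)
    if (is.null(groups) || all(is.na(groups))) groups <- sampleIds(original)
  }
  origMat <- if (is(original, "MRMExperiment")) log2Area(original) else
    as.matrix(original)
  getMat <- function(obj) {
    if (is(obj, "NormalizationResult")) obj <- normalizedData(obj)
    if (is(obj, "MRMExperiment")) obj <- log2Area(obj)
    as.matrix(obj)
  }
  if (is.null(names(normalized)) || any(names(normalized) == ""))
    mrmConfigError("the list of normalized matrices must be named")
  mats <- lapply(normalized, getMat)
  for (nm in names(mats))
    if (!identical(dim(mats[[nm]]), dim(origMat)))
      mrmConfigError(paste0("normalized matrix '", nm,
                            "' does not match the original shape"))
  base <- groupMSE(origMat, groups)
  summarize <- function(tab, method) {
    cv <- tab$cv_percent[tab$evaluable]
    data.frame(method = method, median_cv = median(cv),
               cv_mad = mad(cv), n_features = sum(tab$evaluable),
               stringsAsFactors = FALSE)
  }
  origRow <- summarize(base, "original")
  origRow$improved <- NA
  rows <- list(origRow)
  perFeature <- NULL
  for (nm in sort(names(mats))) {
    tab <- groupMSE(mats[[nm]], groups)
    s <- summarize(tab, nm)
    s$improved <- s$median_cv < origRow$median_cv
    rows[[length(rows) + 1L]] <- s
    pf <- data.frame(method = nm, feature = rownames(tab),
                     mse_ratio = tab$MSE / base$MSE,
                     cv_ratio_log2 = log2(tab$cv_percent / base$cv_percent),
                     stringsAsFactors = FALSE)
    perFeature <- rbind(perFeature, pf)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, perFeature = perFeature)
}

#' Welch two-group screen
#'
#' Per-feature Welch t-test (unequal variances, Welch–Satterthwaite degrees
#' of freedom) between exactly two groups, with the significance flag at
#' \code{alpha} on the raw p-value by default; Benjamini–Hochberg adjustment
#' is available behind \code{adjust = "BH"}.  Features with fewer than two
#' observations in either group are skipped with a flag.
#'
#' @param x log2 matrix or \code{MRMExperiment}
#' @param groups per-run labels with exactly two levels
#' @param alpha significance cutoff (default 0.05)
#' @param adjust \code{"none"} (default) or \code{"BH"}
#' @return data.frame per feature: group means, \code{t}, \code{df},
#'   \code{p_value}, \code{p_adjusted}, \code{significant},
#'   \code{evaluable}
#' @export
welchDE <- function(x, groups = NULL, alpha = 0.05,
                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is(x, "MRMExperiment")) {
    if (is.null(groups)) groups <- groupIds(x)
    x <- log2Area(x)
  }
  m <- as.matrix(x)
  g <- factor(groups)
  if (nlevels(g) != 2L)
    mrmConfigError("welchDE requires exactly two groups")
  lv <- levels(g)
  res <- t(apply(m, 1L, function(v) {
    x1 <- v[g == lv[1L]]; x2 <- v[g == lv[2L]]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2L || length(x2) < 2L)
      return(c(mean(x1), mean(x2), NA, NA, NA))
    tt <- t.test(x1, x2, var.equal = FALSE)
    c(mean(x1), mean(x2), unname(tt$statistic), unname(tt$parameter),
      tt$p.value)
  }))
  out <- data.frame(res)
  names(out) <- c(paste0("mean_", lv), "t", "df", "p_value")
  out$p_adjusted <- if (adjust == "BH") p.adjust(out$p_value, "BH") else
    out$p_value
  out$evaluable <- !is.na(out$p_value)
  out$significant <- out$evaluable & out$p_adjusted < alpha
  rownames(out) <- rownames(m)
  out
}
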