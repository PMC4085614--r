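# Independent oracles used to freeze expected values.  Each is a separate,
# deliberately naive derivation of the quantity it checks; none shares code
# with the package internals.

# closed-form OLS for the complete balanced two-way layout with sum-to-zero
# effects: grand mean / row means / column means
olsTwoWayOracle <- function(y) {
  mu <- mean(y)
  list(mu = mu,
       alpha = rowMeans(y) - mu,
       beta = colMeans(y) - mu)
}

# step-by-step IRLS with Huber weights, written against lm() on factor
# covariates with sum contrasts; scale = MAD/0.6745 of current residuals
irlsOracle <- function(y, k = 1.345, tol = 1e-6, maxIter = 100) {
  obs <- which(!is.na(y), arr.ind = TRUE)
  d <- data.frame(y = y[obs],
                  tr = factor(obs[, 1], levels = seq_len(nrow(y))),
                  rn = factor(obs[, 2], levels = seq_len(ncol(y))))
  w <- rep(1, nrow(d))
  old <- NULL
  for (it in 1:maxIter) {
    fit <- lm(y ~ tr + rn, data = d, weights = w,
              contrasts = list(tr = "contr.sum", rn = "contr.sum"))
    cf <- coef(fit)
    r <- d$y - predict(fit)
    s <- max(mad(r), 1e-8)
    u <- abs(r / s)
    w <- ifelse(u <= k, 1, k / u)
    if (!is.null(old) && max(abs(cf - old)) < tol) break
    old <- cf
  }
  aC <- cf[grep("^tr", names(cf))]
  bC <- cf[grep("^rn", names(cf))]
  W <- matrix(NA_real_, nrow(y), ncol(y))
  W[obs] <- w
  list(mu = unname(cf[1]),
       alpha = unname(c(aC, -sum(aC))),
       beta = unname(c(bC, -sum(bC))),
       weights = W, iterations = it)
}

# brute-force quantile normalization for complete matrices without ties:
# replace each column's order statistics by the cross-column mean
quantileOracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- ref[rank(m[, j])]
  out
}

# Welch statistic, Welch-Satterthwaite df and two-sided p by the hand formula
welchOracle <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  v1 <- var(x1) / n1; v2 <- var(x2) / n2
  t <- (mean(x1) - mean(x2)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# noiseless additive peptide block with known effects
additiveBlock <- function(alpha, beta, mu = 20) {
  outer(alpha, beta, "+") + mu
}

# random additive block: sum-zero effects + N(0, sd) noise
randomBlock <- function(I, J, noiseSd = 0.2, mu = 20) {
  a <- rnorm(I); a <- a - mean(a)
  b <- rnorm(J); b <- b - mean(b)
  list(y = additiveBlock(a, b, mu) + matrix(rnorm(I * J, 0, noiseSd), I, J),
       alpha = a, beta = b, mu = mu)
}
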