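# Robust per-peptide two-way fit, transition QC and NUSE.

test_that("exactly additive data are recovered with unit weights", {
  y <- additiveBlock(alpha = c(1, -1), beta = c(0, 0.5, -0.5), mu = 20)
  fit <- fitPeptide(y)
  expect_equal(fit@mu, 20, tolerance = 1e-9)
  expect_equal(unname(fit@alpha), c(1, -1), tolerance = 1e-9)
  expect_equal(unname(fit@beta), c(0, 0.5, -0.5), tolerance = 1e-9)
  expect_true(all(peakWeights(fit) == 1))
  expect_lte(fit@nIterations, 2L)
  expect_true(fit@converged)
  expect_equal(fittedMatrix(fit), y, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a constant matrix fits as mu with zero effects", {
  y <- matrix(18, 4, 5)
  fit <- fitPeptide(y)
  expect_equal(fit@mu, 18)
  expect_equal(max(abs(fit@alpha)), 0, tolerance = 1e-12)
  expect_equal(max(abs(fit@beta)), 0, tolerance = 1e-12)
  expect_true(all(peakWeights(fit) == 1))
})

test_that("alpha sums to zero and a corrupted cell is downweighted, matching
           the step-by-step IRLS oracle", {
  set.seed(101)
  blk <- randomBlock(5, 6, noiseSd = 0.1)
  y <- blk$y
  y[3, 4] <- y[3, 4] - 3.0
  fit <- fitPeptide(y)
  expect_lt(abs(sum(fit@alpha)), 1e-9)
  W <- peakWeights(fit)
  expect_lt(W[3, 4], 0.5)
  # the corrupted cell is the clear minimum; clean cells sit mostly at 1
  expect_true(all(W[-(3 + (4 - 1) * 5)] > W[3, 4]))
  expect_equal(median(W[-(3 + (4 - 1) * 5)]), 1, tolerance = 1e-6)
  # exact agreement with the independently coded IRLS
  oracle <- irlsOracle(y)
  expect_equal(fit@mu, oracle$mu, tolerance = 1e-8)
  expect_equal(unname(fit@alpha), oracle$alpha, tolerance = 1e-8)
  expect_equal(unname(fit@beta), oracle$beta, tolerance = 1e-8)
  expect_equal(unname(W), oracle$weights, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("missing cells are fitted on observed cells only", {
  set.seed(7)
  blk <- randomBlock(4, 6, noiseSd = 0.05)
  y <- blk$y
  y[cbind(c(1, 2, 4), c(2, 5, 6))] <- NA
  fit <- fitPeptide(y)
  oracle <- irlsOracle(y)
  expect_equal(unname(fit@alpha), oracle$alpha, tolerance = 1e-8)
  expect_equal(unname(fit@beta), oracle$beta, tolerance = 1e-8)
  expect_true(all(is.na(peakWeights(fit)[is.na(y)])))
})

test_that("degenerate layouts raise fit errors", {
  expect_error(fitPeptide(matrix(1:6, 1, 6)), class = "mrm_fit_error")
  y <- matrix(NA_real_, 3, 4)
  y[, 1] <- c(10, 11, 12)
  expect_error(fitPeptide(y), class = "mrm_fit_error")   # single run
  # disconnected incidence: transitions 1-2 only in runs 1-2,
  # transition 3 only in runs 3-4
  y <- matrix(NA_real_, 3, 4)
  y[1:2, 1:2] <- 10; y[3, 3:4] <- 12
  expect_error(fitPeptide(y), class = "mrm_fit_error")
})

test_that("bisquare weighting is available and bounded in [0, 1]", {
  set.seed(13)
  blk <- randomBlock(5, 8, noiseSd = 0.1)
  y <- blk$y; y[2, 2] <- y[2, 2] + 4
  fit <- fitPeptide(y, psi = "bisquare", k = 4.685)
  W <- peakWeights(fit)
  expect_true(all(W >= 0 & W <= 1))
  expect_lt(W[2, 2], 0.5)
})

test_that("fitAllPeptides skips single-transition peptides and aligns weights", {
  sim <- simulateMRM(simConfig(nProteins = 2, seed = 21))
  mse <- buildMRMExperiment(sim$records)
  # cut one peptide down to a single transition
  pep <- unique(peptideIds(mse))[2]
  keep <- !(peptideIds(mse) == pep & transitionIds(mse) != "y3")
  mse <- mse[keep, ]
  expect_warning(res <- fitAllPeptides(mse), "skipping peptide")
  expect_identical(res$skipped$peptide, pep)
  expect_false(pep %in% names(res$fits))
  expect_identical(dim(res$weights), dim(log2Area(mse)))
  # skipped peptide's rows carry no weights; fitted rows do
  expect_true(all(is.na(res$weights[peptideIds(mse) == pep, ])))
  expect_true(all(!is.na(res$weights[peptideIds(mse) != pep, ])))
})

test_that("contaminated cells receive visibly lower weights in a full fit", {
  sim <- simulateMRM(simConfig(nProteins = 7, seed = 33,
                               outlierProportion = 0.05,
                               outlierMagnitude = 3, noiseSd = 0.2))
  mse <- buildMRMExperiment(sim$records)
  res <- fitAllPeptides(mse)
  W <- res$weights
  out <- sim$truth$outliers
  key <- paste(out$peptide_id, out$transition_id, sep = "|")
  idx <- cbind(match(key, rownames(W)), match(out$run_id, colnames(W)))
  contaminated <- W[idx]
  cleanMedian <- median(W[-((idx[, 2] - 1) * nrow(W) + idx[, 1])],
                        na.rm = TRUE)
  expect_gte(mean(contaminated < cleanMedian), 0.9)
})

test_that("transitionQC summarizes median weight and IQR with a strict 0.9
           pass", {
  W <- rbind(good = rep(1, 10),
             mixed = c(rep(0.5, 6), rep(1, 4)),
             border = rep(0.9, 10))
  qc <- transitionQC(W)
  expect_equal(qc["good", "median_weight"], 1)
  expect_equal(qc["good", "weight_iqr"], 0)
  expect_true(qc["good", "pass"])
  expect_equal(qc["mixed", "median_weight"], 0.5)
  expect_false(qc["mixed", "pass"])
  # exactly at the threshold fails: the rule is strictly greater
  expect_false(qc["border", "pass"])
  # configurable threshold
  expect_true(transitionQC(W, threshold = 0.4)["mixed", "pass"])
})

test_that("NUSE is 1 everywhere for balanced unit weights and medians are 1
           by construction", {
  fits <- list(
    p1 = fitPeptide(additiveBlock(c(1, 0, -1), c(0.2, -0.2, 0, 0))),
    p2 = fitPeptide(additiveBlock(c(0.5, -0.5), c(0, 0.1, -0.1, 0))))
  nt <- nuseTable(fits)
  expect_equal(unname(nt$nuse), matrix(1, 2, 4), tolerance = 1e-12)
  expect_true(all(nt$runs$pass))
  # per-peptide median over runs is exactly 1 even with uneven weights
  sim <- simulateMRM(simConfig(nProteins = 4, seed = 17,
                               outlierProportion = 0.08))
  res <- fitAllPeptides(buildMRMExperiment(sim$records))
  nt2 <- nuseTable(res$fits)
  meds <- apply(nt2$nuse, 1, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(1, nrow(nt2$nuse)), tolerance = 1e-12)
})

test_that("NUSE arithmetic matches the 1/sqrt(W) definition", {
  # one run with W = 4.05 against 5.0 elsewhere
  W <- matrix(1, 5, 3, dimnames = list(NULL, paste0("r", 1:3)))
  W[1, 3] <- 0.05   # column sums: 5, 5, 4.05
  fit <- fitPeptide(additiveBlock(c(2, 1, 0, -1, -2), c(0, 0, 0)))
  fit@weights <- W
  nt <- nuseTable(list(p = fit))
  se <- 1 / sqrt(c(5, 5, 4.05))
  expect_equal(unname(nt$nuse[1, ]), se / median(se), tolerance = 1e-9)
  expect_equal(unname(nt$nuse[1, 3]), (1 / sqrt(4.05)) / (1 / sqrt(5)),
               tolerance = 1e-9)
})

test_that("run flagged when median NUSE exceeds 1.05", {
  # weights chosen so run 1 has an SE exactly 6% above the peptide median
  W1 <- matrix(1, 4, 3, dimnames = list(NULL, paste0("r", 1:3)))
  W1[, 1] <- 1 / 1.06^2
  fit <- fitPeptide(additiveBlock(c(1, 0, 0, -1), c(0, 0, 0)))
  fit@weights <- W1
  tab <- nuseTable(list(a = fit, b = fit, c = fit))
  expect_false(tab$runs$pass[1])
  expect_true(all(tab$runs$pass[2:3]))
})

test_that("permuting run order permutes beta, weights and NUSE consistently", {
  set.seed(55)
  blk <- randomBlock(5, 6, noiseSd = 0.15)
  y <- blk$y; y[4, 2] <- y[4, 2] + 2
  colnames(y) <- paste0("r", 1:6)
  perm <- c(3, 1, 6, 2, 5, 4)
  f1 <- fitPeptide(y, tol = 1e-10)
  f2 <- fitPeptide(y[, perm], tol = 1e-10)
  expect_equal(unname(f2@beta), unname(f1@beta[perm]), tolerance = 1e-8)
  expect_equal(unname(peakWeights(f2)), unname(peakWeights(f1)[, perm]),
               tolerance = 1e-6)
  n1 <- nuseTable(list(p = f1))$nuse
  n2 <- nuseTable(list(p = f2))$nuse
  expect_equal(unname(n2[1, ]), unname(n1[1, perm]), tolerance = 1e-8)
})
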