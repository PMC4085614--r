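# The five between-run normalization methods.

test_that("global median matches run medians to the grand median", {
  m <- cbind(r1 = c(8, 10, 12), r2 = c(10, 12, 14))   # medians 10 and 12
  out <- normalizedData(normalizeRuns(m, "global_median"))
  expect_equal(unname(apply(out, 2, median)), c(11, 11))
  # three runs with medians 9, 10, 14 -> all medians become 10
  m3 <- cbind(c(8, 9, 10), c(9, 10, 11), c(13, 14, 15))
  out3 <- normalizedData(normalizeRuns(m3, "global_median"))
  expect_equal(unname(apply(out3, 2, median)), c(10, 10, 10))
  # equal medians: identity
  mi <- cbind(c(1, 5, 9), c(3, 5, 7))
  expect_equal(normalizedData(normalizeRuns(mi, "global_median")), mi)
})

test_that("global median is idempotent and preserves missingness", {
  set.seed(8)
  m <- matrix(rnorm(60, 18), 10, 6)
  m[cbind(1:4, c(2, 3, 3, 5))] <- NA
  once <- normalizedData(normalizeRuns(m, "global_median"))
  twice <- normalizedData(normalizeRuns(once, "global_median"))
  expect_equal(twice, once, tolerance = 1e-9)
  expect_identical(is.na(once), is.na(m))
})

test_that("quantile normalization averages order statistics", {
  m <- cbind(a = c(1, 2, 3), b = c(3, 4, 5))
  out <- normalizedData(normalizeRuns(m, "quantile"))
  expect_equal(unname(out), cbind(c(2, 3, 4), c(2, 3, 4)))
  # identical columns unchanged
  mi <- cbind(c(5, 1, 9), c(5, 1, 9))
  expect_equal(normalizedData(normalizeRuns(mi, "quantile")), mi)
})

test_that("quantile ties receive the mean of their reference values", {
  m <- cbind(c(1, 1, 4), c(2, 3, 4))
  out <- normalizedData(normalizeRuns(m, "quantile"))
  # reference = rowMeans(sorted) = (1.5, 2, 4); both 1s share (1.5+2)/2
  expect_equal(unname(out[, 1]), c(1.75, 1.75, 4))
  expect_equal(unname(out[, 2]), c(1.5, 2, 4))
})

test_that("quantile agrees with the brute-force oracle and limma on
           complete data", {
  set.seed(20)
  for (rep in 1:5) {
    m <- matrix(rnorm(300, 18, 2), 50, 6)
    out <- normalizedData(normalizeRuns(m, "quantile"))
    expect_equal(out, quantileOracle(m), tolerance = 1e-12)
  }
  skip_if_not_installed("limma")
  m <- matrix(rnorm(300, 18, 2), 50, 6)
  expect_equal(unname(normalizedData(normalizeRuns(m, "quantile"))),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-9)
})

test_that("quantile with missing cells preserves missingness and run medians
           converge", {
  set.seed(21)
  m <- matrix(rnorm(600, 18, 2), 100, 6)
  m[sample(length(m), 60)] <- NA
  out <- normalizedData(normalizeRuns(m, "quantile"))
  expect_identical(is.na(out), is.na(m))
  meds <- apply(out, 2, median, na.rm = TRUE)
  expect_lt(diff(range(meds)), 0.2)
})

test_that("cyclic loess removes a constant offset and leaves identical runs
           untouched", {
  set.seed(30)
  base <- rnorm(200, 18, 2)
  m <- cbind(r1 = base + 2, r2 = base)
  out <- normalizedData(normalizeRuns(m, "cyclic_loess", maxCycles = 1))
  expect_lt(abs(median(out[, 1] - out[, 2])), 0.02)   # 1% of the offset
  mi <- cbind(base, base)
  outI <- normalizedData(normalizeRuns(mi, "cyclic_loess"))
  expect_lt(max(abs(outI - mi)), 1e-8)
})

test_that("cyclic loess flattens an intensity-dependent distortion", {
  set.seed(31)
  base <- sort(rnorm(300, 18, 2))
  m <- cbind(r1 = base + 0.1 * base, r2 = base)   # M grows with A
  out <- normalizedData(normalizeRuns(m, "cyclic_loess", maxCycles = 5,
                                      tol = 1e-4))
  A <- rowMeans(out)
  interior <- A > quantile(A, 0.1) & A < quantile(A, 0.9)
  expect_lt(abs(median((out[, 1] - out[, 2])[interior])), 0.02)
})

test_that("pairs with too few shared cells are skipped with a warning", {
  set.seed(32)
  m <- matrix(rnorm(30, 18), 10, 3)
  m[1:8, 3] <- NA   # only 2 shared cells with run 3
  w <- capture_warnings(normalizeRuns(m, "cyclic_loess", minPairObs = 5))
  expect_true(any(grepl("pair skipped", w)))
})

test_that("subset median shifts runs by the control offset only", {
  m <- matrix(rnorm(48, 18, 0.0), 8, 6)   # flat matrix
  rownames(m) <- paste0("f", 1:8)
  m[5:8, ] <- m[5:8, ] + 3    # non-controls at a different level
  m2 <- m; m2[, 2] <- m2[, 2] + 1   # run 2 shifted everywhere
  res <- normalizeRuns(m2, "subset_median", controls = paste0("f", 1:4))
  expect_equal(unname(res@diagnostics$factors),
               c(0, 1, 0, 0, 0, 0))
  expect_equal(normalizedData(res), m, tolerance = 1e-12)
  # controls flat, non-controls shifted: factors all zero, data untouched
  m3 <- m; m3[5:8, 2] <- m3[5:8, 2] + 2
  res3 <- normalizeRuns(m3, "subset_median", controls = paste0("f", 1:4))
  expect_equal(unname(res3@diagnostics$factors), rep(0, 6))
  expect_equal(normalizedData(res3), m3)
})

test_that("subset median never alters within-run contrasts", {
  set.seed(40)
  m <- matrix(rnorm(120, 18, 2), 20, 6)
  rownames(m) <- paste0("f", 1:20)
  out <- normalizedData(normalizeRuns(m, "subset_median",
                                      controls = paste0("f", 1:5)))
  for (j in 1:6)
    expect_equal(diff(out[, j]), diff(m[, j]), tolerance = 1e-12)
})

test_that("subset median validates controls and accepts peptide ids on an
           experiment", {
  m <- matrix(rnorm(40, 18), 10, 4)
  rownames(m) <- paste0("f", 1:10)
  expect_error(normalizeRuns(m, "subset_median", controls = c("f1", "nope")),
               class = "mrm_config_error")
  expect_error(normalizeRuns(m, "subset_median"),
               class = "mrm_config_error")
  sim <- simulateMRM(simConfig(nProteins = 2, seed = 12))
  mse <- buildMRMExperiment(sim$records)
  ctl <- unique(peptideIds(mse))[1:2]   # IS-peptide style control set
  res <- normalizeRuns(mse, "subset_median", controls = ctl)
  expect_s4_class(normalizedData(res), "MRMExperiment")
  expect_identical(sum(res@diagnostics$control_rows > 0), 10L)
})

test_that("invariant set removes a constant run shift", {
  set.seed(50)
  base <- rnorm(100, 18, 2)
  m <- cbind(r1 = base, r2 = base, r3 = base + 1)
  res <- normalizeRuns(m, "invariant_set")
  out <- normalizedData(res)
  # every feature rank-invariant in every run
  expect_true(all(res@diagnostics$set_sizes == 100))
  expect_lt(max(abs(out[, 3] - base)), 0.05)
})

test_that("invariant set inverts a strictly monotone distortion", {
  set.seed(51)
  base <- sort(runif(150, 14, 24))
  g <- base + 0.02 + 0.1 * (base - 19)^2 / 10   # strictly monotone
  m <- cbind(r1 = base, r2 = base, r3 = g)
  res <- normalizeRuns(m, "invariant_set")
  expect_true(all(res@diagnostics$set_sizes[3] == 150))
  out <- normalizedData(res)
  interior <- base > quantile(base, 0.1) & base < quantile(base, 0.9)
  expect_lt(max(abs((out[, 3] - base)[interior])), 0.05)
})

test_that("invariant set excludes strongly shifted features", {
  set.seed(52)
  n <- 200
  base <- runif(n, 12, 24)
  de <- seq_len(n) <= 40   # 20% shifted features
  m <- sapply(1:6, function(j) base + rnorm(n, 0, 0.1))
  for (j in 4:6) m[de, j] <- m[de, j] + rep(c(1.5, -1.5), 20)
  res <- normalizeRuns(m, "invariant_set")
  mem <- res@diagnostics$invariant_members
  # in the shifted runs the invariant set is drawn from the null features
  fracNull <- colSums(mem[!de, 4:6]) / colSums(mem[, 4:6])
  expect_true(all(fracNull >= 0.9))
})

test_that("all methods preserve shape, missingness and the log2 scale", {
  set.seed(60)
  sim <- simulateMRM(simConfig(nProteins = 4, seed = 60, missingRate = 0.05,
                               runEffectSd = 0.4))
  mse <- buildMRMExperiment(sim$records)
  ctl <- unique(peptideIds(mse))[1:3]
  for (meth in c("global_median", "quantile", "cyclic_loess",
                 "subset_median", "invariant_set")) {
    res <- normalizeRuns(mse, meth, controls = ctl, minPairObs = 10)
    out <- normalizedData(res)
    expect_identical(dim(out), dim(mse))
    expect_identical(is.na(log2Area(out)), is.na(log2Area(mse)))
    # overall level preserved (log2 scale retained)
    expect_lt(abs(median(log2Area(out), na.rm = TRUE) -
                    median(log2Area(mse), na.rm = TRUE)), 0.5)
  }
})

test_that("every method removes a pure run-level additive artifact", {
  set.seed(61)
  n <- 120
  base <- runif(n, 14, 24)
  delta <- c(-0.8, -0.3, 0, 0.2, 0.5, 0.9)
  m <- sapply(delta, function(d) base + d + rnorm(n, 0, 0.02))
  rownames(m) <- paste0("f", seq_len(n))
  ctl <- paste0("f", 1:30)
  # pairwise half-corrections converge geometrically; large 6-run drifts
  # need more than the default number of cycles to settle
  for (meth in c("global_median", "quantile", "cyclic_loess",
                 "subset_median", "invariant_set")) {
    out <- normalizedData(normalizeRuns(m, meth, controls = ctl,
                                        maxCycles = 10L, tol = 1e-5))
    resid <- sweep(out, 1, rowMeans(out))
    runBias <- colMeans(resid)
    expect_lt(max(abs(runBias - mean(runBias))), 0.05,
              label = paste("run bias after", meth))
  }
})
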