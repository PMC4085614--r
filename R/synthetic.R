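# Synthetic MRM data with known ground truth.
#
# Emulates the structure of a targeted label-free experiment: proteins
# represented by ~3 peptides, each peptide by ~5 fragment transitions, runs
# organised as technical replicates of biological samples, optionally split
# into treatment groups.  On the log2 scale a cell is
#   peptide level + transition effect + run effect + group effect + noise,
# with sporadic interference outliers added at the cell level, and retention
# times are a peptide elution time plus a run-constant drift plus jitter.

#' Simulation configuration
#'
#' Defaults mirror a single-condition technical-variability study: 5
#' transitions per peptide, 3 peptides per protein, 6 biological samples
#' run 3 times each (18 runs), retention times spread over 20-60 minutes.
#' All effects are on the log2 scale except retention times (minutes).
#'
#' @param nProteins,peptidesPerProtein,transitionsPerPeptide panel layout
#' @param nGroups,samplesPerGroup,techReps run design: runs =
#'   nGroups * samplesPerGroup * techReps
#' @param baseRange range of peptide log2 levels (uniform draw)
#' @param alphaSd sd of transition effects (log2)
#' @param runEffectSd sd of run-constant intensity effects (log2)
#' @param noiseSd residual sd (log2)
#' @param outlierProportion,outlierMagnitude cell-level interference
#'   outliers: Bernoulli proportion, +/- magnitude in log2 units
#' @param deProportion,groupEffectSize fraction of peptides shifted in
#'   non-reference groups (direction-balanced) and the shift size (log2)
#' @param rtRange peptide elution window, minutes (default 20-60)
#' @param rtShiftSd sd of run-constant RT drift, minutes
#' @param rtNoiseSd sd of per-cell RT jitter, minutes
#' @param missingRate missing-at-random cell rate
#' @param seed integer RNG seed; fixes the output exactly
#' @return a \code{SimulationConfig} list
#' @export
simConfig <- function(nProteins = 10L, peptidesPerProtein = 3L,
                      transitionsPerPeptide = 5L, nGroups = 1L,
                      samplesPerGroup = 6L, techReps = 3L,
                      baseRange = c(14, 24), alphaSd = 1.5,
                      runEffectSd = 0.25, noiseSd = 0.25,
                      outlierProportion = 0, outlierMagnitude = 3,
                      deProportion = 0.2, groupEffectSize = 1,
                      rtRange = c(20, 60), rtShiftSd = 0.2,
                      rtNoiseSd = 0.05, missingRate = 0, seed = 1L) {
  cfg <- list(nProteins = as.integer(nProteins),
              peptidesPerProtein = as.integer(peptidesPerProtein),
              transitionsPerPeptide = as.integer(transitionsPerPeptide),
              nGroups = as.integer(nGroups),
              samplesPerGroup = as.integer(samplesPerGroup),
              techReps = as.integer(techReps),
              baseRange = baseRange, alphaSd = alphaSd,
              runEffectSd = runEffectSd, noiseSd = noiseSd,
              outlierProportion = outlierProportion,
              outlierMagnitude = outlierMagnitude,
              deProportion = deProportion,
              groupEffectSize = groupEffectSize,
              rtRange = rtRange, rtShiftSd = rtShiftSd,
              rtNoiseSd = rtNoiseSd, missingRate = missingRate,
              seed = as.integer(seed))
  counts <- c(cfg$nProteins, cfg$peptidesPerProtein,
              cfg$transitionsPerPeptide, cfg$nGroups, cfg$samplesPerGroup,
              cfg$techReps)
  if (any(counts < 1L)) mrmConfigError("all design counts must be >= 1")
  props <- c(cfg$outlierProportion, cfg$deProportion, cfg$missingRate)
  if (any(props < 0 | props > 1))
    mrmConfigError("proportions must lie in [0, 1]")
  if (any(c(cfg$alphaSd, cfg$runEffectSd, cfg$noiseSd, cfg$rtShiftSd,
            cfg$rtNoiseSd) < 0))
    mrmConfigError("spread parameters must be nonnegative")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Generate a synthetic MRM dataset with ground truth
#'
#' @param config a [simConfig()] object
#' @return list with \code{records} (long-format peak records, the ingest
#'   form) and \code{truth} (list: \code{alpha} per transition row key,
#'   \code{runEffects}, \code{groupEffects} per peptide, \code{outliers}
#'   data.frame, \code{rtBase} per peptide, \code{rtShifts} per run,
#'   \code{peptideLevel})
#' @export
#' @examples
#' sim <- simulateMRM(simConfig(nProteins = 2, seed = 7))
#' str(sim$truth$runEffects)
simulateMRM <- function(config = simConfig()) {
  if (!inherits(config, "SimulationConfig"))
    mrmConfigError("config must come from simConfig()")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  nPep <- config$nProteins * config$peptidesPerProtein
  I <- config$transitionsPerPeptide
  J <- config$nGroups * config$samplesPerGroup * config$techReps

  prot <- sprintf("PROT%03d", rep(seq_len(config$nProteins),
                                  each = config$peptidesPerProtein))
  pep <- sprintf("%s_PEP%02d.2", prot,
                 rep(seq_len(config$peptidesPerProtein), config$nProteins))
  # run design
  groups <- sprintf("G%d", rep(seq_len(config$nGroups),
                               each = config$samplesPerGroup * config$techReps))
  samples <- sprintf("%s_S%02d", groups,
                     rep(rep(seq_len(config$samplesPerGroup),
                             each = config$techReps), config$nGroups))
  reps <- rep(seq_len(config$techReps), config$samplesPerGroup * config$nGroups)
  runs <- sprintf("%s_R%d", samples, reps)

  pepLevel <- runif(nPep, config$baseRange[1L], config$baseRange[2L])
  delta <- rnorm(J, 0, config$runEffectSd)
  names(delta) <- runs
  rtShift <- rnorm(J, 0, config$rtShiftSd)
  names(rtShift) <- runs
  rtBase <- runif(nPep, config$rtRange[1L], config$rtRange[2L])
  names(rtBase) <- pep
  names(pepLevel) <- pep

  # direction-balanced group effects on a fraction of peptides
  groupEff <- setNames(rep(0, nPep), pep)
  if (config$nGroups > 1L && config$deProportion > 0) {
    nDE <- round(config$deProportion * nPep)
    dePep <- sample(nPep, nDE)
    sgn <- rep(c(1, -1), length.out = nDE)
    groupEff[dePep] <- sgn * config$groupEffectSize
  }

  recs <- vector("list", nPep)
  truthAlpha <- numeric(0)
  outliers <- NULL
  fragNames <- sprintf("y%d", 2L + seq_len(I))
  for (p in seq_len(nPep)) {
    alpha <- rnorm(I, 0, config$alphaSd)
    alpha <- alpha - mean(alpha)
    names(alpha) <- fragNames
    gE <- ifelse(groups == "G1", 0, groupEff[p])
    y <- pepLevel[p] + outer(alpha, delta + gE, "+") +
      matrix(rnorm(I * J, 0, config$noiseSd), I, J)
    if (config$outlierProportion > 0) {
      hit <- which(matrix(runif(I * J) < config$outlierProportion, I, J))
      if (length(hit)) {
        sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
        y[hit] <- y[hit] + sgn * config$outlierMagnitude
        oi <- arrayInd(hit, c(I, J))
        outliers <- rbind(outliers, data.frame(
          peptide_id = pep[p], transition_id = fragNames[oi[, 1L]],
          run_id = runs[oi[, 2L]], shift = sgn * config$outlierMagnitude,
          stringsAsFactors = FALSE))
      }
    }
    rt <- rtBase[p] + matrix(rep(rtShift, each = I), I, J) +
      matrix(rnorm(I * J, 0, config$rtNoiseSd), I, J)
    truthAlpha <- c(truthAlpha,
                    setNames(alpha, paste(pep[p], fragNames, sep = "|")))
    recs[[p]] <- data.frame(
      protein_id = prot[p], peptide_id = pep[p],
      transition_id = rep(fragNames, J),
      run_id = rep(runs, each = I), sample_id = rep(samples, each = I),
      group_id = rep(groups, each = I), replicate = rep(reps, each = I),
      peak_area = 2^as.vector(y), retention_time = as.vector(rt),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  if (config$missingRate > 0) {
    keep <- runif(nrow(records)) >= config$missingRate
    records <- records[keep, , drop = FALSE]
    rownames(records) <- NULL
  }
  list(records = records,
       truth = list(alpha = truthAlpha, runEffects = delta,
                    groupEffects = groupEff, outliers = outliers,
                    rtBase = rtBase, rtShifts = rtShift,
                    peptideLevel = pepLevel,
                    design = data.frame(run_id = runs, sample_id = samples,
                                        group_id = groups, replicate = reps,
                                        stringsAsFactors = FALSE)),
       config = config)
}

#' Named small fixtures with documented ground truth
#'
#' \describe{
#'   \item{tiny_clean}{4 peptides x 5 transitions x 18 runs, noiseless
#'     intensities, no artifacts; nothing is flagged, by construction.}
#'   \item{rt_shifted}{as tiny_clean but with a known run-constant RT drift
#'     (\code{truth$rtShifts}) and no RT jitter.}
#'   \item{one_bad_transition}{as tiny_clean plus one transition
#'     (\code{truth$badTransition}) given an alternating +/-1.5 log2
#'     interference pattern — non-parallel to its siblings.}
#'   \item{run_artifact}{as tiny_clean with one run (\code{truth$badRun})
#'     shifted +1 log2 unit.}
#'   \item{two_group_de}{10 peptides, 2 groups x 3 samples x 3 reps; 20\%
#'     of peptides shifted in group 2, direction-balanced
#'     (\code{truth$groupEffects}).}
#' }
#'
#' @param name fixture name
#' @param seed RNG seed (default 42)
#' @return list with \code{records} and \code{truth}
#' @export
makeFixture <- function(name = c("tiny_clean", "rt_shifted",
                                 "one_bad_transition", "run_artifact",
                                 "two_group_de"), seed = 42L) {
  name <- match.arg(name)
  base <- function(...) {
    # noiseless intensities over 18 runs (6 samples x 3 replicates): the
    # QC verdicts on these fixtures are then properties of the construction
    # alone, not of a noise realization
    args <- list(nProteins = 4L, peptidesPerProtein = 1L, nGroups = 1L,
                 samplesPerGroup = 6L, techReps = 3L, noiseSd = 0,
                 runEffectSd = 0.1, rtShiftSd = 0, rtNoiseSd = 0.01,
                 seed = seed)
    do.call(simConfig, utils::modifyList(args, list(...)))
  }
  if (name == "tiny_clean") {
    sim <- simulateMRM(base())
  } else if (name == "rt_shifted") {
    sim <- simulateMRM(base(rtNoiseSd = 0))
    J <- nrow(sim$truth$design)
    shifts <- seq(-0.6, 0.6, length.out = J)
    names(shifts) <- sim$truth$design$run_id
    sim$records$retention_time <- sim$records$retention_time +
      shifts[sim$records$run_id]
    sim$truth$rtShifts <- shifts
  } else if (name == "one_bad_transition") {
    sim <- simulateMRM(base())
    pep <- unique(sim$records$peptide_id)[1L]
    tr <- "y5"
    sel <- sim$records$peptide_id == pep & sim$records$transition_id == tr
    runs <- sim$truth$design$run_id
    wob <- setNames(rep(c(1.5, -1.5), length.out = length(runs)), runs)
    sim$records$peak_area[sel] <-
      sim$records$peak_area[sel] * 2^wob[sim$records$run_id[sel]]
    sim$truth$badTransition <- paste(pep, tr, sep = "|")
  } else if (name == "run_artifact") {
    sim <- simulateMRM(base(runEffectSd = 0))
    badRun <- sim$truth$design$run_id[2L]
    sel <- sim$records$run_id == badRun
    sim$records$peak_area[sel] <- sim$records$peak_area[sel] * 2
    sim$truth$badRun <- badRun
    sim$truth$runEffects[badRun] <- sim$truth$runEffects[badRun] + 1
  } else {  # two_group_de
    sim <- simulateMRM(simConfig(nProteins = 10L, peptidesPerProtein = 1L,
                                 nGroups = 2L, samplesPerGroup = 3L,
                                 techReps = 3L, noiseSd = 0.15,
                                 runEffectSd = 0.15, deProportion = 0.2,
                                 groupEffectSize = 1.5, seed = seed))
  }
  sim
}
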