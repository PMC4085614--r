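# End-to-end pipeline: import -> RT QC -> robust fit -> transition/run QC ->
# normalization -> evaluation -> Welch screen, with file outputs and a
# machine-readable run log.

#' Build a pipeline configuration
#'
#' @param input path to a long-format transition report (CSV/TSV)
#' @param outDir output directory (created)
#' @param columnMap see [defaultColumnMap()]
#' @param minRuns detection filter (default 2)
#' @param rtLow,rtHigh,rtSingle RT CV thresholds in percent (defaults 4, 7, 5)
#' @param weightThresh transition pass threshold on median weight (0.9)
#' @param nuseThresh run pass threshold on median NUSE (1.05)
#' @param huberK robust tuning constant (1.345)
#' @param methods normalization methods to run (subset of
#'   \code{global_median, quantile, cyclic_loess, subset_median,
#'   invariant_set})
#' @param controls control feature ids for \code{subset_median}
#' @param alpha Welch screen significance cutoff (0.05)
#' @param fdr \code{"none"} or \code{"bh"}
#' @param removeFlagged drop flagged transitions before normalization
#'   (default FALSE: flag-and-report only, reversible)
#' @param seed recorded in the run log
#' @return a \code{PipelineConfig} list
#' @export
pipelineConfig <- function(input, outDir, columnMap = defaultColumnMap(),
                           minRuns = 2L, rtLow = 4, rtHigh = 7, rtSingle = 5,
                           weightThresh = 0.9, nuseThresh = 1.05,
                           huberK = 1.345,
                           methods = c("global_median", "quantile"),
                           controls = NULL, alpha = 0.05,
                           fdr = c("none", "bh"), removeFlagged = FALSE,
                           seed = 1L) {
  fdr <- match.arg(fdr)
  thr <- c(minRuns, rtLow, rtHigh, rtSingle, weightThresh, nuseThresh,
           huberK, alpha)
  if (any(thr <= 0)) mrmConfigError("all thresholds must be positive")
  bad <- setdiff(methods, .NORM_METHODS)
  if (length(bad))
    mrmConfigError(paste("unknown normalization method(s):",
                         paste(bad, collapse = ", ")))
  cfg <- list(input = input, outDir = outDir, columnMap = columnMap,
              minRuns = as.integer(minRuns), rtLow = rtLow, rtHigh = rtHigh,
              rtSingle = rtSingle, weightThresh = weightThresh,
              nuseThresh = nuseThresh, huberK = huberK, methods = methods,
              controls = controls, alpha = alpha, fdr = fdr,
              removeFlagged = isTRUE(removeFlagged), seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys match the arguments of [pipelineConfig()]; a
#' \code{column_map} mapping overrides [defaultColumnMap()] entries.
#'
#' @param path YAML file
#' @return a \code{PipelineConfig}
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) mrmConfigError(paste("config file not found:", path))
  y <- yaml::read_yaml(path)
  cm <- defaultColumnMap()
  if (!is.null(y$column_map)) {
    override <- unlist(y$column_map)
    cm[names(override)] <- override
  }
  arg <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  pipelineConfig(
    input = y$input, outDir = arg("out_dir", "mrmprep_out"), columnMap = cm,
    minRuns = arg("min_runs", 2L), rtLow = arg("rt_low_cv", 4),
    rtHigh = arg("rt_high_cv", 7), rtSingle = arg("rt_single_cv", 5),
    weightThresh = arg("weight_thresh", 0.9),
    nuseThresh = arg("nuse_thresh", 1.05), huberK = arg("huber_k", 1.345),
    methods = arg("methods", c("global_median", "quantile")),
    controls = y$controls, alpha = arg("alpha", 0.05),
    fdr = arg("fdr", "none"), removeFlagged = arg("remove_flagged", FALSE),
    seed = arg("seed", 1L))
}

#' Run the whole pre-processing pipeline
#'
#' Imports the transition report, applies the minimum-detection filter, runs
#' retention-time QC, fits the robust per-peptide model, summarizes
#' transition and run quality, applies each requested normalization,
#' evaluates them with the group-aware MSE/CV framework, and runs the Welch
#' screen when the design has exactly two groups.  All tables are written as
#' CSV under \code{outDir} together with a YAML run log (package version,
#' seed, thresholds).  Data errors abort with a stage-named condition;
#' warnings never abort.
#'
#' @param config a [pipelineConfig()] (or path to a YAML config)
#' @return invisibly, a list with every intermediate result (experiment,
#'   rtQuality, fits, transitionQC, nuse, normalizations, evaluation, de,
#'   flaggedTransitions, flaggedRuns)
#' @export
#' @examples
#' fx <- makeFixture("tiny_clean")
#' tmp <- tempfile(); dir.create(tmp)
#' writeTransitionReport(fx$records, file.path(tmp, "report.csv"))
#' cfg <- pipelineConfig(file.path(tmp, "report.csv"),
#'                       file.path(tmp, "out"), methods = "global_median")
#' res <- runPipeline(cfg)
#' res$transitionQC[!res$transitionQC$pass, ]
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  if (!inherits(config, "PipelineConfig"))
    mrmConfigError("config must come from pipelineConfig()")
  stage <- function(name, expr) {
    tryCatch(expr, mrm_error = function(e) {
      stop(errorCondition(paste0("[", name, "] ", conditionMessage(e)),
                          class = class(e)))
    })
  }
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

  records <- stage("import",
    readTransitionReport(config$input, columnMap = config$columnMap))
  mse <- stage("import", buildMRMExperiment(records))
  mse <- stage("filter", filterMinDetected(mse, config$minRuns))

  rtq <- stage("rt-qc",
    rtQuality(mse, config$rtLow, config$rtHigh, config$rtSingle))
  write.csv(rtq$report, file.path(config$outDir, "rt_report.csv"),
            row.names = FALSE)

  fits <- stage("robust-fit", fitAllPeptides(mse, k = config$huberK))
  tqc <- stage("qc", transitionQC(fits$weights, config$weightThresh))
  nus <- stage("qc", nuseTable(fits$fits, config$nuseThresh))
  write.csv(tqc, file.path(config$outDir, "transition_qc.csv"),
            row.names = FALSE)
  write.csv(nus$runs, file.path(config$outDir, "run_qc.csv"),
            row.names = FALSE)

  flaggedTr <- rownames(log2Area(mse))[!tqc$pass |
                                         rtq$report$flag_two_sided]
  flaggedRuns <- nus$runs$run[!nus$runs$pass]
  work <- mse
  if (config$removeFlagged && length(flaggedTr))
    work <- work[!rownames(log2Area(work)) %in% flaggedTr, ]

  norms <- list()
  for (meth in config$methods) {
    norms[[meth]] <- stage("normalize",
      normalizeRuns(work, meth, controls = config$controls))
    writeMRMExperiment(normalizedData(norms[[meth]]),
                       file.path(config$outDir, paste0("normalized_", meth)))
  }

  groups <- groupIds(work)
  if (is.null(groups) || all(is.na(groups))) groups <- sampleIds(work)
  evalTab <- NULL
  if (length(norms) && length(unique(groups)) >= 1L) {
    evalTab <- stage("evaluate",
      compareNormalizations(work, norms, groups = groups))
    write.csv(evalTab$summary, file.path(config$outDir, "evaluation.csv"),
              row.names = FALSE)
  }

  de <- NULL
  gid <- groupIds(work)
  if (!is.null(gid) && !all(is.na(gid)) &&
      length(unique(gid[!is.na(gid)])) == 2L) {
    deIn <- if (length(norms)) normalizedData(norms[[1L]]) else work
    de <- stage("de", welchDE(deIn, gid, alpha = config$alpha,
                              adjust = if (config$fdr == "bh") "BH" else
                                "none"))
    write.csv(cbind(feature = rownames(de), de),
              file.path(config$outDir, "de.csv"), row.names = FALSE)
  }

  log <- list(package = "mrmprep",
              version = as.character(packageVersion("mrmprep")),
              r_version = as.character(getRversion()),
              seed = config$seed,
              thresholds = config[c("minRuns", "rtLow", "rtHigh", "rtSingle",
                                    "weightThresh", "nuseThresh", "huberK",
                                    "alpha")],
              methods = config$methods,
              n_transitions = nrow(mse), n_runs = ncol(mse),
              flagged_transitions = as.list(flaggedTr),
              flagged_runs = as.list(flaggedRuns))
  yaml::write_yaml(log, file.path(config$outDir, "run_log.yaml"))

  invisible(list(experiment = mse, rtQuality = rtq, fits = fits,
                 transitionQC = tqc, nuse = nus, normalizations = norms,
                 evaluation = evalTab, de = de,
                 flaggedTransitions = flaggedTr, flaggedRuns = flaggedRuns,
                 config = config))
}
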