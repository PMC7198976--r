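## End-to-end orchestration: one validated config drives simulate -> pool ->
## PRE -> error -> test (or the 100-repetition binomial procedure) and writes
## a reproducible report bundle.

VARIANT_DEFAULTS <- list(
  anesthetized_activation = list(th = 0.1, bin_width_s = 0.010,
                                 window_s = c(-0.040, 0.100),
                                 n_neurons = 13, n_trials = 150),
  anesthetized_inhibition = list(th = 0.04, bin_width_s = 0.010,
                                 window_s = c(-0.040, 0.100),
                                 n_neurons = 19, n_trials = 150),
  awake_touch = list(th = 0.1, bin_width_s = 0.004,
                     window_s = c(-0.020, 0.040), n_neurons = 12,
                     n_rep = 100, per_cell_sample = 53,
                     touches_per_cell = c(60, 90)),
  linear_probe = list(th = 0.05, bin_width_s = 0.010,
                      window_s = c(-0.040, 0.100), n_neurons = 16,
                      n_trials = 150))

#' Build and validate a pipeline configuration
#'
#' @param variant one of \code{"anesthetized_activation"},
#'   \code{"anesthetized_inhibition"}, \code{"awake_touch"},
#'   \code{"linear_probe"}.
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it deterministically.
#' @param outDir output directory for the report bundle (created if needed);
#'   NULL to skip writing.
#' @param ... overrides of the variant defaults (\code{th},
#'   \code{bin_width_s}, \code{window_s}, \code{n_neurons}, \code{n_trials},
#'   \code{alpha}, \code{n_rep}, \code{per_cell_sample}, \code{rho},
#'   \code{profiles} - a named list of \linkS4class{RateProfile}s, reference
#'   condition first).
#' @return A validated config (list, class \code{popspike_config}).
#' @export
pipelineConfig <- function(variant = c("anesthetized_activation",
                                       "anesthetized_inhibition",
                                       "awake_touch", "linear_probe"),
                           seed, outDir = NULL, ...) {
  variant <- match.arg(variant)
  stopifnot(!missing(seed))
  cfg <- VARIANT_DEFAULTS[[variant]]
  cfg$alpha <- 0.05
  cfg$rho <- 0
  over <- list(...)
  cfg[names(over)] <- over
  cfg$variant <- variant
  cfg$seed <- as.integer(seed)
  cfg$out_dir <- outDir
  validatePipelineConfig(cfg)
}

validatePipelineConfig <- function(cfg) {
  need <- c("variant", "seed", "th", "bin_width_s", "window_s", "alpha")
  missing <- need[vapply(need, function(f) is.null(cfg[[f]]), logical(1))]
  if (length(missing))
    stop(sprintf("config is missing required field(s): %s",
                 paste(missing, collapse = ", ")))
  stopifnot(cfg$th > 0, cfg$bin_width_s > 0,
            length(cfg$window_s) == 2, cfg$alpha > 0, cfg$alpha < 1)
  makeBinEdges(cfg$window_s, cfg$bin_width_s)  # must tile exactly
  class(cfg) <- "popspike_config"
  cfg
}

#' Read / write a pipeline config as YAML
#' @param path YAML file path.
#' @return \code{readPipelineConfig}: a validated config.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$window_s <- as.numeric(cfg$window_s)
  validatePipelineConfig(cfg)
}

#' @rdname readPipelineConfig
#' @param cfg a config from \code{\link{pipelineConfig}}.
#' @export
writePipelineConfig <- function(cfg, path) {
  out <- unclass(cfg)
  out$profiles <- NULL  # profiles are code-level objects, not serialized
  yaml::write_yaml(out, path)
  invisible(path)
}

defaultProfiles <- function(variant) {
  switch(variant,
    anesthetized_activation = list(
      control = rateProfile(condition = "control"),
      opto_activation = rateProfile(condition = "opto_activation",
                                    truncationS = 0.030)),
    anesthetized_inhibition = ,
    linear_probe = list(
      control = rateProfile(condition = "control"),
      opto_inhibition = rateProfile(condition = "opto_inhibition",
                                    lateGain = 2)),
    awake_touch = list(
      control = rateProfile(baselineHz = 5, earlyHz = 40, lateHz = 15,
                            earlyWindow = c(0, 0.020),
                            lateWindow = c(0.020, 0.040),
                            condition = "control"),
      opto_inhibition = rateProfile(baselineHz = 5, earlyHz = 40,
                                    lateHz = 15,
                                    earlyWindow = c(0, 0.020),
                                    lateWindow = c(0.020, 0.040),
                                    condition = "opto_inhibition",
                                    lateGain = 2)),
    stop(sprintf("unknown variant")))
}

#' Run the end-to-end pipeline on synthetic data
#'
#' Executes the stage graph of the configured variant: simulate populations
#' for each condition, build pseudo-simultaneous trials, detect PREs, compute
#' absolute errors and run the condition contrast (anesthetized / probe
#' variants) or the 100-repetition subsample + binomial procedure (awake
#' variant). When \code{out_dir} is set, writes \code{results.json},
#' \code{errors.tsv}, \code{config.yaml} and a human-readable
#' \code{report.txt}.
#'
#' @param cfg a config from \code{\link{pipelineConfig}} or
#'   \code{\link{readPipelineConfig}}.
#' @return The results list (also serialized to JSON), invisibly when writing.
#' @export
runPipeline <- function(cfg) {
  if (!inherits(cfg, "popspike_config")) cfg <- validatePipelineConfig(cfg)
  profiles <- cfg$profiles %||% defaultProfiles(cfg$variant)
  conds <- names(profiles)
  res <- list(variant = cfg$variant, seed = cfg$seed, th = cfg$th,
              bin_width_ms = 1000 * cfg$bin_width_s,
              window_ms = 1000 * cfg$window_s, alpha = cfg$alpha)
  errTab <- NULL
  if (cfg$variant == "awake_touch") {
    nTouch <- cfg$touches_per_cell
    set.seed(deriveSeed(cfg$seed, 11L))
    nev <- sample(nTouch[1]:nTouch[2], cfg$n_neurons, replace = TRUE)
    peris <- setNames(lapply(seq_along(conds), function(ci)
      simulatePeriEvents(profiles[[ci]], nCells = cfg$n_neurons,
                         nEventsPerCell = nev, window = cfg$window_s,
                         seed = deriveSeed(cfg$seed, 12L, ci))), conds)
    proc <- subsampleBinomialProcedure(
      peris, nRep = cfg$n_rep, perCellSample = cfg$per_cell_sample,
      alpha = cfg$alpha, th = cfg$th, binWidth = cfg$bin_width_s,
      window = cfg$window_s, masterSeed = deriveSeed(cfg$seed, 13L))
    res$binomial <- list(decision = proc$decision,
                         n_increase = proc$n_increase,
                         n_decrease = proc$n_decrease,
                         binom_p = as.list(proc$binom_p),
                         fdr = proc$fdr)
    res$median_error_ms <- as.list(1000 * c(
      setNames(median(proc$repetitions$median_ref_s, na.rm = TRUE),
               conds[1]),
      setNames(median(proc$repetitions$median_s, na.rm = TRUE), conds[2])))
    errTab <- proc$repetitions
  } else {
    pres <- list()
    for (ci in seq_along(conds)) {
      sim <- simulatePopulation(profiles[[ci]], nNeurons = cfg$n_neurons,
                                nTrials = cfg$n_trials,
                                binWidth = cfg$bin_width_s,
                                window = cfg$window_s, rho = cfg$rho,
                                seed = deriveSeed(cfg$seed, 21L, ci))
      pooled <- apply(sim$counts, c(1, 3), sum)
      pres[[conds[ci]]] <- pseudoPopFromCounts(pooled, sim$bin_edges,
                                               cfg$n_neurons, conds[ci])
    }
    pre <- absoluteError(detectPREs(pres, th = cfg$th))
    er <- preErrors(pre)
    alt <- if (conds[2] == "opto_activation") "less" else "greater"
    tt <- compareConditions(er$abs_error_s[er$condition == conds[2]],
                            er$abs_error_s[er$condition == conds[1]],
                            alternative = alt, alpha = cfg$alpha)
    res$n_pres <- as.list(table(er$condition))
    res$modes_ms <- as.list(1000 * preModes(pre))
    res$median_error_ms <- lapply(split(er$abs_error_s, er$condition),
                                  function(v) 1000 * median(v))
    res$contrast <- list(test = tt$method, alternative = alt,
                         p = tt$p.value, significant = tt$significant,
                         direction = tt$direction)
    errTab <- er
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(res, file.path(cfg$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(errTab, file.path(cfg$out_dir, "errors.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    writePipelineConfig(cfg, file.path(cfg$out_dir, "config.yaml"))
    rpt <- c(sprintf("popspike pipeline: variant %s, seed %d", cfg$variant,
                     cfg$seed),
             sprintf("Th = %g spikes/unit, bin %g ms, window [%g, %g] ms",
                     cfg$th, 1000 * cfg$bin_width_s, 1000 * cfg$window_s[1],
                     1000 * cfg$window_s[2]),
             if (!is.null(res$contrast))
               sprintf("contrast (%s): p = %.3g, direction %d",
                       res$contrast$test, res$contrast$p,
                       res$contrast$direction),
             if (!is.null(res$binomial))
               sprintf("binomial decision: %s (increase %d, decrease %d of %d reps)",
                       res$binomial$decision, res$binomial$n_increase,
                       res$binomial$n_decrease, cfg$n_rep))
    writeLines(rpt, file.path(cfg$out_dir, "report.txt"))
    return(invisible(res))
  }
  res
}
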