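## Accessor generics; slots are never reached into from user code.

#' @name accessors
#' @title Accessors for popspike classes
#' @param x an object.
#' @param object an object (for \code{show}).
#' @description Small accessor family: \code{spikes}, \code{events},
#'   \code{neuronIds}, \code{periWindow}, \code{counts}, \code{binEdges},
#'   \code{binCenters}, \code{nUnits}, \code{preTimes}, \code{preModes},
#'   \code{preErrors}, \code{traces}, \code{samplingRate}, \code{sweepStates},
#'   \code{psthRates}.
NULL

#' @rdname accessors
#' @export
setGeneric("spikes", function(x) standardGeneric("spikes"))
#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("neuronIds", function(x) standardGeneric("neuronIds"))
#' @rdname accessors
#' @export
setGeneric("periWindow", function(x) standardGeneric("periWindow"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @rdname accessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))
#' @rdname accessors
#' @export
setGeneric("preTimes", function(x) standardGeneric("preTimes"))
#' @rdname accessors
#' @export
setGeneric("preModes", function(x) standardGeneric("preModes"))
#' @rdname accessors
#' @export
setGeneric("preErrors", function(x) standardGeneric("preErrors"))
#' @rdname accessors
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("sweepStates", function(x) standardGeneric("sweepStates"))
#' @rdname accessors
#' @export
setGeneric("psthRates", function(x) standardGeneric("psthRates"))

#' Absolute stimulus-time-estimation error of PREs
#'
#' For each condition, the mode of the (binned) PRE-time distribution is the
#' population's typical latency between stimulus and response; the absolute
#' error of each PRE is |t_PRE - mode|. Ties in the mode are broken by the
#' earliest time.
#'
#' @param x a numeric vector of PRE times (one condition) or a
#'   \linkS4class{PREResult}.
#' @param ... unused.
#' @return For numeric input, a list with \code{mode} and \code{errors}; for a
#'   PREResult, the same object with \code{preModes} and \code{preErrors}
#'   filled.
#' @export
setGeneric("absoluteError", function(x, ...) standardGeneric("absoluteError"))

#' @rdname accessors
#' @export
setMethod("spikes", "SpikeDataset", function(x) x@spikes)
#' @rdname accessors
#' @export
setMethod("spikes", "PeriEventSet", function(x) x@spikes)
#' @rdname accessors
#' @export
setMethod("events", "EventTable", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("events", "PeriEventSet", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("neuronIds", "SpikeDataset",
          function(x) x@neurons$neuron_id)
#' @rdname accessors
#' @export
setMethod("neuronIds", "PeriEventSet", function(x) x@neurons)
#' @rdname accessors
#' @export
setMethod("periWindow", "PeriEventSet", function(x) x@window)
#' @rdname accessors
#' @export
setMethod("counts", "PseudoPopulation", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("binEdges", "PseudoPopulation", function(x) x@bin_edges)
#' @rdname accessors
#' @export
setMethod("binEdges", "PSTH", function(x) x@bin_edges)
#' @rdname accessors
#' @export
setMethod("binCenters", "PseudoPopulation",
          function(x) (x@bin_edges[-1] + x@bin_edges[-length(x@bin_edges)]) / 2)
#' @rdname accessors
#' @export
setMethod("binCenters", "PSTH",
          function(x) (x@bin_edges[-1] + x@bin_edges[-length(x@bin_edges)]) / 2)
#' @rdname accessors
#' @export
setMethod("nUnits", "PseudoPopulation", function(x) x@n_units)
#' @rdname accessors
#' @export
setMethod("preTimes", "PREResult", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("preModes", "PREResult", function(x) x@modes)
#' @rdname accessors
#' @export
setMethod("preErrors", "PREResult", function(x) x@errors)
#' @rdname accessors
#' @export
setMethod("traces", "VmSweepSet", function(x) x@traces)
#' @rdname accessors
#' @export
setMethod("samplingRate", "VmSweepSet", function(x) x@sampling_rate_hz)
#' @rdname accessors
#' @export
setMethod("sweepStates", "VmSweepSet", function(x) x@states)
#' @rdname accessors
#' @export
setMethod("psthRates", "PSTH", function(x) x@rates)

setMethod("show", "SpikeDataset", function(object) {
  cat(sprintf("SpikeDataset: %d spikes, %d neurons, %d trials, conditions: %s\n",
              nrow(object@spikes), nrow(object@neurons),
              length(unique(object@spikes$trial_id)),
              paste(unique(object@spikes$condition), collapse = ", ")))
})

setMethod("show", "EventTable", function(object) {
  ev <- object@events
  cat(sprintf("EventTable: %d events (%s)\n", nrow(ev),
              paste(sprintf("%s: %d", names(table(ev$event_type)),
                            table(ev$event_type)), collapse = ", ")))
})

setMethod("show", "PeriEventSet", function(object) {
  cat(sprintf(
    "PeriEventSet: %d neurons x %d events, window [%g, %g) ms, %d spikes\n",
    length(object@neurons), nrow(object@events),
    1000 * object@window[1], 1000 * object@window[2], nrow(object@spikes)))
})

setMethod("show", "PseudoPopulation", function(object) {
  cat(sprintf(
    "PseudoPopulation: %d trials x %d bins (%g ms), %d units, condition %s\n",
    nrow(object@counts), ncol(object@counts),
    1000 * diff(object@bin_edges)[1], object@n_units, object@condition))
})

setMethod("show", "PREResult", function(object) {
  cat(sprintf("PREResult: Th = %g spikes/unit, %d PREs", object@th,
              nrow(object@events)))
  if (length(object@modes))
    cat(sprintf("; modes (ms): %s",
                paste(sprintf("%s = %g", names(object@modes),
                              1000 * object@modes), collapse = ", ")))
  cat("\n")
})

setMethod("show", "VmSweepSet", function(object) {
  cat(sprintf("VmSweepSet '%s': %d sweeps x %.3g s at %g kHz (%s)\n",
              object@cell_id, ncol(object@traces),
              nrow(object@traces) / object@sampling_rate_hz,
              object@sampling_rate_hz / 1000, object@unit))
})

setMethod("show", "PSTH", function(object) {
  cat(sprintf("PSTH: %d neurons x %d bins (%g ms)%s\n",
              nrow(object@rates), ncol(object@rates),
              1000 * diff(object@bin_edges)[1],
              if (is.na(object@smoothing_sd_s)) "" else
                sprintf(", Gaussian smoothing sd %g ms",
                        1000 * object@smoothing_sd_s)))
})

setMethod("show", "RateProfile", function(object) {
  cat(sprintf(
    "RateProfile [%s]: baseline %g Hz, early +%g Hz %g-%g ms, late +%g Hz %g-%g ms",
    object@condition, object@baseline_hz, object@early_hz,
    1000 * object@early_window[1], 1000 * object@early_window[2],
    object@late_hz, 1000 * object@late_window[1],
    1000 * object@late_window[2]))
  if (is.finite(object@truncation_s))
    cat(sprintf(", truncated at %g ms", 1000 * object@truncation_s))
  if (object@late_gain != 1)
    cat(sprintf(", baseline/late gain x%g", object@late_gain))
  cat("\n")
})
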