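## Central S4 containers. Times are stored in seconds; windows are half-open
## [lo, hi) so that bin assignment is unambiguous.

KNOWN_EVENT_TYPES <- c("whisker_deflection", "pole_presentation", "touch",
                       "light_blue", "light_yellow")
KNOWN_LAYERS <- c("L2/3", "L4", "L5", "L6", "deep", "unknown")
REFRACTORY_TOL <- 0.001 # s; duplicate / refractory-violation tolerance

#' SpikeDataset: trial-structured spike times
#'
#' Event-aligned spike times per (neuron, trial, condition), the substrate of
#' all spike analyses. Spike times are in seconds relative to the start of the
#' trial's recording sweep and must be strictly increasing within a
#' (neuron, trial) pair, with no two spikes closer than the 1-ms refractory
#' tolerance.
#'
#' @slot spikes data.frame with columns \code{neuron_id}, \code{trial_id},
#'   \code{condition}, \code{spike_time_s} (one row per spike).
#' @slot neurons data.frame with column \code{neuron_id} and optional
#'   \code{depth_um}, \code{layer}; lists every neuron, including silent ones.
#' @slot metadata list of free-form provenance (seed, generator config, ...).
#' @export
setClass("SpikeDataset",
         representation(spikes = "data.frame", neurons = "data.frame",
                        metadata = "list"),
         prototype(spikes = data.frame(neuron_id = character(),
                                       trial_id = character(),
                                       condition = character(),
                                       spike_time_s = numeric()),
                   neurons = data.frame(neuron_id = character()),
                   metadata = list()))

setValidity("SpikeDataset", function(object) {
  sp <- object@spikes
  need <- c("neuron_id", "trial_id", "condition", "spike_time_s")
  if (!all(need %in% names(sp)))
    return(paste("spikes must have columns:", paste(need, collapse = ", ")))
  if (!is.numeric(sp$spike_time_s))
    return("spike_time_s must be numeric")
  if (nrow(sp)) {
    key <- paste(sp$neuron_id, sp$trial_id, sep = "\r")
    ord <- order(key, sp$spike_time_s)
    d <- diff(sp$spike_time_s[ord])
    same <- key[ord][-1] == key[ord][-length(ord)]
    bad <- which(same & d < REFRACTORY_TOL)
    if (length(bad))
      return(sprintf(
        "spike times must be strictly increasing (refractory tolerance %g s) within a trial; %d violation(s), first at row %d",
        REFRACTORY_TOL, length(bad), ord[bad[1] + 1]))
  }
  if (!"neuron_id" %in% names(object@neurons))
    return("neurons must have a neuron_id column")
  if (anyDuplicated(object@neurons$neuron_id))
    return("duplicated neuron_id in neurons table")
  if (!all(sp$neuron_id %in% object@neurons$neuron_id))
    return("spikes reference neurons missing from the neurons table")
  TRUE
})

#' EventTable: stimulus / touch / light epochs
#'
#' Events with onset, offset and condition label; drives peri-event alignment
#' and the touch filtering rules.
#'
#' @slot events data.frame with columns \code{trial_id}, \code{event_type},
#'   \code{onset_s}, \code{offset_s}, \code{condition} (extra columns such as
#'   a per-cell grouping are carried along untouched).
#' @slot metadata list; filtering functions record removal logs here.
#' @export
setClass("EventTable",
         representation(events = "data.frame", metadata = "list"),
         prototype(events = data.frame(trial_id = character(),
                                       event_type = character(),
                                       onset_s = numeric(),
                                       offset_s = numeric(),
                                       condition = character()),
                   metadata = list()))

setValidity("EventTable", function(object) {
  ev <- object@events
  need <- c("trial_id", "event_type", "onset_s", "offset_s", "condition")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  if (nrow(ev)) {
    if (any(ev$offset_s < ev$onset_s))
      return("event offset_s must be >= onset_s")
    if (!all(ev$event_type %in% KNOWN_EVENT_TYPES))
      return(paste("unknown event_type; known types:",
                   paste(KNOWN_EVENT_TYPES, collapse = ", ")))
  }
  TRUE
})

#' PeriEventSet: spikes re-referenced to event onsets
#'
#' One record per (neuron, event): spike times shifted so that the event onset
#' is 0 s, restricted to a half-open analysis window [t_lo, t_hi).
#'
#' @slot spikes data.frame with columns \code{neuron_id}, \code{event_id},
#'   \code{time_s}.
#' @slot events data.frame with columns \code{event_id}, \code{trial_id},
#'   \code{condition}, \code{onset_s} (original onset) and optionally a
#'   per-cell grouping column \code{cell_id} for datasets where each neuron
#'   has its own event stream.
#' @slot neurons character vector of all neuron ids in the set (a neuron with
#'   zero in-window spikes is still a member).
#' @slot window numeric(2), half-open analysis window in seconds.
#' @export
setClass("PeriEventSet",
         representation(spikes = "data.frame", events = "data.frame",
                        neurons = "character", window = "numeric"),
         prototype(spikes = data.frame(neuron_id = character(),
                                       event_id = character(),
                                       time_s = numeric()),
                   events = data.frame(event_id = character(),
                                       trial_id = character(),
                                       condition = character(),
                                       onset_s = numeric()),
                   neurons = character(), window = c(0, 1)))

setValidity("PeriEventSet", function(object) {
  w <- object@window
  if (length(w) != 2 || !all(is.finite(w)) || w[1] >= w[2])
    return("window must be finite with t_lo < t_hi")
  sp <- object@spikes
  if (nrow(sp)) {
    if (any(sp$time_s < w[1] | sp$time_s >= w[2]))
      return("all spikes must fall inside the half-open window [t_lo, t_hi)")
    if (!all(sp$event_id %in% object@events$event_id))
      return("spikes reference unknown event_id")
    if (!all(sp$neuron_id %in% object@neurons))
      return("spikes reference unknown neuron_id")
  }
  if (anyDuplicated(object@events$event_id))
    return("duplicated event_id")
  TRUE
})

#' RateProfile: baseline + early + late evoked firing-rate profile
#'
#' Piecewise-constant peri-stimulus rate model: a baseline rate everywhere,
#' an additive early component on [0, 40) ms and an additive late component on
#' [40, 100) ms by default. Optogenetic modifiers: activation truncates the
#' evoked response (rate falls back to baseline) after \code{truncation_s};
#' inhibition multiplies the baseline and the late component by
#' \code{late_gain} >= 1.
#'
#' @slot baseline_hz,early_hz,late_hz non-negative rates (Hz); the early/late
#'   values are added on top of baseline inside their windows. The early
#'   component is triangular (linear rise from the window start to its peak
#'   \code{early_hz} at \code{early_peak_s}, then linear decay to the window
#'   end), matching the peaked shape of deflection-evoked responses; the late
#'   component is flat.
#' @slot early_window,late_window numeric(2) windows in seconds.
#' @slot early_peak_s time (s) of the early-component peak.
#' @slot condition one of "control", "opto_activation", "opto_inhibition".
#' @slot truncation_s time (s, from stimulus onset) after which the rate falls
#'   to baseline under opto_activation; NA otherwise.
#' @slot late_gain multiplier (>= 1) on baseline and late component under
#'   opto_inhibition; 1 otherwise.
#' @export
setClass("RateProfile",
         representation(baseline_hz = "numeric", early_hz = "numeric",
                        late_hz = "numeric", early_window = "numeric",
                        late_window = "numeric", early_peak_s = "numeric",
                        condition = "character", truncation_s = "numeric",
                        late_gain = "numeric"),
         prototype(baseline_hz = 1, early_hz = 40, late_hz = 5,
                   early_window = c(0, 0.040), late_window = c(0.040, 0.100),
                   early_peak_s = 0.010, condition = "control",
                   truncation_s = NA_real_, late_gain = 1))

setValidity("RateProfile", function(object) {
  if (any(c(object@baseline_hz, object@early_hz, object@late_hz) < 0))
    return("all rates must be >= 0")
  pk <- object@early_peak_s
  if (!is.finite(pk) || pk < object@early_window[1] ||
      pk > object@early_window[2])
    return("early_peak_s must lie inside the early window")
  if (object@late_gain < 1)
    return("late_gain must be >= 1")
  if (object@condition == "opto_activation") {
    tr <- object@truncation_s
    if (!is.finite(tr) || tr < object@early_window[1] ||
        tr > object@late_window[2])
      return("truncation_s must lie within the evoked response window")
  }
  TRUE
})

#' PseudoPopulation: per-trial pooled population counts
#'
#' Single-trial pseudo-simultaneous population responses: pooled spike counts
#' of all units per time bin, for a set of trials of one condition. Input to
#' PRE detection.
#'
#' @slot counts integer matrix, trials x bins, pooled over units.
#' @slot bin_edges numeric(nbins + 1), uniform half-open bins tiling the
#'   analysis window exactly.
#' @slot n_units number of neurons (or channels) pooled.
#' @slot condition condition label of these trials.
#' @export
setClass("PseudoPopulation",
         representation(counts = "matrix", bin_edges = "numeric",
                        n_units = "integer", condition = "character"),
         prototype(counts = matrix(0L, 0, 0), bin_edges = c(0, 0.01),
                   n_units = 1L, condition = "control"))

setValidity("PseudoPopulation", function(object) {
  ct <- object@counts
  if (any(ct < 0) || any(ct != round(ct)))
    return("counts must be non-negative integers")
  be <- object@bin_edges
  if (length(be) != ncol(ct) + 1 && ncol(ct) > 0)
    return("bin_edges must have ncol(counts) + 1 entries")
  w <- diff(be)
  if (any(w <= 0) || (length(w) > 1 && diff(range(w)) > 1e-9))
    return("bins must be uniform and increasing")
  if (object@n_units < 1L) return("n_units must be >= 1")
  TRUE
})

#' PREResult: detected population response events
#'
#' PRE times per trial (bin centers), the per-condition mode of the PRE-time
#' distribution and the absolute stimulus-time-estimation errors
#' |t_PRE - mode|.
#'
#' @slot th threshold in spikes per unit (strict: a PRE requires
#'   pooled count / n_units > th).
#' @slot events data.frame with columns \code{condition}, \code{trial},
#'   \code{time_s} (bin center of each PRE).
#' @slot modes named numeric, per-condition mode of the PRE-time distribution
#'   (earliest time on ties); filled by \code{\link{absoluteError}}.
#' @slot errors data.frame with columns \code{condition}, \code{trial},
#'   \code{time_s}, \code{abs_error_s}; filled by \code{\link{absoluteError}}.
#' @slot window,bin_width analysis window (s) and bin width (s).
#' @export
setClass("PREResult",
         representation(th = "numeric", events = "data.frame",
                        modes = "numeric", errors = "data.frame",
                        window = "numeric", bin_width = "numeric"),
         prototype(th = 0.1,
                   events = data.frame(condition = character(),
                                       trial = integer(), time_s = numeric()),
                   modes = setNames(numeric(), character()),
                   errors = data.frame(condition = character(),
                                       trial = integer(), time_s = numeric(),
                                       abs_error_s = numeric()),
                   window = c(-0.04, 0.10), bin_width = 0.01))

setValidity("PREResult", function(object) {
  if (object@th <= 0) return("th must be > 0")
  if (nrow(object@errors) && any(object@errors$abs_error_s < 0))
    return("absolute errors must be >= 0")
  ev <- object@events
  if (nrow(ev) &&
      (any(ev$time_s < object@window[1]) || any(ev$time_s > object@window[2])))
    return("PRE times must lie inside the analysis window")
  TRUE
})

#' VmSweepSet: membrane-potential or current sweeps
#'
#' Uniformly sampled intracellular sweeps with stimulus markers; substrate of
#' the state classification and evoked-response metrics.
#'
#' @slot traces numeric matrix, samples x sweeps (mV for voltage, pA for
#'   current).
#' @slot sampling_rate_hz sampling rate (Hz).
#' @slot unit "mV" or "pA".
#' @slot markers named list of marker times (s from sweep start), e.g.
#'   \code{light_onset_s}, \code{light_offset_s}, \code{whisker_onset_s}.
#' @slot states character per sweep: "resting", "activated", "unclassified" or
#'   NA; carries simulator ground truth or classification output.
#' @slot cell_id cell identifier.
#' @export
setClass("VmSweepSet",
         representation(traces = "matrix", sampling_rate_hz = "numeric",
                        unit = "character", markers = "list",
                        states = "character", cell_id = "character"),
         prototype(traces = matrix(numeric(), 0, 0), sampling_rate_hz = 1e4,
                   unit = "mV", markers = list(), states = character(),
                   cell_id = "cell"))

setValidity("VmSweepSet", function(object) {
  if (object@sampling_rate_hz <= 0) return("sampling_rate_hz must be > 0")
  if (!object@unit %in% c("mV", "pA")) return("unit must be 'mV' or 'pA'")
  dur <- nrow(object@traces) / object@sampling_rate_hz
  mk <- unlist(object@markers)
  if (length(mk) && (any(mk < 0) || any(mk > dur)))
    return("markers must lie inside the sweep")
  if (length(object@states) &&
      length(object@states) != ncol(object@traces))
    return("states must have one entry per sweep")
  TRUE
})

#' PSTH: peri-stimulus time histogram
#'
#' Per-neuron trial-averaged firing rate per bin, with across-neuron mean and
#' SEM (the field's display convention: average across trials first, then
#' across neurons).
#'
#' @slot bin_edges numeric(nbins + 1), half-open bins (s).
#' @slot rates numeric matrix, neurons x bins (Hz), one row per neuron.
#' @slot mean,sem across-neuron mean and standard error per bin (Hz).
#' @slot smoothing_sd_s Gaussian smoothing SD (s) or NA for none.
#' @export
setClass("PSTH",
         representation(bin_edges = "numeric", rates = "matrix",
                        mean = "numeric", sem = "numeric",
                        smoothing_sd_s = "numeric"),
         prototype(bin_edges = c(0, 0.01), rates = matrix(numeric(), 0, 0),
                   mean = numeric(), sem = numeric(),
                   smoothing_sd_s = NA_real_))

setValidity("PSTH", function(object) {
  if (nrow(object@rates) && any(object@rates < -1e-12))
    return("rates must be >= 0")
  TRUE
})
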