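# Small in-code fixture builders shared across test files.

# A PeriEventSet built directly from spike / event rows.
makePeri <- function(spikes, events, neurons = NULL, window = c(-0.1, 0.1)) {
  if (is.null(neurons))
    neurons <- sort(unique(c(spikes$neuron_id, events$cell_id)))
  methods::new("PeriEventSet",
               spikes = as.data.frame(spikes),
               events = as.data.frame(events),
               neurons = as.character(neurons),
               window = as.numeric(window))
}

# A PeriEventSet with one neuron and per-event spike-time lists.
periFromTrials <- function(trialSpikes, window = c(-0.1, 0.1),
                           neuron = "n1", condition = "control") {
  eids <- sprintf("e%04d", seq_along(trialSpikes))
  ev <- data.frame(event_id = eids, trial_id = eids, condition = condition,
                   onset_s = 0, stringsAsFactors = FALSE)
  rows <- lapply(seq_along(trialSpikes), function(i) {
    tt <- trialSpikes[[i]]
    if (!length(tt)) return(NULL)
    data.frame(neuron_id = neuron, event_id = eids[i], time_s = tt,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  sp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(neuron_id = character(), event_id = character(),
               time_s = numeric(), stringsAsFactors = FALSE)
  makePeri(sp, ev, neurons = neuron, window = window)
}

# A PseudoPopulation from a plain count matrix.
popFromCounts <- function(cnt, binWidth = 0.01, t0 = -0.04, nUnits = 10,
                          condition = "control") {
  cnt <- matrix(as.integer(cnt), nrow = nrow(cnt))
  edges <- seq(t0, by = binWidth, length.out = ncol(cnt) + 1)
  methods::new("PseudoPopulation", counts = cnt, bin_edges = edges,
               n_units = as.integer(nUnits), condition = condition)
}

# Exhaustive brute-force PRE enumeration (independent oracle).
brutePREs <- function(cnt, nUnits, th, centers) {
  out <- list()
  for (tr in seq_len(nrow(cnt))) for (b in seq_len(ncol(cnt))) {
    if (cnt[tr, b] / nUnits > th)
      out[[length(out) + 1L]] <- data.frame(trial = tr, time_s = centers[b])
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(trial = integer(), time_s = numeric())
}

# Pool a simulatePopulation() result into a PseudoPopulation.
poolSim <- function(sim, nNeurons, condition) {
  popspike:::pseudoPopFromCounts(apply(sim$counts, c(1, 3), sum),
                                 sim$bin_edges, nNeurons, condition)
}

awakeProfile <- function(condition = "control", truncationS = 0.020,
                         lateGain = 2) {
  rateProfile(baselineHz = 5, earlyHz = 40, lateHz = 15,
              earlyWindow = c(0, 0.020), lateWindow = c(0.020, 0.040),
              earlyPeak = 0.010, condition = condition,
              truncationS = truncationS, lateGain = lateGain)
}
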