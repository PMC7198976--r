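## Intracellular quantification: membrane-state classification, light- and
## whisker-evoked response metrics, hyperpolarization response probability,
## synaptic charge transfer and intrinsic properties from current steps.

sweepBaselines <- function(vms, eventOnset, preS = 0.020) {
  fs <- samplingRate(vms)
  i1 <- max(1L, round((eventOnset - preS) * fs) + 1L)
  i2 <- round(eventOnset * fs)
  if (i2 < i1) stop("missing pre-stimulus segment")
  colMeans(traces(vms)[i1:i2, , drop = FALSE])
}

#' Classify sweeps as resting or activated membrane state
#'
#' The pre-stimulus baseline of each sweep (mean Vm in the 20 ms before light
#' onset) is referenced to the most hyperpolarized baseline observed in the
#' same cell (V_min): resting iff baseline <= V_min + 5 mV, activated iff
#' baseline > V_min + 13 mV, otherwise unclassified (the gap between the two
#' rules).
#'
#' @param vms a \linkS4class{VmSweepSet} (voltage, with a
#'   \code{light_onset_s} marker).
#' @param preS pre-stimulus baseline segment length (s).
#' @param restingBand,activatedBand thresholds (mV) above V_min.
#' @return list with \code{state} (character per sweep), \code{baseline_mv}
#'   and \code{v_min_mv}.
#' @export
classifyTrialState <- function(vms, preS = 0.020, restingBand = 5,
                               activatedBand = 13) {
  stopifnot(is(vms, "VmSweepSet"))
  if (ncol(traces(vms)) < 2)
    stop("at least 2 sweeps are needed to define the most hyperpolarized baseline")
  onset <- vms@markers$light_onset_s %||% vms@markers$whisker_onset_s
  if (is.null(onset)) stop("no stimulus onset marker")
  b <- sweepBaselines(vms, onset, preS)
  vmin <- min(b)
  state <- ifelse(b <= vmin + restingBand, "resting",
                  ifelse(b > vmin + activatedBand, "activated",
                         "unclassified"))
  list(state = state, baseline_mv = b, v_min_mv = vmin)
}

#' Evoked-response metrics on a state-averaged sweep
#'
#' Sweeps of the requested state are averaged first; the baseline is the mean
#' over \code{baselineS} before the response onset. Positive peak =
#' max(V - baseline), negative peak = min(V - baseline), area = trapezoidal
#' integral of (V - baseline) over the analysis window (mV*ms). Canonical
#' windows: 200 ms from light onset for light responses; 150 ms from the
#' rising phase for whisker responses, with a 5-ms pre-onset baseline. For
#' whisker responses the Vm at the time of the maximal response is also
#' returned.
#'
#' @param vms a \linkS4class{VmSweepSet}.
#' @param onset response / stimulus onset (s); defaults to the light marker.
#' @param windowS analysis window length (s) from onset.
#' @param baselineS baseline segment length (s) before onset.
#' @param state restrict averaging to sweeps of this state (requires
#'   \code{sweepStates}); all sweeps when NULL.
#' @return data.frame: baseline (mV), positive and negative peak (mV), area
#'   (mV*ms), Vm at peak time (mV), n sweeps averaged.
#' @export
responseMetrics <- function(vms, onset = NULL, windowS = 0.200,
                            baselineS = 0.020, state = NULL) {
  stopifnot(is(vms, "VmSweepSet"))
  onset <- onset %||% vms@markers$light_onset_s
  if (is.null(onset)) stop("no onset given and no light marker present")
  fs <- samplingRate(vms)
  tr <- traces(vms)
  if (!is.null(state)) {
    keep <- sweepStates(vms) == state
    if (!any(keep)) stop(sprintf("no sweeps in state '%s'", state))
    tr <- tr[, keep, drop = FALSE]
  }
  avg <- rowMeans(tr)
  i0 <- round(onset * fs) + 1L
  i1 <- round((onset + windowS) * fs)
  if (i1 > length(avg)) stop("analysis window exceeds the sweep")
  ib <- max(1L, round((onset - baselineS) * fs) + 1L)
  baseline <- mean(avg[ib:(i0 - 1L)])
  seg <- avg[i0:i1] - baseline
  peakIdx <- which.max(abs(seg))
  data.frame(baseline_mv = baseline,
             positive_peak_mv = max(seg),
             negative_peak_mv = min(seg),
             area_mv_ms = trapint(seg, 1 / fs) * 1000,
             vm_at_peak_mv = avg[i0:i1][peakIdx],
             peak_time_s = onset + (peakIdx - 1L) / fs,
             n_sweeps = ncol(tr))
}

#' Onset of the whisker-evoked rising phase
#'
#' The rising phase is the first time the state-averaged Vm exceeds
#' baseline + k x SD of the baseline noise for at least \code{sustainS}.
#'
#' @param vms a \linkS4class{VmSweepSet} with a \code{whisker_onset_s} marker.
#' @param k SD multiplier (default 2).
#' @param sustainS required supra-threshold duration (s, default 2 ms).
#' @param state restrict to sweeps of this state.
#' @return Onset time (s from sweep start), or NA when never crossed.
#' @export
risingPhaseOnset <- function(vms, k = 2, sustainS = 0.002, state = NULL) {
  stopifnot(is(vms, "VmSweepSet"))
  stim <- vms@markers$whisker_onset_s
  if (is.null(stim)) stop("no whisker onset marker")
  fs <- samplingRate(vms)
  tr <- traces(vms)
  if (!is.null(state)) tr <- tr[, sweepStates(vms) == state, drop = FALSE]
  avg <- rowMeans(tr)
  iStim <- round(stim * fs) + 1L
  base <- avg[1:(iStim - 1L)]
  thr <- mean(base) + k * sd(base)
  m <- round(sustainS * fs)
  above <- avg > thr
  for (i in iStim:(length(avg) - m + 1L))
    if (all(above[i:(i + m - 1L)])) return((i - 1L) / fs)
  NA_real_
}

#' Probability of a light-evoked prolonged hyperpolarization
#'
#' Fraction of (activated-state) trials in which the Vm drops by strictly more
#' than \code{thresholdMv} below the pre-stimulus baseline within the
#' post-stimulus window.
#'
#' @param vms a \linkS4class{VmSweepSet}.
#' @param thresholdMv hyperpolarization threshold (mV, default 4.5).
#' @param windowS post-stimulus window (s, default 200 ms).
#' @param state restrict to sweeps of this state (e.g. "activated").
#' @return Fraction of qualifying trials in [0, 1].
#' @export
responseProbability <- function(vms, thresholdMv = 4.5, windowS = 0.200,
                                state = NULL) {
  stopifnot(is(vms, "VmSweepSet"))
  onset <- vms@markers$light_onset_s
  if (is.null(onset)) stop("no light onset marker")
  fs <- samplingRate(vms)
  tr <- traces(vms)
  if (!is.null(state)) {
    keep <- sweepStates(vms) == state
    if (!any(keep)) stop(sprintf("no sweeps in state '%s'", state))
    tr <- tr[, keep, drop = FALSE]
  }
  b <- colMeans(tr[max(1L, round((onset - 0.020) * fs) + 1L):
                     round(onset * fs), , drop = FALSE])
  i0 <- round(onset * fs) + 1L
  i1 <- min(nrow(tr), round((onset + windowS) * fs))
  dips <- apply(tr[i0:i1, , drop = FALSE], 2, min) - b
  mean(dips < -thresholdMv)
}

#' Synaptic charge transfer from a current sweep
#'
#' Baseline-subtracted inward (negative) and outward (positive) currents are
#' integrated separately from the stimulus onset to the first sustained return
#' of the current to baseline; if the current never returns, integration runs
#' to the sweep end with a warning. With current in pA and time in s the
#' charge is in pC.
#'
#' @param current numeric vector, current trace (pA).
#' @param samplingRate sampling rate (Hz).
#' @param onset stimulus onset (s).
#' @param baselineS baseline segment length (s) before onset.
#' @param returnTol return-to-baseline tolerance (pA); estimated from the
#'   baseline noise (3 SD, floor 1e-9) when NULL.
#' @param sustainS how long the current must stay within tolerance to count
#'   as returned (s).
#' @return list: \code{inward_pc}, \code{outward_pc}, \code{peak_inward_pa},
#'   \code{peak_outward_pa}, \code{return_time_s}.
#' @export
synapticCharge <- function(current, samplingRate, onset, baselineS = 0.020,
                           returnTol = NULL, sustainS = 0.001) {
  fs <- samplingRate
  i0 <- round(onset * fs) + 1L
  ib <- max(1L, round((onset - baselineS) * fs) + 1L)
  base <- current[ib:(i0 - 1L)]
  x <- current - mean(base)
  tol <- returnTol %||% max(3 * sd(base), 1e-9)
  n <- length(x)
  m <- max(1L, round(sustainS * fs))
  # first sustained return to baseline after the response extremum
  post <- x[i0:n]
  iExt <- which.max(abs(post))
  end <- n
  returned <- FALSE
  if (i0 + iExt <= n - m + 1L) {
    within <- abs(x) <= tol
    for (i in (i0 + iExt):(n - m + 1L)) {
      if (all(within[i:(i + m - 1L)])) { end <- i; returned <- TRUE; break }
    }
  }
  if (!returned)
    warning("current never returned to baseline; integrating to sweep end")
  seg <- x[i0:end]
  dt <- 1 / fs
  list(inward_pc = trapint(pmin(seg, 0), dt),
       outward_pc = trapint(pmax(seg, 0), dt),
       peak_inward_pa = min(seg, 0),
       peak_outward_pa = max(seg, 0),
       return_time_s = if (returned) (end - 1L) / fs else NA_real_)
}

# Spike times in a current-clamp trace via dV/dt threshold crossing.
apOnsets <- function(v, fs, dvdtThr = 20, refractory = 0.002) {
  dvdt <- c(0, diff(v)) * fs / 1000  # V/s when v is in mV
  above <- dvdt >= dvdtThr
  onsets <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(onsets)) return(integer())
  keep <- enforceRefractory((onsets - 1) / fs, refractory)
  round(keep * fs) + 1L
}

#' Intrinsic properties from a current-step series
#'
#' Input resistance from the steady-state voltage deflection of the
#' hyperpolarizing step (dV/dI); rheobase as the smallest step current that
#' evokes at least one action potential; frequency adaptation as ISI_1 /
#' ISI_n during the step at twice rheobase; AP threshold (first dV/dt
#' crossing of 20 V/s), amplitude (peak - threshold), half-width (width at
#' half amplitude) and AHP (minimum within 50 ms after the peak, relative to
#' threshold) measured on the first spike at rheobase.
#'
#' @param stepTraces numeric matrix, samples x steps (mV).
#' @param stepCurrents injected current per step (pA), e.g.
#'   \code{seq(-100, 400, by = 50)}.
#' @param samplingRate sampling rate (Hz).
#' @param stepOnset,stepDur current-step onset and duration (s; 400-ms steps).
#' @param dvdtThr AP threshold criterion on dV/dt (V/s).
#' @return list: \code{rheobase_pa}, \code{input_resistance_mohm},
#'   \code{adaptation_ratio} (NA with < 3 spikes at 2x rheobase),
#'   \code{ap} (threshold, amplitude, half-width, AHP) or NULL.
#' @export
intrinsicProperties <- function(stepTraces, stepCurrents, samplingRate,
                                stepOnset = 0.1, stepDur = 0.4,
                                dvdtThr = 20) {
  stopifnot(ncol(stepTraces) == length(stepCurrents))
  fs <- samplingRate
  i0 <- round(stepOnset * fs) + 1L
  i1 <- round((stepOnset + stepDur) * fs)
  spk <- lapply(seq_along(stepCurrents), function(j) {
    on <- apOnsets(stepTraces[, j], fs, dvdtThr)
    on[on >= i0 & on <= i1]
  })
  nspk <- vapply(spk, length, integer(1))
  # input resistance from the most hyperpolarizing step
  hyp <- which(stepCurrents < 0)
  rin <- NA_real_
  if (length(hyp)) {
    j <- hyp[which.min(stepCurrents[hyp])]
    baseline <- mean(stepTraces[1:(i0 - 1L), j])
    ss <- mean(stepTraces[round(i1 - 0.2 * (i1 - i0)):i1, j])
    rin <- 1000 * (ss - baseline) / stepCurrents[j]  # mV/pA -> MOhm
  }
  supra <- which(nspk >= 1 & stepCurrents > 0)
  rheobase <- if (length(supra)) min(stepCurrents[supra]) else NA_real_
  adaptation <- NA_real_
  if (is.finite(rheobase)) {
    j2 <- which.min(abs(stepCurrents - 2 * rheobase))
    if (nspk[j2] >= 3) {
      isi <- diff((spk[[j2]] - 1) / fs)
      adaptation <- isi[1] / isi[length(isi)]
    }
  }
  ap <- NULL
  if (is.finite(rheobase)) {
    j <- which(stepCurrents == rheobase)[1]
    on <- spk[[j]][1]
    v <- stepTraces[, j]
    thrV <- v[on]
    iEnd <- min(length(v), on + round(0.005 * fs))
    pk <- which.max(v[on:iEnd]) + on - 1L
    amp <- v[pk] - thrV
    half <- thrV + amp / 2
    up <- on + which(v[on:pk] >= half)[1] - 1L
    downRange <- pk:min(length(v), pk + round(0.005 * fs))
    dn <- pk + which(v[downRange] <= half)[1] - 1L
    hw <- if (is.na(dn) || is.na(up)) NA_real_ else (dn - up) / fs
    ahpEnd <- min(length(v), pk + round(0.050 * fs))
    ahp <- min(v[pk:ahpEnd]) - thrV
    ap <- list(threshold_mv = thrV, amplitude_mv = amp, half_width_s = hw,
               ahp_mv = ahp)
  }
  list(rheobase_pa = rheobase, input_resistance_mohm = rin,
       adaptation_ratio = adaptation, ap = ap, n_spikes_per_step = nspk)
}
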