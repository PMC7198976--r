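## Synthetic-data generators: inhomogeneous-Poisson / latent-Gaussian-copula
## spike counts with exact peri-stimulus rate profiles, touch streams and
## bimodal membrane-potential sweeps. Defaults are the study conditions the
## analyses assume (see the methods vignette).

#' Construct a peri-stimulus RateProfile
#'
#' @param baselineHz spontaneous rate (Hz), applies everywhere.
#' @param earlyHz,lateHz additive evoked rates (Hz) inside the early
#'   (default 0-40 ms) and late (default 40-100 ms) response windows;
#'   \code{earlyHz} is the peak of a triangular early component (linear rise
#'   to the peak at \code{earlyPeak}, linear decay to the window end), the
#'   late component is flat.
#' @param earlyWindow,lateWindow component windows in seconds.
#' @param earlyPeak time (s) of the early-component peak.
#' @param condition "control", "opto_activation" (evoked response truncated:
#'   the rate falls back to baseline after \code{truncationS}), or
#'   "opto_inhibition" (baseline and late component multiplied by
#'   \code{lateGain}).
#' @param truncationS truncation time (s) for opto_activation.
#' @param lateGain multiplier >= 1 for opto_inhibition.
#' @return A \linkS4class{RateProfile}.
#' @export
rateProfile <- function(baselineHz = 1, earlyHz = 40, lateHz = 5,
                        earlyWindow = c(0, 0.040),
                        lateWindow = c(0.040, 0.100),
                        earlyPeak = 0.010,
                        condition = c("control", "opto_activation",
                                      "opto_inhibition"),
                        truncationS = 0.030, lateGain = 2) {
  condition <- match.arg(condition)
  new("RateProfile", baseline_hz = baselineHz, early_hz = earlyHz,
      late_hz = lateHz, early_window = as.numeric(earlyWindow),
      late_window = as.numeric(lateWindow), early_peak_s = earlyPeak,
      condition = condition,
      truncation_s = if (condition == "opto_activation") truncationS
                     else NA_real_,
      late_gain = if (condition == "opto_inhibition") lateGain else 1)
}

#' Instantaneous firing rate of a profile
#' @param profile a \linkS4class{RateProfile}.
#' @param t times in seconds relative to stimulus onset.
#' @return Rate in Hz at each time.
#' @export
profileRate <- function(profile, t) {
  g <- profile@late_gain
  r <- rep(profile@baseline_hz * g, length(t))
  w <- profile@early_window
  pk <- profile@early_peak_s
  inEarly <- t >= w[1] & t < w[2]
  if (any(inEarly)) {
    te <- t[inEarly]
    shape <- ifelse(te < pk,
                    if (pk > w[1]) (te - w[1]) / (pk - w[1]) else 1,
                    if (w[2] > pk) (w[2] - te) / (w[2] - pk) else 1)
    r[inEarly] <- r[inEarly] + profile@early_hz * shape
  }
  inLate <- t >= profile@late_window[1] & t < profile@late_window[2]
  r[inLate] <- r[inLate] + profile@late_hz * g
  if (profile@condition == "opto_activation" && is.finite(profile@truncation_s))
    r[t >= profile@truncation_s] <- profile@baseline_hz
  r
}

#' Mean firing rate per bin of a profile
#' @param profile a \linkS4class{RateProfile}.
#' @param binEdges uniform half-open bin edges (s).
#' @return Mean rate (Hz) in each bin, by exact piecewise integration.
#' @export
profileBinRates <- function(profile, binEdges) {
  brk <- sort(unique(c(binEdges, 0, profile@early_window, profile@late_window,
                       profile@early_peak_s, profile@truncation_s)))
  brk <- brk[is.finite(brk)]
  out <- numeric(length(binEdges) - 1L)
  for (b in seq_along(out)) {
    lo <- binEdges[b]; hi <- binEdges[b + 1]
    cuts <- sort(unique(c(lo, hi, brk[brk > lo & brk < hi])))
    mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
    out[b] <- sum(profileRate(profile, mids) * diff(cuts)) / (hi - lo)
  }
  out
}

## ---- latent-Gaussian (Gaussian-copula) correlated count model -------------
## Counts in each bin are qpois(pnorm(Z), mu) with Z equicorrelated standard
## normal across neurons; the marginal of each count is exactly Poisson(mu),
## so rate profiles are matched exactly, while the latent correlation r sets
## the pairwise count correlation. r is calibrated to a target count
## correlation by bisection on a deterministic Gauss-grid quadrature of
## E[X1 X2]; the map r -> corr is continuous and increasing with corr(0) = 0.

.calibCache <- new.env(parent = emptyenv())
.zGrid <- local({
  z <- seq(-6, 6, length.out = 161)
  w <- dnorm(z); w <- w / sum(w)
  list(z = z, w = w)
})

copulaCountCorr <- function(mu1, mu2, r) {
  if (r <= 0) return(0)
  z <- .zGrid$z; w <- .zGrid$w
  clamp <- function(u) pmin(pmax(u, 1e-13), 1 - 1e-13)  # keep qpois finite
  g1 <- qpois(clamp(pnorm(z)), mu1)
  m <- outer(r * z, sqrt(1 - r^2) * z, "+")
  g2cond <- qpois(clamp(pnorm(m)), mu2) %*% w      # E[g2 | z1]
  e12 <- sum(w * g1 * g2cond)
  (e12 - mu1 * mu2) / sqrt(mu1 * mu2)
}

#' Calibrate the latent correlation for a target count correlation
#'
#' Finds the equicorrelated latent-Gaussian correlation r such that the mean
#' pairwise Poisson-count correlation across the supplied per-neuron bin means
#' equals \code{rho}.
#'
#' @param mus per-neuron expected counts in the bin (only positive means
#'   participate in correlations).
#' @param rho target pairwise count correlation (>= 0).
#' @param tol calibration tolerance on the achieved correlation.
#' @return Latent correlation r in [0, 1).
#' @export
calibrateLatentCorr <- function(mus, rho, tol = 1e-3) {
  stopifnot(rho >= 0, all(mus > 0))
  if (rho == 0 || length(mus) < 2) return(0)
  key <- paste(signif(sort(mus), 8), collapse = ","); key <- paste(key, rho)
  hit <- .calibCache[[key]]
  if (!is.null(hit)) return(hit)
  uq <- sort(unique(signif(mus, 10)))
  cnt <- vapply(uq, function(u) sum(signif(mus, 10) == u), numeric(1))
  pairs <- list(); wts <- numeric()
  for (i in seq_along(uq)) for (j in i:length(uq)) {
    wij <- if (i == j) choose(cnt[i], 2) else cnt[i] * cnt[j]
    if (wij > 0) {
      pairs[[length(pairs) + 1L]] <- c(uq[i], uq[j])
      wts <- c(wts, wij)
    }
  }
  f <- function(r) {
    cc <- vapply(pairs, function(p) copulaCountCorr(p[1], p[2], r), numeric(1))
    sum(cc * wts) / sum(wts)
  }
  rmax <- 0.9995
  fmax <- f(rmax)
  if (rho > fmax + tol)
    stop(sprintf(
      "target count correlation %.3f infeasible for these marginals; maximum achievable is %.3f",
      rho, fmax))
  lo <- 0; hi <- rmax
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - rho) < tol / 2) { lo <- hi <- mid; break }
    if (fm < rho) lo <- mid else hi <- mid
  }
  r <- (lo + hi) / 2
  .calibCache[[key]] <- r
  r
}

# Place k spikes in a half-open bin [lo, lo + width) so that consecutive
# spikes (including across bin borders) are at least `refractory` apart:
# one spike per equal sub-slot, uniform within the slot minus half-refractory
# margins. Counts are preserved exactly (they are capped beforehand at the
# physical limit floor(width / refractory)).
placeSpikes <- function(k, lo, width, refractory = REFRACTORY_TOL) {
  slot <- width / k
  jit <- runif(k) * (slot - refractory)
  lo + (seq_len(k) - 1) * slot + refractory / 2 + jit
}

#' Simulate a trial-structured population with matched rates and correlations
#'
#' Generates per-trial spike trains for a population of neurons whose
#' trial-averaged peri-stimulus rate follows the given profiles exactly at the
#' bin resolution. With \code{rho = 0}, per-bin counts are independent Poisson
#' draws; with \code{rho > 0}, counts are drawn from a latent-Gaussian
#' (Gaussian-copula) model whose marginals remain Poisson at the profile rates
#' and whose pairwise per-bin count correlation is calibrated to \code{rho}.
#' Spike times are jittered within their bin (one spike per sub-slot, so that
#' the 1-ms refractory constraint holds while per-bin counts are preserved).
#'
#' @param profiles a single \linkS4class{RateProfile} (shared by all neurons)
#'   or a list of one profile per neuron.
#' @param nNeurons number of neurons when \code{profiles} is a single profile.
#' @param nTrials trials to simulate.
#' @param binWidth count-bin width (s); 0.010 by default.
#' @param window analysis window (s) around the stimulus, tiled exactly by the
#'   bins.
#' @param rho target pairwise per-bin count (noise) correlation.
#' @param seed mandatory RNG seed.
#' @param eventOnset absolute time (s) of the stimulus in each simulated
#'   trial's recording.
#' @return A list with \code{spikes} (\linkS4class{SpikeDataset}),
#'   \code{events} (\linkS4class{EventTable}, one whisker_deflection per
#'   trial), \code{counts} (trials x neurons x bins integer array) and
#'   \code{bin_edges}.
#' @export
simulatePopulation <- function(profiles, nNeurons = NULL, nTrials,
                               binWidth = 0.010, window = c(-0.040, 0.100),
                               rho = 0, seed, eventOnset = 0.5) {
  stopifnot(!missing(seed))
  if (is(profiles, "RateProfile")) {
    stopifnot(!is.null(nNeurons))
    profiles <- rep(list(profiles), nNeurons)
  }
  stopifnot(length(profiles) >= 1)
  nN <- length(profiles)
  edges <- makeBinEdges(window, binWidth)
  nB <- length(edges) - 1L
  M <- t(vapply(profiles, function(p) profileBinRates(p, edges) * binWidth,
                numeric(nB)))          # neurons x bins expected counts
  condition <- profiles[[1]]@condition
  set.seed(seed)
  cnt <- array(0L, dim = c(nTrials, nN, nB))
  maxK <- floor(binWidth / REFRACTORY_TOL)
  for (b in seq_len(nB)) {
    mu <- M[, b]
    nz <- which(mu > 0)
    if (!length(nz)) next
    if (rho > 0 && length(nz) >= 2) {
      r <- calibrateLatentCorr(mu[nz], rho)
      f <- rnorm(nTrials)
      e <- matrix(rnorm(nTrials * length(nz)), nTrials)
      z <- sqrt(r) * f + sqrt(1 - r) * e
      k <- qpois(pnorm(z), matrix(mu[nz], nTrials, length(nz), byrow = TRUE))
    } else {
      k <- matrix(rpois(nTrials * length(nz),
                        rep(mu[nz], each = nTrials)), nTrials)
    }
    cnt[, nz, b] <- pmin(k, maxK)
  }
  # spike placement
  nzIdx <- which(cnt > 0, arr.ind = TRUE)
  spkList <- list()
  if (nrow(nzIdx)) {
    ks <- cnt[nzIdx]
    for (k in sort(unique(ks))) {
      rows <- nzIdx[ks == k, , drop = FALSE]
      nrw <- nrow(rows)
      slot <- binWidth / k
      base <- edges[rows[, 3]] + eventOnset
      offs <- matrix((seq_len(k) - 1) * slot + REFRACTORY_TOL / 2,
                     nrw, k, byrow = TRUE)
      tms <- base + offs + matrix(runif(nrw * k), nrw, k) *
        (slot - REFRACTORY_TOL)
      spkList[[length(spkList) + 1L]] <- data.frame(
        neuron = rep(rows[, 2], k), trial = rep(rows[, 1], k),
        time = as.vector(tms))
    }
  }
  nid <- sprintf("n%02d", seq_len(nN))
  tid <- sprintf("t%04d", seq_len(nTrials))
  spkDf <- if (length(spkList)) {
    z <- do.call(rbind, spkList)
    data.frame(neuron_id = nid[z$neuron], trial_id = tid[z$trial],
               condition = condition, spike_time_s = z$time,
               stringsAsFactors = FALSE)
  } else data.frame(neuron_id = character(), trial_id = character(),
                    condition = character(), spike_time_s = numeric())
  sd_ <- SpikeDataset(spkDf,
                      neurons = data.frame(neuron_id = nid,
                                           stringsAsFactors = FALSE),
                      metadata = list(seed = seed, rho = rho,
                                      config = list(n_trials = nTrials,
                                                    bin_width_s = binWidth,
                                                    window_s = window)))
  ev <- EventTable(data.frame(trial_id = tid,
                              event_type = "whisker_deflection",
                              onset_s = eventOnset,
                              offset_s = eventOnset + 0.010,
                              condition = condition,
                              stringsAsFactors = FALSE),
                   metadata = list(seed = seed))
  list(spikes = sd_, events = ev, counts = cnt, bin_edges = edges)
}

#' Simulate per-cell peri-event spike responses
#'
#' Convenience generator for sequential-recording designs (e.g. peri-touch
#' responses) where each cell has its own event stream: independent
#' inhomogeneous Poisson spikes per (cell, event) following a rate profile,
#' realized by thinning a homogeneous Poisson process and enforcing a 1-ms
#' refractory period.
#'
#' @param profile a \linkS4class{RateProfile} (time 0 = event onset).
#' @param nCells number of cells.
#' @param nEventsPerCell events per cell; scalar or one value per cell.
#' @param window half-open peri-event window (s).
#' @param seed mandatory RNG seed.
#' @return A \linkS4class{PeriEventSet} whose events carry a \code{cell_id}
#'   column (each event belongs to one cell).
#' @export
simulatePeriEvents <- function(profile, nCells, nEventsPerCell, window, seed) {
  stopifnot(!missing(seed))
  nev <- rep(nEventsPerCell, length.out = nCells)
  set.seed(seed)
  rmax <- max(profileRate(profile, seq(window[1], window[2] - 1e-6,
                                       by = 1e-4))) + 1e-9
  cid <- sprintf("c%02d", seq_len(nCells))
  evRows <- list(); spkRows <- list()
  eix <- 0L
  for (i in seq_len(nCells)) {
    for (e in seq_len(nev[i])) {
      eix <- eix + 1L
      eid <- sprintf("%s.e%05d", cid[i], e)
      evRows[[eix]] <- data.frame(event_id = eid, trial_id = eid,
                                  condition = profile@condition,
                                  onset_s = 0, cell_id = cid[i],
                                  stringsAsFactors = FALSE)
      nH <- rpois(1, rmax * diff(window))
      if (nH == 0) next
      tt <- sort(runif(nH, window[1], window[2]))
      tt <- tt[runif(nH) < profileRate(profile, tt) / rmax]
      tt <- enforceRefractory(tt)
      if (length(tt))
        spkRows[[length(spkRows) + 1L]] <- data.frame(
          neuron_id = cid[i], event_id = eid, time_s = tt,
          stringsAsFactors = FALSE)
    }
  }
  spkDf <- if (length(spkRows)) do.call(rbind, spkRows) else
    data.frame(neuron_id = character(), event_id = character(),
               time_s = numeric(), stringsAsFactors = FALSE)
  new("PeriEventSet", spikes = spkDf, events = do.call(rbind, evRows),
      neurons = cid, window = as.numeric(window))
}

#' Simulate a renewal touch stream
#'
#' Touch onsets form a renewal process within each pole-presentation epoch:
#' start-to-start intervals and touch durations are gamma distributed
#' (shape 4 by default) with the given means; a touch never overlaps the next
#' one.
#'
#' @param meanTouchDuration mean touch duration (s), default 27.1 ms.
#' @param meanInterTouch mean start-to-start inter-touch interval (s),
#'   default 70.2 ms.
#' @param poleEpoch pole-presentation epoch (s) within each trial.
#' @param nTrials number of trials.
#' @param shape gamma shape for both distributions.
#' @param seed mandatory RNG seed.
#' @param condition condition label.
#' @return An \linkS4class{EventTable} with one \code{pole_presentation} per
#'   trial and the generated \code{touch} events.
#' @export
simulateTouchStream <- function(meanTouchDuration = 0.0271,
                                meanInterTouch = 0.0702,
                                poleEpoch = c(0, 2), nTrials, shape = 4,
                                seed, condition = "control") {
  stopifnot(!missing(seed))
  if (meanTouchDuration >= meanInterTouch)
    stop("mean touch duration must be smaller than the mean inter-touch interval (touches would overlap)")
  set.seed(seed)
  rows <- list()
  tid <- sprintf("t%04d", seq_len(nTrials))
  for (i in seq_len(nTrials)) {
    rows[[length(rows) + 1L]] <- data.frame(
      trial_id = tid[i], event_type = "pole_presentation",
      onset_s = poleEpoch[1], offset_s = poleEpoch[2], condition = condition,
      stringsAsFactors = FALSE)
    if (diff(poleEpoch) <= 0) next
    t <- poleEpoch[1] + rgamma(1, shape, scale = meanInterTouch / shape)
    while (t < poleEpoch[2]) {
      gap <- rgamma(1, shape, scale = meanInterTouch / shape)
      dur <- rgamma(1, shape, scale = meanTouchDuration / shape)
      dur <- min(dur, gap - REFRACTORY_TOL, poleEpoch[2] - t)
      if (dur > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          trial_id = tid[i], event_type = "touch", onset_s = t,
          offset_s = t + dur, condition = condition, stringsAsFactors = FALSE)
      t <- t + gap
    }
  }
  EventTable(do.call(rbind, rows),
             metadata = list(seed = seed,
                             config = list(mean_touch_duration_s =
                                             meanTouchDuration,
                                           mean_inter_touch_s = meanInterTouch,
                                           shape = shape)))
}

#' Simulate bimodal membrane-potential sweeps with light responses
#'
#' Sweeps are drawn from a two-state (resting / activated) membrane-potential
#' model: the pre-stimulus baseline sits at \code{restingVm} in the resting
#' state and \code{restingVm + activatedOffset} in the activated state. A
#' stereotyped light-evoked response is added at \code{lightOnset}:
#' depolarizing (alpha-shaped) in the resting state; a small, fast
#' depolarization followed by a large, long-lasting hyperpolarization in the
#' activated state. Gaussian sample noise is added on top.
#'
#' @param nSweeps number of sweeps.
#' @param stateMix fraction of activated-state sweeps in [0, 1].
#' @param restingVm resting baseline (mV).
#' @param activatedOffset depolarization of the activated baseline (mV).
#' @param noiseSd Gaussian noise SD per sample (mV).
#' @param samplingRate sampling rate (Hz).
#' @param duration sweep duration (s).
#' @param lightOnset light onset (s from sweep start).
#' @param seed mandatory RNG seed.
#' @return A \linkS4class{VmSweepSet} with ground-truth \code{sweepStates}.
#' @export
simulateVmSweeps <- function(nSweeps, stateMix = 0.5, restingVm = -70,
                             activatedOffset = 15, noiseSd = 0.5,
                             samplingRate = 2e4, duration = 0.5,
                             lightOnset = 0.15, seed) {
  stopifnot(!missing(seed), stateMix >= 0, stateMix <= 1)
  set.seed(seed)
  n <- round(duration * samplingRate)
  tt <- (seq_len(n) - 1) / samplingRate
  s <- pmax(tt - lightOnset, 0)
  alpha <- function(a, tau) a * (s / tau) * exp(1 - s / tau) * (s > 0)
  respResting <- alpha(8, 0.020)
  respActivated <- alpha(2, 0.005) + alpha(-8, 0.050)
  activated <- runif(nSweeps) < stateMix
  tr <- matrix(0, n, nSweeps)
  for (j in seq_len(nSweeps)) {
    base <- restingVm + if (activated[j]) activatedOffset else 0
    resp <- if (activated[j]) respActivated else respResting
    noise <- if (noiseSd > 0) rnorm(n, 0, noiseSd) else 0
    tr[, j] <- base + resp + noise
  }
  new("VmSweepSet", traces = tr, sampling_rate_hz = samplingRate, unit = "mV",
      markers = list(light_onset_s = lightOnset,
                     light_offset_s = lightOnset + 0.010),
      states = ifelse(activated, "activated", "resting"),
      cell_id = "simulated")
}
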