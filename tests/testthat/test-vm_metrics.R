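flatSweeps <- function(levels, fs = 2e4, dur = 0.3, onset = 0.1) {
  tr <- matrix(rep(levels, each = dur * fs), ncol = length(levels))
  methods::new("VmSweepSet", traces = tr, sampling_rate_hz = fs, unit = "mV",
               markers = list(light_onset_s = onset), states = character(),
               cell_id = "fix")
}

test_that("state classification applies the 5 / 13 mV rules with a gap", {
  vs <- flatSweeps(c(-70, -67, -55, -60))
  st <- classifyTrialState(vs)
  expect_equal(st$state, c("resting", "resting", "activated", "unclassified"))
  expect_equal(st$v_min_mv, -70)
  expect_error(classifyTrialState(flatSweeps(-70)), "at least 2 sweeps")
})

test_that("states are recovered near-perfectly on simulated bimodal sweeps", {
  vm <- simulateVmSweeps(400, stateMix = 0.5, activatedOffset = 15,
                         noiseSd = 1, seed = 41)
  st <- classifyTrialState(vm)
  expect_gte(mean(st$state == sweepStates(vm)), 0.99)
})

test_that("response metrics match rectangles and closed-form alpha responses", {
  fs <- 2e4; dur <- 0.4; onset <- 0.1
  # constant sweep: zero peaks, zero area
  r0 <- responseMetrics(flatSweeps(c(-70, -70), fs = fs, dur = dur,
                                   onset = onset))
  expect_equal(r0$positive_peak_mv, 0)
  expect_equal(r0$negative_peak_mv, 0)
  expect_equal(r0$area_mv_ms, 0)

  # +5 mV rectangle for 100 ms inside a 200 ms window: peak 5, area 500 mV*ms
  n <- dur * fs
  tr <- matrix(-70, n, 2)
  i0 <- onset * fs + 1
  tr[i0:(i0 + 0.1 * fs - 1), ] <- -65
  vr <- methods::new("VmSweepSet", traces = tr, sampling_rate_hz = fs,
                     unit = "mV", markers = list(light_onset_s = onset),
                     states = character(), cell_id = "rect")
  rr <- responseMetrics(vr)
  expect_equal(rr$positive_peak_mv, 5)
  expect_equal(rr$area_mv_ms, 500, tolerance = 1e-3)

  # alpha-shaped response: area equals the closed-form integral to 0.1%
  tau <- 0.02; A <- 6; W <- 0.2
  tt <- (seq_len(n) - 1) / fs
  s <- pmax(tt - onset, 0)
  tr2 <- matrix(-70 + A * (s / tau) * exp(1 - s / tau) * (s > 0), n, 2)
  va <- methods::new("VmSweepSet", traces = tr2, sampling_rate_hz = fs,
                     unit = "mV", markers = list(light_onset_s = onset),
                     states = character(), cell_id = "alpha")
  ra <- responseMetrics(va, windowS = W)
  closedForm <- A * exp(1) * tau * (1 - exp(-W / tau) * (1 + W / tau)) * 1000
  expect_lt(abs(ra$area_mv_ms - closedForm) / closedForm, 0.001)
  # invariance to adding a constant to the whole sweep
  vb <- methods::new("VmSweepSet", traces = tr2 + 12, sampling_rate_hz = fs,
                     unit = "mV", markers = list(light_onset_s = onset),
                     states = character(), cell_id = "alpha2")
  rb <- responseMetrics(vb, windowS = W)
  expect_equal(rb$area_mv_ms, ra$area_mv_ms, tolerance = 1e-9)
  expect_equal(rb$positive_peak_mv, ra$positive_peak_mv, tolerance = 1e-9)
  expect_error(responseMetrics(va, windowS = 1), "exceeds")
})

test_that("hyperpolarization response probability uses a strict threshold", {
  fs <- 2e4; n <- 0.3 * fs; onset <- 0.1
  mkTr <- function(dip) {
    v <- rep(-55, n)
    v[(onset * fs + 200):(onset * fs + 600)] <- -55 + dip
    v
  }
  tr <- vapply(c(rep(-6, 4), rep(-1, 6)), mkTr, numeric(n))
  vs <- methods::new("VmSweepSet", traces = tr, sampling_rate_hz = fs,
                     unit = "mV", markers = list(light_onset_s = onset),
                     states = character(), cell_id = "rp")
  expect_equal(responseProbability(vs), 0.4)     # 4 of 10 cross -4.5 mV
  trNone <- vapply(rep(-1, 5), mkTr, numeric(n))
  vs0 <- methods::new("VmSweepSet", traces = trNone, sampling_rate_hz = fs,
                      unit = "mV", markers = list(light_onset_s = onset),
                      states = character(), cell_id = "rp0")
  expect_equal(responseProbability(vs0), 0)
  # a dip of exactly -4.5 mV does not count ("more than")
  trEq <- vapply(rep(-4.5, 5), mkTr, numeric(n))
  vsEq <- methods::new("VmSweepSet", traces = trEq, sampling_rate_hz = fs,
                       unit = "mV", markers = list(light_onset_s = onset),
                       states = character(), cell_id = "rpEq")
  expect_equal(responseProbability(vsEq), 0)
})

test_that("synaptic charge integrates lobes to analytic values", {
  fs <- 2e4; n <- 0.5 * fs; onset <- 0.1
  # rectangular -10 pA for 100 ms: charge -1 pC, peak -10 pA
  i <- rep(0, n)
  i[(onset * fs + 1):(onset * fs + 0.1 * fs)] <- -10
  r <- synapticCharge(i, fs, onset)
  expect_equal(r$inward_pc, -1, tolerance = 1e-3)
  expect_equal(r$peak_inward_pa, -10)
  expect_equal(r$outward_pc, 0)
  # zero current: zero charge
  r0 <- synapticCharge(rep(0, n), fs, onset)
  expect_equal(r0$inward_pc, 0)
  expect_equal(r0$outward_pc, 0)
  # alpha-function current: charge equals the analytic integral
  tau <- 0.01; A <- -50
  tt <- (seq_len(n) - 1) / fs
  s <- pmax(tt - onset, 0)
  ia <- A * (s / tau) * exp(1 - s / tau) * (s > 0)
  ra <- synapticCharge(ia, fs, onset, returnTol = 1e-4)
  total <- A * exp(1) * tau  # integral over [0, Inf)
  expect_lt(abs(ra$inward_pc - total) / abs(total), 0.005)
  # never returning to baseline: warns and integrates to the end
  expect_warning(synapticCharge(c(rep(0, 2000), rep(-5, 2000)), fs, 0.1),
                 "never returned")
})

test_that("intrinsic properties recover a leaky-cell ground truth", {
  fs <- 2e4; dur <- 0.6; onset <- 0.1; stepDur <- 0.4
  n <- dur * fs
  tt <- (seq_len(n) - 1) / fs
  E <- -70; R <- 120; tau <- 0.02  # MOhm, s
  stepV <- function(I_pA, spikesAt = numeric()) {
    dV <- ifelse(tt >= onset & tt < onset + stepDur,
                 R * I_pA / 1000 * (1 - exp(-(tt - onset) / tau)),
                 0)
    v <- E + dV
    for (a in spikesAt) {
      j <- round((onset + a) * fs)
      v[j:(j + 20)] <- v[j:(j + 20)] + 80 * (1 - abs(seq(-1, 1,
                                                         length.out = 21)))
    }
    v
  }
  cur <- c(-100, 50, 100, 150, 300)
  tr <- cbind(stepV(-100), stepV(50), stepV(100),
              stepV(150, 0.200),
              stepV(300, c(0.050, 0.100, 0.200, 0.350)))
  ip <- intrinsicProperties(tr, cur, fs, stepOnset = onset, stepDur = stepDur)
  expect_equal(ip$rheobase_pa, 150)
  expect_lt(abs(ip$input_resistance_mohm - R) / R, 0.05)
  # ISIs 50 / 100 / 150 ms: adaptation ratio 1/3
  expect_equal(ip$adaptation_ratio, 1 / 3, tolerance = 0.02)
  expect_true(is.finite(ip$ap$amplitude_mv))
  expect_gt(ip$ap$amplitude_mv, 40)
  expect_true(is.finite(ip$ap$half_width_s))
  # no spiking step: rheobase missing
  ip0 <- intrinsicProperties(tr[, 1:3], cur[1:3], fs, stepOnset = onset,
                             stepDur = stepDur)
  expect_true(is.na(ip0$rheobase_pa))
})
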