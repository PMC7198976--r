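test_that("null and constant-rate populations behave like Poisson", {
  # zero rate everywhere: no spikes
  z <- simulatePopulation(rateProfile(0, 0, 0), nNeurons = 3, nTrials = 20,
                          seed = 1)
  expect_equal(nrow(spikes(z$spikes)), 0L)
  expect_equal(sum(z$counts), 0)

  # constant 10 Hz: empirical rate within 3 Poisson SEs over 1000 trials x 1 s
  p10 <- rateProfile(10, 0, 0, earlyWindow = c(0, 0.002),
                     earlyPeak = 0.001, lateWindow = c(0.002, 0.004))
  sim <- simulatePopulation(p10, nNeurons = 1, nTrials = 1000,
                            window = c(0, 1), seed = 2, eventOnset = 0)
  totalT <- 1000 * 1
  rate <- sum(sim$counts) / totalT
  se <- sqrt(10 / totalT)
  expect_lt(abs(rate - 10), 3 * se)
})

test_that("latent-Gaussian counts hit the target pairwise correlation", {
  p20 <- rateProfile(20, 0, 0, earlyWindow = c(0, 0.002),
                     earlyPeak = 0.001, lateWindow = c(0.002, 0.004))
  sim <- simulatePopulation(p20, nNeurons = 2, nTrials = 10000, rho = 0.3,
                            seed = 3)
  cc <- vapply(seq_len(dim(sim$counts)[3]), function(b)
    cor(sim$counts[, 1, b], sim$counts[, 2, b]), numeric(1))
  expect_lt(abs(mean(cc) - 0.3), 0.05)
  # marginal rates unchanged by the copula (exactly Poisson marginals)
  rate <- sum(sim$counts) / (2 * 10000 * 0.14)
  expect_lt(abs(rate - 20), 3 * sqrt(20 / (2 * 10000 * 0.14)))
})

test_that("correlation calibration is monotone and flags infeasible targets", {
  rs <- seq(0.05, 0.95, by = 0.1)
  cc <- vapply(rs, function(r) popspike:::copulaCountCorr(0.2, 0.2, r),
               numeric(1))
  expect_true(all(diff(cc) > 0))
  expect_error(calibrateLatentCorr(c(0.01, 8), 0.9), "maximum achievable")
})

test_that("simulated PSTHs match the rate profile within 3 SE per bin", {
  prof <- rateProfile(condition = "control")
  sim <- simulatePopulation(prof, nNeurons = 1, nTrials = 1500, seed = 4)
  peri <- alignToEvents(sim$spikes, sim$events, window = c(-0.040, 0.100))
  ps <- computePSTH(peri, binWidth = 0.010)
  target <- profileBinRates(prof, binEdges(ps))
  se <- sqrt(target / (1500 * 0.010)) + 1e-9
  expect_true(all(abs(psthRates(ps)[1, ] - target) <= 3 * se))
})

test_that("optogenetic modifiers shape the late window as designed", {
  # activation truncated at 30 ms: late-window (40-100 ms) rate == baseline
  act <- rateProfile(condition = "opto_activation", truncationS = 0.030)
  simA <- simulatePopulation(act, nNeurons = 1, nTrials = 500, seed = 5)
  lateBins <- 9:14  # 40-100 ms of the [-40, 100) / 10 ms grid
  kA <- sum(simA$counts[, 1, lateBins])
  lam0 <- act@baseline_hz * 500 * 0.06
  expect_lt(abs(kA - lam0), 3 * sqrt(lam0))
  # inhibition doubles baseline + late: late-window rate strictly above control
  ctl <- rateProfile(condition = "control")
  inh <- rateProfile(condition = "opto_inhibition", lateGain = 2)
  simC <- simulatePopulation(ctl, nNeurons = 1, nTrials = 500, seed = 6)
  simI <- simulatePopulation(inh, nNeurons = 1, nTrials = 500, seed = 7)
  pp <- poisson.test(c(sum(simI$counts[, 1, lateBins]),
                       sum(simC$counts[, 1, lateBins])),
                     alternative = "greater")
  expect_lt(pp$p.value, 0.05)
})

test_that("touch streams have the configured statistics and are reproducible", {
  # zero-length pole epoch: no touches
  e0 <- simulateTouchStream(poleEpoch = c(1, 1), nTrials = 5, seed = 8)
  expect_equal(sum(events(e0)$event_type == "touch"), 0L)
  # defaults, 200 trials: sample mean duration within 10% of 27 ms
  ts <- simulateTouchStream(nTrials = 200, seed = 9)
  tch <- events(ts)[events(ts)$event_type == "touch", ]
  expect_lt(abs(mean(tch$offset_s - tch$onset_s) - 0.0271), 0.1 * 0.0271)
  # touches never overlap
  for (tr in unique(tch$trial_id)) {
    e <- tch[tch$trial_id == tr, ]
    e <- e[order(e$onset_s), ]
    if (nrow(e) > 1) expect_true(all(e$onset_s[-1] >= e$offset_s[-nrow(e)]))
  }
  # determinism
  ts2 <- simulateTouchStream(nTrials = 200, seed = 9)
  expect_identical(events(ts), events(ts2))
  # impossible parameters
  expect_error(simulateTouchStream(meanTouchDuration = 0.08,
                                   meanInterTouch = 0.07, nTrials = 1,
                                   seed = 1), "overlap")
})

test_that("Vm sweep generator honors states, noise and seeds", {
  # noiseless, all resting: baseline exactly -70 mV
  v0 <- simulateVmSweeps(10, stateMix = 0, noiseSd = 0, seed = 10)
  pre <- traces(v0)[1:100, ]
  expect_true(all(pre == -70))
  # activated fraction near the mix
  v1 <- simulateVmSweeps(1000, stateMix = 0.5, seed = 11)
  expect_lt(abs(mean(sweepStates(v1) == "activated") - 0.5), 0.05)
  # determinism
  v2 <- simulateVmSweeps(50, seed = 12)
  v3 <- simulateVmSweeps(50, seed = 12)
  expect_identical(traces(v2), traces(v3))
})

test_that("population simulation is reproducible and events sit at the onset", {
  s1 <- simulatePopulation(rateProfile(), nNeurons = 3, nTrials = 30, seed = 13)
  s2 <- simulatePopulation(rateProfile(), nNeurons = 3, nTrials = 30, seed = 13)
  expect_identical(spikes(s1$spikes), spikes(s2$spikes))
  expect_identical(s1$counts, s2$counts)
  ev <- events(s1$events)
  expect_true(all(ev$event_type == "whisker_deflection"))
  expect_equal(nrow(ev), 30L)
  # spike trains respect the refractory constraint (dataset validity)
  expect_true(validObject(s1$spikes))
})
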