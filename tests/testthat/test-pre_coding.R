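test_that("pseudo-population pooling samples per cell without replacement", {
  # 2 cells x 2 events: both cells' spikes appear in the 2 population trials
  evs <- data.frame(event_id = c("a1", "a2", "b1", "b2"),
                    trial_id = c("a1", "a2", "b1", "b2"),
                    condition = "control", onset_s = 0,
                    cell_id = c("c1", "c1", "c2", "c2"))
  sp <- data.frame(neuron_id = c("c1", "c1", "c2", "c2"),
                   event_id = c("a1", "a2", "b1", "b2"),
                   time_s = c(0.005, 0.015, 0.005, 0.025))
  peri <- makePeri(sp, evs, neurons = c("c1", "c2"), window = c(-0.02, 0.04))
  pop <- buildPseudoPopulation(peri, "min", binWidth = 0.010, seed = 1)
  expect_equal(nrow(counts(pop)), 2L)
  expect_equal(nUnits(pop), 2L)
  expect_equal(sum(counts(pop)), 4L)          # every spike used exactly once
  expect_equal(unname(rowSums(counts(pop))), c(2, 2)) # one event per cell per trial

  # single cell: the population trial is that cell's trial
  peri1 <- makePeri(sp[1:2, ], evs[1:2, ], neurons = "c1",
                    window = c(-0.02, 0.04))
  pop1 <- buildPseudoPopulation(peri1, "min", binWidth = 0.010, seed = 2)
  expect_equal(sum(counts(pop1)), 2L)

  # determinism and the too-few-events error
  popA <- buildPseudoPopulation(peri, 2, binWidth = 0.01, seed = 9)
  popB <- buildPseudoPopulation(peri, 2, binWidth = 0.01, seed = 9)
  expect_identical(counts(popA), counts(popB))
  expect_error(buildPseudoPopulation(peri, 3, binWidth = 0.01, seed = 1),
               "c1")
})

test_that("PRE detection applies the strict per-unit threshold", {
  # counts [1, 0, 3, 2, 0] over 10 units, Th = 0.1: bins 3 and 4 only
  pop <- popFromCounts(matrix(c(1, 0, 3, 2, 0), 1), nUnits = 10, t0 = 0)
  pre <- detectPREs(pop, th = 0.1)
  expect_equal(preTimes(pre)$time_s, c(0.025, 0.035))
  # all-zero counts: no PREs
  expect_equal(nrow(preTimes(detectPREs(popFromCounts(matrix(0, 3, 5)),
                                        th = 0.1))), 0L)
})

test_that("PRE detection matches brute-force enumeration on random instances", {
  set.seed(6)
  for (k in 1:300) {
    nu <- sample(1:5, 1)
    nb <- sample(2:14, 1)
    nt <- sample(1:6, 1)
    cnt <- matrix(rpois(nt * nb, 0.8), nt, nb)
    th <- runif(1, 0.01, 1)
    pop <- popFromCounts(cnt, nUnits = nu)
    pre <- preTimes(detectPREs(pop, th = th))
    oracle <- brutePREs(cnt, nu, th, binCenters(pop))
    expect_equal(pre$trial, oracle$trial)
    expect_equal(pre$time_s, oracle$time_s)
  }
})

test_that("PRE detection is invariant to doubling spikes and units", {
  set.seed(7)
  cnt <- matrix(rpois(60, 1), 6, 10)
  a <- preTimes(detectPREs(popFromCounts(cnt, nUnits = 5), th = 0.3))
  b <- preTimes(detectPREs(popFromCounts(2 * cnt, nUnits = 10), th = 0.3))
  expect_equal(a, b)
})

test_that("absolute error uses the per-condition mode with earliest-tie rule", {
  # [10, 10, 20, 40] ms: mode 10, errors 0, 0, 10, 30
  ae <- absoluteError(c(0.010, 0.010, 0.020, 0.040))
  expect_equal(ae$mode, 0.010)
  expect_equal(ae$errors, c(0, 0, 0.010, 0.030))
  # all PREs at one time: all errors 0
  expect_equal(absoluteError(rep(0.02, 5))$errors, rep(0, 5))
  # bimodal: earliest mode wins
  ae2 <- absoluteError(c(0.010, 0.010, 0.020, 0.020))
  expect_equal(ae2$mode, 0.010)
  expect_equal(ae2$errors, c(0, 0, 0.010, 0.010))
  expect_error(absoluteError(numeric()), "no PREs")
  # invariance to a common time shift
  x <- c(0.01, 0.02, 0.02, 0.05, 0.09)
  expect_equal(absoluteError(x)$errors, absoluteError(x + 0.013)$errors)
})

test_that("absoluteError on a PREResult fills per-condition modes and errors", {
  popA <- popFromCounts(matrix(c(0, 5, 0, 0, 2, 0), 2, 3, byrow = TRUE),
                        nUnits = 10, condition = "control")
  popB <- popFromCounts(matrix(c(0, 0, 4), 1), nUnits = 10,
                        condition = "light")
  pre <- absoluteError(detectPREs(list(popA, popB), th = 0.1))
  expect_equal(sort(names(preModes(pre))), c("control", "light"))
  er <- preErrors(pre)
  expect_true(all(er$abs_error_s[er$condition == "light"] == 0))
})

test_that("condition comparison picks the right test family", {
  # identical samples: degenerate, no rejection
  expect_warning(r0 <- compareConditions(rep(1, 10), rep(1, 10)),
                 "degenerate")
  expect_gte(r0$p.value, 0.05)
  # large shift: rejection, p agrees with the Mann-Whitney oracle
  set.seed(8)
  a <- rexp(100); b <- rexp(100) + 3
  r1 <- compareConditions(a, b)
  expect_lt(r1$p.value, 1e-10)
  expect_equal(r1$p.value,
               suppressWarnings(wilcox.test(a, b)$p.value))
  # three conditions: Kruskal-Wallis + Dunn path
  r2 <- compareConditions(list(a = a, b = b, c = rexp(100) + 6))
  expect_match(r2$method, "Kruskal-Wallis")
  expect_equal(nrow(r2$dunn), 3L)
  expect_true(all(r2$dunn$p.adjusted >= r2$dunn$p))
  expect_lt(r2$dunn$p.adjusted[r2$dunn$group1 == "a" &
                                 r2$dunn$group2 == "c"], 0.05)
})

test_that("stationary independent Poisson noise yields uniform PRE times", {
  prof <- rateProfile(5, 0, 0, earlyWindow = c(0, 0.002),
                      earlyPeak = 0.001, lateWindow = c(0.002, 0.004))
  sim <- simulatePopulation(prof, nNeurons = 13, nTrials = 10000, seed = 15)
  pop <- poolSim(sim, 13, "control")
  pre <- preTimes(detectPREs(pop, th = 0.1))
  counts <- table(factor(pre$time_s, levels = binCenters(pop)))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("spurious PREs grow with noise correlation before saturating", {
  prof <- rateProfile(condition = "control")
  spurRate <- function(rho) {
    sim <- simulatePopulation(prof, nNeurons = 13, nTrials = 3000,
                              rho = rho, seed = 16)
    pooled <- apply(sim$counts[, , 1:4], c(1, 3), sum)  # pre-stimulus bins
    mean(pooled / 13 > 0.1) * 4
  }
  grid <- c(0, 0.02, 0.05, 0.1)
  rates <- vapply(grid, spurRate, numeric(1))
  # amplification is monotone over the rising range of the grid ...
  expect_true(all(diff(rates) > 0))
  # ... and even the strongest tested correlation stays well above the
  # uncorrelated pooling baseline (saturation, not disappearance)
  expect_gt(spurRate(0.4), rates[1])
})

test_that("the condition contrast direction is stable across a Th band", {
  simC <- simulatePopulation(rateProfile(condition = "control"),
                             nNeurons = 13, nTrials = 150, seed = 17)
  simA <- simulatePopulation(rateProfile(condition = "opto_activation",
                                         truncationS = 0.030),
                             nNeurons = 13, nTrials = 150, seed = 18)
  sw <- thSweep(poolSim(simA, 13, "opto_activation"),
                poolSim(simC, 13, "control"), th = 0.1, band = 0.5,
                alternative = "less")
  # one-sided "less" significance at every Th encodes the stable direction
  expect_true(all(sw$p < 0.05))
  expect_true(all(sw$direction <= 0))
})
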