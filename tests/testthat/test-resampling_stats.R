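test_that("the normality gate routes to t or rank tests and handles degeneracy", {
  set.seed(31)
  x <- rnorm(200); y <- rnorm(200, 0.5)
  r <- chooseTwoSampleTest(x, y)
  expect_equal(r$method, "t test")
  expect_equal(r$p.value, t.test(x, y)$p.value)
  # heavily skewed: Mann-Whitney branch, p agrees with the oracle
  xs <- rexp(200)^2; ys <- rexp(200)^2 * 2
  rs <- chooseTwoSampleTest(xs, ys)
  expect_equal(rs$method, "Mann-Whitney")
  expect_equal(rs$p.value, suppressWarnings(wilcox.test(xs, ys)$p.value))
  # paired identical: p = 1, no effect
  z <- rnorm(20)
  expect_warning(rp <- chooseTwoSampleTest(z, z, paired = TRUE),
                 "degenerate")
  expect_equal(rp$p.value, 1)
  expect_error(chooseTwoSampleTest(rnorm(10), rnorm(9), paired = TRUE),
               "equal sample sizes")
  # one-tailed direction is honored
  r1 <- chooseTwoSampleTest(ys, xs, alternative = "greater")
  expect_lt(r1$p.value, 0.05)
  expect_equal(r1$direction, 1L)
})

test_that("multiple-testing procedures match hand step-up / step-down decisions", {
  p <- c(0.01, 0.02, 0.04, 0.5)
  # BH step-up by hand: thresholds i/m * alpha = 0.0125 0.025 0.0375 0.05
  handBH <- function(p, alpha) {
    m <- length(p); o <- order(p)
    below <- which(p[o] <= seq_len(m) / m * alpha)
    rej <- logical(m)
    if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
    rej
  }
  bh <- adjustPvalues(p, "benjamini_hochberg")
  expect_equal(bh$reject, handBH(p, 0.05))
  expect_equal(sum(bh$reject), 2L)
  # BY: same with alpha / sum(1/i)
  handBY <- function(p, alpha) handBH(p, alpha / sum(1 / seq_along(p)))
  expect_equal(adjustPvalues(p, "benjamini_yekutieli")$reject, handBY(p, 0.05))
  # Holm step-down by hand
  handHolm <- function(p, alpha) {
    m <- length(p); o <- order(p); rej <- logical(m)
    for (i in seq_len(m)) {
      if (p[o[i]] <= alpha / (m - i + 1)) rej[o[i]] <- TRUE else break
    }
    rej
  }
  expect_equal(adjustPvalues(p, "holm_bonferroni")$reject, handHolm(p, 0.05))
  expect_true(adjustPvalues(0.03, "holm_bonferroni")$reject)  # m = 1
  expect_false(any(adjustPvalues(rep(1, 6), "benjamini_hochberg")$reject))
  # BH never rejects fewer than BY; Holm never more than unadjusted
  set.seed(32)
  for (k in 1:20) {
    pv <- runif(sample(3:30, 1))^sample(1:3, 1)
    expect_gte(sum(adjustPvalues(pv, "benjamini_hochberg")$reject),
               sum(adjustPvalues(pv, "benjamini_yekutieli")$reject))
    expect_lte(sum(adjustPvalues(pv, "holm_bonferroni")$reject),
               sum(pv <= 0.05))
  }
})

test_that("exact binomial tails match an independent summation oracle", {
  oracle <- function(k, n, p) sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - k:n))
  expect_equal(binomialTail(12, 100, 0.05), oracle(12, 100, 0.05),
               tolerance = 1e-12)
  expect_lt(binomialTail(12, 100, 0.05), 0.05)   # 12/100 significant
  expect_gt(binomialTail(5, 100, 0.05), 0.05)    # 5/100 is the expectation
  expect_equal(binomialTail(0, 100, 0.05), 1)
  for (k in c(1, 7, 30)) expect_equal(binomialTail(k, 100, 0.05),
                                      oracle(k, 100, 0.05), tolerance = 1e-12)
})

test_that("the subsample-binomial procedure is reproducible and guards inclusion", {
  prof <- awakeProfile()
  set.seed(33)
  nev <- sample(58:70, 6, replace = TRUE)
  pA <- simulatePeriEvents(prof, 6, nev, c(-0.02, 0.04), seed = 34)
  pB <- simulatePeriEvents(prof, 6, nev, c(-0.02, 0.04), seed = 35)
  r1 <- subsampleBinomialProcedure(list(a = pA, b = pB), nRep = 20,
                                   masterSeed = 5)
  r2 <- subsampleBinomialProcedure(list(a = pA, b = pB), nRep = 20,
                                   masterSeed = 5)
  expect_identical(r1$repetitions, r2$repetitions)
  expect_identical(r1$decision, r2$decision)
  # a cell below the 53-event inclusion bound is a hard error
  pSmall <- simulatePeriEvents(prof, 2, c(40, 60), c(-0.02, 0.04), seed = 36)
  expect_error(subsampleBinomialProcedure(list(a = pSmall, b = pSmall),
                                          nRep = 5, masterSeed = 1),
               "fewer than 53")
})

test_that("reaction-time normalization and paired contrasts behave", {
  s <- data.frame(mouse_id = "m1", condition = c("OFF", "WIN"),
                  rt = c(900, 990))
  r <- normalizeReactionTimes(s)
  expect_equal(r$normalized$rt_norm, c(1, 1.1))
  # all conditions identical: everything normalizes to 1, nothing rejected
  s2 <- expand.grid(mouse_id = paste0("m", 1:4),
                    condition = c("OFF", "WIN", "EXT"))
  s2$rt <- 800
  r2 <- normalizeReactionTimes(s2)
  expect_true(all(r2$normalized$rt_norm == 1))
  expect_true(all(r2$tests$p.adjusted >= 0.05))
  # a +5% WIN shift across 15 sessions is detected (paired, one-tailed)
  set.seed(37)
  mice <- paste0("m", 1:5)
  s3 <- do.call(rbind, lapply(mice, function(m) {
    base <- runif(1, 700, 1100)
    data.frame(mouse_id = m,
               condition = rep(c("OFF", "WIN", "EXT"), each = 3),
               rt = c(base * rnorm(3, 1, 0.01), base * rnorm(3, 1.05, 0.01),
                      base * rnorm(3, 1, 0.01)))
  }))
  r3 <- normalizeReactionTimes(s3, contrasts = list(c("WIN", "OFF"),
                                                    c("WIN", "EXT"),
                                                    c("OFF", "EXT")))
  winOff <- r3$tests[r3$tests$contrast == "WIN > OFF", ]
  expect_lt(winOff$p.adjusted, 0.05)
  # a mouse without OFF sessions is excluded with a warning
  s4 <- rbind(s3, data.frame(mouse_id = "m9", condition = "WIN", rt = 1000))
  expect_warning(normalizeReactionTimes(s4,
                                        contrasts = list(c("WIN", "OFF"))),
                 "m9")
})
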