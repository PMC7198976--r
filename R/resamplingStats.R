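## Normality-gated test selection, the 100-repetition subsample + binomial
## aggregation procedure, FDR / Holm-Bonferroni corrections and reaction-time
## normalization.

#' Normality-gated two-sample test
#'
#' Each sample is checked for normality with a Kolmogorov-Smirnov test against
#' a normal with sample-estimated mean and SD (Lilliefors-corrected when
#' requested and the nortest package is available). If both samples pass at
#' \code{normalityAlpha}, a t test is used (paired or unpaired); otherwise
#' Mann-Whitney (unpaired) or Wilcoxon signed-rank (paired). Degenerate input
#' (all values tied, or all paired differences zero) returns p = 1 with a
#' warning: no evidence of an effect.
#'
#' @param x,y numeric samples (n >= 3 each); the alternative refers to x vs y.
#' @param paired paired comparison (requires equal lengths).
#' @param alternative "two.sided", "greater" or "less" (one-tailed).
#' @param alpha significance level recorded in the result.
#' @param normalityAlpha level of the KS normality gate.
#' @param lilliefors use the Lilliefors correction for the normality check.
#' @return list with \code{method}, \code{statistic}, \code{p.value},
#'   \code{n}, \code{direction} (sign of the location difference x - y),
#'   \code{normal} (the two gate outcomes) and \code{significant}.
#' @export
chooseTwoSampleTest <- function(x, y, paired = FALSE,
                                alternative = c("two.sided", "greater",
                                                "less"),
                                alpha = 0.05, normalityAlpha = 0.05,
                                lilliefors = FALSE) {
  alternative <- match.arg(alternative)
  if (paired && length(x) != length(y))
    stop("paired comparison requires equal sample sizes")
  stopifnot(length(x) >= 3, length(y) >= 3)
  degenerate <- if (paired) all(x == y) else
    (length(unique(c(x, y))) == 1L)
  if (degenerate) {
    warning("degenerate samples (all ties); returning p = 1")
    return(list(method = "degenerate", statistic = NA_real_, p.value = 1,
                n = c(length(x), length(y)), direction = 0L,
                normal = c(NA, NA), significant = FALSE))
  }
  ksNormal <- function(v) {
    if (sd(v) == 0) return(FALSE)
    p <- if (lilliefors && requireNamespace("nortest", quietly = TRUE))
      nortest::lillie.test(v)$p.value
    else suppressWarnings(ks.test(v, "pnorm", mean(v), sd(v))$p.value)
    p >= normalityAlpha
  }
  normal <- c(ksNormal(x), ksNormal(y))
  if (all(normal)) {
    tt <- t.test(x, y, paired = paired, alternative = alternative)
    method <- if (paired) "paired t test" else "t test"
  } else {
    tt <- suppressWarnings(
      wilcox.test(x, y, paired = paired, alternative = alternative))
    method <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney"
  }
  dir <- if (paired) sign(median(x - y)) else sign(median(x) - median(y))
  if (dir == 0) dir <- sign(mean(x) - mean(y))
  list(method = method, statistic = unname(tt$statistic),
       p.value = unname(tt$p.value), n = c(length(x), length(y)),
       direction = as.integer(dir), normal = normal,
       significant = tt$p.value < alpha)
}

#' Exact one-sided binomial tail
#'
#' P(X >= k) for X ~ Binomial(n, p); the aggregation statistic for counting
#' significant repetitions.
#'
#' @param k observed number of successes.
#' @param n number of trials.
#' @param p success probability under the null (the per-repetition alpha).
#' @return Upper-tail probability.
#' @export
binomialTail <- function(k, n, p) {
  if (k <= 0) return(1)
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Multiple-testing correction
#'
#' Step-up FDR control (Benjamini-Hochberg, Benjamini-Yekutieli) or step-down
#' family-wise control (Holm-Bonferroni) over a vector of p-values.
#'
#' @param pvals p-values in [0, 1].
#' @param method one of \code{"benjamini_hochberg"},
#'   \code{"benjamini_yekutieli"}, \code{"holm_bonferroni"}.
#' @param alpha decision level.
#' @return list with \code{adjusted} p-values and logical \code{reject}.
#' @export
adjustPvalues <- function(pvals, method = c("benjamini_hochberg",
                                            "benjamini_yekutieli",
                                            "holm_bonferroni"),
                          alpha = 0.05) {
  method <- match.arg(method)
  if (!length(pvals)) return(list(adjusted = numeric(), reject = logical()))
  stopifnot(all(pvals >= 0 & pvals <= 1))
  adj <- p.adjust(pvals, switch(method, benjamini_hochberg = "BH",
                                benjamini_yekutieli = "BY",
                                holm_bonferroni = "holm"))
  list(adjusted = adj, reject = adj <= alpha)
}

#' Subsample + binomial aggregation over repetitions
#'
#' The touch counts of sequentially recorded cells differ, so pseudo-
#' population construction subsamples a common number of events per cell (53
#' touches, without replacement). The whole construction is repeated
#' \code{nRep} times with fresh subsamples: per repetition, PREs and absolute
#' errors are computed for both conditions and compared with a two-sided
#' Mann-Whitney test, recording the direction of the difference. Repetitions
#' significant in each direction are then counted and an exact one-sided
#' binomial tail against success probability \code{alpha} decides whether a
#' systematic increase or decrease is declared. The repetition p-values are
#' also submitted to FDR control with both the Benjamini-Hochberg and
#' Benjamini-Yekutieli procedures for cross-checking.
#'
#' @param periByCondition named list of two \linkS4class{PeriEventSet}s
#'   (reference condition first); each must carry per-cell event streams
#'   (\code{cell_id} in its events) with at least \code{perCellSample} events
#'   per cell.
#' @param nRep number of random repetitions (100).
#' @param perCellSample events sampled per cell per repetition (53).
#' @param alpha per-repetition and aggregation significance level.
#' @param th PRE threshold (spikes per neuron, 0.1).
#' @param binWidth,window PRE binning (4 ms bins, [-20, 40) ms window).
#' @param masterSeed master seed; repetition r uses a derived seed.
#' @return list with \code{decision} ("increase", "decrease" or "none":
#'   direction of the second condition's absolute error relative to the
#'   first), \code{n_increase}, \code{n_decrease}, \code{binom_p} (named tail
#'   probabilities), \code{repetitions} (per-repetition log: seed, medians,
#'   p, direction), and \code{fdr} (BH / BY rejection counts and their
#'   agreement with the binomial decision).
#' @export
subsampleBinomialProcedure <- function(periByCondition, nRep = 100,
                                       perCellSample = 53, alpha = 0.05,
                                       th = 0.1, binWidth = 0.004,
                                       window = c(-0.020, 0.040),
                                       masterSeed = 1) {
  stopifnot(length(periByCondition) == 2, !is.null(names(periByCondition)))
  conds <- names(periByCondition)
  edges <- makeBinEdges(window, binWidth)
  nB <- length(edges) - 1L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  # Precompute per condition: per cell, an events x bins count matrix.
  prep <- lapply(periByCondition, function(peri) {
    stopifnot(is(peri, "PeriEventSet"))
    ev <- events(peri)
    if (!"cell_id" %in% names(ev))
      stop("per-cell event streams (cell_id) are required")
    sp <- spikes(peri)
    cells <- neuronIds(peri)
    mats <- lapply(setNames(cells, cells), function(cc) {
      eids <- ev$event_id[ev$cell_id == cc]
      s <- sp[sp$neuron_id == cc, , drop = FALSE]
      byEv <- split(s$time_s, factor(s$event_id, levels = eids))
      t(vapply(byEv, binCounts, integer(nB), edges = edges))
    })
    short <- names(mats)[vapply(mats, nrow, integer(1)) < perCellSample]
    if (length(short))
      stop(sprintf("cell(s) with fewer than %d events: %s", perCellSample,
                   paste(short, collapse = ", ")))
    mats
  })
  nUnits <- vapply(prep, length, integer(1))
  reps <- vector("list", nRep)
  for (r in seq_len(nRep)) {
    sd_r <- deriveSeed(masterSeed, 53L, r)
    set.seed(sd_r)
    errs <- setNames(vector("list", 2), conds)
    for (ci in 1:2) {
      mats <- prep[[ci]]
      pooled <- matrix(0L, perCellSample, nB)
      for (m in mats)
        pooled <- pooled + m[sample(nrow(m), perCellSample), , drop = FALSE]
      hits <- pooled / nUnits[ci] > th
      tms <- centers[which(hits, arr.ind = TRUE)[, 2]]
      errs[[ci]] <- if (length(tms)) absoluteError(tms)$errors else numeric()
    }
    if (length(errs[[1]]) && length(errs[[2]])) {
      wt <- suppressWarnings(wilcox.test(errs[[2]], errs[[1]]))
      p <- wt$p.value
      d <- sign(median(errs[[2]]) - median(errs[[1]]))
      if (d == 0) d <- sign(mean(errs[[2]]) - mean(errs[[1]]))
    } else {
      p <- NA_real_; d <- 0
    }
    reps[[r]] <- data.frame(rep = r, seed = sd_r,
                            n_pre_ref = length(errs[[1]]),
                            n_pre = length(errs[[2]]),
                            median_ref_s = if (length(errs[[1]]))
                              median(errs[[1]]) else NA_real_,
                            median_s = if (length(errs[[2]]))
                              median(errs[[2]]) else NA_real_,
                            p = p, direction = as.integer(d))
  }
  repDf <- do.call(rbind, reps)
  sig <- !is.na(repDf$p) & repDf$p < alpha
  nInc <- sum(sig & repDf$direction > 0)
  nDec <- sum(sig & repDf$direction < 0)
  pInc <- binomialTail(nInc, nRep, alpha)
  pDec <- binomialTail(nDec, nRep, alpha)
  decision <- if (pInc < alpha && (nInc >= nDec || pDec >= alpha)) "increase"
  else if (pDec < alpha) "decrease" else "none"
  ok <- !is.na(repDf$p)
  bh <- adjustPvalues(repDf$p[ok], "benjamini_hochberg", alpha)
  by <- adjustPvalues(repDf$p[ok], "benjamini_yekutieli", alpha)
  list(decision = decision, n_increase = nInc, n_decrease = nDec,
       binom_p = c(increase = pInc, decrease = pDec),
       repetitions = repDf,
       fdr = list(bh_rejections = sum(bh$reject),
                  by_rejections = sum(by$reject),
                  agrees_with_binomial =
                    (sum(bh$reject) > 0) == (decision != "none")))
}

#' Normalize reaction times to each mouse's light-off mean
#'
#' Each session's mean reaction time is divided by the mean reaction time of
#' the same mouse in the reference (light-off) condition, removing
#' between-animal RT covariation; condition contrasts are then one-tailed
#' paired t tests across per-mouse condition means with Holm-Bonferroni
#' correction.
#'
#' @param sessions data.frame with columns \code{mouse_id}, \code{condition},
#'   \code{rt} (per-session mean reaction time).
#' @param offLabel label of the reference condition (default "OFF").
#' @param contrasts list of 2-vectors \code{c(a, b)}, each testing the
#'   alternative normalized RT(a) > RT(b); all ordered pairs against the
#'   remaining conditions when NULL.
#' @return list with \code{normalized} (sessions plus \code{rt_norm}) and
#'   \code{tests} (per contrast: t, raw and Holm-adjusted one-tailed p).
#' @export
normalizeReactionTimes <- function(sessions, offLabel = "OFF",
                                   contrasts = NULL) {
  need <- c("mouse_id", "condition", "rt")
  stopifnot(all(need %in% names(sessions)))
  offMean <- tapply(sessions$rt[sessions$condition == offLabel],
                    sessions$mouse_id[sessions$condition == offLabel], mean)
  noOff <- setdiff(unique(sessions$mouse_id), names(offMean))
  if (length(noOff)) {
    warning(sprintf("mouse/mice without %s sessions excluded: %s", offLabel,
                    paste(noOff, collapse = ", ")))
    sessions <- sessions[!sessions$mouse_id %in% noOff, , drop = FALSE]
  }
  sessions$rt_norm <- as.numeric(sessions$rt / offMean[sessions$mouse_id])
  perMouse <- aggregate(rt_norm ~ mouse_id + condition, sessions, mean)
  conds <- unique(sessions$condition)
  if (is.null(contrasts)) {
    prs <- combn(conds, 2, simplify = FALSE)
    contrasts <- lapply(prs, function(p)
      if (p[1] == offLabel) rev(p) else p)  # test light > off by default
  }
  res <- lapply(contrasts, function(ct) {
    a <- perMouse[perMouse$condition == ct[1], c("mouse_id", "rt_norm")]
    b <- perMouse[perMouse$condition == ct[2], c("mouse_id", "rt_norm")]
    m <- merge(a, b, by = "mouse_id", suffixes = c("_a", "_b"))
    if (nrow(m) < 3 || all(m$rt_norm_a == m$rt_norm_b))
      return(data.frame(contrast = paste(ct, collapse = " > "),
                        n_mice = nrow(m), t = NA_real_, p = 1))
    tt <- t.test(m$rt_norm_a, m$rt_norm_b, paired = TRUE,
                 alternative = "greater")
    data.frame(contrast = paste(ct, collapse = " > "), n_mice = nrow(m),
               t = unname(tt$statistic), p = unname(tt$p.value))
  })
  tests <- do.call(rbind, res)
  tests$p.adjusted <- p.adjust(tests$p, "holm")
  list(normalized = sessions, tests = tests)
}
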