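## Spike detection from raw traces and the per-neuron classifiers: opsin
## status (light-response rules) and whisker-/touch-responsiveness via
## sliding-window max-interval testing.

#' Threshold-based spike detection
#'
#' Detects spikes as upward threshold crossings of a sampled trace, with the
#' threshold anchored to noise estimated from a stimulus-free segment:
#' either 3x the peak-to-peak noise (juxtasomal convention) or 4x the SD of
#' the high-frequency signal (linear-probe convention). One spike per
#' refractory period; deterministic given the trace.
#'
#' @param trace numeric vector, sampled voltage.
#' @param samplingRate sampling rate (Hz), must be >= 10 kHz.
#' @param rule \code{"peak_to_peak"} (threshold = factor x peak-to-peak noise,
#'   factor 3) or \code{"sd"} (threshold = factor x noise SD, factor 4).
#' @param factor override for the rule's multiplier.
#' @param refractory minimum spike separation (s).
#' @param noiseSegment index range (2 integers) of a stimulus-free segment of
#'   \code{trace} used to estimate the noise; required.
#' @return Spike times in seconds from trace start (crossing onsets).
#' @export
detectSpikesThreshold <- function(trace, samplingRate,
                                  rule = c("peak_to_peak", "sd"),
                                  factor = NULL, refractory = 0.001,
                                  noiseSegment = NULL) {
  rule <- match.arg(rule)
  stopifnot(samplingRate >= 1e4)
  if (is.null(noiseSegment))
    stop("a stimulus-free noiseSegment is required to estimate the noise")
  seg <- trace[noiseSegment[1]:noiseSegment[2]]
  center <- median(seg)
  thr <- switch(rule,
                peak_to_peak = (factor %||% 3) * (max(seg) - min(seg)),
                sd = (factor %||% 4) * sd(seg))
  x <- trace - center
  above <- x > thr
  onsets <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(onsets)) return(numeric())
  enforceRefractory((onsets - 1) / samplingRate, refractory)
}

#' Classify a neuron's opsin status from light-pulse responses
#'
#' Three protocols: \code{juxta_blue_10ms} (ChR2-positive iff the neuron
#' spikes during the 10-ms blue pulse in strictly more than 90\% of trials),
#' \code{juxta_yellow_500ms} (Halo-positive iff the neuron is completely
#' silent during the 500-ms yellow pulse in strictly more than 90\% of
#' trials), \code{patch_latency} (ChR2-positive iff the median first-spike
#' latency is below 1 ms).
#'
#' @param peri a \linkS4class{PeriEventSet} aligned to light onsets (0 =
#'   pulse onset).
#' @param protocol one of \code{"patch_latency"}, \code{"juxta_blue_10ms"},
#'   \code{"juxta_yellow_500ms"}.
#' @param pulseDuration pulse length (s); defaults to the protocol's value.
#' @param minTrials minimum light trials for a conclusive label.
#' @return data.frame with one row per neuron: \code{neuron_id},
#'   \code{label} (chr2_positive / halo_positive / opsin_negative /
#'   inconclusive) and \code{evidence} (trial fraction meeting the rule, or
#'   latency in s).
#' @export
classifyOpsinStatus <- function(peri,
                                protocol = c("juxta_blue_10ms",
                                             "juxta_yellow_500ms",
                                             "patch_latency"),
                                pulseDuration = NULL, minTrials = 10) {
  protocol <- match.arg(protocol)
  stopifnot(is(peri, "PeriEventSet"))
  dur <- pulseDuration %||%
    switch(protocol, juxta_blue_10ms = 0.010, juxta_yellow_500ms = 0.500,
           patch_latency = 0.010)
  sp <- spikes(peri)
  ev <- events(peri)
  perCell <- "cell_id" %in% names(ev)
  out <- lapply(neuronIds(peri), function(nid) {
    evIds <- if (perCell) ev$event_id[ev$cell_id == nid] else ev$event_id
    nTr <- length(evIds)
    s <- sp[sp$neuron_id == nid & sp$event_id %in% evIds, , drop = FALSE]
    inPulse <- s[s$time_s >= 0 & s$time_s < dur, , drop = FALSE]
    if (nTr < minTrials) {
      warning(sprintf("neuron %s: only %d light trials (< %d); inconclusive",
                      nid, nTr, minTrials))
      return(data.frame(neuron_id = nid, label = "inconclusive",
                        evidence = NA_real_, stringsAsFactors = FALSE))
    }
    if (protocol == "patch_latency") {
      lat <- vapply(split(inPulse$time_s, inPulse$event_id),
                    min, numeric(1))
      med <- if (length(lat)) median(lat) else NA_real_
      lab <- if (is.finite(med) && med < 0.001) "chr2_positive" else
        "opsin_negative"
      return(data.frame(neuron_id = nid, label = lab, evidence = med,
                        stringsAsFactors = FALSE))
    }
    nWith <- length(unique(inPulse$event_id))
    if (protocol == "juxta_blue_10ms") {
      frac <- nWith / nTr
      lab <- if (frac > 0.9) "chr2_positive" else "opsin_negative"
    } else {
      frac <- 1 - nWith / nTr   # fraction of trials with zero pulse spikes
      lab <- if (frac > 0.9) "halo_positive" else "opsin_negative"
    }
    data.frame(neuron_id = nid, label = lab, evidence = frac,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Sliding max-count interval of length m (in 1-ms samples) over trial-summed
# counts; earliest start on ties. Returns 1-based start index.
maxCountInterval <- function(summed, m) {
  n <- length(summed) - m + 1L
  cs <- c(0, cumsum(summed))
  sums <- cs[(m + 1):(m + n)] - cs[1:n]
  which.max(sums)  # earliest on ties
}

#' Sliding-window responsiveness classification
#'
#' A neuron is responsive when, for at least one sliding-window duration, the
#' per-trial spike count in the post-stimulus interval with maximal
#' trial-summed count significantly exceeds (one-tailed, alpha) the count in
#' the analogous maximal pre-stimulus interval. Counts are taken on a 1-ms
#' grid; the interval with the maximal trial-summed count is located
#' separately in the pre and post windows (earliest start on ties) and the
#' per-trial counts in those two fixed intervals are compared with the
#' normality-gated two-sample test (\code{\link{chooseTwoSampleTest}}).
#'
#' Anesthetized whisker variant: pre [-100, 0) ms, post [0, 100) ms, durations
#' 10-100 ms in 1-ms steps. Awake touch variant: pre [-20, 0) ms, post
#' [0, 40) ms, durations 5-20 ms.
#'
#' @param peri a \linkS4class{PeriEventSet}.
#' @param preWindow,postWindow comparison windows (s).
#' @param durations sliding-window durations (s).
#' @param alpha significance level of the one-tailed test.
#' @param minConsecutive optional stringency: require at least this many
#'   consecutive significant durations (default 1, the plain
#'   "at least one duration" rule).
#' @param paired use a paired comparison across trials instead of the default
#'   unpaired one.
#' @return A list with one entry per neuron: \code{responsive} (logical),
#'   \code{best} (duration, post-interval start, p of the most significant
#'   duration) and \code{table} (per-duration pre/post max-interval counts and
#'   p-values).
#' @export
classifyResponsive <- function(peri, preWindow = c(-0.100, 0),
                               postWindow = c(0, 0.100),
                               durations = seq(0.010, 0.100, by = 0.001),
                               alpha = 0.05, minConsecutive = 1L,
                               paired = FALSE) {
  stopifnot(is(peri, "PeriEventSet"))
  stopifnot(diff(preWindow) >= max(durations),
            diff(postWindow) >= max(durations))
  sp <- spikes(peri)
  ev <- events(peri)
  if (!nrow(ev)) stop("no trials in the PeriEventSet")
  perCell <- "cell_id" %in% names(ev)
  res <- 0.001
  preEdges <- seq(preWindow[1], preWindow[2], by = res)
  postEdges <- seq(postWindow[1], postWindow[2], by = res)
  out <- list()
  for (nid in neuronIds(peri)) {
    evIds <- if (perCell) ev$event_id[ev$cell_id == nid] else ev$event_id
    s <- sp[sp$neuron_id == nid, , drop = FALSE]
    bySp <- split(s$time_s, factor(s$event_id, levels = evIds))
    preC <- t(vapply(bySp, binCounts, integer(length(preEdges) - 1L),
                     edges = preEdges))
    postC <- t(vapply(bySp, binCounts, integer(length(postEdges) - 1L),
                      edges = postEdges))
    preSum <- colSums(preC)
    postSum <- colSums(postC)
    tab <- data.frame(duration_s = durations, pre_start_s = NA_real_,
                      post_start_s = NA_real_, pre_count = NA_real_,
                      post_count = NA_real_, p = NA_real_)
    for (di in seq_along(durations)) {
      m <- round(durations[di] / res)
      i0 <- maxCountInterval(preSum, m)
      j0 <- maxCountInterval(postSum, m)
      preTrial <- rowSums(preC[, i0:(i0 + m - 1L), drop = FALSE])
      postTrial <- rowSums(postC[, j0:(j0 + m - 1L), drop = FALSE])
      tt <- chooseTwoSampleTest(postTrial, preTrial, paired = paired,
                                alternative = "greater", alpha = alpha)
      tab$pre_start_s[di] <- preWindow[1] + (i0 - 1L) * res
      tab$post_start_s[di] <- postWindow[1] + (j0 - 1L) * res
      tab$pre_count[di] <- sum(preTrial)
      tab$post_count[di] <- sum(postTrial)
      tab$p[di] <- tt$p.value
    }
    sig <- tab$p < alpha
    runs <- rle(sig)
    responsive <- any(runs$values & runs$lengths >= minConsecutive)
    best <- if (any(sig)) {
      bi <- which.min(tab$p)
      list(duration_s = tab$duration_s[bi], start_s = tab$post_start_s[bi],
           p = tab$p[bi])
    } else NULL
    out[[nid]] <- list(neuron_id = nid, responsive = responsive, best = best,
                       table = tab)
  }
  out
}
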