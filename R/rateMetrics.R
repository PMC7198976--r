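## PSTH construction, windowed firing rates, mean spike latency and touch
## kinematics summaries. The display convention throughout: average across
## trials first, then across neurons; error bars are SEM across neurons.

#' Compute a peri-stimulus time histogram
#'
#' Per neuron, spike counts are binned over events and divided by
#' (n_events x bin width) to give Hz, then optionally smoothed with a Gaussian
#' kernel (truncated at +/- 4 SD; the kernel mass falling outside the window
#' is renormalized per source bin, so total spike counts are conserved
#' exactly). The across-neuron mean and SEM are attached.
#'
#' @param peri a \linkS4class{PeriEventSet}.
#' @param binWidth bin width (s); 10 ms for anesthetized whisker PSTHs, 1 ms
#'   (with 2-ms Gaussian smoothing) for awake peri-touch histograms.
#' @param smoothingSd Gaussian smoothing SD (s) or NULL for none.
#' @return A \linkS4class{PSTH}.
#' @export
computePSTH <- function(peri, binWidth = 0.010, smoothingSd = NULL) {
  stopifnot(is(peri, "PeriEventSet"), binWidth > 0)
  ev <- events(peri)
  if (!nrow(ev)) stop("empty PeriEventSet")
  edges <- makeBinEdges(periWindow(peri), binWidth)
  nB <- length(edges) - 1L
  sp <- spikes(peri)
  perCell <- "cell_id" %in% names(ev)
  nids <- neuronIds(peri)
  rates <- matrix(0, length(nids), nB,
                  dimnames = list(nids, NULL))
  for (i in seq_along(nids)) {
    nEv <- if (perCell) sum(ev$cell_id == nids[i]) else nrow(ev)
    if (nEv == 0) { rates[i, ] <- NA_real_; next }
    cnt <- binCounts(sp$time_s[sp$neuron_id == nids[i]], edges)
    rates[i, ] <- cnt / (nEv * binWidth)
  }
  if (!is.null(smoothingSd) && is.finite(smoothingSd) && smoothingSd > 0) {
    K <- outer(seq_len(nB), seq_len(nB), function(i, j)
      dnorm((i - j) * binWidth, sd = smoothingSd))
    K[abs(row(K) - col(K)) * binWidth > 4 * smoothingSd] <- 0
    K <- sweep(K, 2, colSums(K), "/")  # each source bin redistributes mass 1
    rates <- rates %*% t(K)
  }
  mu <- colMeans(rates)
  new("PSTH", bin_edges = edges, rates = rates, mean = mu,
      sem = semAcross(rates),
      smoothing_sd_s = if (is.null(smoothingSd)) NA_real_ else smoothingSd)
}

#' Windowed firing rate per neuron
#'
#' Spikes in the half-open window summed over events, divided by
#' (n_events x window length).
#'
#' @param peri a \linkS4class{PeriEventSet}.
#' @param window numeric(2) \code{[a, b)} in seconds, inside the peri-event
#'   window.
#' @param average also return the across-neuron mean and SEM.
#' @return Named numeric of per-neuron rates (Hz), or a list with
#'   \code{per_neuron}, \code{mean}, \code{sem} when \code{average}.
#' @export
windowRate <- function(peri, window, average = FALSE) {
  stopifnot(is(peri, "PeriEventSet"))
  if (window[2] <= window[1]) stop("window must have b > a")
  w <- periWindow(peri)
  if (window[1] < w[1] - 1e-12 || window[2] > w[2] + 1e-12)
    stop("window must lie within the peri-event window")
  sp <- spikes(peri)
  ev <- events(peri)
  perCell <- "cell_id" %in% names(ev)
  nids <- neuronIds(peri)
  out <- vapply(nids, function(nid) {
    nEv <- if (perCell) sum(ev$cell_id == nid) else nrow(ev)
    if (nEv == 0) return(NA_real_)
    k <- sum(sp$neuron_id == nid & sp$time_s >= window[1] &
               sp$time_s < window[2])
    k / (nEv * diff(window))
  }, numeric(1))
  if (!average) return(out)
  list(per_neuron = out, mean = mean(out, na.rm = TRUE),
       sem = sd(out, na.rm = TRUE) / sqrt(sum(is.finite(out))))
}

#' Mean spike latency per neuron
#'
#' Arithmetic mean of spike times inside the window, pooled over events.
#' A neuron with no in-window spikes yields NA (missing, not zero).
#'
#' @param peri a \linkS4class{PeriEventSet}.
#' @param window numeric(2) latency window (s), default the 0-100 ms response
#'   window.
#' @return Named numeric, mean latency (s) per neuron.
#' @export
meanSpikeTime <- function(peri, window = c(0, 0.100)) {
  stopifnot(is(peri, "PeriEventSet"))
  sp <- spikes(peri)
  vapply(neuronIds(peri), function(nid) {
    tt <- sp$time_s[sp$neuron_id == nid & sp$time_s >= window[1] &
                      sp$time_s < window[2]]
    if (!length(tt)) NA_real_ else mean(tt)
  }, numeric(1))
}

#' Touch kinematics summaries
#'
#' Per cell: median touch duration and median start-to-start inter-touch
#' interval across touches (plus median whisker amplitude and set-point when a
#' per-frame angle table is supplied); then across-cell mean and SEM per
#' condition.
#'
#' @param eventData an \linkS4class{EventTable} of touches; a \code{cell_id}
#'   column groups touches per recorded cell (a single implicit cell
#'   otherwise).
#' @param angles optional data.frame of per-frame whisker angles with columns
#'   \code{cell_id}, \code{condition}, \code{angle_deg}; whisker amplitude is
#'   the half-width of the angle envelope and the set-point its median.
#' @return A list with \code{per_cell} (one row per cell x condition) and
#'   \code{summary} (across-cell mean and SEM per condition and metric).
#' @export
summarizeTouchKinematics <- function(eventData, angles = NULL) {
  stopifnot(is(eventData, "EventTable"))
  ev <- events(eventData)
  ev <- ev[ev$event_type == "touch", , drop = FALSE]
  if (!"cell_id" %in% names(ev)) ev$cell_id <- "cell01"
  rows <- list()
  for (cc in unique(ev$cell_id)) for (cond in unique(ev$condition)) {
    e <- ev[ev$cell_id == cc & ev$condition == cond, , drop = FALSE]
    if (!nrow(e)) next
    e <- e[order(e$trial_id, e$onset_s), , drop = FALSE]
    dur <- median(e$offset_s - e$onset_s)
    iti <- unlist(lapply(split(e$onset_s, e$trial_id), function(on)
      if (length(on) >= 2) diff(sort(on)) else numeric()))
    amp <- sp <- NA_real_
    if (!is.null(angles)) {
      a <- angles$angle_deg[angles$cell_id == cc & angles$condition == cond]
      if (length(a)) {
        amp <- (max(a) - min(a)) / 2
        sp <- median(a)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = cc, condition = cond, n_touches = nrow(e),
      median_duration_s = dur,
      median_inter_touch_s = if (length(iti)) median(iti) else NA_real_,
      median_amplitude_deg = amp, median_set_point_deg = sp,
      stringsAsFactors = FALSE)
  }
  perCell <- do.call(rbind, rows)
  metrics <- c("median_duration_s", "median_inter_touch_s",
               "median_amplitude_deg", "median_set_point_deg")
  summ <- do.call(rbind, lapply(unique(perCell$condition), function(cond) {
    sub <- perCell[perCell$condition == cond, , drop = FALSE]
    do.call(rbind, lapply(metrics, function(m) {
      v <- sub[[m]][is.finite(sub[[m]])]
      data.frame(condition = cond, metric = m,
                 mean = if (length(v)) mean(v) else NA_real_,
                 sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else
                   NA_real_,
                 n_cells = length(v), stringsAsFactors = FALSE)
    }))
  }))
  list(per_cell = perCell, summary = summ)
}
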