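## Data model constructors, CSV I/O, peri-event alignment and the trial /
## touch inclusion rules used throughout the package.

#' Construct a SpikeDataset
#'
#' @param spikes data.frame with columns \code{neuron_id}, \code{trial_id},
#'   \code{condition}, \code{spike_time_s}.
#' @param neurons optional data.frame with \code{neuron_id} (and optional
#'   \code{depth_um}, \code{layer}); derived from \code{spikes} when NULL.
#' @param metadata optional provenance list.
#' @return A validated \linkS4class{SpikeDataset}; spikes are sorted by
#'   neuron, trial and time.
#' @export
SpikeDataset <- function(spikes, neurons = NULL, metadata = list()) {
  spikes <- as.data.frame(spikes)
  for (col in c("neuron_id", "trial_id", "condition"))
    if (col %in% names(spikes)) spikes[[col]] <- as.character(spikes[[col]])
  if (nrow(spikes))
    spikes <- spikes[order(spikes$neuron_id, spikes$trial_id,
                           spikes$spike_time_s), , drop = FALSE]
  rownames(spikes) <- NULL
  if (is.null(neurons))
    neurons <- data.frame(neuron_id = sort(unique(spikes$neuron_id)),
                          stringsAsFactors = FALSE)
  neurons$neuron_id <- as.character(neurons$neuron_id)
  new("SpikeDataset", spikes = spikes, neurons = neurons, metadata = metadata)
}

#' Construct an EventTable
#'
#' @param events data.frame with columns \code{trial_id}, \code{event_type},
#'   \code{onset_s}, \code{offset_s}, \code{condition}; extra columns (e.g. a
#'   per-cell grouping \code{cell_id}) are preserved.
#' @param metadata optional provenance list.
#' @return A validated \linkS4class{EventTable}, sorted by trial and onset.
#' @export
EventTable <- function(events, metadata = list()) {
  events <- as.data.frame(events)
  for (col in c("trial_id", "event_type", "condition"))
    if (col %in% names(events)) events[[col]] <- as.character(events[[col]])
  if (nrow(events))
    events <- events[order(events$trial_id, events$event_type,
                           events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  new("EventTable", events = events, metadata = metadata)
}

checkColumns <- function(df, need, what, path) {
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("%s '%s' is missing required column(s): %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

#' Read a SpikeDataset from disk
#'
#' CSV dialect: comma-separated, UTF-8, mandatory header with columns
#' \code{neuron_id}, \code{trial_id}, \code{condition}, \code{spike_time_s}.
#' Malformed rows (non-numeric spike times) are reported with their line
#' numbers; non-monotone or refractory-violating spike times within a trial
#' fail validation naming the offending row.
#'
#' @param path file path.
#' @param format only \code{"csv"} is supported.
#' @return A \linkS4class{SpikeDataset}.
#' @export
readSpikeDataset <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("hdf5 input is not supported by this build; use the csv interchange format")
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  checkColumns(df, c("neuron_id", "trial_id", "condition", "spike_time_s"),
               "spike table", path)
  tm <- suppressWarnings(as.numeric(df$spike_time_s))
  bad <- which(is.na(tm) & !is.na(df$spike_time_s) & df$spike_time_s != "")
  if (length(bad))
    stop(sprintf("malformed spike_time_s at line(s): %s",
                 paste(bad + 1L, collapse = ", ")))  # +1 for the header line
  df$spike_time_s <- tm
  SpikeDataset(df, metadata = list(source = path))
}

#' Read an EventTable from disk
#'
#' @inheritParams readSpikeDataset
#' @return An \linkS4class{EventTable}.
#' @export
readEventTable <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("hdf5 input is not supported by this build; use the csv interchange format")
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  checkColumns(df, c("trial_id", "event_type", "onset_s", "offset_s",
                     "condition"), "event table", path)
  EventTable(df, metadata = list(source = path))
}

writeWithSidecar <- function(df, path, metadata) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               n_rows = nrow(df),
               seed = metadata$seed,
               config = metadata$config,
               checksum = sum(vapply(df, function(col)
                 if (is.numeric(col)) sum(col) else length(col), numeric(1))))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Write a SpikeDataset (CSV + JSON provenance sidecar)
#' @param x a \linkS4class{SpikeDataset}.
#' @param path output CSV path; a \code{<path>.json} sidecar records
#'   provenance (seed, config, checksum).
#' @export
writeSpikeDataset <- function(x, path) {
  stopifnot(is(x, "SpikeDataset"))
  writeWithSidecar(spikes(x), path, x@metadata)
}

#' Write an EventTable (CSV + JSON provenance sidecar)
#' @param x an \linkS4class{EventTable}.
#' @param path output CSV path.
#' @export
writeEventTable <- function(x, path) {
  stopifnot(is(x, "EventTable"))
  writeWithSidecar(events(x), path, x@metadata)
}

#' Align spikes to event onsets
#'
#' Re-references every neuron's spikes to the onsets of the requested events:
#' one peri-event record per (neuron, event), spike times shifted so that the
#' event onset is 0 s, and spikes outside the half-open window dropped.
#'
#' @param spikeData a \linkS4class{SpikeDataset}.
#' @param eventData an \linkS4class{EventTable}.
#' @param window numeric(2), half-open window \code{[t_lo, t_hi)} in seconds
#'   around each onset.
#' @param eventType which events to align to (e.g. \code{"touch"},
#'   \code{"whisker_deflection"}).
#' @return A \linkS4class{PeriEventSet}. If the event table carries a
#'   \code{cell_id} column, events are matched only to their own cell's
#'   spikes (per-cell event streams, as in sequential recordings); otherwise
#'   every event is paired with every neuron recorded in its trial.
#' @export
alignToEvents <- function(spikeData, eventData, window,
                          eventType = "whisker_deflection") {
  stopifnot(is(spikeData, "SpikeDataset"), is(eventData, "EventTable"),
            length(window) == 2, all(is.finite(window)), window[1] < window[2])
  ev <- events(eventData)
  ev <- ev[ev$event_type == eventType, , drop = FALSE]
  if (!nrow(ev))
    warning(sprintf("no events of type '%s'; returning an empty PeriEventSet",
                    eventType))
  sp <- spikes(spikeData)
  byTrial <- split(sp, sp$trial_id)
  perCell <- "cell_id" %in% names(ev)
  outSpk <- vector("list", nrow(ev))
  evOut <- data.frame(event_id = character(nrow(ev)),
                      trial_id = ev$trial_id,
                      condition = ev$condition,
                      onset_s = ev$onset_s,
                      stringsAsFactors = FALSE)
  if (perCell) evOut$cell_id <- ev$cell_id
  i <- 0L
  for (r in seq_len(nrow(ev))) {
    i <- i + 1L
    eid <- sprintf("%s.e%04d", ev$trial_id[r], r)
    evOut$event_id[r] <- eid
    st <- byTrial[[ev$trial_id[r]]]
    if (is.null(st) || !nrow(st)) next
    if (perCell) st <- st[st$neuron_id == ev$cell_id[r], , drop = FALSE]
    t0 <- ev$onset_s[r]
    keep <- st$spike_time_s >= t0 + window[1] & st$spike_time_s < t0 + window[2]
    if (!any(keep)) next
    outSpk[[r]] <- data.frame(neuron_id = st$neuron_id[keep],
                              event_id = eid,
                              time_s = st$spike_time_s[keep] - t0,
                              stringsAsFactors = FALSE)
  }
  outSpk <- outSpk[!vapply(outSpk, is.null, logical(1))]
  spkDf <- if (length(outSpk)) do.call(rbind, outSpk) else
    data.frame(neuron_id = character(), event_id = character(),
               time_s = numeric(), stringsAsFactors = FALSE)
  new("PeriEventSet", spikes = spkDf, events = evOut,
      neurons = neuronIds(spikeData), window = as.numeric(window))
}

#' Filter touches whose peri-touch windows overlap or cross epoch borders
#'
#' Implements the two exclusion rules used for awake peri-touch analysis:
#' (a) successive touches whose peri-touch windows overlap are removed (both
#' members of each overlapping adjacent pair), and (b) touches whose
#' peri-touch window crosses the boundary of their condition epoch are
#' removed. Removed touches are logged with reasons in the returned table's
#' metadata (\code{removal_log}).
#'
#' @param eventData an \linkS4class{EventTable}; only \code{touch} rows are
#'   filtered, other event types pass through.
#' @param periWindow numeric(2) peri-touch window in seconds, e.g.
#'   \code{c(-0.020, 0.040)}; treated as closed for the overlap test.
#' @param epochBounds optional named list of condition epochs (seconds, in the
#'   same time base as the touch onsets), e.g.
#'   \code{list(control = c(0.5, 1), light = c(1, 1.5))}; rule (b) is skipped
#'   when NULL or when a touch's condition has no epoch entry.
#' @return An \linkS4class{EventTable} of surviving touches (plus untouched
#'   non-touch events).
#' @export
filterTouchEvents <- function(eventData, periWindow = c(-0.020, 0.040),
                              epochBounds = NULL) {
  stopifnot(is(eventData, "EventTable"))
  ev <- events(eventData)
  touches <- ev[ev$event_type == "touch", , drop = FALSE]
  others <- ev[ev$event_type != "touch", , drop = FALSE]
  log <- list()
  keepRows <- logical(nrow(touches))
  for (tr in unique(touches$trial_id)) {
    idx <- which(touches$trial_id == tr)
    idx <- idx[order(touches$onset_s[idx])]
    on <- touches$onset_s[idx]
    lo <- on + periWindow[1]
    hi <- on + periWindow[2]
    keep <- rep(TRUE, length(idx))
    if (length(idx) > 1) {
      overl <- lo[-1] < hi[-length(hi)]  # next window starts before previous ends
      for (j in which(overl)) {
        keep[j] <- FALSE
        keep[j + 1] <- FALSE
        log[[length(log) + 1L]] <- data.frame(
          trial_id = tr, onset_s = on[c(j, j + 1)],
          reason = "overlapping_peri_touch_windows",
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(epochBounds)) {
      for (j in seq_along(idx)) {
        epoch <- epochBounds[[touches$condition[idx[j]]]]
        if (is.null(epoch)) next
        if (lo[j] < epoch[1] || hi[j] > epoch[2]) {
          if (keep[j])
            log[[length(log) + 1L]] <- data.frame(
              trial_id = tr, onset_s = on[j],
              reason = "peri_touch_window_crosses_epoch_border",
              stringsAsFactors = FALSE)
          keep[j] <- FALSE
        }
      }
    }
    keepRows[idx] <- keep
  }
  out <- rbind(touches[keepRows, , drop = FALSE], others)
  removal <- if (length(log)) do.call(rbind, log) else
    data.frame(trial_id = character(), onset_s = numeric(),
               reason = character(), stringsAsFactors = FALSE)
  md <- eventData@metadata
  md$removal_log <- unique(removal)
  EventTable(out, metadata = md)
}

#' Assign touches to control / light analysis epochs
#'
#' Touches are labeled by their latency from the pole-presentation onset of
#' their trial: \code{[0.5, 1) s} is the control epoch and \code{[1, 1.5) s}
#' the light epoch by default. Touches in the first and last half second of
#' the pole presentation are discarded (pole-movement artifacts and post-light
#' rebound), as are touches outside any pole presentation.
#'
#' @param eventData an \linkS4class{EventTable} containing \code{touch} and
#'   \code{pole_presentation} events.
#' @param controlEpoch,lightEpoch numeric(2) epochs in seconds from pole
#'   onset; half-open.
#' @param labels condition labels assigned to the two epochs.
#' @return An \linkS4class{EventTable} of surviving touches with re-assigned
#'   \code{condition}; discards are logged in \code{metadata$removal_log}.
#' @export
selectAnalysisEpochs <- function(eventData, controlEpoch = c(0.5, 1.0),
                                 lightEpoch = c(1.0, 1.5),
                                 labels = c("control", "light")) {
  stopifnot(is(eventData, "EventTable"))
  ev <- events(eventData)
  poles <- ev[ev$event_type == "pole_presentation", , drop = FALSE]
  if (!nrow(poles)) stop("no pole_presentation events found")
  touches <- ev[ev$event_type == "touch", , drop = FALSE]
  keep <- logical(nrow(touches))
  cond <- character(nrow(touches))
  dropped <- 0L
  log <- list()
  for (i in seq_len(nrow(touches))) {
    p <- poles[poles$trial_id == touches$trial_id[i], , drop = FALSE]
    hit <- which(touches$onset_s[i] >= p$onset_s &
                 touches$onset_s[i] < p$offset_s)
    if (!length(hit)) {
      dropped <- dropped + 1L
      log[[length(log) + 1L]] <- data.frame(
        trial_id = touches$trial_id[i], onset_s = touches$onset_s[i],
        reason = "outside_pole_presentation", stringsAsFactors = FALSE)
      next
    }
    lat <- touches$onset_s[i] - p$onset_s[hit[1]]
    if (lat >= controlEpoch[1] && lat < controlEpoch[2]) {
      keep[i] <- TRUE; cond[i] <- labels[1]
    } else if (lat >= lightEpoch[1] && lat < lightEpoch[2]) {
      keep[i] <- TRUE; cond[i] <- labels[2]
    } else {
      log[[length(log) + 1L]] <- data.frame(
        trial_id = touches$trial_id[i], onset_s = touches$onset_s[i],
        reason = "outside_analysis_epochs", stringsAsFactors = FALSE)
    }
  }
  if (dropped)
    warning(sprintf("%d touch(es) outside any pole presentation discarded",
                    dropped))
  out <- touches[keep, , drop = FALSE]
  out$condition <- cond[keep]
  removal <- if (length(log)) do.call(rbind, log) else
    data.frame(trial_id = character(), onset_s = numeric(),
               reason = character(), stringsAsFactors = FALSE)
  md <- eventData@metadata
  md$removal_log <- removal
  EventTable(out, metadata = md)
}

#' Keep only cells with strictly more than a minimum number of trials
#'
#' Inclusion rule used for all spike analyses: a neuron enters the analysis
#' only if it has strictly more than \code{minCount} trials (anesthetized
#' protocols: > 50 trials) or touches (awake: > 53 touches) in every
#' condition.
#'
#' @param x a \linkS4class{PeriEventSet} (events counted per cell via the
#'   \code{cell_id} event column when present) or a \linkS4class{SpikeDataset}
#'   (distinct trials with at least one spike per neuron).
#' @param minCount strict lower bound on the per-condition count.
#' @param perCondition if TRUE (default) the bound must hold in every
#'   condition; otherwise on the total.
#' @return The subset of \code{x} restricted to surviving neurons.
#' @export
filterCellsByTrialCount <- function(x, minCount, perCondition = TRUE) {
  stopifnot(minCount >= 0)
  if (is(x, "PeriEventSet")) {
    ev <- events(x)
    if ("cell_id" %in% names(ev)) {
      tab <- table(ev$cell_id, if (perCondition) ev$condition else
        rep("all", nrow(ev)))
      ok <- rownames(tab)[apply(tab, 1, function(z) all(z > minCount))]
      spk <- spikes(x)
      keepEv <- ev$cell_id %in% ok
      new("PeriEventSet",
          spikes = spk[spk$neuron_id %in% ok &
                       spk$event_id %in% ev$event_id[keepEv], , drop = FALSE],
          events = ev[keepEv, , drop = FALSE],
          neurons = intersect(neuronIds(x), ok), window = periWindow(x))
    } else {
      # shared event stream: the count constraint applies to the set itself
      tab <- table(if (perCondition) ev$condition else rep("all", nrow(ev)))
      if (all(tab > minCount)) x else
        new("PeriEventSet", spikes = spikes(x)[0, , drop = FALSE],
            events = ev[0, , drop = FALSE], neurons = character(),
            window = periWindow(x))
    }
  } else if (is(x, "SpikeDataset")) {
    sp <- spikes(x)
    key <- unique(sp[, c("neuron_id", "trial_id", "condition")])
    tab <- table(key$neuron_id, if (perCondition) key$condition else
      rep("all", nrow(key)))
    ok <- rownames(tab)[apply(tab, 1, function(z) all(z > minCount))]
    SpikeDataset(sp[sp$neuron_id %in% ok, , drop = FALSE],
                 neurons = x@neurons[x@neurons$neuron_id %in% ok, ,
                                     drop = FALSE],
                 metadata = x@metadata)
  } else stop("x must be a PeriEventSet or SpikeDataset")
}
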