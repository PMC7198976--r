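## Internal helpers shared across modules.

# Deterministic per-stage seed derivation; keeps derived seeds < 2^31.
deriveSeed <- function(master, stage, k = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((abs(master) %% 1e5) * 19993 + stage * 10007 + k) %% 2147483647L
}

# Count spikes into uniform half-open bins [edges[i], edges[i+1]).
binCounts <- function(times, edges) {
  n <- length(edges) - 1L
  if (!length(times)) return(integer(n))
  idx <- findInterval(times, edges)
  idx <- idx[idx >= 1L & idx <= n & times < edges[n + 1L]]
  tabulate(idx, nbins = n)
}

makeBinEdges <- function(window, bin_width) {
  n <- round(diff(window) / bin_width)
  if (abs(n * bin_width - diff(window)) > 1e-9)
    stop("bin width must tile the analysis window exactly")
  seq(window[1], by = bin_width, length.out = n + 1L)
}

# Enforce a refractory period on a sorted spike train (drop followers).
enforceRefractory <- function(times, refractory = REFRACTORY_TOL) {
  if (length(times) < 2L) return(times)
  keep <- logical(length(times))
  keep[1] <- TRUE
  last <- times[1]
  for (i in 2:length(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

# Trapezoidal integral of y sampled at fixed dt.
trapint <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}

semAcross <- function(m) {
  # SEM across rows (neurons) of a matrix, per column
  if (nrow(m) < 2L) return(rep(NA_real_, ncol(m)))
  apply(m, 2, sd) / sqrt(nrow(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
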