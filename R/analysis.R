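# Post-hoc trace analysis: spike detection, spike-triggered average currents,
# K-vs-Na dominance fractions, and Welch spectral estimation.

#' Detect spikes in a voltage trace
#'
#' Upward crossings of a voltage threshold, with a refractory dead time.
#' Spike shapes in conductance-based models overshoot 0 mV, so counts are
#' insensitive to the exact threshold within roughly \[-30, 0\] mV.
#'
#' @param trace a `cn_trace`.
#' @param threshold detection voltage (mV).
#' @param refractory minimum separation between detections (ms).
#' @return An object of class `cn_spikes`: list with `times` (ms),
#'   `threshold`, `refractory`.
#' @export
detect_spikes <- function(trace, threshold = -20, refractory = 2) {
  stopifnot(inherits(trace, "cn_trace"))
  v <- trace$v
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  times <- trace$t[up]
  keep <- numeric(0)
  last <- -Inf
  for (tt in times) {
    if (tt - last >= refractory) {
      keep <- c(keep, tt)
      last <- tt
    }
  }
  structure(list(times = keep, threshold = threshold,
                 refractory = refractory), class = "cn_spikes")
}

#' @export
print.cn_spikes <- function(x, ...) {
  cat(sprintf("<spike train> %d spikes (threshold %g mV, refractory %g ms)\n",
              length(x$times), x$threshold, x$refractory))
  invisible(x)
}

.spike_times <- function(spikes) {
  if (inherits(spikes, "cn_spikes")) spikes$times else as.numeric(spikes)
}

# per-population resting current: mean over spike-free epochs (no spike
# within +/- margin ms)
.resting_current <- function(trace, spike_times, margin = 50) {
  quiet <- rep(TRUE, length(trace$t))
  for (ts in spike_times)
    quiet[trace$t > ts - margin & trace$t < ts + margin] <- FALSE
  if (!any(quiet)) quiet <- rep(TRUE, length(trace$t))  # fallback: all data
  colMeans(trace$currents[quiet, , drop = FALSE])
}

#' Spike-triggered average population currents
#'
#' Averages each population's current over a window preceding every spike:
#' `I_sta(lag) = mean_i I(t_i - lag)`.  Currents are stored outward-positive
#' (the plotting convention of depolarizing-negative is left to the caller);
#' `delta` is the STA current minus the population's resting current, the
#' mean over spike-free epochs (no spike within +/- 50 ms).
#'
#' @param trace a `cn_trace` with recorded currents.
#' @param spikes a `cn_spikes` or numeric spike times (ms).
#' @param window look-back window (ms).
#' @return An object of class `cn_sta`: `lags` (ms before spike, increasing),
#'   `mean` and `delta` (matrices lag x population, pA), `resting` (pA),
#'   `n_events`.
#' @export
sta_currents <- function(trace, spikes, window = 10) {
  stopifnot(inherits(trace, "cn_trace"))
  st <- .spike_times(spikes)
  st <- st[st > window + trace$t[1]]
  if (length(st) == 0) stop("no usable spikes (all closer than the window ",
                            "to the trace start)")
  lags <- seq(0, window, by = trace$dt)
  P <- ncol(trace$currents)
  rest <- .resting_current(trace, st)
  acc <- matrix(0, length(lags), P,
                dimnames = list(NULL, colnames(trace$currents)))
  t0 <- trace$t[1]
  for (ts in st) {
    idx <- round((ts - lags - t0) / trace$dt) + 1L
    acc <- acc + trace$currents[idx, , drop = FALSE]
  }
  mean_i <- acc / length(st)
  structure(list(lags = lags, mean = mean_i,
                 delta = sweep(mean_i, 2, rest),
                 resting = rest, n_events = length(st)),
            class = "cn_sta")
}

#' @export
print.cn_sta <- function(x, ...) {
  cat(sprintf("<STA> %d events, window %g ms, %d population(s)\n",
              x$n_events, max(x$lags), ncol(x$mean)))
  invisible(x)
}

#' Fraction of spikes where K+ fluctuations dominate Na+
#'
#' For each pre-spike lag, the proportion of spikes in which the K+
#' population's current change contributes more depolarization than the Na+
#' population's, i.e. `-delta I_K > -delta I_Na` with currents
#' outward-positive (the K+ route to depolarization is channel closure).
#' Ties count as not-exceeding.
#'
#' @inheritParams sta_currents
#' @param k_pop,na_pop column names of the K+ and Na+ populations in
#'   `trace$currents`.
#' @return An object of class `cn_dominance`: `lags` (ms) and `fraction` in
#'   \[0, 1\].
#' @export
dominance_fraction <- function(trace, spikes, window = 10,
                               k_pop = "hh_k", na_pop = "hh_na") {
  stopifnot(inherits(trace, "cn_trace"),
            all(c(k_pop, na_pop) %in% colnames(trace$currents)))
  st <- .spike_times(spikes)
  st <- st[st > window + trace$t[1]]
  if (length(st) == 0) stop("no usable spikes")
  lags <- seq(0, window, by = trace$dt)
  rest <- .resting_current(trace, st)
  t0 <- trace$t[1]
  wins <- sapply(st, function(ts) {
    idx <- round((ts - lags - t0) / trace$dt) + 1L
    dk <- trace$currents[idx, k_pop] - rest[k_pop]
    dna <- trace$currents[idx, na_pop] - rest[na_pop]
    (-dk) > (-dna)
  })
  structure(list(lags = lags, fraction = rowMeans(wins),
                 n_events = length(st)), class = "cn_dominance")
}

#' Welch power spectral density estimate
#'
#' Averaged periodogram with Hann-windowed segments and 50% overlap, scaled
#' to the one-sided density convention in which the integral of the spectrum
#' over f >= 0 recovers the series variance (Parseval).  Each segment is
#' demeaned before windowing.
#'
#' @param series numeric series (any units `u`).
#' @param dt sample interval (ms).
#' @param segment_length samples per segment; should exceed ~10x the slowest
#'   time constant of interest over `dt`.
#' @param overlap fractional overlap between segments.
#' @return List of class `cn_psd` with `freqs` (Hz, excluding DC) and
#'   `power` (u^2/Hz).
#' @export
estimate_psd <- function(series, dt, segment_length = 8192, overlap = 0.5) {
  n <- length(series)
  L <- min(segment_length, n)
  if (n < 2 * segment_length)
    stop("series too short: need at least 2 segments of ", segment_length)
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))   # Hann
  wss <- sum(w^2)
  fs_hz <- 1000 / dt
  acc <- numeric(L %/% 2)
  for (s in starts) {
    seg <- series[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)
    acc <- acc + (Mod(X[2:(L %/% 2 + 1)])^2)
  }
  # one-sided density: 2 |X|^2 / (fs * sum w^2), averaged over segments
  power <- 2 * acc / (length(starts) * fs_hz * wss)
  freqs <- fs_hz * seq_len(L %/% 2) / L
  structure(list(freqs = freqs, power = power), class = "cn_psd")
}
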