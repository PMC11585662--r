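#' Robust rolling noise estimate of a voltage trace
#'
#' Estimates the noise standard deviation per rolling window as the median
#' absolute deviation divided by 0.6745 (the Gaussian consistency
#' constant), which is robust to the spikes riding on the noise. The
#' scalar returned is the median of the per-window estimates; the full
#' per-window profile is available via `attr(, "windows")`.
#'
#' @param trace a [voltage_trace].
#' @param window_s window length in seconds (default 1); the trace must be
#'   at least one window long and each window must hold >= 32 samples.
#' @return estimated noise SD in microvolts (scalar); attribute `"windows"`
#'   holds the per-window estimates.
#' @export
estimate_noise_sd <- function(trace, window_s = 1) {
  stopifnot(inherits(trace, "voltage_trace"), window_s > 0)
  w <- as.integer(floor(window_s * trace$sample_rate))
  if (w < 32L) stop("window must contain at least 32 samples")
  n <- length(trace$samples)
  if (n < w) stop("trace is shorter than one window")
  starts <- seq.int(1L, n - w + 1L, by = w)
  sig <- vapply(starts, function(s) {
    x <- trace$samples[s:(s + w - 1L)]
    stats::median(abs(x - stats::median(x))) / 0.6745
  }, numeric(1))
  structure(stats::median(sig), windows = sig)
}

#' Adaptive-threshold spike detection
#'
#' Detects spike events where the absolute voltage exceeds `k` times the
#' local noise SD (default `k = 6`, so a 2 uV noise floor gives a 12 uV
#' threshold). The noise SD is estimated per rolling window
#' ([estimate_noise_sd]) and the threshold applied locally, making the
#' detector adaptive to slow drifts in noise level. Both polarities are
#' detected; each contiguous supra-threshold excursion yields one event
#' timed at its absolute-extremum sample, and excursions closer than the
#' refractory interval (default 1 ms) are merged into one event.
#'
#' @param trace a [voltage_trace].
#' @param k threshold in noise SDs (default 6).
#' @param window_s noise-estimation window, seconds (default 1).
#' @param refractory_s merge interval, seconds (default 1e-3).
#' @return a [spike_train] on `[0, n_samples / sample_rate]`.
#' @export
detect_spikes <- function(trace, k = 6, window_s = 1, refractory_s = 1e-3) {
  stopifnot(inherits(trace, "voltage_trace"), k > 0, refractory_s >= 0)
  x <- trace$samples
  n <- length(x)
  fs <- trace$sample_rate
  t_stop <- n / fs
  w <- as.integer(floor(window_s * fs))
  if (n < w || w < 32L) {
    # short traces: single global estimate
    sigma_of <- function(i) rep(stats::median(abs(x - stats::median(x))) /
                                  0.6745, length(i))
  } else {
    sig <- attr(estimate_noise_sd(trace, window_s), "windows")
    sigma_of <- function(i) sig[pmin((i - 1L) %/% w + 1L, length(sig))]
  }
  thr <- k * sigma_of(seq_len(n))
  over <- abs(x) > thr
  if (!any(over))
    return(spike_train(numeric(0), 0, t_stop, trace$electrode_id))
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  exc <- which(r$values)
  ev_start <- starts[exc]; ev_end <- ends[exc]
  # merge excursions separated by less than the refractory interval
  gap_samples <- refractory_s * fs
  merged_s <- ev_start[1L]; merged_e <- ev_end[1L]
  if (length(exc) > 1L) {
    ms <- integer(0); me <- integer(0)
    cs <- ev_start[1L]; ce <- ev_end[1L]
    for (i in 2L:length(exc)) {
      if (ev_start[i] - ce < gap_samples) {
        ce <- ev_end[i]
      } else {
        ms <- c(ms, cs); me <- c(me, ce)
        cs <- ev_start[i]; ce <- ev_end[i]
      }
    }
    merged_s <- c(ms, cs); merged_e <- c(me, ce)
  }
  times <- mapply(function(s, e) {
    seg <- s:e
    (seg[which.max(abs(x[seg]))] - 1L) / fs
  }, merged_s, merged_e)
  spike_train(times, 0, t_stop, trace$electrode_id)
}

#' Synthesise a noisy trace with planted biphasic spikes
#'
#' Test helper for the detection stage: Gaussian noise plus biphasic
#' (negative-then-positive) spike waveforms of given peak amplitude at the
#' requested times.
#'
#' @param duration seconds.
#' @param sample_rate Hz.
#' @param noise_sd noise SD, microvolts.
#' @param spike_times event times, seconds.
#' @param amplitude peak amplitude, microvolts.
#' @param seed optional RNG seed.
#' @return a [voltage_trace]; attribute `"spike_times"` stores the planted
#'   times.
#' @export
synth_trace <- function(duration, sample_rate = 12500, noise_sd = 2,
                        spike_times = numeric(0), amplitude = 20,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration * sample_rate))
  x <- stats::rnorm(n, 0, noise_sd)
  if (length(spike_times)) {
    # biphasic waveform: 0.4 ms trough then 0.4 ms peak, raised-cosine lobes
    half <- as.integer(round(4e-4 * sample_rate))
    lobe <- sin(seq(0, pi, length.out = half))
    wave <- c(-lobe, lobe) * amplitude
    for (t0 in spike_times) {
      i0 <- as.integer(round(t0 * sample_rate)) + 1L
      idx <- i0:(i0 + length(wave) - 1L)
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + wave[ok]
    }
  }
  structure(voltage_trace(x, sample_rate, "synthetic"),
            spike_times = spike_times)
}
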