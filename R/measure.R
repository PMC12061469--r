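#' Measure the six call parameters of one call
#'
#' Computes the standard parameter set for a pulsatile advertisement call:
#' call duration, call interval (silent gap to the next call; `NA` for the
#' last call in a bout), dominant frequency (peak of the time-averaged
#' power spectrum over the call), 5-95% bandwidth (span between the 5% and
#' 95% cumulative spectral-energy quantiles, linearly interpolated between
#' bins), pulse number, and pulse rate computed as
#' `(pulse_number - 1) / (last onset - first onset)`.
#'
#' @param rec A [recording()].
#' @param bounds A [call_bounds()] with pulse onsets (see
#'   [detect_pulses()]); at least 2 onsets are required for pulse rate.
#' @param next_onset_s Onset time of the following call, or `NULL`/`NA`
#'   for the last call in a bout.
#' @param config A [spectrogram_config()].
#' @param interval_mode `"offset_to_onset"` (silent gap, default) or
#'   `"onset_to_onset"`.
#' @return A one-row data.frame with columns `call_duration_ms`,
#'   `call_interval_ms`, `dominant_frequency_hz`, `bandwidth_hz`,
#'   `pulse_number`, `pulse_rate_pps`, plus `snr_db` (used by
#'   [select_calls()]).
#' @export
measure_call <- function(rec, bounds, next_onset_s = NULL,
                         config = spectrogram_config(),
                         interval_mode = c("offset_to_onset",
                                           "onset_to_onset")) {
  interval_mode <- match.arg(interval_mode)
  fs <- rec$sample_rate
  np <- length(bounds$pulse_onsets_s)
  if (np < 2L) {
    stop("pulse rate undefined: call has fewer than 2 pulse onsets",
         call. = FALSE)
  }
  span <- bounds$pulse_onsets_s[np] - bounds$pulse_onsets_s[1L]
  pulse_rate <- (np - 1) / span

  i0 <- max(1L, as.integer(round(bounds$onset_s * fs)) + 1L)
  i1 <- min(length(rec$samples), as.integer(round(bounds$offset_s * fs)) + 1L)
  seg <- rec$samples[i0:i1]
  if (sum(seg^2) <= 0) stop("zero-energy call", call. = FALSE)
  sp <- avg_power_spectrum(seg, fs, config)
  dom <- sp$freq[which.max(sp$power)]
  bw <- energy_bandwidth(sp$freq, sp$power, lo = 0.05, hi = 0.95)

  interval <- NA_real_
  if (!is.null(next_onset_s) && length(next_onset_s) && is.finite(next_onset_s)) {
    interval <- if (interval_mode == "offset_to_onset") {
      (next_onset_s - bounds$offset_s) * 1000
    } else {
      (next_onset_s - bounds$onset_s) * 1000
    }
  }
  rms_call <- sqrt(mean(seg^2))
  data.frame(
    call_duration_ms = (bounds$offset_s - bounds$onset_s) * 1000,
    call_interval_ms = interval,
    dominant_frequency_hz = dom,
    bandwidth_hz = bw,
    pulse_number = np,
    pulse_rate_pps = pulse_rate,
    snr_db = 20 * log10(rms_call / max(noise_rms(rec), 1e-12))
  )
}

# time-averaged one-sided power spectrum over the call, at the configured
# window resolution; short calls fall back to a single zero-padded window
avg_power_spectrum <- function(seg, fs, config) {
  n <- config$window_samples
  w <- hann_window(n)
  nbin <- n %/% 2L + 1L
  if (length(seg) < n) {
    seg <- c(seg, rep(0, n - length(seg)))
  }
  starts <- seq(1L, length(seg) - n + 1L, by = config$hop_samples)
  acc <- numeric(nbin)
  for (s in starts) {
    sp <- stats::fft(seg[s:(s + n - 1L)] * w)[1:nbin]
    acc <- acc + Re(sp * Conj(sp))
  }
  list(freq = (0:(nbin - 1L)) * fs / n, power = acc / length(starts))
}

# frequency span between cumulative-energy quantiles, linear interpolation
energy_bandwidth <- function(freq, power, lo, hi) {
  cum <- cumsum(power)
  tot <- cum[length(cum)]
  if (tot <= 0) return(NA_real_)
  f_at <- function(q) {
    target <- q * tot
    i <- which(cum >= target)[1L]
    if (i == 1L) return(freq[1L])
    c0 <- cum[i - 1L]
    frac <- (target - c0) / (cum[i] - c0)
    freq[i - 1L] + frac * (freq[i] - freq[i - 1L])
  }
  f_at(hi) - f_at(lo)
}

noise_rms <- function(rec) {
  env <- amplitude_envelope(rec)
  stats::quantile(env, 0.1, names = FALSE)
}

#' Select the best consecutive calls of a bout
#'
#' Mirrors the field practice of measuring a fixed number of continuous,
#' high signal-to-noise calls: chooses the `k` consecutive calls whose
#' summed SNR is maximal. If fewer than `k` calls are available, all are
#' returned and the result is flagged.
#'
#' @param measurements Data.frame of per-call measurements in bout order
#'   (one row per call, with an `snr_db` column).
#' @param k Number of consecutive calls wanted (default 5).
#' @return The selected rows, with attribute `shortfall = TRUE` (plus a
#'   warning) when fewer than `k` calls were available.
#' @export
select_calls <- function(measurements, k = 5L) {
  stopifnot(k >= 1L)
  n <- nrow(measurements)
  if (is.null(n) || n == 0L) {
    warning("no calls to select")
    out <- measurements
    attr(out, "shortfall") <- TRUE
    return(out)
  }
  if (n <= k) {
    out <- measurements
    if (n < k) {
      warning(sprintf("only %d call(s) available, %d requested", n, k))
      attr(out, "shortfall") <- TRUE
    }
    return(out)
  }
  snr <- measurements$snr_db
  sums <- vapply(1:(n - k + 1L), function(s) sum(snr[s:(s + k - 1L)]),
                 numeric(1))
  s <- which.max(sums)
  measurements[s:(s + k - 1L), , drop = FALSE]
}

#' Measure all calls in a recording
#'
#' Full per-recording front end: high-pass filter, segment into calls,
#' detect pulses, measure each call, then keep the best `k` consecutive
#' calls. Calls in which pulse detection fails are dropped with a warning.
#'
#' @param rec A [recording()].
#' @param k Calls to keep per recording (default 5).
#' @param cutoff_hz High-pass cutoff (default 500 Hz).
#' @param config A [spectrogram_config()].
#' @param ... Passed to [segment_calls()].
#' @return Data.frame of measurements, one row per selected call, with
#'   `individual_id` and `call_index` columns prepended.
#' @export
measure_recording <- function(rec, k = 5L, cutoff_hz = 500,
                              config = spectrogram_config(), ...) {
  filt <- highpass_filter(rec, cutoff_hz)
  bounds <- segment_calls(filt, ...)
  if (!length(bounds)) {
    return(empty_measurement_frame())
  }
  rows <- list()
  for (i in seq_along(bounds)) {
    bi <- tryCatch(detect_pulses(filt, bounds[[i]]), error = function(e) NULL)
    if (is.null(bi) || length(bi$pulse_onsets_s) < 2L) {
      warning(sprintf("call %d dropped: pulse detection failed", i))
      next
    }
    nxt <- if (i < length(bounds)) bounds[[i + 1L]]$onset_s else NULL
    m <- tryCatch(measure_call(filt, bi, nxt, config),
                  error = function(e) NULL)
    if (!is.null(m)) {
      m$call_index <- i
      rows[[length(rows) + 1L]] <- m
    }
  }
  if (!length(rows)) return(empty_measurement_frame())
  out <- do.call(rbind, rows)
  out <- select_calls(out, k)
  out$individual_id <- rec$metadata$individual_id %||% NA_character_
  out[, c("individual_id", "call_index", measurement_columns(), "snr_db")]
}

measurement_columns <- function() {
  c("call_duration_ms", "call_interval_ms", "dominant_frequency_hz",
    "bandwidth_hz", "pulse_number", "pulse_rate_pps")
}

empty_measurement_frame <- function() {
  out <- data.frame(individual_id = character(0), call_index = integer(0),
                    call_duration_ms = numeric(0),
                    call_interval_ms = numeric(0),
                    dominant_frequency_hz = numeric(0),
                    bandwidth_hz = numeric(0), pulse_number = integer(0),
                    pulse_rate_pps = numeric(0), snr_db = numeric(0))
  out
}
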