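#' Smoothed RMS amplitude envelope
#'
#' Moving root-mean-square of the waveform over a short window (default
#' 2 ms), evaluated at every sample. This is the detection signal for both
#' call segmentation and pulse counting.
#'
#' @param rec A [recording()].
#' @param window_ms RMS window length in milliseconds.
#' @return Numeric vector, same length as the waveform.
#' @export
amplitude_envelope <- function(rec, window_ms = 2) {
  n <- max(3L, as.integer(round(rec$sample_rate * window_ms / 1000)))
  if (n %% 2L == 0L) n <- n + 1L
  sq <- rec$samples^2
  m <- as.numeric(stats::filter(sq, rep(1 / n, n), sides = 2L))
  # taper ends: reuse nearest interior value instead of NA
  first <- which(!is.na(m))[1L]
  last <- max(which(!is.na(m)))
  m[seq_len(first - 1L)] <- m[first]
  if (last < length(m)) m[(last + 1L):length(m)] <- m[last]
  sqrt(pmax(m, 0))
}

#' Bounds of one call
#'
#' @param onset_s,offset_s Call start/end in seconds from recording start.
#' @param pulse_onsets_s Optional ordered pulse-onset times (seconds),
#'   all inside `[onset_s, offset_s]`.
#' @return A `callvar_bounds` list.
#' @export
call_bounds <- function(onset_s, offset_s, pulse_onsets_s = numeric(0)) {
  stopifnot(onset_s < offset_s)
  if (length(pulse_onsets_s)) {
    stopifnot(all(diff(pulse_onsets_s) > 0),
              all(pulse_onsets_s >= onset_s - 1e-9),
              all(pulse_onsets_s <= offset_s + 1e-9))
  }
  structure(list(onset_s = onset_s, offset_s = offset_s,
                 pulse_onsets_s = pulse_onsets_s),
            class = "callvar_bounds")
}

#' Segment a recording into calls
#'
#' Energy-based segmentation standing in for manual selection: the RMS
#' envelope is compared against an adaptive threshold set a fixed number of
#' dB above the noise floor (estimated from the quietest fraction of
#' envelope samples), with hysteresis. Active stretches separated by less
#' than `min_gap_ms` are merged; stretches shorter than `min_call_ms` are
#' discarded as clicks.
#'
#' @param rec A (high-pass filtered) [recording()].
#' @param min_gap_ms Minimum silent gap separating two calls (default 50).
#' @param threshold_db_above_noise Onset threshold relative to the noise
#'   floor (default 10 dB); the offset (hysteresis) threshold is 4 dB lower.
#' @param min_call_ms Minimum call duration retained (default 20).
#' @param noise_quantile Fraction of quietest envelope samples defining the
#'   noise floor (default 0.1).
#' @return List of [call_bounds()] (empty for silence), sorted, without
#'   pulse onsets (see [detect_pulses()]).
#' @export
segment_calls <- function(rec, min_gap_ms = 50, threshold_db_above_noise = 10,
                          min_call_ms = 20, noise_quantile = 0.1) {
  env <- amplitude_envelope(rec)
  floor_rms <- stats::quantile(env, noise_quantile, names = FALSE)
  floor_rms <- max(floor_rms, 1e-12)
  thr_on <- floor_rms * 10^(threshold_db_above_noise / 20)
  thr_off <- floor_rms * 10^((threshold_db_above_noise - 4) / 20)
  segs <- hysteresis_runs(env, thr_on, thr_off)
  if (!nrow(segs)) return(list())
  fs <- rec$sample_rate
  min_gap <- min_gap_ms / 1000 * fs
  # merge runs separated by less than the minimum gap
  merged <- segs[1, , drop = FALSE]
  if (nrow(segs) > 1) {
    for (i in 2:nrow(segs)) {
      if (segs$start[i] - merged$end[nrow(merged)] < min_gap) {
        merged$end[nrow(merged)] <- segs$end[i]
      } else {
        merged <- rbind(merged, segs[i, ])
      }
    }
  }
  keep <- (merged$end - merged$start) >= min_call_ms / 1000 * fs
  merged <- merged[keep, , drop = FALSE]
  lapply(seq_len(nrow(merged)), function(i) {
    call_bounds((merged$start[i] - 1L) / fs, (merged$end[i] - 1L) / fs)
  })
}

# runs where x rises above thr_on, extended until it falls below thr_off
hysteresis_runs <- function(x, thr_on, thr_off) {
  above_on <- x >= thr_on
  above_off <- x >= thr_off
  n <- length(x)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (above_on[i]) {
      s <- i
      while (s > 1L && above_off[s - 1L]) s <- s - 1L
      e <- i
      while (e < n && above_off[e + 1L]) e <- e + 1L
      starts <- c(starts, s); ends <- c(ends, e)
      i <- e + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, end = ends)
}

#' Detect pulses within a call
#'
#' Pulses (amplitude-modulation bursts) are located as upward crossings of
#' the smoothed envelope through an adaptive per-call threshold at a fixed
#' fraction of the call's envelope peak, with hysteresis: after an onset
#' the detector re-arms only once the envelope has fallen below a lower
#' threshold, so noise jitter around the threshold cannot double-count a
#' pulse. Accepted onsets are additionally debounced at `debounce_ms`.
#'
#' @param rec A [recording()].
#' @param bounds A [call_bounds()] lying inside the recording.
#' @param threshold_fraction Pulse threshold as a fraction of the call's
#'   peak envelope (default 0.5).
#' @param rearm_fraction Re-arm threshold as a fraction of
#'   `threshold_fraction` (default 0.8, i.e. 40% of the peak).
#' @param debounce_ms Minimum spacing between accepted onsets (default 3).
#' @return `bounds` with `pulse_onsets_s` filled (strictly increasing,
#'   length >= 1).
#' @export
detect_pulses <- function(rec, bounds, threshold_fraction = 0.5,
                          rearm_fraction = 0.8, debounce_ms = 3) {
  fs <- rec$sample_rate
  i0 <- max(1L, as.integer(round(bounds$onset_s * fs)) + 1L)
  i1 <- min(length(rec$samples), as.integer(round(bounds$offset_s * fs)) + 1L)
  stopifnot(i1 > i0)
  sub <- recording_slice(rec, i0, i1)
  env <- amplitude_envelope(sub)
  thr <- threshold_fraction * max(env)
  thr_lo <- rearm_fraction * thr
  if (!is.finite(thr) || thr <= 0) {
    stop("no envelope energy above threshold in call", call. = FALSE)
  }
  up <- which(env[-1L] >= thr & env[-length(env)] < thr) + 1L
  if (length(env) && env[1L] >= thr) up <- c(1L, up)  # call starts hot
  if (!length(up)) stop("no pulse onset found in call", call. = FALSE)
  debounce <- debounce_ms / 1000 * fs
  # hysteresis + sequential debounce: accept a crossing only if the
  # envelope dipped below the re-arm level since the last accepted onset
  # and the spacing exceeds the debounce interval
  kept <- up[1L]
  for (u in up[-1L]) {
    last <- kept[length(kept)]
    if (u - last < debounce) next
    if (min(env[last:u]) >= thr_lo) next
    kept <- c(kept, u)
  }
  onsets <- (i0 - 1L + kept - 1L) / fs
  call_bounds(bounds$onset_s, bounds$offset_s, onsets)
}

recording_slice <- function(rec, i0, i1) {
  x <- rec$samples[i0:i1]
  if (length(x) < 512L) x <- c(x, rep(0, 512L - length(x)))
  recording(x, rec$sample_rate, rec$metadata)
}
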