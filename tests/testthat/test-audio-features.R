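fs <- 44100L

tone <- function(freq, dur_s = 0.5, fs. = fs, amp = 0.5) {
  recording(amp * sin(2 * pi * freq * (0:(dur_s * fs. - 1)) / fs.), fs.)
}

test_that("high-pass filter attenuates the stop band and passes the pass band", {
  low <- highpass_filter(tone(100), cutoff_hz = 500)
  expect_lt(sqrt(mean(low$samples^2)), 0.1 * sqrt(mean(tone(100)$samples^2)))

  high <- highpass_filter(tone(3000), cutoff_hz = 500)
  expect_equal(sqrt(mean(high$samples^2)),
               sqrt(mean(tone(3000)$samples^2)), tolerance = 0.05)

  # >= 24 dB one octave below cutoff
  oct <- highpass_filter(tone(250), cutoff_hz = 500)
  atten_db <- 20 * log10(sqrt(mean(oct$samples^2)) /
                           sqrt(mean(tone(250)$samples^2)))
  expect_lt(atten_db, -24)

  zero <- highpass_filter(recording(numeric(1000), fs), cutoff_hz = 500)
  expect_equal(zero$samples, numeric(1000))
  expect_length(low$samples, length(tone(100)$samples))
  expect_error(highpass_filter(tone(100), cutoff_hz = fs), "Nyquist")
})

test_that("spectrogram localises tones at their DFT bins", {
  cfg <- spectrogram_config()
  f20 <- 20 * fs / 512
  sp <- compute_spectrogram(tone(f20), cfg)
  expect_equal(sp$freq_hz[2] - sp$freq_hz[1], fs / 512)
  expect_true(all(sp$power >= 0))
  argmax <- apply(sp$power, 2, which.max)
  expect_true(all(argmax == 21))  # bin 20, 1-based index 21

  silence <- compute_spectrogram(recording(numeric(4096), fs), cfg)
  expect_true(all(silence$power < 1e-20))

  # two equal tones at bins 10 and 30: local maxima at both, matching a
  # direct DFT oracle on one frame
  x <- 0.4 * sin(2 * pi * (10 * fs / 512) * (0:8191) / fs) +
    0.4 * sin(2 * pi * (30 * fs / 512) * (0:8191) / fs)
  sp2 <- compute_spectrogram(recording(x, fs), cfg)
  col <- sp2$power[, 3]
  for (bin in c(11, 31)) {
    expect_gt(col[bin], col[bin - 1]); expect_gt(col[bin], col[bin + 1])
  }
  frame <- x[(2 * 256 + 1):(2 * 256 + 512)]
  expect_equal(col[11], oracle_dft_power(frame, 10), tolerance = 1e-8)
  expect_equal(col[31], oracle_dft_power(frame, 30), tolerance = 1e-8)

  expect_error(compute_spectrogram(recording(numeric(600), fs),
                                   spectrogram_config(window_samples = 1024)),
               "shorter")
})

test_that("spectrogram energy is hop-invariant for stationary signals", {
  set.seed(42)
  rec <- recording(rnorm(fs / 2, sd = 0.1), fs)
  e_half <- spectrogram_energy(
    compute_spectrogram(rec, spectrogram_config(overlap_fraction = 0.5)))
  e_three_q <- spectrogram_energy(
    compute_spectrogram(rec, spectrogram_config(overlap_fraction = 0.75)))
  expect_equal(e_half, e_three_q, tolerance = 0.01)
  expect_equal(e_half, sum(rec$samples^2), tolerance = 0.02)
})

test_that("segmentation finds synthetic calls and obeys the gap rule", {
  # silence -> nothing
  set.seed(1)
  noise <- recording(rnorm(fs, sd = 1e-3), fs)
  expect_length(segment_calls(noise), 0)

  spec <- call_spec(call_duration_ms = 215, pulse_number = 14,
                    pulse_rate_pps = 64.1)
  sr <- synthesize_recording(spec, n_calls = 2, call_intervals_ms = 272,
                             seed = 7)
  rec <- highpass_filter(sr$recording)
  b <- segment_calls(rec)
  expect_length(b, 2)
  for (i in 1:2) {
    expect_lt(abs(b[[i]]$onset_s - sr$truth[[i]]$onset_s), 0.005)
  }
  expect_true(b[[2]]$onset_s > b[[1]]$offset_s)

  # a 10 ms dip inside one call is bridged when min_gap_ms = 50
  x <- sr$recording$samples
  i0 <- round((sr$truth[[1]]$onset_s + 0.1) * fs)
  x[i0:(i0 + round(0.010 * fs))] <- 0
  b2 <- segment_calls(highpass_filter(recording(x, fs)))
  expect_length(b2, 2)
})

test_that("pulse detection recovers count and onset span", {
  spec <- call_spec(pulse_number = 14, pulse_rate_pps = 64.04,
                    call_duration_ms = 215.1)
  sr <- synthesize_recording(spec, n_calls = 1, noise_floor_db = -45,
                             seed = 11)  # ~30 dB SNR
  rec <- highpass_filter(sr$recording)
  b <- segment_calls(rec)
  expect_length(b, 1)
  bp <- detect_pulses(rec, b[[1]])
  expect_length(bp$pulse_onsets_s, 14)
  expect_true(all(diff(bp$pulse_onsets_s) > 0))
  span_true <- 13 / 64.04  # 0.203 s
  span_det <- diff(range(bp$pulse_onsets_s))
  expect_lt(abs(span_det - span_true), 0.003)

  # unmodulated burst -> a single onset
  burst <- recording(c(numeric(4410),
                       sin(2 * pi * 3000 * (0:8819) / fs) *
                         c(seq(0, 1, length.out = 441), rep(1, 7938),
                           seq(1, 0, length.out = 441)),
                       numeric(4410)), fs)
  bb <- call_bounds(0.1, 0.3)
  expect_length(detect_pulses(burst, bb)$pulse_onsets_s, 1)
})

test_that("measure_call implements the printed parameter definitions", {
  # pulse rate straight from the (n-1)/span formula
  sr <- synthesize_recording(call_spec(), n_calls = 2, seed = 5)
  rec <- highpass_filter(sr$recording)
  onsets <- seq(0, by = 0.203 / 13, length.out = 14) + sr$truth[[1]]$onset_s
  b <- call_bounds(sr$truth[[1]]$onset_s, sr$truth[[1]]$offset_s, onsets)
  m <- measure_call(rec, b, next_onset_s = sr$truth[[2]]$onset_s)
  expect_equal(m$pulse_rate_pps, 13 / 0.203, tolerance = 1e-12)
  expect_equal(m$pulse_number, 14)
  expect_equal(m$call_duration_ms,
               (sr$truth[[1]]$offset_s - sr$truth[[1]]$onset_s) * 1000)
  expect_equal(m$call_interval_ms,
               (sr$truth[[2]]$onset_s - sr$truth[[1]]$offset_s) * 1000)
  expect_lt(abs(m$dominant_frequency_hz - 3416), fs / 512)

  # last call of the bout: interval is NA
  m2 <- measure_call(rec, b, next_onset_s = NULL)
  expect_true(is.na(m2$call_interval_ms))

  expect_error(measure_call(rec, call_bounds(b$onset_s, b$offset_s,
                                             onsets[1]), NULL),
               "fewer than 2")
})

test_that("bandwidth is the 5-95% cumulative-energy span", {
  # flat band-limited noise on [2000, 4000]: expect ~0.9 * 2000 Hz
  set.seed(9)
  n <- 2^16
  f <- (0:(n - 1)) * (fs / n)
  band <- f >= 2000 & f <= 4000
  phases <- runif(sum(band), 0, 2 * pi)
  spec_full <- complex(n)
  spec_full[band] <- exp(1i * phases)
  spec_full[n - which(band) + 2] <- Conj(spec_full[which(band)])
  x <- Re(fft(spec_full, inverse = TRUE)) / n
  x <- x / max(abs(x)) * 0.8
  rec <- recording(x, fs)
  b <- call_bounds(0, (n - 1) / fs, c(0.01, 0.02))
  m <- measure_call(rec, b, NULL)
  expect_lt(abs(m$bandwidth_hz - 1800), fs / 512)

  # pure tone: bandwidth no wider than 3 bins
  tb <- call_bounds(0, 0.49, c(0.01, 0.02))
  mt <- measure_call(tone(3416), tb, NULL)
  expect_lte(mt$bandwidth_hz, 3 * fs / 512)
})

test_that("measurements are invariant to amplitude scaling", {
  sr <- synthesize_recording(call_spec(), n_calls = 1, noise_floor_db = -200,
                             seed = 2)
  rec <- sr$recording
  rec2 <- recording(rec$samples * 0.31, fs)
  b <- sr$truth[[1]]
  bp1 <- detect_pulses(rec, b); bp2 <- detect_pulses(rec2, b)
  m1 <- measure_call(rec, bp1, NULL); m2 <- measure_call(rec2, bp2, NULL)
  cols <- c("call_duration_ms", "dominant_frequency_hz", "bandwidth_hz",
            "pulse_number", "pulse_rate_pps")
  expect_equal(m1[, cols], m2[, cols], tolerance = 1e-10)
})

test_that("select_calls picks the best consecutive window", {
  df <- data.frame(call_index = 1:8, snr_db = c(5, 6, 20, 21, 22, 23, 24, 4))
  sel <- select_calls(df, 5)
  expect_equal(sel$call_index, 3:7)  # exhaustive window scan agrees
  sums <- sapply(1:4, function(s) sum(df$snr_db[s:(s + 4)]))
  expect_equal(which.max(sums), 3L)

  expect_identical(select_calls(df[1:5, ], 5), df[1:5, ])
  expect_warning(short <- select_calls(df[1:3, ], 5), "3 call")
  expect_equal(nrow(short), 3)
  expect_true(attr(short, "shortfall"))
})

test_that("full round trip meets the stated tolerances across specs", {
  set.seed(123)
  for (i in 1:5) {
    f <- runif(1, 2600, 4200)
    np <- sample(11:18, 1)
    rate <- runif(1, 45, 75)
    dur <- ((np - 1) / rate + 0.7 / rate) * 1000
    spec <- call_spec(f, np, rate, dur)
    sr <- synthesize_recording(spec, n_calls = 1, noise_floor_db = -45,
                               seed = i)
    rec <- highpass_filter(sr$recording)
    b <- segment_calls(rec)
    expect_length(b, 1)
    bp <- detect_pulses(rec, b[[1]])
    m <- measure_call(rec, bp, NULL)
    expect_equal(m$pulse_number, np)
    expect_lt(abs(m$call_duration_ms - dur), 10)
    expect_lt(abs(m$dominant_frequency_hz - f), fs / 512)
    expect_lt(abs(m$pulse_rate_pps - rate) / rate, 0.05)
  }
})

test_that("WAV files round-trip through the reader and writer", {
  sr <- synthesize_recording(call_spec(), n_calls = 1, seed = 4)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(sr$recording, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 44100L)
  expect_lt(max(abs(back$samples - pmax(-1, pmin(1, sr$recording$samples)))),
            1e-4)  # PCM-16 quantisation step
})
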