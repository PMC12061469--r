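#' Specification of one synthetic advertisement call
#'
#' Defaults are the study grand means: a 3416 Hz carrier, 14 pulses at
#' 64.1 pulses/s, 215.1 ms call duration. Pulse onsets are placed at
#' `i / pulse_rate`; the onset span `(pulse_number - 1) / pulse_rate` must
#' fit inside the call duration.
#'
#' @param dominant_frequency_hz Carrier frequency (Hz).
#' @param pulse_number Number of pulses (>= 1).
#' @param pulse_rate_pps Pulse rate, pulses per second.
#' @param call_duration_ms Call duration, ms.
#' @param pulse_shape Envelope of each pulse; `"raised_cosine"` only.
#' @param amplitude Peak amplitude in `(0, 1]`.
#' @return A `callvar_callspec` list.
#' @export
call_spec <- function(dominant_frequency_hz = 3416, pulse_number = 14L,
                      pulse_rate_pps = 64.1, call_duration_ms = 215.1,
                      pulse_shape = "raised_cosine", amplitude = 0.9) {
  pulse_shape <- match.arg(pulse_shape, "raised_cosine")
  stopifnot(dominant_frequency_hz > 0, pulse_number >= 1L,
            pulse_rate_pps > 0, call_duration_ms > 0,
            amplitude > 0, amplitude <= 1)
  span_s <- (pulse_number - 1) / pulse_rate_pps
  if (span_s > call_duration_ms / 1000 + 1e-12) {
    stop("pulse-onset span exceeds call duration", call. = FALSE)
  }
  structure(list(dominant_frequency_hz = dominant_frequency_hz,
                 pulse_number = as.integer(pulse_number),
                 pulse_rate_pps = pulse_rate_pps,
                 call_duration_ms = call_duration_ms,
                 pulse_shape = pulse_shape, amplitude = amplitude),
            class = "callvar_callspec")
}

#' Synthesise one pulsatile call
#'
#' A pulse train of raised-cosine-enveloped carrier bursts. Pulse `i`
#' (0-based) starts at `i / pulse_rate` seconds; each burst lasts
#' `min(call_duration - onset_span, 0.9 / pulse_rate)` so consecutive
#' envelopes are separated by a silent gap. Ground truth (call bounds and
#' exact pulse onsets) is returned with the waveform.
#'
#' @param spec A [call_spec()].
#' @param sample_rate Sampling rate (Hz); carrier must be below Nyquist.
#' @return List: `samples` (numeric vector covering exactly the call
#'   duration) and `truth` (a [call_bounds()] relative to the call start).
#' @export
synthesize_call <- function(spec, sample_rate = 44100L) {
  stopifnot(inherits(spec, "callvar_callspec"))
  if (spec$dominant_frequency_hz >= sample_rate / 2) {
    stop("carrier frequency at or above Nyquist", call. = FALSE)
  }
  fs <- sample_rate
  dur_s <- spec$call_duration_ms / 1000
  n <- as.integer(round(dur_s * fs))
  x <- numeric(n)
  onsets <- (seq_len(spec$pulse_number) - 1L) / spec$pulse_rate_pps
  span <- onsets[length(onsets)]
  width <- min(dur_s - span, 0.9 / spec$pulse_rate_pps)
  if (spec$pulse_number == 1L) width <- min(dur_s, width)
  wn <- max(8L, as.integer(round(width * fs)))
  env <- 0.5 - 0.5 * cos(2 * pi * (0:(wn - 1L)) / (wn - 1L))  # raised cosine
  for (on in onsets) {
    i0 <- as.integer(round(on * fs)) + 1L
    idx <- i0:min(n, i0 + wn - 1L)
    tt <- (idx - 1L) / fs
    x[idx] <- x[idx] + spec$amplitude * env[seq_along(idx)] *
      sin(2 * pi * spec$dominant_frequency_hz * tt)
  }
  list(samples = x, truth = call_bounds(0, dur_s, onsets))
}

#' Synthesise a bout of calls with additive noise
#'
#' Places calls separated by the given silent gaps (offset-to-onset,
#' default the study mean interval), embeds them in white Gaussian noise
#' at a fixed noise floor, and returns the ground-truth bounds of every
#' call in recording time.
#'
#' @param specs List of [call_spec()] (or a single spec, recycled).
#' @param n_calls Number of calls when a single spec is given (default 5).
#' @param call_intervals_ms Silent gaps between consecutive calls
#'   (length `length(specs) - 1`, recycled from a scalar; default 272.7).
#' @param noise_floor_db Noise RMS in dB relative to full scale
#'   (default -50).
#' @param lead_s Leading/trailing noise-only padding, seconds.
#' @param sample_rate Sampling rate (Hz).
#' @param seed Integer seed (noise reproducibility).
#' @param metadata Metadata list for the returned [recording()].
#' @return List: `recording` and `truth` (list of [call_bounds()] in
#'   recording time).
#' @export
synthesize_recording <- function(specs, n_calls = 5L,
                                 call_intervals_ms = 272.7,
                                 noise_floor_db = -50, lead_s = 0.3,
                                 sample_rate = 44100L, seed = 1L,
                                 metadata = list()) {
  if (inherits(specs, "callvar_callspec")) {
    specs <- rep(list(specs), n_calls)
  }
  k <- length(specs)
  if (k == 0L) stop("need at least one call spec", call. = FALSE)
  gaps <- if (k > 1L) rep_len(call_intervals_ms, k - 1L) / 1000 else numeric(0)
  if (any(gaps < 0)) stop("negative call interval", call. = FALSE)
  calls <- lapply(specs, synthesize_call, sample_rate = sample_rate)
  durs <- vapply(specs, function(s) s$call_duration_ms / 1000, numeric(1))
  onsets <- lead_s + cumsum(c(0, durs[-k] + gaps))
  total_s <- lead_s * 2 + sum(durs) + sum(gaps)
  n <- as.integer(ceiling(total_s * sample_rate))
  set.seed(seed)
  x <- stats::rnorm(n, sd = 10^(noise_floor_db / 20))
  truth <- vector("list", k)
  for (i in seq_len(k)) {
    i0 <- as.integer(round(onsets[i] * sample_rate)) + 1L
    seg <- calls[[i]]$samples
    idx <- i0:min(n, i0 + length(seg) - 1L)
    x[idx] <- x[idx] + seg[seq_along(idx)]
    tr <- calls[[i]]$truth
    truth[[i]] <- call_bounds(onsets[i], onsets[i] + durs[i],
                              tr$pulse_onsets_s + onsets[i])
  }
  list(recording = recording(x, sample_rate, metadata), truth = truth)
}

#' Default per-parameter generator configuration
#'
#' Variance components derived from the published multi-level CVs: the
#' within-individual SD from the mean CV_i, the among-individual
#' (within-locality) SD from the mean CV_p, and the among-locality SD from
#' `sqrt(CV_g^2 - CV_p^2)` (clamped at 0 when CV_p exceeds CV_g, as the
#' published bandwidth values do). Group means are the published NE/SW
#' values. Temperature slopes default to 0 (the study reports none).
#'
#' @return Data.frame: `parameter`, `mean_ne`, `mean_sw`, `sd_locality`,
#'   `sd_individual`, `sd_within`, `slope_b`, `exempt`.
#' @export
default_parameter_config <- function() {
  s <- study_call_statistics()
  data.frame(
    parameter = s$parameter,
    mean_ne = s$mean_ne,
    mean_sw = s$mean_sw,
    sd_locality = s$mean *
      sqrt(pmax(0, (s$cv_g_mean / 100)^2 - (s$cv_p_mean / 100)^2)),
    sd_individual = s$mean * s$cv_p_mean / 100,
    sd_within = s$mean * s$cv_i_mean / 100,
    slope_b = 0,
    exempt = s$parameter == "pulse_number"
  )
}

#' Generator configuration for hierarchical measurement tables
#'
#' @param localities Locality design table (columns as in
#'   [study_localities()]); default the study design (9 localities, two
#'   groups, 33 males).
#' @param parameters Per-parameter config as in
#'   [default_parameter_config()].
#' @param calls_per_individual Calls recorded per male (default 5).
#' @param reference_temperature_c Temperature the slope effects are
#'   centred on; default the count-weighted locality mean.
#' @param distribution `"gaussian"` (additive effects, default) or
#'   `"lognormal"` (multiplicative, for strictly positive parameters).
#' @param seed Integer seed.
#' @return A `callvar_popconfig` list.
#' @export
population_config <- function(localities = study_localities(),
                              parameters = default_parameter_config(),
                              calls_per_individual = 5L,
                              reference_temperature_c = NULL,
                              distribution = c("gaussian", "lognormal"),
                              seed = 1L) {
  distribution <- match.arg(distribution)
  stopifnot(all(c("group", "locality", "temperature_c", "n_males") %in%
                  names(localities)),
            all(c("parameter", "mean_ne", "mean_sw", "sd_locality",
                  "sd_individual", "sd_within", "slope_b") %in%
                  names(parameters)),
            calls_per_individual >= 2L,
            all(parameters$sd_locality >= 0),
            all(parameters$sd_individual >= 0),
            all(parameters$sd_within >= 0))
  if (is.null(reference_temperature_c)) {
    reference_temperature_c <- reference_temperature(localities)
  }
  structure(list(localities = localities, parameters = parameters,
                 calls_per_individual = as.integer(calls_per_individual),
                 reference_temperature_c = reference_temperature_c,
                 distribution = distribution, seed = as.integer(seed)),
            class = "callvar_popconfig")
}

#' Generate a hierarchical call-parameter table with known truth
#'
#' Each value is
#' `group_mean + locality_effect + individual_effect +
#'  b * (T_locality - T_ref) + within_noise`,
#' with all effects Gaussian at the configured SDs (or their
#' multiplicative log-normal analogue). The drawn effects are returned so
#' recovery tests can compare estimates against the exact truth.
#'
#' @param config A [population_config()].
#' @return List: `table` (long measurement table with `individual_id`,
#'   `locality`, `group`, `parameter`, `call_index`, `value`),
#'   `individuals` (metadata: locality, group, temperature, coordinates),
#'   and `truth` (per-parameter locality and individual effects).
#' @export
generate_parameter_table <- function(config) {
  stopifnot(inherits(config, "callvar_popconfig"))
  set.seed(config$seed)
  loc <- config$localities
  pars <- config$parameters
  ids <- unlist(lapply(seq_len(nrow(loc)), function(i) {
    sprintf("%s_%02d", loc$locality[i], seq_len(loc$n_males[i]))
  }))
  ind <- data.frame(
    individual_id = ids,
    locality = rep(loc$locality, loc$n_males),
    group = rep(loc$group, loc$n_males),
    temperature_c = rep(loc$temperature_c, loc$n_males),
    latitude = rep(loc$latitude %||% NA_real_, loc$n_males),
    longitude = rep(loc$longitude %||% NA_real_, loc$n_males)
  )
  nc <- config$calls_per_individual
  tref <- config$reference_temperature_c
  tables <- list(); truth <- list()
  for (r in seq_len(nrow(pars))) {
    p <- pars[r, ]
    gmean <- ifelse(ind$group == "SW", p$mean_sw, p$mean_ne)
    loc_eff <- stats::rnorm(nrow(loc), 0, p$sd_locality)
    names(loc_eff) <- loc$locality
    ind_eff <- stats::rnorm(nrow(ind), 0, p$sd_individual)
    base <- gmean + loc_eff[ind$locality] + ind_eff +
      p$slope_b * (ind$temperature_c - tref)
    vals <- rep(base, each = nc) +
      stats::rnorm(nrow(ind) * nc, 0, p$sd_within)
    if (config$distribution == "lognormal") {
      # multiplicative analogue: relative effects on the log scale
      m <- mean(c(p$mean_ne, p$mean_sw))
      base_ln <- log(gmean) + (loc_eff[ind$locality] + ind_eff) / m +
        p$slope_b * (ind$temperature_c - tref) / m
      vals <- exp(rep(base_ln, each = nc) +
                    stats::rnorm(nrow(ind) * nc, 0, p$sd_within / m))
    }
    tables[[p$parameter]] <- data.frame(
      individual_id = rep(ind$individual_id, each = nc),
      locality = rep(ind$locality, each = nc),
      group = rep(ind$group, each = nc),
      parameter = p$parameter,
      call_index = rep(seq_len(nc), times = nrow(ind)),
      value = vals
    )
    truth[[p$parameter]] <- list(locality_effects = loc_eff,
                                 individual_effects =
                                   stats::setNames(ind_eff,
                                                   ind$individual_id))
  }
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  list(table = out, individuals = ind, truth = truth)
}

#' Collapse a long measurement table to per-individual means
#'
#' @param table Long measurement table.
#' @param individuals Individual metadata (from
#'   [generate_parameter_table()] or a metadata CSV) used to attach
#'   temperatures/coordinates; optional.
#' @return Data.frame with one row per individual x parameter.
#' @export
individual_means_table <- function(table, individuals = NULL) {
  agg <- stats::aggregate(value ~ individual_id + locality + group +
                            parameter, data = table, FUN = mean,
                          na.rm = TRUE, na.action = stats::na.pass)
  if (!is.null(individuals)) {
    keep <- intersect(c("individual_id", "temperature_c", "latitude",
                        "longitude"), names(individuals))
    agg <- merge(agg, individuals[, keep, drop = FALSE],
                 by = "individual_id", sort = FALSE)
  }
  agg[order(agg$parameter, agg$individual_id), ]
}
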