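#' Construct a recording object
#'
#' A `callvar_recording` bundles a mono waveform with its sample rate and
#' the field metadata attached to the recorded male (individual ID,
#' locality, geographic group, air temperature, coordinates).
#'
#' @param samples Numeric vector of amplitudes, nominally in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (positive integer).
#' @param metadata Named list; recognised fields are `individual_id`,
#'   `locality`, `group`, `temperature_c`, `latitude`, `longitude`,
#'   `date`. Missing fields are allowed for purely acoustic work.
#' @return An object of class `callvar_recording`.
#' @export
recording <- function(samples, sample_rate, metadata = list()) {
  samples <- as.numeric(samples)
  if (length(samples) < 512L) {
    stop("recording must contain at least 512 samples", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be a single positive number", call. = FALSE)
  }
  if (!is.list(metadata)) stop("metadata must be a list", call. = FALSE)
  if (!is.null(metadata$temperature_c) && !is.finite(metadata$temperature_c)) {
    stop("metadata temperature_c must be finite", call. = FALSE)
  }
  if (!is.null(metadata$latitude) &&
      (metadata$latitude < -90 || metadata$latitude > 90)) {
    stop("latitude must lie in [-90, 90]", call. = FALSE)
  }
  if (!is.null(metadata$longitude) &&
      (metadata$longitude < -180 || metadata$longitude > 180)) {
    stop("longitude must lie in [-180, 180]", call. = FALSE)
  }
  structure(
    list(samples = samples, sample_rate = as.integer(round(sample_rate)),
         metadata = metadata),
    class = "callvar_recording"
  )
}

#' @export
print.callvar_recording <- function(x, ...) {
  cat(sprintf("<callvar_recording> %d samples @ %d Hz (%.2f s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  if (!is.null(x$metadata$individual_id)) {
    cat("  individual:", x$metadata$individual_id,
        " locality:", x$metadata$locality %||% "?", "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nyquist <- function(rec) rec$sample_rate / 2

#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader covering PCM 16/24-bit and IEEE float-32, the
#' formats field recorders produce. Stereo files are collapsed to the first
#' channel with a warning.
#'
#' @param path Path to a `.wav` file.
#' @param metadata Optional metadata list forwarded to [recording()].
#' @return A `callvar_recording`.
#' @export
read_wav <- function(path, metadata = list()) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      blob <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(blob[1:2], "integer", 1, 2, endian = "little"),
        n_channels   = readBin(blob[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(blob[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(blob[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  }
  n_bytes <- fmt$bits %/% 8L
  n_frames <- length(data_raw) %/% (n_bytes * fmt$n_channels)
  if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", n_frames * fmt$n_channels, 4,
                 endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n_frames * fmt$n_channels, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    b <- as.integer(data_raw)
    i1 <- seq(1L, length(b) - 2L, by = 3L)
    v <- b[i1] + 256L * b[i1 + 1L] + 65536L * b[i1 + 2L]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else {
    stop(sprintf("unsupported WAV format (fmt %d, %d-bit)",
                 fmt$audio_format, fmt$bits), call. = FALSE)
  }
  if (fmt$n_channels > 1L) {
    warning("multi-channel WAV: keeping channel 1 only")
    x <- x[seq(1L, length(x), by = fmt$n_channels)]
  }
  recording(x, fmt$sample_rate, metadata)
}

#' Write a recording to a mono PCM-16 WAV file
#'
#' @param rec A `callvar_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "callvar_recording"))
  x <- pmax(-1, pmin(1, rec$samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")            # PCM
  writeBin(1L, con, 2, endian = "little")            # mono
  writeBin(rec$sample_rate, con, 4, endian = "little")
  writeBin(rec$sample_rate * 2L, con, 4, endian = "little")  # byte rate
  writeBin(2L, con, 2, endian = "little")            # block align
  writeBin(16L, con, 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
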