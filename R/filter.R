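#' High-pass filter a recording
#'
#' Applies a Butterworth high-pass (default 4th order) via the bilinear
#' transform, replacing the interactive low-band noise reduction used when
#' recordings are cleaned by hand. The default 500 Hz cutoff sits below the
#' lowest call energy of interest, so call spectra pass unchanged while
#' wind/handling rumble is attenuated at 24 dB per octave.
#'
#' @param rec A [recording()].
#' @param cutoff_hz Cutoff frequency in Hz; must lie in `(0, Nyquist)`.
#' @param order Filter order (even; default 4).
#' @return A filtered `callvar_recording` of identical length and rate.
#' @export
highpass_filter <- function(rec, cutoff_hz = 500, order = 4L) {
  stopifnot(inherits(rec, "callvar_recording"))
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyquist(rec)) {
    stop("cutoff_hz must lie strictly between 0 and the Nyquist frequency",
         call. = FALSE)
  }
  ba <- butter_highpass(order, cutoff_hz, rec$sample_rate)
  y <- iir_filter(ba$b, ba$a, rec$samples)
  out <- rec
  out$samples <- y
  out
}

# Butterworth high-pass coefficients by pole placement + bilinear transform.
# Prototype low-pass poles on the unit circle are mapped LP->HP (p -> wc/p),
# then to the z-plane; gain is normalised to unity at Nyquist (z = -1).
butter_highpass <- function(order, cutoff_hz, sample_rate) {
  n <- as.integer(order)
  stopifnot(n >= 1L)
  fs2 <- 2 * sample_rate
  wc <- fs2 * tan(pi * cutoff_hz / sample_rate)  # prewarped analog cutoff
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # left-half-plane poles
  p_hp <- wc / p_lp
  z_pole <- (fs2 + p_hp) / (fs2 - p_hp)
  a <- Re(poly_from_roots(z_pole))
  b <- poly_from_roots(rep(1 + 0i, n))  # n zeros at z = 1
  b <- Re(b)
  # unity gain at Nyquist: H(-1) = sum(b * (-1)^k) / sum(a * (-1)^k)
  sgn <- (-1)^(0:n)
  gain <- sum(a * sgn) / sum(b * sgn)
  list(b = b * gain, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Direct-form IIR: convolution (MA) then recursion (AR), both vectorised
# through stats::filter. Zero initial conditions.
iir_filter <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1L), x)
  ma <- stats::filter(xp, b, method = "convolution", sides = 1L)
  ma <- as.numeric(ma)[nb:length(xp)]
  y <- stats::filter(ma, -a[-1L] / a[1L], method = "recursive")
  as.numeric(y) / a[1L]
}
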