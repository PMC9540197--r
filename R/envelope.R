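#' Nonnegative amplitude-envelope series
#'
#' Container for an amplitude envelope with an explicit sampling rate.
#' Values must be nonnegative up to a small numerical tolerance (zero-phase
#' filters and polyphase resampling can ring slightly below zero); such
#' dips are clipped to exactly zero.
#'
#' @param values Numeric vector, finite, `>= -1e-9 * max(|values|)`.
#' @param rate Sampling rate in Hz, > 0.
#' @return An object of class `envelope_series` with elements `values`
#'   and `rate`.
#' @export
envelope_series <- function(values, rate) {
  stopifnot(is.numeric(values), length(values) > 0L,
            is.numeric(rate), length(rate) == 1L, rate > 0)
  if (!all(is.finite(values))) stop("envelope values must be finite")
  tol <- 1e-9 * max(abs(values), 1e-300)
  if (any(values < -tol)) {
    stop("envelope values must be nonnegative (beyond numerical tolerance)")
  }
  structure(list(values = pmax(as.double(values), 0), rate = as.double(rate)),
            class = "envelope_series")
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series> %d samples @ %g Hz, mean %.4g\n",
              length(x$values), x$rate, mean(x$values)))
  invisible(x)
}

#' Broadband cochlear speech envelope
#'
#' Extracts the acoustic speech envelope with a cochlear-map filterbank:
#' nine frequency bands spanning 100--10,000 Hz equidistant in Greenwood
#' position, zero-phase (forward and reverse) 4th-order Butterworth
#' band-pass filtering, per-band envelopes as absolute values of the
#' Hilbert transform, and an unweighted average across bands. This is the
#' full-band envelope used for envelope-brain coherence.
#'
#' @param audio An [audio_signal]; rate must exceed `2 * fmax` (20 kHz for
#'   the default top edge) so the top band is below Nyquist.
#' @param n_bands Number of filterbank bands (default 9).
#' @param fmin,fmax Filterbank range in Hz (defaults 100 and 10,000).
#' @param order Butterworth order (default 4, applied zero-phase).
#' @return An [envelope_series] at the audio rate.
#' @seealso [resample_envelope()] to bring the envelope to the neural
#'   sampling rate before coherence analysis.
#' @export
cochlear_envelope <- function(audio, n_bands = 9, fmin = 100, fmax = 10000,
                              order = 4) {
  audio <- as_audio_signal(audio)
  if (audio$rate <= 2 * fmax) {
    stop(sprintf(
      "sampling rate %.0f Hz too low for a %.0f Hz top band edge (need > %.0f Hz); resample the audio first",
      audio$rate, fmax, 2 * fmax
    ))
  }
  bands <- design_cochlear_bands(n_bands, fmin, fmax)
  # filter at unit scale so the envelope is exactly homogeneous in the
  # input amplitude (IIR rounding noise would otherwise break scaling)
  s <- max(abs(audio$samples))
  if (s == 0) return(envelope_series(numeric(length(audio$samples)), audio$rate))
  x <- audio$samples / s
  acc <- numeric(length(x))
  for (b in seq_len(n_bands)) {
    xb <- butter_bandpass(x, bands$low_hz[b], bands$high_hz[b],
                          audio$rate, order = order)
    acc <- acc + hilbert_magnitude(xb)
  }
  envelope_series(acc * (s / n_bands), audio$rate)
}

#' Resample an envelope to a lower rate
#'
#' Polyphase anti-aliased resampling (via `signal::resample`) of an
#' envelope, typically down to the 150 Hz neural sampling rate so that
#' envelope and brain signals share a time axis for coherence analysis.
#' Duration is preserved within one output sample; small negative ringing
#' introduced by the anti-aliasing filter is clipped at zero.
#'
#' @param env An [envelope_series].
#' @param target_rate Target rate in Hz (default 150); must not exceed the
#'   input rate (upsampling is rejected).
#' @return An [envelope_series] at `target_rate`.
#' @export
resample_envelope <- function(env, target_rate = 150) {
  stopifnot(inherits(env, "envelope_series"))
  if (target_rate > env$rate) {
    stop("target_rate exceeds the envelope rate; upsampling is not supported")
  }
  if (target_rate == env$rate) return(env)
  # rational approximation of the rate ratio
  scale <- 1e6
  p <- round(target_rate * scale)
  q <- round(env$rate * scale)
  g <- gcd_int(p, q)
  p <- p / g
  q <- q / g
  v <- env$values
  n <- length(v)
  # replicate the edges before filtering so the polyphase startup
  # transient falls in the padding, then trim to the exact duration
  pad <- as.integer(ceiling(q / p) * 10)
  xx <- c(rep(v[1L], pad), v, rep(v[n], pad))
  y <- signal::resample(xx, p, q)
  off <- round(pad * p / q)
  n_out <- round(n * target_rate / env$rate)
  y <- y[(off + 1L):(off + n_out)]
  if (anyNA(y)) stop("resampling produced NA; input too short for padding")
  envelope_series(pmax(y, 0), target_rate)
}

gcd_int <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}
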