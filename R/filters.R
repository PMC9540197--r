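# Zero-phase Butterworth filtering and Hilbert-transform helpers.
# All band filters in the pipeline are applied forward and reverse
# (signal::filtfilt) so that group delay never misaligns bands.

butter_bandpass <- function(x, low_hz, high_hz, rate, order = 4) {
  nyq <- rate / 2
  if (!(low_hz > 0 && high_hz > low_hz)) {
    stop("need 0 < low_hz < high_hz")
  }
  if (high_hz >= nyq) {
    stop(sprintf("band edge %.1f Hz is at or above Nyquist (%.1f Hz)",
                 high_hz, nyq))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  signal::filtfilt(bf, x)
}

butter_lowpass <- function(x, cutoff_hz, rate, order = 4) {
  nyq <- rate / 2
  if (cutoff_hz >= nyq) {
    stop(sprintf("cutoff %.1f Hz is at or above Nyquist (%.1f Hz)",
                 cutoff_hz, nyq))
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  signal::filtfilt(bf, x)
}

butter_highpass <- function(x, cutoff_hz, rate, order = 6) {
  nyq <- rate / 2
  if (cutoff_hz >= nyq) {
    stop(sprintf("cutoff %.1f Hz is at or above Nyquist (%.1f Hz)",
                 cutoff_hz, nyq))
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = "high")
  signal::filtfilt(bf, x)
}

# Magnitude of the analytic signal, computed with an exact-length FFT so no
# periodic-extension artifacts are introduced beyond the usual edge effects.
hilbert_magnitude <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1L] <- 1
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Spectrally shaped 1/f^exponent noise, one column per channel, each column
# normalized to the requested standard deviation. exponent = 0 gives white
# noise.
one_over_f_noise <- function(n_samples, n_channels, rate,
                             exponent = 1, sd = 1) {
  w <- matrix(stats::rnorm(n_samples * n_channels), n_samples, n_channels)
  if (exponent != 0) {
    f <- seq(0, rate, length.out = n_samples + 1L)[seq_len(n_samples)]
    f[f > rate / 2] <- rate - f[f > rate / 2]  # fold to physical frequency
    f[1L] <- f[2L]                             # avoid DC blow-up
    amp <- f^(-exponent / 2)
    W <- stats::mvfft(w) * amp
    w <- Re(stats::mvfft(W, inverse = TRUE)) / n_samples
  }
  scale_to <- function(col) col * (sd / stats::sd(col))
  apply(w, 2L, scale_to)
}
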