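#' Set of fixed-length epochs for one subject and condition
#'
#' @param data Numeric array `trials x channels x samples`, finite.
#' @param rate Sampling rate in Hz (default 150).
#' @param subject_id,condition_id Optional metadata labels.
#' @param channel_ids Optional channel labels (default `1:n_channels`).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, rate = 150, subject_id = NA, condition_id = NA,
                      channel_ids = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, rate > 0)
  if (!all(is.finite(data))) stop("epoch data must be finite")
  if (dim(data)[1L] < 1L) stop("need at least one trial")
  channel_ids <- channel_ids %||% seq_len(dim(data)[2L])
  stopifnot(length(channel_ids) == dim(data)[2L])
  structure(list(data = data, rate = as.double(rate),
                 subject_id = subject_id, condition_id = condition_id,
                 channel_ids = channel_ids),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz (subject %s, condition %s)\n",
              d[1L], d[2L], d[3L], x$rate, x$subject_id, x$condition_id))
  invisible(x)
}

#' Cut a continuous recording into fixed-length epochs
#'
#' Splits a multichannel time series (or a single envelope) into
#' consecutive non-overlapping epochs of `epoch_s` seconds; a trailing
#' remainder shorter than one epoch is dropped. Concatenating the epochs
#' reproduces the retained part of the recording exactly.
#'
#' @param ts A `channels x samples` matrix, a numeric vector, or an
#'   [envelope_series].
#' @param rate Sampling rate in Hz (taken from `ts` when it is an
#'   [envelope_series]).
#' @param epoch_s Epoch length in seconds (default 2).
#' @param ... Passed to [epoch_set()] (metadata).
#' @return For matrix input, an [epoch_set]; for vector/envelope input, a
#'   `trials x samples` matrix.
#' @export
segment_trials <- function(ts, rate = 150, epoch_s = 2, ...) {
  if (inherits(ts, "envelope_series")) {
    rate <- ts$rate
    ts <- ts$values
  }
  ns <- round(epoch_s * rate)
  if (is.matrix(ts)) {
    n <- ncol(ts)
    n_trials <- n %/% ns
    if (n_trials < 1L) stop("recording shorter than one epoch")
    arr <- array(0, c(n_trials, nrow(ts), ns))
    for (tr in seq_len(n_trials)) {
      arr[tr, , ] <- ts[, ((tr - 1L) * ns + 1L):(tr * ns)]
    }
    epoch_set(arr, rate = rate, ...)
  } else {
    n <- length(ts)
    n_trials <- n %/% ns
    if (n_trials < 1L) stop("recording shorter than one epoch")
    matrix(ts[seq_len(n_trials * ns)], n_trials, ns, byrow = TRUE)
  }
}

#' Equalize epoch counts across conditions
#'
#' Subsamples every condition's epochs (uniformly, without replacement,
#' seeded) down to the smallest count, so that coherence estimates are
#' comparable across conditions (coherence is biased by the number of
#' averaged segments).
#'
#' @param sets Named list, one element per condition: either [epoch_set]s
#'   or `trials x samples` envelope-epoch matrices.
#' @param seed Integer seed for the subsampling.
#' @return A list of the same shape with equal trial counts; with equal
#'   counts in, the input is returned unchanged.
#' @export
equalize_epoch_counts <- function(sets, seed = 1L) {
  counts <- vapply(sets, function(s) {
    if (inherits(s, "epoch_set")) dim(s$data)[1L] else nrow(s)
  }, integer(1))
  if (any(counts < 1L)) stop("every condition needs at least one epoch")
  n_min <- min(counts)
  if (all(counts == n_min)) return(sets)
  with_seed(seed, {
    lapply(sets, function(s) {
      n <- if (inherits(s, "epoch_set")) dim(s$data)[1L] else nrow(s)
      keep <- sort(sample.int(n, n_min))
      if (inherits(s, "epoch_set")) {
        s$data <- s$data[keep, , , drop = FALSE]
        s
      } else {
        s[keep, , drop = FALSE]
      }
    })
  })
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the `K = 2 N W - 1` leading DPSS tapers for a window of
#' `n_samples` samples at rate `rate` with spectral half-bandwidth
#' `half_bandwidth` Hz (time-bandwidth product `NW = T * W`), via the
#' eigenvectors of the standard symmetric tridiagonal matrix that commutes
#' with the concentration operator. For 2-s windows and 3 Hz smoothing
#' this gives the conventional 11 tapers.
#'
#' @param n_samples Window length in samples.
#' @param rate Sampling rate in Hz.
#' @param half_bandwidth Spectral smoothing half-width W in Hz; `T * W`
#'   must be >= 1.
#' @return A `K x n_samples` matrix of orthonormal tapers (rows), ordered
#'   by decreasing spectral concentration, with attributes `nw` and `w`
#'   (half-bandwidth in cycles per sample).
#' @export
dpss_tapers <- function(n_samples, rate, half_bandwidth = 3) {
  T_s <- n_samples / rate
  nw <- T_s * half_bandwidth
  if (nw < 1) stop("time-bandwidth product T*W must be >= 1")
  K <- as.integer(floor(2 * nw - 1))
  N <- as.integer(n_samples)
  w <- half_bandwidth / rate
  i <- 0:(N - 1L)
  main <- ((N - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (1:(N - 1L)) * (N - (1:(N - 1L))) / 2
  A <- matrix(0, N, N)
  diag(A) <- main
  A[cbind(2:N, 1:(N - 1L))] <- off
  A[cbind(1:(N - 1L), 2:N)] <- off
  eg <- eigen(A, symmetric = TRUE)
  V <- eg$vectors[, seq_len(K), drop = FALSE]
  # deterministic sign convention: positive mean for symmetric tapers,
  # positive initial slope for antisymmetric ones
  for (k in seq_len(K)) {
    s <- sum(V[, k])
    if (abs(s) < 1e-8) s <- sum(V[seq_len(N %/% 2), k] * -1) # leading half
    if (s < 0) V[, k] <- -V[, k]
  }
  tapers <- t(V)
  attr(tapers, "nw") <- nw
  attr(tapers, "w") <- w
  tapers
}

#' Multitaper auto- and cross-spectra of brain epochs and envelope epochs
#'
#' Applies DPSS multitaper spectral estimation to matched 2-s brain and
#' envelope epochs on an integer-Hz grid (default 1--25 Hz, the FFT length
#' being the smallest multiple of the sampling rate that covers the epoch,
#' so integer frequencies fall exactly on bins). Auto-spectra per channel,
#' the envelope auto-spectrum, and channel-by-envelope cross-spectra are
#' summed over tapers and trials; [coherence()] and [power_spectra()]
#' normalize them.
#'
#' @param brain An [epoch_set] (`trials x channels x samples`).
#' @param env_epochs A `trials x samples` matrix of envelope epochs cut
#'   from the same time axis (e.g. by [segment_trials()]), or `NULL` to
#'   compute auto-spectra only.
#' @param fmin,fmax Frequency grid limits in Hz (defaults 1 and 25, 1 Hz
#'   steps).
#' @param half_bandwidth DPSS half-bandwidth in Hz (default 3).
#' @return An object of class `spectral_estimate` with fields `freqs`,
#'   `sxx` (channels x frequencies), `syy` (frequencies), `sxy` (complex,
#'   channels x frequencies), `n_trials`, `n_tapers`, `rate`,
#'   `channel_ids`.
#' @export
mtm_cross_spectra <- function(brain, env_epochs = NULL, fmin = 1, fmax = 25,
                              half_bandwidth = 3) {
  stopifnot(inherits(brain, "epoch_set"))
  d <- dim(brain$data)
  n_trials <- d[1L]
  n_ch <- d[2L]
  ns <- d[3L]
  rate <- brain$rate
  if (!is.null(env_epochs)) {
    stopifnot(is.matrix(env_epochs))
    if (nrow(env_epochs) != n_trials || ncol(env_epochs) != ns) {
      stop("envelope epochs must match brain epochs in trial count and length")
    }
  }
  tapers <- dpss_tapers(ns, rate, half_bandwidth)
  K <- nrow(tapers)
  nfft <- as.integer(ceiling(ns / rate) * rate)
  bins_per_hz <- nfft / rate
  freqs <- fmin:fmax
  idx <- round(freqs * bins_per_hz) + 1L
  if (max(idx) > nfft) stop("fmax exceeds the resolvable range")
  nf <- length(freqs)

  sxx <- matrix(0, n_ch, nf)
  syy <- numeric(nf)
  sxy <- matrix(0 + 0i, n_ch, nf)
  buf <- matrix(0, nfft, n_ch + 1L)
  for (tr in seq_len(n_trials)) {
    xt <- t(matrix(brain$data[tr, , ], n_ch, ns))   # samples x channels
    for (k in seq_len(K)) {
      tp <- tapers[k, ]
      buf[] <- 0
      buf[seq_len(ns), seq_len(n_ch)] <- xt * tp
      if (!is.null(env_epochs)) {
        buf[seq_len(ns), n_ch + 1L] <- env_epochs[tr, ] * tp
      }
      Z <- stats::mvfft(buf)[idx, , drop = FALSE]
      zx <- Z[, seq_len(n_ch), drop = FALSE]        # nf x channels
      sxx <- sxx + t(Mod(zx)^2)
      if (!is.null(env_epochs)) {
        ze <- Z[, n_ch + 1L]
        syy <- syy + Mod(ze)^2
        sxy <- sxy + t(zx * Conj(ze))
      }
    }
  }
  structure(list(freqs = freqs, sxx = sxx, syy = syy, sxy = sxy,
                 n_trials = n_trials, n_tapers = K, rate = rate,
                 channel_ids = brain$channel_ids,
                 subject_id = brain$subject_id,
                 condition_id = brain$condition_id,
                 has_envelope = !is.null(env_epochs)),
            class = "spectral_estimate")
}

#' Envelope-brain coherence map
#'
#' Magnitude-squared coherence between each channel and the envelope,
#' \eqn{C(ch, f) = |\sum S_{xy}|^2 / (\sum S_{xx} \sum S_{yy})} with sums
#' over trials and tapers, bounded in `[0, 1]`. This trial-averaged
#' envelope-brain coherence is the "speech tracking" measure. Bins with a
#' zero auto-spectrum get coherence 0 with a warning.
#'
#' @param est A `spectral_estimate` from [mtm_cross_spectra()] computed
#'   with envelope epochs.
#' @return A `coherence_map`: `channels x frequencies` matrix with
#'   attributes `freqs`, `n_trials`, `n_tapers`, `subject_id`,
#'   `condition_id`.
#' @export
coherence <- function(est) {
  stopifnot(inherits(est, "spectral_estimate"))
  if (!est$has_envelope) stop("estimate has no envelope cross-spectra")
  denom <- est$sxx * matrix(est$syy, nrow(est$sxx), length(est$syy),
                            byrow = TRUE)
  C <- Mod(est$sxy)^2
  zero <- denom <= 0
  if (any(zero)) {
    warning("zero auto-spectrum bins; coherence set to 0 there")
    C[zero] <- 0
    denom[zero] <- 1
  }
  C <- C / denom
  structure(C, freqs = est$freqs, n_trials = est$n_trials,
            n_tapers = est$n_tapers, subject_id = est$subject_id,
            condition_id = est$condition_id, channel_ids = est$channel_ids,
            class = c("coherence_map", "matrix"))
}

#' Trial- and taper-averaged power map
#'
#' @param est A `spectral_estimate`.
#' @return A `power_map`: `channels x frequencies` matrix of averaged
#'   auto-spectra (nonnegative), with the same attributes as a
#'   coherence map.
#' @export
power_spectra <- function(est) {
  stopifnot(inherits(est, "spectral_estimate"))
  P <- est$sxx / (est$n_trials * est$n_tapers)
  structure(P, freqs = est$freqs, n_trials = est$n_trials,
            n_tapers = est$n_tapers, subject_id = est$subject_id,
            condition_id = est$condition_id, channel_ids = est$channel_ids,
            class = c("power_map", "matrix"))
}

#' Average a coherence or power map over a frequency band
#'
#' Unweighted mean over all grid bins with `band[1] <= f <= band[2]`
#' (inclusive); on the default 1 Hz grid the 1--7 Hz band averages exactly
#' seven bins and 8--12 Hz exactly five.
#'
#' @param map A `coherence_map` or `power_map` (or any matrix with a
#'   `freqs` attribute).
#' @param band Length-2 numeric `c(f_lo, f_hi)` within the grid.
#' @return Named numeric vector, one value per channel.
#' @export
band_average <- function(map, band) {
  freqs <- attr(map, "freqs")
  if (is.null(freqs)) stop("map carries no frequency axis")
  sel <- freqs >= band[1L] & freqs <= band[2L]
  if (!any(sel)) stop("band contains no grid frequencies")
  out <- rowMeans(map[, sel, drop = FALSE])
  names(out) <- attr(map, "channel_ids")
  out
}

#' Alpha-band power per channel
#'
#' Band-averaged (8--12 Hz by default) trial- and taper-averaged spectral
#' power, the "activation" proxy of the pipeline: alpha power decreases
#' are read as stronger engagement.
#'
#' @param est A `spectral_estimate`.
#' @param band Frequency band in Hz (default `c(8, 12)`).
#' @return Named numeric vector, one nonnegative value per channel.
#' @export
alpha_power <- function(est, band = c(8, 12)) {
  band_average(power_spectra(est), band)
}
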