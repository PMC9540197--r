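#' Greenwood cochlear frequency-position map
#'
#' The Greenwood function relates a characteristic frequency to its relative
#' place along the basilar membrane, \eqn{F = A (10^{a x} - k)} with the
#' standard human constants \eqn{A = 165.4}, \eqn{a = 2.1} (for \eqn{x}
#' expressed as a proportion of cochlear length) and \eqn{k = 0.88}.
#' `greenwood_position()` inverts the map (frequency to place) and
#' `greenwood_frequency()` evaluates it (place to frequency). Filterbanks
#' whose band edges are equally spaced in Greenwood position implement
#' "equal distances along the basilar membrane".
#'
#' @param frequency Frequency in Hz. Must exceed \eqn{A (1 - k)} (about
#'   19.85 Hz for the human constants), the frequency mapped to the apex.
#' @param place Relative cochlear place (proportion of cochlear length,
#'   0 = apex).
#' @param A,a,k Greenwood constants; defaults are the human map.
#' @return `greenwood_position()` returns the relative place (0 at the apex,
#'   1 near the base for ~20 kHz); `greenwood_frequency()` returns Hz.
#'   The two functions are exact inverses.
#' @examples
#' greenwood_position(1000)
#' greenwood_frequency(greenwood_position(1000))
#' @export
greenwood_position <- function(frequency, A = 165.4, a = 2.1, k = 0.88) {
  stopifnot(is.numeric(frequency), all(is.finite(frequency)))
  f_apex <- A * (1 - k)
  if (any(frequency <= f_apex)) {
    stop(sprintf(
      "frequency must lie above the apex frequency A*(1-k) = %.4f Hz",
      f_apex
    ))
  }
  log10(frequency / A + k) / a
}

#' @rdname greenwood_position
#' @export
greenwood_frequency <- function(place, A = 165.4, a = 2.1, k = 0.88) {
  stopifnot(is.numeric(place), all(is.finite(place)))
  A * (10^(a * place) - k)
}

#' Design cochlear-spaced analysis bands
#'
#' Partitions `[fmin, fmax]` into `n_channels` contiguous band-pass
#' specifications whose `n_channels + 1` edges are equally spaced in
#' Greenwood position, i.e. the bands cover equal distances along the
#' basilar membrane. Adjacent bands share an edge exactly; the first and
#' last edges are `fmin` and `fmax` themselves.
#'
#' @param n_channels Number of bands (>= 1).
#' @param fmin,fmax Frequency range in Hz, `0 < fmin < fmax`.
#' @return A data frame with columns `low_hz` and `high_hz`, one row per
#'   band, ordered from low to high frequency.
#' @examples
#' design_cochlear_bands(7, 200, 7000)
#' @export
design_cochlear_bands <- function(n_channels, fmin = 200, fmax = 7000) {
  if (!is.numeric(n_channels) || length(n_channels) != 1L ||
      !is.finite(n_channels) || n_channels < 1 ||
      n_channels != round(n_channels)) {
    stop("n_channels must be a positive integer")
  }
  stopifnot(is.numeric(fmin), is.numeric(fmax), fmin > 0, fmin < fmax)
  places <- seq(greenwood_position(fmin), greenwood_position(fmax),
                length.out = n_channels + 1L)
  edges <- greenwood_frequency(places)
  edges[1L] <- fmin
  edges[n_channels + 1L] <- fmax
  data.frame(low_hz = edges[-(n_channels + 1L)], high_hz = edges[-1L])
}
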