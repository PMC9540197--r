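#' Sampled audio waveform
#'
#' Lightweight container for a mono waveform with an explicit sampling rate.
#'
#' @param samples Numeric vector of samples (arbitrary units), finite,
#'   length >= 1.
#' @param rate Sampling rate in Hz, > 0.
#' @return An object of class `audio_signal`: a list with elements
#'   `samples` and `rate`.
#' @examples
#' a <- audio_signal(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' @export
audio_signal <- function(samples, rate) {
  stopifnot(is.numeric(samples), length(samples) > 0L)
  if (!all(is.finite(samples))) stop("samples must be finite")
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate), rate > 0)
  structure(list(samples = as.double(samples), rate = as.double(rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

as_audio_signal <- function(x, rate = NULL) {
  if (inherits(x, "audio_signal")) return(x)
  if (is.null(rate)) stop("rate required when input is a bare vector")
  audio_signal(x, rate)
}

# --- WAV I/O -----------------------------------------------------------------
# Minimal RIFF/WAVE reader and writer for mono PCM16 (format 1) and IEEE
# float32 (format 3) files; sufficient for exchanging stimuli with standard
# audio tooling.

#' Read a mono WAV file
#'
#' Supports PCM16 and IEEE float32 encodings. Multichannel files are
#' rejected; use external tools to downmix first.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal] with samples scaled to `[-1, 1]` for PCM16 and
#'   taken verbatim for float32.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        format = sum(as.integer(raw_fmt[1:2]) * c(1L, 256L)),
        channels = sum(as.integer(raw_fmt[3:4]) * c(1L, 256L)),
        rate = sum(as.integer(raw_fmt[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(raw_fmt[15:16]) * c(1L, 256L))
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$channels != 1L) stop("only mono WAV files are supported")
      if (fmt$format == 1L && fmt$bits == 16L) {
        n <- size %/% 2L
        samples <- readBin(con, "integer", n, size = 2L, signed = TRUE,
                           endian = "little") / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        n <- size %/% 4L
        samples <- readBin(con, "double", n, size = 4L, endian = "little")
      } else {
        stop("unsupported WAV encoding (need PCM16 or float32)")
      }
      break
    } else {
      invisible(readBin(con, "raw", size + (size %% 2L)))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  audio_signal(samples, fmt$rate)
}

#' Write a mono WAV file
#'
#' @param audio An [audio_signal] (or numeric vector with `rate`).
#' @param path Output path.
#' @param rate Sampling rate, required when `audio` is a bare vector.
#' @param format `"pcm16"` (samples clipped to `[-1, 1]` and quantized) or
#'   `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, rate = NULL,
                      format = c("pcm16", "float32")) {
  audio <- as_audio_signal(audio, rate)
  format <- match.arg(format)
  x <- audio$samples
  n <- length(x)
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_size <- n * bytes_per
  fmt_code <- if (format == "pcm16") 1L else 3L
  bits <- 8L * bytes_per
  sr <- as.integer(round(audio$rate))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmt_code, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")        # mono
  writeBin(sr, con, size = 4L, endian = "little")
  writeBin(as.integer(sr * bytes_per), con, size = 4L, endian = "little")
  writeBin(bytes_per, con, size = 2L, endian = "little") # block align
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(pmax(-32768, pmin(32767, round(pmax(-1, pmin(1, x)) * 32767))))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(x, con, size = 4L, endian = "little")
  }
  invisible(path)
}
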