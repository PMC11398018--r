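#' Mono waveform container
#'
#' A waveform is a finite mono sample sequence together with its sampling
#' rate in Hz. All signal-level operations in the package (loud-region
#' segmentation, MFCC extraction, embedding) take and return this class.
#'
#' @param samples Numeric vector of samples; must be finite and non-empty.
#' @param rate Sampling rate in Hz (positive scalar).
#' @return An object of class `waveform`: a list with elements `samples`
#'   and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 1, length.out = 16000)), 16000)
#' duration(w)
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop2("waveform needs at least one sample")
  if (!all(is.finite(samples))) stop2("waveform samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop2("sampling rate must be a positive scalar")
  }
  structure(list(samples = samples, rate = rate), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$rate, duration(x)))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w A [waveform()].
#' @return Duration in seconds.
#' @export
duration <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$rate
}

#' Read a mono WAV file
#'
#' Reads RIFF/WAVE files containing 16-bit integer PCM or 32-bit IEEE float
#' samples. Stereo and multi-channel files are rejected: the analysis is
#' defined on mono speech recordings.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()]; PCM samples are scaled to `[-1, 1]`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop2("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop2("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop2("malformed WAV: data chunk before fmt chunk")
      if (fmt$channels != 1L) stop2("only mono WAV files are supported")
      if (fmt$format == 1L && fmt$bits == 16L) {
        n <- size %/% 2L
        samples <- readBin(con, "integer", n, 2, endian = "little") / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        n <- size %/% 4L
        samples <- readBin(con, "double", n, 4, endian = "little")
      } else {
        stop2("unsupported WAV encoding (need PCM16 or float32)")
      }
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (is.null(samples)) stop2("no data chunk found in ", path)
  waveform(samples, fmt$rate)
}

#' Write a mono WAV file
#'
#' @param w A [waveform()].
#' @param path Output path.
#' @param format `"pcm16"` (samples clipped to `[-1, 1]` and quantized) or
#'   `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, format = c("pcm16", "float32")) {
  stopifnot(inherits(w, "waveform"))
  format <- match.arg(format)
  n <- length(w$samples)
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(w$rate), con, 4, endian = "little")
  writeBin(as.integer(w$rate * bytes_per), con, 4, endian = "little")
  writeBin(bytes_per, con, 2, endian = "little")
  writeBin(8L * bytes_per, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "pcm16") {
    q <- pmin(pmax(w$samples, -1), 32767 / 32768)
    writeBin(as.integer(round(q * 32768)), con, 2, endian = "little")
  } else {
    writeBin(w$samples, con, 4, endian = "little")
  }
  invisible(path)
}

#' Resample a waveform to 16 kHz
#'
#' Embedding providers and the MFCC extractor operate on 16 kHz audio, the
#' rate the pretrained speech models expect. Uses polyphase resampling
#' (`signal::resample`) with the rational factor 16000 / rate. A waveform
#' already at 16 kHz is returned unchanged, sample for sample.
#'
#' @param w A [waveform()].
#' @return A [waveform()] with `rate == 16000`.
#' @export
resample_to_16k <- function(w) {
  stopifnot(inherits(w, "waveform"))
  target <- 16000
  if (w$rate == target) return(w)
  r <- as.integer(round(w$rate))
  g <- gcd_int(target, r)
  p <- target %/% g
  q <- r %/% g
  y <- signal::resample(w$samples, p, q)
  # resample can over/undershoot by a sample; trim to the expected length
  n_expect <- round(length(w$samples) * target / w$rate)
  if (length(y) > n_expect) y <- y[seq_len(n_expect)]
  if (length(y) < n_expect) y <- c(y, rep(0, n_expect - length(y)))
  waveform(y, target)
}

gcd_int <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}
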