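# Minimal RIFF/WAVE layer. Reads/writes mono or multichannel PCM
# (16/24/32-bit integer) and IEEE float32 files; amplitudes are normalized
# doubles in [-1, 1].

#' Audio signal container
#'
#' A lightweight container for a mono audio signal: a numeric sample vector
#' plus its sample rate in Hz.
#'
#' @param samples Numeric vector of amplitudes (finite).
#' @param rate Sample rate in Hz (positive number).
#' @return An object of class `audio_signal` with elements `samples` and
#'   `rate`.
#' @examples
#' a <- audio_signal(sin(2 * pi * 440 * seq(0, 1, by = 1/8000)), 8000)
#' duration(a)
#' @export
audio_signal <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("audio signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("audio samples must be finite")
  stop_if_not_scalar_number(rate, "rate", 0, strict_min = TRUE)
  structure(list(samples = samples, rate = rate), class = "audio_signal")
}

# Internal constructor without the finite-amplitude scan, for hot paths
# whose inputs are already validated audio.
audio_signal_fast <- function(samples, rate) {
  structure(list(samples = samples, rate = rate), class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %.2f s at %g Hz (%d samples)>\n",
              duration(x), x$rate, length(x$samples)))
  invisible(x)
}

#' @rdname audio_signal
#' @param x An `audio_signal`.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  length(x$samples) / x$rate
}

read_u32le <- function(con) {
  b <- readBin(con, "integer", 2L, size = 2L, signed = FALSE, endian = "little")
  b[1] + b[2] * 65536
}

#' Read a WAV file
#'
#' Reads a RIFF/WAVE file (PCM 16/24/32-bit or IEEE float32). Multichannel
#' files are mixed down to mono by channel averaging. Amplitudes are scaled
#' to `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(read_u32le(con))
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readBin(con, "raw", 4L)
    if (length(id) < 4L) break
    id <- rawToChar(id)
    size <- read_u32le(con)
    if (identical(id, "fmt ")) {
      blob <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(blob[1:2], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        channels = readBin(blob[3:4], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        rate = readBin(blob[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(blob[15:16], "integer", 1L, 2L, signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1L))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw) || length(data_raw) == 0L)
    stop("empty or malformed WAV file: ", path)

  x <- if (fmt$format == 3L || (fmt$format == 65534L && fmt$bits == 32L)) {
    readBin(data_raw, "double", length(data_raw) / 4L, size = 4L, endian = "little")
  } else if (fmt$bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) / 2L, size = 2L,
            signed = TRUE, endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    n <- length(data_raw) %/% 3L
    m <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
    v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (fmt$bits == 32L) {
    readBin(data_raw, "integer", length(data_raw) / 4L, size = 4L,
            endian = "little") / 2147483648
  } else stop("unsupported WAV bit depth: ", fmt$bits)

  if (fmt$channels > 1L) {
    n <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(n * fmt$channels)], nrow = fmt$channels))
  }
  audio_signal(x, fmt$rate)
}

write_u32le <- function(con, x) {
  writeBin(as.raw(c(x %% 256, (x %/% 256) %% 256,
                    (x %/% 65536) %% 256, (x %/% 16777216) %% 256)), con)
}

#' Write a WAV file
#'
#' Writes a mono [audio_signal()] as 16-bit PCM (default) or IEEE float32.
#' For PCM, amplitudes are clipped to `[-1, 1]`.
#'
#' @param audio An [audio_signal()].
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, bits = 16L) {
  stopifnot(inherits(audio, "audio_signal"), bits %in% c(16L, 32L))
  x <- audio$samples
  n <- length(x)
  bytes <- n * (bits / 8L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  write_u32le(con, 36 + bytes)
  writeChar("WAVEfmt ", con, eos = NULL)
  write_u32le(con, 16)
  fmt_code <- if (bits == 32L) 3L else 1L
  writeBin(as.integer(c(fmt_code, 1L)), con, size = 2L, endian = "little")
  write_u32le(con, round(audio$rate))
  write_u32le(con, round(audio$rate) * bits / 8L)
  writeBin(as.integer(c(bits / 8L, bits)), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  write_u32le(con, bytes)
  if (bits == 16L) {
    q <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(x, con, size = 4L, endian = "little")
  }
  invisible(path)
}
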