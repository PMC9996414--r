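# Night audio loading and epoch segmentation.

#' Load night audio from a WAV file
#'
#' Reads a WAV recording, mixes multichannel audio down to mono and, if
#' `target_rate` differs from the file's rate, resamples with a polyphase
#' filter ([signal::resample()]).
#'
#' @param path WAV path.
#' @param target_rate Desired sample rate in Hz, or `NULL` to keep the
#'   file's rate.
#' @return An [audio_signal()] at `target_rate`.
#' @export
load_audio <- function(path, target_rate = NULL) {
  a <- read_wav(path)
  if (is.null(target_rate) || target_rate == a$rate) return(a)
  resample_audio(a, target_rate)
}

#' Resample an audio signal
#'
#' @param audio An [audio_signal()].
#' @param target_rate New rate in Hz.
#' @return An [audio_signal()] at `target_rate`, with length
#'   `round(n * target_rate / rate)` (within one sample).
#' @export
resample_audio <- function(audio, target_rate) {
  stopifnot(inherits(audio, "audio_signal"))
  stop_if_not_scalar_number(target_rate, "target_rate", 0, strict_min = TRUE)
  if (target_rate == audio$rate) return(audio)
  fr <- rational_approx(target_rate / audio$rate)
  y <- signal::resample(audio$samples, fr[1], fr[2])
  audio_signal(as.numeric(y), target_rate)
}

# p/q approximation of a positive ratio with bounded denominator.
rational_approx <- function(r, max_den = 1000L) {
  best <- c(round(r), 1L)
  best_err <- abs(r - best[1] / best[2])
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    err <- abs(r - p / q)
    if (err < best_err - 1e-15) {
      best <- c(p, q); best_err <- err
      if (err < 1e-12) break
    }
  }
  g <- gcd_int(best[1], best[2])
  as.integer(best / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Cut a night signal into 30-second epochs
#'
#' Epoch `k` (0-based) covers samples `[k*L*rate, (k+1)*L*rate)`; a
#' trailing partial epoch is dropped, matching the epoch grid convention.
#'
#' @param audio An [audio_signal()].
#' @param grid Optional [epoch_grid()]; defaults to the grid implied by the
#'   signal duration.
#' @return A list of [audio_signal()] epochs (possibly empty).
#' @export
segment_epochs <- function(audio, grid = NULL) {
  stopifnot(inherits(audio, "audio_signal"))
  if (is.null(grid)) grid <- epoch_grid(duration(audio))
  spe <- round(grid$epoch_length * audio$rate)
  n <- min(grid$n_epochs, length(audio$samples) %/% spe)
  if (n <= 0L) return(list())
  lapply(seq_len(n), function(k) {
    audio_signal_fast(audio$samples[((k - 1L) * spe + 1L):(k * spe)], audio$rate)
  })
}
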