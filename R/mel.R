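# Log-mel spectrogram features and the 14-epoch detector windows.

#' Mel feature configuration
#'
#' Defaults follow common practice for breathing-sound analysis: 64 mel
#' bands over the full band, 50 ms Hann analysis windows with a 25 ms hop,
#' power spectrogram, natural-log compression with a small floor.
#'
#' @param sample_rate Audio sample rate the features expect, Hz.
#' @param n_mels Number of mel bands.
#' @param window_sec Analysis window length in seconds.
#' @param hop_sec Hop between consecutive frames in seconds.
#' @param fmin,fmax Filter-bank edge frequencies in Hz (`fmax` defaults to
#'   Nyquist).
#' @param log_epsilon Floor added inside the log so silent input maps to a
#'   finite constant.
#' @return A list of class `mel_config`.
#' @export
mel_config <- function(sample_rate = 16000, n_mels = 64,
                       window_sec = 0.05, hop_sec = 0.025,
                       fmin = 0, fmax = sample_rate / 2,
                       log_epsilon = 1e-10) {
  stopifnot(fmax <= sample_rate / 2 + 1e-9, fmin >= 0, fmin < fmax,
            n_mels >= 2, window_sec > 0, hop_sec > 0, log_epsilon > 0)
  structure(list(sample_rate = sample_rate, n_mels = as.integer(n_mels),
                 window_sec = window_sec, hop_sec = hop_sec,
                 fmin = fmin, fmax = fmax, log_epsilon = log_epsilon),
            class = "mel_config")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filter bank
#'
#' Triangular filters with peak amplitude 1, centers equally spaced on the
#' mel scale (HTK convention).
#'
#' @param config A [mel_config()].
#' @param n_fft FFT length the filters apply to.
#' @return Matrix `n_mels x (n_fft/2 + 1)`; attribute `"centers_hz"` holds
#'   the filter center frequencies.
#' @export
mel_filterbank <- function(config, n_fft) {
  n_bins <- n_fft %/% 2 + 1L
  freqs <- (0:(n_bins - 1L)) * config$sample_rate / n_fft
  mels <- seq(hz_to_mel(config$fmin), hz_to_mel(config$fmax),
              length.out = config$n_mels + 2L)
  hz <- mel_to_hz(mels)
  fb <- matrix(0, config$n_mels, n_bins)
  for (m in seq_len(config$n_mels)) {
    lo <- hz[m]; cen <- hz[m + 1L]; hi <- hz[m + 2L]
    up <- (freqs - lo) / (cen - lo)
    down <- (hi - freqs) / (hi - cen)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  attr(fb, "centers_hz") <- hz[2:(config$n_mels + 1L)]
  fb
}

# Memo for STFT frame indices, Hann windows and filter banks: mel
# extraction runs once per epoch all night, so geometry is cached per
# (signal length, window, hop) and per configuration.
.mel_memo <- new.env(parent = emptyenv())

memo_get <- function(key, build) {
  v <- .mel_memo[[key]]
  if (is.null(v)) {
    v <- build()
    assign(key, v, envir = .mel_memo)
  }
  v
}

stft_power <- function(x, win_len, hop_len) {
  n <- length(x)
  if (n < win_len) stop("signal shorter than one analysis window")
  idx <- memo_get(sprintf("idx_%d_%d_%d", n, win_len, hop_len), function() {
    starts <- seq(1L, n - win_len + 1L, by = hop_len)
    as.vector(outer(0:(win_len - 1L), starts, `+`))
  })
  frames <- matrix(x[idx], nrow = win_len)
  w <- memo_get(sprintf("hann_%d", win_len), function() {
    0.5 - 0.5 * cos(2 * pi * (0:(win_len - 1L)) / win_len)   # periodic Hann
  })
  spec <- mvfft(frames * w)
  n_bins <- win_len %/% 2 + 1L
  Mod(spec[seq_len(n_bins), , drop = FALSE])^2
}

#' Log-mel spectrogram of one epoch
#'
#' Short-time power spectra (Hann window) are pooled through the triangular
#' mel filter bank and log-compressed: `log(fb %*% power + epsilon)`.
#' Deterministic; an all-zero segment yields the constant
#' `log(log_epsilon)` floor.
#'
#' @param audio An [audio_signal()] whose rate matches `config$sample_rate`.
#' @param config A [mel_config()].
#' @return Matrix of class `mel_spectrogram` (`n_mels` rows x frames), with
#'   attributes `hop_sec` and `sample_rate`.
#' @export
mel_spectrogram <- function(audio, config = mel_config()) {
  stopifnot(inherits(audio, "audio_signal"))
  if (abs(audio$rate - config$sample_rate) > 1e-6)
    stop("audio rate ", audio$rate, " does not match mel_config sample_rate ",
         config$sample_rate)
  win_len <- round(config$window_sec * config$sample_rate)
  hop_len <- max(1L, round(config$hop_sec * config$sample_rate))
  p <- stft_power(audio$samples, win_len, hop_len)
  fb <- memo_get(sprintf("fb_%d_%d_%g_%g_%g", config$n_mels, win_len,
                         config$sample_rate, config$fmin, config$fmax),
                 function() mel_filterbank(config, win_len))
  m <- log(fb %*% p + config$log_epsilon)
  structure(m, class = c("mel_spectrogram", "matrix", "array"),
            hop_sec = hop_len / config$sample_rate,
            sample_rate = config$sample_rate)
}

#' Log-mel spectrograms for every epoch of a night
#'
#' @param audio Whole-night [audio_signal()].
#' @param config A [mel_config()].
#' @param grid Optional [epoch_grid()].
#' @return List of [mel_spectrogram()] matrices, one per epoch, all of
#'   identical shape.
#' @export
night_mels <- function(audio, config = mel_config(), grid = NULL) {
  segs <- segment_epochs(audio, grid)
  lapply(segs, mel_spectrogram, config = config)
}

# Window plan: which epochs feed each 14-epoch window and which global
# epochs its 10 outputs land on. Stride = output_epochs; the final window
# is shifted back so its outputs end at the last epoch (the later window
# wins where outputs overlap); nights shorter than output_epochs get one
# edge-replicated window.
window_plan <- function(n_epochs, input_epochs = 14L, output_epochs = 10L) {
  stopifnot(n_epochs >= 1L, output_epochs <= input_epochs,
            (input_epochs - output_epochs) %% 2L == 0L)
  ctx <- (input_epochs - output_epochs) %/% 2L
  n_win <- max(1L, ceiling(n_epochs / output_epochs))
  lapply(seq_len(n_win) - 1L, function(w) {
    out_start <- if (n_epochs <= output_epochs) 0L
                 else min(w * output_epochs, n_epochs - output_epochs)
    out_pos <- out_start + seq_len(output_epochs) - 1L        # 0-based, may exceed
    out_idx <- pmin(out_pos, n_epochs - 1L) + 1L              # 1-based, clipped
    in_idx <- pmin(pmax((out_start - ctx) + seq_len(input_epochs) - 1L, 0L),
                   n_epochs - 1L) + 1L
    list(input_idx = in_idx, output_idx = out_idx)
  })
}

#' Slide 14-epoch windows over a night of mel spectrograms
#'
#' Windows advance by `output_epochs` so that, after stitching (later
#' windows overwrite overlapping outputs), every epoch of the night
#' receives exactly one prediction. The first/last windows replicate the
#' terminal epochs to fill the context; a night shorter than
#' `output_epochs` yields a single padded window.
#'
#' @param mels List of per-epoch [mel_spectrogram()] matrices.
#' @param input_epochs,output_epochs Window geometry (defaults 14 and 10;
#'   their difference must be even).
#' @return List of `mel_window` objects, each with `epochs` (list of
#'   `input_epochs` mel matrices), `input_idx` and `output_idx` (1-based
#'   epoch indices of the night).
#' @export
make_windows <- function(mels, input_epochs = 14L, output_epochs = 10L) {
  n <- length(mels)
  if (n < 1L) stop("night contains no epochs")
  plan <- window_plan(n, as.integer(input_epochs), as.integer(output_epochs))
  lapply(plan, function(p) {
    structure(list(epochs = mels[p$input_idx],
                   input_idx = p$input_idx,
                   output_idx = p$output_idx),
              class = "mel_window")
  })
}
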