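# Home-noise corruption: SNR-controlled additive mixing of concatenated
# noise clips, plus pitch-shift augmentation.

#' Nine home-noise categories
#'
#' Category labels used by the noise library and the synthetic noise
#' generator.
#'
#' @format Character vector of length 9.
#' @export
noise_categories <- c("home_appliance", "room_noise", "contents", "clock",
                      "speech", "animal", "air_conditioner_fan",
                      "rain_wind", "car_motorbike")

#' Mean signal power
#'
#' Mean of squared amplitudes, the power estimator used for all SNR
#' computations in the package (one global value per window, no
#' frame-wise tracking).
#'
#' @param audio An [audio_signal()] or numeric vector.
#' @return Mean squared amplitude.
#' @export
mean_power <- function(audio) {
  x <- if (inherits(audio, "audio_signal")) audio$samples else as.numeric(audio)
  if (length(x) == 0L) stop("cannot compute power of an empty signal")
  mean(x^2)
}

#' Gain that scales noise to a target SNR
#'
#' Returns `g` such that `signal_power / (g^2 * noise_power)` equals
#' `10^(target_db / 10)`.
#'
#' @param signal_power,noise_power Mean powers, both > 0.
#' @param target_db Target signal-to-noise ratio in dB.
#' @return Scalar gain to apply to the noise.
#' @export
snr_gain <- function(signal_power, noise_power, target_db) {
  stop_if_not_scalar_number(signal_power, "signal_power", 0, strict_min = TRUE)
  stop_if_not_scalar_number(noise_power, "noise_power", 0, strict_min = TRUE)
  stop_if_not_scalar_number(target_db, "target_db")
  sqrt(signal_power / (noise_power * 10^(target_db / 10)))
}

#' Noise-clip library
#'
#' A collection of noise clips with category tags and a disjoint
#' train/test split. Build one from a manifest CSV
#' (`path,category,split`) of WAV clips, or synthesize one with
#' [synth_noise_library()].
#'
#' @param manifest Path to a manifest CSV, or a data frame with columns
#'   `path`, `category`, `split`.
#' @param rate Sample rate clips are resampled to on load.
#' @return Object of class `noise_library`: clips (list of
#'   [audio_signal()]), `category`, `split`, `rate`.
#' @export
noise_library <- function(manifest, rate = 4000) {
  df <- if (is.character(manifest)) read.csv(manifest, stringsAsFactors = FALSE)
        else as.data.frame(manifest)
  req <- c("path", "category", "split")
  if (!all(req %in% names(df)))
    stop("noise manifest needs columns: ", paste(req, collapse = ", "))
  clips <- lapply(df$path, load_audio, target_rate = rate)
  new_noise_library(clips, df$category, df$split, rate)
}

new_noise_library <- function(clips, category, split, rate, kind = NULL) {
  stopifnot(length(clips) == length(category), length(category) == length(split),
            all(split %in% c("train", "test")))
  structure(list(clips = clips, category = as.character(category),
                 split = as.character(split), rate = rate,
                 kind = kind %||% rep(NA_character_, length(clips))),
            class = "noise_library")
}

#' @export
print.noise_library <- function(x, ...) {
  cat(sprintf("<noise_library: %d clips, %d categories, %d train / %d test, %g Hz>\n",
              length(x$clips), length(unique(x$category)),
              sum(x$split == "train"), sum(x$split == "test"), x$rate))
  invisible(x)
}

#' Sample a noise cover of a given length
#'
#' Draws clips (with replacement) uniformly from the eligible categories of
#' the requested split and concatenates them until the total duration
#' reaches the requested cover length, then truncates to exactly that
#' length. This mirrors covering a 7-minute (14-epoch) input window by
#' sampling noise until enough is available.
#'
#' @param library A [noise_library()].
#' @param needed_sec Cover length in seconds.
#' @param categories Subset of [noise_categories] to draw from (default:
#'   all present).
#' @param split `"train"` (default) or `"test"`.
#' @param seed Integer seed; the draw is reproducible.
#' @return An [audio_signal()] of exactly `needed_sec` seconds.
#' @export
sample_noise_cover <- function(library, needed_sec, categories = NULL,
                               split = "train", seed = NULL) {
  stopifnot(inherits(library, "noise_library"))
  stop_if_not_scalar_number(needed_sec, "needed_sec", 0, strict_min = TRUE)
  eligible <- which(library$split == split &
                    (if (is.null(categories)) TRUE
                     else library$category %in% categories))
  if (length(eligible) == 0L)
    stop("no eligible noise clips for split '", split, "'",
         if (!is.null(categories))
           paste0(" in categories: ", paste(categories, collapse = ", ")))
  needed <- as.integer(round(needed_sec * library$rate))
  with_seed(seed, {
    parts <- list(); total <- 0L
    while (total < needed) {
      i <- eligible[sample.int(length(eligible), 1L)]
      parts[[length(parts) + 1L]] <- library$clips[[i]]$samples
      total <- total + length(library$clips[[i]]$samples)
    }
    audio_signal_fast(unlist(parts, use.names = FALSE)[seq_len(needed)], library$rate)
  })
}

#' Corrupt a clean signal with home noise at a target SNR
#'
#' Samples a noise cover of the same length as the clean input, scales it
#' with [snr_gain()] and adds it, so the realized SNR equals `snr_db`
#' exactly (by the mean-power definition).
#'
#' @param clean Clean [audio_signal()] with nonzero power.
#' @param library A [noise_library()] at the same rate.
#' @param snr_db Target SNR in dB; `Inf` returns the clean signal.
#' @param categories,split,seed Passed to [sample_noise_cover()].
#' @return The corrupted [audio_signal()].
#' @export
corrupt <- function(clean, library, snr_db, categories = NULL,
                    split = "train", seed = NULL) {
  stopifnot(inherits(clean, "audio_signal"))
  if (is.infinite(snr_db) && snr_db > 0) return(clean)
  if (abs(library$rate - clean$rate) > 1e-6)
    stop("noise library rate does not match the clean signal rate")
  cover <- sample_noise_cover(library, duration(clean), categories, split, seed)
  g <- snr_gain(mean_power(clean), mean_power(cover), snr_db)
  audio_signal_fast(clean$samples + g * cover$samples, clean$rate)
}

#' Pitch-shift augmentation
#'
#' Shifts the pitch of a signal by a number of semitones while preserving
#' its duration, using granular resampling: the signal is cut into short
#' overlapping grains, each grain is resampled by `2^(semitones/12)`
#' (scaling all frequencies by that factor) from its original time anchor,
#' and grains are crossfaded back together so global timing is unchanged.
#' This is an augmentation primitive: within-grain frequency scaling is
#' exact, grain boundaries introduce a small broadband floor.
#'
#' @param audio An [audio_signal()].
#' @param semitones Shift in semitones, within \[-12, 12\].
#' @param grain_sec Grain length in seconds (default 0.5).
#' @return An [audio_signal()] of identical length and rate.
#' @export
pitch_shift <- function(audio, semitones, grain_sec = 0.5) {
  stopifnot(inherits(audio, "audio_signal"))
  stop_if_not_scalar_number(semitones, "semitones")
  if (abs(semitones) > 12) stop("|semitones| must be <= 12")
  if (semitones == 0) return(audio)
  x <- audio$samples
  n <- length(x)
  r <- 2^(semitones / 12)
  G <- max(64L, as.integer(round(grain_sec * audio$rate)))
  Fd <- min(G %/% 2L, max(8L, as.integer(round(0.04 * audio$rate))))
  gl <- G + Fd                                   # grain length incl. crossfade
  starts <- seq(0L, n - 1L, by = G)              # grain anchors (0-based)
  pos <- outer((0:(gl - 1L)) * r, starts, `+`)   # source read positions
  pos <- pmin(pmax(pos, 0), n - 1L)
  ip <- floor(pos); fr <- pos - ip
  v <- x[ip + 1L] * (1 - fr) + x[pmin(ip + 2L, n)] * fr
  dim(v) <- dim(pos)
  ramp <- seq(0, 1, length.out = Fd + 2L)[2:(Fd + 1L)]
  w <- c(ramp, rep(1, gl - 2L * Fd), rev(ramp))
  v <- v * w
  out <- numeric(n + gl); wsum <- numeric(n + gl)
  ng <- length(starts)
  for (g in 1:2) {                   # odd/even grains never overlap each other
    sel <- seq(g, ng, by = 2L)
    tgt <- as.vector(outer(seq_len(gl), starts[sel], `+`))
    out[tgt] <- out[tgt] + as.vector(v[, sel, drop = FALSE])
    wsum[tgt] <- wsum[tgt] + rep(w, length(sel))
  }
  wsum[wsum < 1e-8] <- 1
  audio_signal_fast((out / wsum)[seq_len(n)], audio$rate)
}
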