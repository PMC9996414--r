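# Robustness experiments: SNR sweeps, noise-group cross-testing and the
# noise-fraction saturation curve.

# Pooled macro F1 of a detector over nights whose mels are supplied.
pooled_macro_f1 <- function(det, mels_per_night, labels_per_night) {
  prd <- lapply(mels_per_night, function(m)
    as.character(predict_night(det, m)$predicted_class))
  suppressWarnings(epoch_metrics(confusion_matrix(
    unlist(lapply(labels_per_night, as.character)), unlist(prd)))$macro_f1)
}

#' Macro F1 versus SNR for one or more models
#'
#' For each test night, `covers_per_night` noise covers are drawn from the
#' test split of the library; for every SNR in the grid the same covers
#' are rescaled with [snr_gain()] and added, so the sweep is paired across
#' SNR values, and epochs are pooled over nights and covers before the
#' macro F1 is computed. `Inf` in the grid means the clean (no-noise)
#' condition.
#'
#' @param models Named list of `osa_model` / `osa_detector` objects (e.g.
#'   `list(consistency = ..., control = ...)`).
#' @param test_nights List of `osa_night` objects with audio.
#' @param noise A [noise_library()].
#' @param snrs SNR grid in dB; default clean plus 5 down to -30.
#' @param categories Optional category subset for the covers.
#' @param covers_per_night Independent noise covers per night (pooled).
#' @param mel_cfg The [mel_config()] used for features.
#' @param seed Seed for the per-night covers.
#' @return Data frame (`model`, `snr_db`, `macro_f1`), one row per model
#'   and SNR.
#' @export
run_snr_sweep <- function(models, test_nights, noise,
                          snrs = c(Inf, 5, 0, -5, -10, -15, -20, -25, -30),
                          categories = NULL, covers_per_night = 1L,
                          mel_cfg = mel_config(), seed = 1L) {
  stopifnot(length(models) >= 1L, !is.null(names(models)), length(snrs) >= 1L,
            covers_per_night >= 1L)
  grid <- expand.grid(night = seq_along(test_nights),
                      rep = seq_len(covers_per_night))
  seeds <- derive_seeds(seed, nrow(grid))
  covers <- lapply(seq_len(nrow(grid)), function(k) {
    sample_noise_cover(noise, duration(test_nights[[grid$night[k]]]$audio),
                       categories = categories, split = "test",
                       seed = seeds[k])
  })
  labels_once <- lapply(test_nights, `[[`, "labels")
  out <- data.frame()
  for (snr in snrs) {
    if (is.infinite(snr) && snr > 0) {
      mels <- lapply(test_nights, `[[`, "mels")
      labels <- labels_once
    } else {
      mels <- lapply(seq_len(nrow(grid)), function(k) {
        nt <- test_nights[[grid$night[k]]]
        g <- snr_gain(mean_power(nt$audio), mean_power(covers[[k]]), snr)
        night_mels(audio_signal_fast(nt$audio$samples + g * covers[[k]]$samples,
                                     nt$audio$rate), mel_cfg)
      })
      labels <- labels_once[grid$night]
    }
    for (nm in names(models)) {
      f1 <- pooled_macro_f1(as_detector(models[[nm]]), mels, labels)
      out <- rbind(out, data.frame(model = nm, snr_db = snr, macro_f1 = f1))
    }
  }
  out
}

#' Noise-group cross-testing matrix
#'
#' Trains one consistency model per noise group (only that group's clips
#' are drawn during training) plus one all-group model, then evaluates
#' every model on test sets corrupted with each group and with all groups
#' combined, at a fixed SNR. Diagonal dominance is a soft observation to
#' read off the matrix, not an assertion.
#'
#' @param train_nights,val_nights,test_nights Lists of `osa_night`.
#' @param noise A [noise_library()] covering the groups.
#' @param groups Noise groups (default all nine).
#' @param snr_db Test corruption SNR.
#' @param mel_cfg,det_config,config Pipeline configuration.
#' @param pretrained Optional shared [pretrain_1to1()] checkpoint; fitted
#'   once internally when NULL.
#' @param seed Seed for the test covers.
#' @return Matrix of macro F1 with rows `c(groups, "all_groups")` and
#'   columns `c(groups, "combined")`.
#' @export
run_noise_group_matrix <- function(train_nights, val_nights, test_nights,
                                   noise, groups = noise_categories,
                                   snr_db = -10, mel_cfg = mel_config(),
                                   det_config = detector_config(n_mels = mel_cfg$n_mels),
                                   config = training_config(),
                                   pretrained = NULL, seed = 1L) {
  if (is.null(pretrained))
    pretrained <- pretrain_1to1(train_nights, val_nights, det_config, config)
  labels <- lapply(test_nights, `[[`, "labels")
  test_sets <- c(as.list(groups), list(groups))
  names(test_sets) <- c(groups, "combined")
  seeds <- derive_seeds(seed, length(test_sets) * length(test_nights))
  test_mels <- lapply(seq_along(test_sets), function(g) {
    lapply(seq_along(test_nights), function(i) {
      nt <- test_nights[[i]]
      corr <- corrupt(nt$audio, noise, snr_db, categories = test_sets[[g]],
                      split = "test",
                      seed = seeds[(g - 1L) * length(test_nights) + i])
      night_mels(corr, mel_cfg)
    })
  })
  model_sets <- c(as.list(groups), list(groups))
  names(model_sets) <- c(groups, "all_groups")
  out <- matrix(NA_real_, length(model_sets), length(test_sets),
                dimnames = list(model = names(model_sets),
                                test = names(test_sets)))
  for (m in seq_along(model_sets)) {
    lib_m <- subset_noise_library(noise, categories = model_sets[[m]])
    ck <- train_14to10(pretrained, train_nights, val_nights, noise = lib_m,
                       mel_cfg = mel_cfg, det_config = det_config,
                       config = config)
    for (g in seq_along(test_sets))
      out[m, g] <- pooled_macro_f1(as_detector(ck), test_mels[[g]], labels)
  }
  out
}

# Restrict a noise library to categories and/or a clip subset.
subset_noise_library <- function(library, categories = NULL, keep_idx = NULL) {
  sel <- seq_along(library$clips)
  if (!is.null(categories)) sel <- sel[library$category[sel] %in% categories]
  if (!is.null(keep_idx)) sel <- intersect(sel, keep_idx)
  if (length(sel) == 0L) stop("noise library subset is empty")
  new_noise_library(library$clips[sel], library$category[sel],
                    library$split[sel], library$rate, kind = library$kind[sel])
}

#' Macro F1 versus the fraction of noise clips used in training
#'
#' Trains the consistency model with nested subsets of the training noise
#' clips (a fixed seeded permutation, truncated at each fraction) and
#' evaluates each on the same noise-corrupted test set. Fraction 0 is the
#' clean-only control model by definition.
#'
#' @param train_nights,val_nights,test_nights Lists of `osa_night`.
#' @param noise A [noise_library()].
#' @param fractions Fractions of training noise clips (default 0, 0.05,
#'   0.1, 0.2, 0.5, 1).
#' @param snr_db Test corruption SNR.
#' @param mel_cfg,det_config,config Pipeline configuration.
#' @param pretrained Optional shared pretraining checkpoint.
#' @param seed Seed for the clip permutation and the test covers.
#' @return Data frame (`fraction`, `n_clips`, `macro_f1`).
#' @export
run_noise_fraction_curve <- function(train_nights, val_nights, test_nights,
                                     noise,
                                     fractions = c(0, 0.05, 0.1, 0.2, 0.5, 1),
                                     snr_db = -10, mel_cfg = mel_config(),
                                     det_config = detector_config(n_mels = mel_cfg$n_mels),
                                     config = training_config(),
                                     pretrained = NULL, seed = 1L) {
  if (is.null(pretrained))
    pretrained <- pretrain_1to1(train_nights, val_nights, det_config, config)
  train_clips <- which(noise$split == "train")
  perm <- with_seed(seed, sample(train_clips))
  labels <- lapply(test_nights, `[[`, "labels")
  seeds <- derive_seeds(seed + 1L, length(test_nights))
  test_mels <- lapply(seq_along(test_nights), function(i) {
    corr <- corrupt(test_nights[[i]]$audio, noise, snr_db, split = "test",
                    seed = seeds[i])
    night_mels(corr, mel_cfg)
  })
  out <- data.frame()
  for (f in fractions) {
    n_keep <- ceiling(f * length(perm))
    ck <- if (n_keep == 0L) {
      train_14to10(pretrained, train_nights, val_nights, noise = NULL,
                   mel_cfg = mel_cfg, det_config = det_config, config = config)
    } else {
      lib_f <- subset_noise_library(noise,
                                    keep_idx = c(perm[seq_len(n_keep)],
                                                 which(noise$split == "test")))
      train_14to10(pretrained, train_nights, val_nights, noise = lib_f,
                   mel_cfg = mel_cfg, det_config = det_config, config = config)
    }
    f1 <- pooled_macro_f1(as_detector(ck), test_mels, labels)
    out <- rbind(out, data.frame(fraction = f, n_clips = n_keep, macro_f1 = f1))
  }
  out
}
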