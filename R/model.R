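# The user-facing model: preparing labeled nights, fitting the two-step
# detector, and predicting whole nights.

#' Prepare one labeled night for training or evaluation
#'
#' Filters the annotations to obstructive events, labels the epoch grid,
#' and computes per-epoch mel spectrograms.
#'
#' @param audio Whole-night [audio_signal()] (its rate must match
#'   `mel_cfg$sample_rate`).
#' @param events A [respiratory_events()] data frame (unfiltered is fine).
#' @param mel_cfg A [mel_config()].
#' @param subject_id Optional identifier.
#' @param reference_ahi Optional reference AHI attached to the night.
#' @param keep_audio Keep the raw audio in the night object (needed for
#'   consistency training and corrupted evaluation).
#' @return A list of class `osa_night`: `mels`, `labels`, `audio` (or
#'   NULL), `hours` (epochs on the grid times 30 s), `id`,
#'   `reference_ahi`.
#' @export
prepare_night <- function(audio, events, mel_cfg = mel_config(),
                          subject_id = NULL, reference_ahi = NULL,
                          keep_audio = TRUE) {
  grid <- epoch_grid(duration(audio))
  labels <- label_epochs(filter_obstructive(events), grid)$label
  mels <- night_mels(audio, mel_cfg, grid)
  structure(list(mels = mels, labels = labels,
                 audio = if (keep_audio) audio else NULL,
                 hours = grid$n_epochs * grid$epoch_length / 3600,
                 id = subject_id, reference_ahi = reference_ahi),
            class = "osa_night")
}

#' Prepare a whole cohort of nights
#'
#' Accepts either an in-memory [generate_cohort()] result or a manifest
#' (data frame or CSV path with columns `subject_id, audio_path,
#' annotation_path, reference_ahi, hours`).
#'
#' @param cohort A `synthetic_cohort` or manifest.
#' @param mel_cfg A [mel_config()].
#' @param keep_audio Keep raw audio in each night.
#' @return List of `osa_night` objects.
#' @export
prepare_cohort <- function(cohort, mel_cfg = mel_config(), keep_audio = TRUE) {
  if (inherits(cohort, "synthetic_cohort")) {
    return(lapply(seq_along(cohort$nights), function(i) {
      n <- cohort$nights[[i]]
      prepare_night(n$audio, n$events, mel_cfg,
                    subject_id = cohort$manifest$subject_id[i],
                    reference_ahi = n$reference_ahi, keep_audio = keep_audio)
    }))
  }
  mf <- if (is.character(cohort)) read.csv(cohort, stringsAsFactors = FALSE)
        else as.data.frame(cohort)
  lapply(seq_len(nrow(mf)), function(i) {
    prepare_night(load_audio(mf$audio_path[i], mel_cfg$sample_rate),
                  read_events(mf$annotation_path[i]), mel_cfg,
                  subject_id = mf$subject_id[i],
                  reference_ahi = mf$reference_ahi[i],
                  keep_audio = keep_audio)
  })
}

#' Generate and prepare a synthetic cohort night by night
#'
#' Streams through a [cohort_plan()]: each night is generated, labeled and
#' converted to mel features, and its raw audio is dropped unless
#' `keep_audio = TRUE`, so memory stays bounded for large cohorts.
#'
#' @param n_subjects Number of subjects.
#' @param mel_cfg A [mel_config()].
#' @param keep_audio Keep raw audio in each night (needed for corruption).
#' @param duration_hours,strata_props,seed Passed to [cohort_plan()].
#' @param sample_rate Sample rate in Hz.
#' @param ... Further [night_spec()] arguments.
#' @return List of `osa_night` objects (with `reference_ahi` set).
#' @export
prepare_synthetic_cohort <- function(n_subjects, mel_cfg,
                                     keep_audio = FALSE,
                                     duration_hours = 1,
                                     strata_props = c(0.18, 0.32, 0.32, 0.18),
                                     sample_rate = 4000, seed = 1L, ...) {
  plan <- cohort_plan(n_subjects, strata_props, duration_hours, seed)
  lapply(seq_len(n_subjects), function(i) {
    nt <- generate_night(night_spec(duration_hours = duration_hours,
                                    event_rate = plan$target_ahi[i],
                                    seed = plan$seed[i], ...),
                         sample_rate)
    prepare_night(nt$audio, nt$events, mel_cfg,
                  subject_id = plan$subject_id[i],
                  reference_ahi = nt$reference_ahi,
                  keep_audio = keep_audio)
  })
}

#' Severity-stratified train/test split of a cohort
#'
#' Allocates test nights evenly across the AHI severity strata (normal /
#' mild / moderate / severe by [classify_severity()]), the usual design
#' for OSA evaluation sets, which keeps small test sets representative
#' instead of concentrating one severity class by chance.
#'
#' @param nights List of `osa_night` objects with `reference_ahi`.
#' @param n_test Number of test nights.
#' @param seed Integer seed for the within-stratum draws.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(nights, n_test, seed = 1L) {
  ahis <- vapply(nights, function(n) n$reference_ahi %||% NA_real_, 0)
  if (anyNA(ahis)) stop("all nights need a reference_ahi for a stratified split")
  stopifnot(n_test >= 1L, n_test < length(nights))
  sev <- as.integer(classify_severity(ahis))
  test_idx <- with_seed(seed, {
    strata <- split(seq_along(nights), sev)
    strata <- strata[order(-vapply(strata, length, 0L))]
    picked <- integer(0)
    while (length(picked) < n_test) {
      for (s in seq_along(strata)) {
        avail <- setdiff(strata[[s]], picked)
        if (length(avail) && length(picked) < n_test)
          picked <- c(picked, avail[sample.int(length(avail), 1L)])
      }
    }
    sort(picked)
  })
  list(train = setdiff(seq_along(nights), test_idx), test = test_idx)
}

#' Fit the OSA event detector
#'
#' Runs the two-step training procedure on a set of labeled nights:
#' single-epoch pretraining of the feature extractor, then 14-to-10
#' training of the full detector, with home-noise consistency when a
#' noise library is supplied (`noise = NULL` or `lambda = 0` trains the
#' clean-only control model). A fraction of nights is held out for
#' validation and checkpoint selection.
#'
#' @param nights List of `osa_night` objects (see [prepare_night()]).
#' @param noise A [noise_library()] or `NULL`.
#' @param mel_cfg The [mel_config()] the nights were prepared with.
#' @param det_config A [detector_config()]; its `n_mels` must match
#'   `mel_cfg`.
#' @param config A [training_config()].
#' @return An object of class `osa_model`.
#' @export
osa_train <- function(nights, noise = NULL, mel_cfg = mel_config(),
                      det_config = detector_config(n_mels = mel_cfg$n_mels),
                      config = training_config()) {
  stopifnot(length(nights) >= 2L)
  if (det_config$n_mels != mel_cfg$n_mels)
    stop("det_config$n_mels must match mel_cfg$n_mels")
  n_val <- max(1L, round(config$val_fraction * length(nights)))
  if (n_val >= length(nights)) stop("not enough nights for a validation split")
  val_idx <- with_seed(config$seed, sort(sample.int(length(nights), n_val)))
  val_nights <- nights[val_idx]
  train_nights <- nights[-val_idx]

  pre <- pretrain_1to1(train_nights, val_nights, det_config, config)
  ckpt <- train_14to10(pre, train_nights, val_nights, noise = noise,
                       mel_cfg = mel_cfg, det_config = det_config,
                       config = config)
  structure(list(detector = structure(list(config = ckpt$config,
                                           params = ckpt$params),
                                      class = "osa_detector"),
                 pretrain = pre, training = ckpt,
                 val_macro_f1 = ckpt$val_macro_f1,
                 mel_cfg = mel_cfg, config = config,
                 val_idx = val_idx,
                 consistency = !is.null(noise) && config$lambda > 0),
            class = "osa_model")
}

#' Fit the detector with seeded random restarts
#'
#' Runs [osa_train()] `n_restarts` times with seeds derived from the
#' master seed and returns the model with the highest validation macro
#' F1 — the usual guard against an unlucky initialization.
#'
#' @param nights,noise,mel_cfg Passed to [osa_train()].
#' @param n_restarts Number of restarts (default 3).
#' @param det_config,config Base configurations; their seeds are replaced
#'   by the derived restart seeds.
#' @param seed Master seed.
#' @return The selected `osa_model`, with a `restart_val_f1` element
#'   holding every restart's validation score.
#' @export
osa_train_restarts <- function(nights, noise = NULL, mel_cfg = mel_config(),
                               n_restarts = 3L,
                               det_config = detector_config(n_mels = mel_cfg$n_mels),
                               config = training_config(), seed = 1L) {
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL; scores <- numeric(0)
  for (s in seeds) {
    det_config$seed <- s; config$seed <- s
    m <- osa_train(nights, noise = noise, mel_cfg = mel_cfg,
                   det_config = det_config, config = config)
    scores <- c(scores, m$val_macro_f1)
    if (is.null(best) || m$val_macro_f1 > best$val_macro_f1) best <- m
  }
  best$restart_val_f1 <- scores
  best
}

#' @export
print.osa_model <- function(x, ...) {
  cat(sprintf("OSA event detector (%s)\n",
              if (x$consistency) "home-noise consistency training"
              else "clean-only control training"))
  cat(sprintf("  preset %s, %d->%d epochs, %d mel bands\n",
              x$detector$config$preset, x$detector$config$input_epochs,
              x$detector$config$output_epochs, x$detector$config$n_mels))
  cat(sprintf("  best checkpoint: training epoch %d, validation macro F1 %.3f\n",
              x$training$epoch, x$val_macro_f1))
  invisible(x)
}

#' @export
summary.osa_model <- function(object, ...) {
  cat("Two-step training summary\n\n1-to-1 pretraining:\n")
  print(object$pretrain$history, row.names = FALSE)
  cat("\n14-to-10 training:\n")
  print(object$training$history, row.names = FALSE)
  if (length(object$training$snr_log))
    cat(sprintf("\nSNR draws: n = %d, range [%.1f, %.1f] dB\n",
                length(object$training$snr_log),
                min(object$training$snr_log), max(object$training$snr_log)))
  invisible(object)
}

#' Predict epoch classes for a night
#'
#' @param object An `osa_model`.
#' @param newdata An `osa_night`, a list of per-epoch mel matrices, or an
#'   [audio_signal()] (features are computed with the model's
#'   [mel_config()]).
#' @param ... Unused.
#' @return A [predict_night()] data frame.
#' @export
predict.osa_model <- function(object, newdata, ...) {
  mels <- if (inherits(newdata, "osa_night")) newdata$mels
          else if (inherits(newdata, "audio_signal"))
            night_mels(newdata, object$mel_cfg)
          else newdata
  predict_night(object$detector, mels,
                subject_id = if (inherits(newdata, "osa_night")) newdata$id)
}

#' @export
plot.osa_model <- function(x, ...) {
  h <- x$training$history
  graphics::plot(h$epoch, h$val_macro_f1, type = "b", pch = 19,
                 xlab = "training epoch", ylab = "validation macro F1",
                 ylim = c(0, 1), ...)
  graphics::abline(v = x$training$epoch, lty = 2, col = "grey")
  invisible(x)
}

#' Persist / restore a detector checkpoint as JSON
#'
#' The file is self-describing: it stores the detector configuration and
#' all parameter matrices.
#'
#' @param x An `osa_detector`, `osa_checkpoint` or `osa_model`.
#' @param path JSON path.
#' @return `path` (write) or an `osa_detector` (read).
#' @export
write_checkpoint <- function(x, path) {
  det <- as_detector(x)
  cfg <- unclass(det$config)
  pl <- lapply(det$params, function(p) {
    if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
    else list(dim = length(p), data = as.vector(p))
  })
  jsonlite::write_json(list(config = cfg, params = pl), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- do.call(detector_config,
                 j$config[c("input_epochs", "output_epochs", "n_classes",
                            "preset", "n_mels", "norm_center", "norm_scale",
                            "seed")])
  params <- lapply(j$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  structure(list(config = cfg, params = params), class = "osa_detector")
}

#' Write night predictions to CSV
#'
#' @param prediction A [predict_night()] data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(prediction, path) {
  write.csv(as.data.frame(prediction), path, row.names = FALSE)
  invisible(path)
}
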