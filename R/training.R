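# Losses and the 2-step training procedure: clean 1-to-1 pretraining of
# the feature extractor, then 14-to-10 training with home-noise
# consistency regularization.

#' Class weights for the imbalanced event classes
#'
#' Defaults 1.0 / 1.3 / 2.1 for no-event / apnea / hypopnea penalize
#' mistakes on the rare event classes more than on the dominant no-event
#' class.
#'
#' @param no_event,apnea,hypopnea Positive weights.
#' @return Named numeric vector in [osa_classes] order.
#' @export
class_weights <- function(no_event = 1.0, apnea = 1.3, hypopnea = 2.1) {
  w <- c(no_event = no_event, apnea = apnea, hypopnea = hypopnea)
  if (any(w <= 0)) stop("class weights must be positive")
  w
}

as_prob_matrix <- function(pred) {
  p <- as.matrix(pred)
  if (ncol(p) != 3L && nrow(p) == 3L) p <- t(p)
  if (ncol(p) != 3L) stop("predictions must be probability triples")
  p
}

#' Class-weighted cross-entropy
#'
#' Mean over epochs of `-w(label) * log p(label)`. Zero probability at a
#' true label is clamped to `epsilon` with a warning.
#'
#' @param pred Matrix of probability triples, one row per epoch (columns
#'   in [osa_classes] order); a 3-row matrix is transposed.
#' @param labels Factor or character vector of true classes.
#' @param weights [class_weights()].
#' @param epsilon Clamp for zero probabilities.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(pred, labels, weights = class_weights(),
                                   epsilon = 1e-12) {
  p <- as_prob_matrix(pred)
  y <- match(as.character(labels), osa_classes)
  if (anyNA(y)) stop("labels must be among: ", paste(osa_classes, collapse = ", "))
  if (length(y) != nrow(p)) stop("predictions and labels differ in length")
  pt <- p[cbind(seq_along(y), y)]
  if (any(pt <= 0)) {
    warning("zero probability at a true label; clamped to epsilon")
    pt <- pmax(pt, epsilon)
  }
  mean(-weights[y] * log(pt))
}

#' Consistency loss between clean and corrupted predictions
#'
#' Mean squared error over all epochs and classes between the two
#' probability matrices.
#'
#' @param clean_pred,corrupted_pred Probability matrices of equal shape.
#' @return Scalar loss.
#' @export
consistency_loss <- function(clean_pred, corrupted_pred) {
  p <- as_prob_matrix(clean_pred); q <- as_prob_matrix(corrupted_pred)
  if (!all(dim(p) == dim(q))) stop("prediction shapes differ")
  mean((p - q)^2)
}

#' Combined training loss
#'
#' The weighted sum `ce + lambda * cons` of the supervised cross-entropy
#' term (clean branch) and the consistency term.
#'
#' @param ce,cons Loss components.
#' @param lambda Consistency weight (default 1: plain summation).
#' @return Scalar loss.
#' @export
combined_loss <- function(ce, cons, lambda = 1) ce + lambda * cons

#' Training configuration
#'
#' @param lr_pretrain Initial learning rate of 1-to-1 pretraining (0.01),
#'   decayed by `1/lr_decay_factor` whenever validation macro F1 has not
#'   increased for `patience` consecutive epochs.
#' @param lr_decay_factor Plateau decay divisor (10).
#' @param patience Stagnant validation epochs before decay (3).
#' @param n_training_epochs Fixed number of training epochs (10), for both
#'   steps.
#' @param momentum SGD momentum.
#' @param clip_norm Global L2 gradient-norm clip applied before each SGD
#'   update (guards against the very large gradients that low-SNR
#'   corrupted windows can produce).
#' @param batch_epochs Single-epoch batch size for pretraining.
#' @param batch_windows Window batch size for 14-to-10 training.
#' @param window_stride Stride (in epochs) of the training-window tiling;
#'   `NULL` uses the non-overlapping inference tiling, smaller values
#'   create overlapping training windows (more views per night).
#' @param max_lr Peak learning rate of the slanted-triangular schedule in
#'   14-to-10 training. 0.05 suits clean (control) training; consistency
#'   fine-tuning is more stable at 0.02, where the supervised term cannot
#'   simply memorize the clean windows and starve the consistency term.
#' @param stlr_warmup Warmup fraction of the slanted-triangular schedule.
#' @param stlr_ratio Ratio between the peak and the final learning rate.
#' @param lambda Consistency-loss weight (0 disables the corrupted branch:
#'   the control-model path).
#' @param snr_range Training SNR range in dB; each iteration draws one SNR
#'   uniformly from it.
#' @param pitch_prob Probability of pitch-shift augmentation per window
#'   per iteration (applied to the clean input before corruption).
#' @param pitch_range Semitone range of the augmentation.
#' @param weights [class_weights()].
#' @param val_fraction Fraction of training nights held out for
#'   validation (at least one night).
#' @param unfreeze Gradually unfreeze the pretrained extractor, one stage
#'   per training epoch, during 14-to-10 training.
#' @param consistency_stop_gradient Treat the clean-branch prediction as a
#'   fixed target in the consistency term (gradient flows only through the
#'   corrupted branch). This is the standard guard against the collapsed
#'   solution in which both branches converge to a constant output; with
#'   `FALSE` the consistency gradient flows through both branches.
#' @param seed Master seed for batching, SNR draws, noise sampling and
#'   augmentation.
#' @return A list of class `training_config`.
#' @export
training_config <- function(lr_pretrain = 0.01, lr_decay_factor = 10,
                            patience = 3L, n_training_epochs = 10L,
                            momentum = 0.9, clip_norm = 1,
                            batch_epochs = 32L,
                            batch_windows = 4L, window_stride = NULL,
                            max_lr = 0.05,
                            stlr_warmup = 0.1, stlr_ratio = 32,
                            lambda = 1.0, snr_range = c(-20, 5),
                            pitch_prob = 0.5, pitch_range = c(-2, 2),
                            weights = class_weights(), val_fraction = 0.1,
                            unfreeze = TRUE, consistency_stop_gradient = TRUE,
                            seed = 1L) {
  stopifnot(lr_pretrain > 0, lr_decay_factor > 1, patience >= 1,
            n_training_epochs >= 1, momentum >= 0, momentum < 1,
            max_lr > 0, stlr_warmup > 0, stlr_warmup < 1, stlr_ratio >= 1,
            lambda >= 0, length(snr_range) == 2L, snr_range[1] < snr_range[2],
            pitch_prob >= 0, pitch_prob <= 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(lr_pretrain = lr_pretrain, lr_decay_factor = lr_decay_factor,
                 patience = as.integer(patience),
                 n_training_epochs = as.integer(n_training_epochs),
                 momentum = momentum, clip_norm = clip_norm,
                 batch_epochs = as.integer(batch_epochs),
                 batch_windows = as.integer(batch_windows),
                 window_stride = window_stride, max_lr = max_lr,
                 stlr_warmup = stlr_warmup, stlr_ratio = stlr_ratio,
                 lambda = lambda, snr_range = snr_range,
                 pitch_prob = pitch_prob, pitch_range = pitch_range,
                 weights = weights, val_fraction = val_fraction,
                 unfreeze = isTRUE(unfreeze),
                 consistency_stop_gradient = isTRUE(consistency_stop_gradient),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Plateau learning-rate schedule
#'
#' Given a validation-score history, returns the learning rate of each
#' completed epoch: the rate is divided by `decay_factor` whenever the
#' score has not increased for `patience` consecutive epochs (the counter
#' resets after a decay).
#'
#' @param scores Numeric vector of per-epoch validation scores.
#' @param initial_lr Starting learning rate.
#' @param decay_factor Division factor per decay.
#' @param patience Number of consecutive non-improving epochs tolerated.
#' @return Numeric vector: learning rate in force during each epoch.
#' @export
plateau_schedule <- function(scores, initial_lr = 0.01, decay_factor = 10,
                             patience = 3L) {
  lr <- initial_lr
  best <- -Inf
  stagnant <- 0L
  out <- numeric(length(scores))
  for (i in seq_along(scores)) {
    out[i] <- lr
    if (scores[i] > best) {
      best <- scores[i]; stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= patience) {
        lr <- lr / decay_factor
        stagnant <- 0L
      }
    }
  }
  out
}

#' Slanted-triangular learning rate
#'
#' Linear warmup to `max_lr` over the first `warmup` fraction of
#' iterations, then linear decay to `max_lr / ratio`.
#'
#' @param t Iteration index (1-based), vectorized.
#' @param total Total number of iterations.
#' @param max_lr Peak learning rate.
#' @param warmup Warmup fraction.
#' @param ratio Peak-to-floor ratio.
#' @return Learning rate(s).
#' @export
slanted_triangular_lr <- function(t, total, max_lr = 0.1, warmup = 0.1,
                                  ratio = 32) {
  cut <- max(1, floor(total * warmup))
  p <- ifelse(t <= cut, t / cut, pmax(0, (total - t) / max(1, total - cut)))
  max_lr * (1 + p * (ratio - 1)) / ratio
}

# --- SGD machinery -----------------------------------------------------------

sgd_step <- function(params, grads, vel, lr, momentum, trainable,
                     clip_norm = Inf) {
  if (is.finite(clip_norm)) {
    gn <- sqrt(sum(vapply(grads[names(grads) %in% trainable],
                          function(g) sum(g^2), 0)))
    if (gn > clip_norm)
      grads <- lapply(grads, function(g) g * (clip_norm / gn))
  }
  for (nm in names(grads)) {
    if (!nm %in% trainable) next
    vel[[nm]] <- momentum * vel[[nm]] - lr * grads[[nm]]
    params[[nm]] <- params[[nm]] + vel[[nm]]
  }
  list(params = params, vel = vel)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

label_int <- function(labels) match(as.character(labels), osa_classes)

# dL/dlogits of the weighted CE (mean over epochs), given probs (C x E)
# and integer labels.
ce_grad_logits <- function(probs, y, weights) {
  E <- length(y)
  G <- probs * rep(weights[y], each = nrow(probs))
  G[cbind(y, seq_len(E))] <- G[cbind(y, seq_len(E))] - weights[y]
  G / E
}

# Macro F1 of a detector on a list of nights (clean mels), via stitched
# whole-night prediction.
validation_macro_f1 <- function(det, nights) {
  ref <- list(); prd <- list()
  for (i in seq_along(nights)) {
    np <- predict_night(det, nights[[i]]$mels)
    ref[[i]] <- as.character(nights[[i]]$labels)
    prd[[i]] <- as.character(np$predicted_class)
  }
  suppressWarnings(
    epoch_metrics(confusion_matrix(unlist(ref), unlist(prd)))$macro_f1)
}

# --- step 1: 1-to-1 pretraining ---------------------------------------------

#' Pretrain the feature extractor on single epochs
#'
#' Trains extractor + single-epoch softmax head with class-weighted
#' cross-entropy and SGD under the plateau learning-rate schedule
#' (initial rate `lr_pretrain`, divided by `lr_decay_factor` after
#' `patience` consecutive epochs without validation improvement). The
#' checkpoint with the highest validation macro F1 is returned.
#'
#' @param train_nights,val_nights Lists of nights; each night is a list
#'   with `mels` (per-epoch mel matrices) and `labels` (factor over
#'   [osa_classes]).
#' @param det_config A [detector_config()].
#' @param config A [training_config()].
#' @return A list of class `osa_checkpoint`: `params`, `config`
#'   (detector config), `val_macro_f1`, `epoch`, `history` (per-epoch data
#'   frame: loss, validation macro F1, learning rate).
#' @export
pretrain_1to1 <- function(train_nights, val_nights, det_config = detector_config(),
                          config = training_config()) {
  if (length(train_nights) == 0L) stop("no training nights")
  if (is.null(det_config$norm_center))
    det_config <- fit_input_normalization(det_config, train_nights)
  det <- build_detector(det_config)
  all_mels <- unlist(lapply(train_nights, `[[`, "mels"), recursive = FALSE)
  all_y <- label_int(unlist(lapply(train_nights, function(n) as.character(n$labels))))
  stopifnot(length(all_mels) == length(all_y), length(all_mels) > 0L)
  trainable <- c("Wc", "bc", "Wf", "bf", "Wp", "bp")
  vel <- zero_like(det$params)
  history <- data.frame()
  best <- list(f1 = -Inf, params = det$params, epoch = 0L)
  lr <- config$lr_pretrain
  best_seen <- -Inf; stagnant <- 0L

  with_seed(config$seed, {
    for (ep in seq_len(config$n_training_epochs)) {
      ord <- sample.int(length(all_mels))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_epochs))
      ep_loss <- 0
      for (b in batches) {
        ext <- extractor_forward(det$params, det_config, all_mels[b])
        logits <- det$params$Wp %*% ext$Fm + det$params$bp
        probs <- softmax_cols(logits)
        y <- all_y[b]
        ep_loss <- ep_loss + weighted_cross_entropy(t(probs), osa_classes[y],
                                                    config$weights) * length(b)
        dlogits <- ce_grad_logits(probs, y, config$weights)
        dWp <- dlogits %*% t(ext$Fm)
        dbp <- rowSums(dlogits)
        dFm <- crossprod(det$params$Wp, dlogits)
        g <- extractor_backward(det$params, det_config, ext$cache, dFm)
        g$Wp <- dWp; g$bp <- dbp
        upd <- sgd_step(det$params, g, vel, lr, config$momentum, trainable,
                        config$clip_norm)
        det$params <- upd$params; vel <- upd$vel
      }
      f1 <- pretrain_val_f1(det, val_nights, config)
      history <- rbind(history, data.frame(
        epoch = ep, loss = ep_loss / length(all_mels), val_macro_f1 = f1, lr = lr))
      if (f1 > best$f1) best <- list(f1 = f1, params = det$params, epoch = ep)
      if (f1 > best_seen) { best_seen <- f1; stagnant <- 0L }
      else {
        stagnant <- stagnant + 1L
        if (stagnant >= config$patience) { lr <- lr / config$lr_decay_factor
                                           stagnant <- 0L }
      }
    }
  })
  structure(list(params = best$params, config = det_config,
                 val_macro_f1 = best$f1, epoch = best$epoch, history = history),
            class = "osa_checkpoint")
}

# Validation macro F1 of the 1-to-1 classifier (per single epoch).
pretrain_val_f1 <- function(det, val_nights, config) {
  mels <- unlist(lapply(val_nights, `[[`, "mels"), recursive = FALSE)
  y <- unlist(lapply(val_nights, function(n) as.character(n$labels)))
  ext <- extractor_forward(det$params, det$config, mels)
  probs <- softmax_cols(det$params$Wp %*% ext$Fm + det$params$bp)
  pred <- osa_classes[apply(probs, 2L, which.max)]
  suppressWarnings(epoch_metrics(confusion_matrix(y, pred))$macro_f1)
}

#' @export
print.osa_checkpoint <- function(x, ...) {
  cat(sprintf("<osa_checkpoint: epoch %d, validation macro F1 %.3f>\n",
              x$epoch, x$val_macro_f1))
  invisible(x)
}

# --- step 2: 14-to-10 training ----------------------------------------------

# Assemble the window-level training items of one night. A stride below
# output_epochs tiles overlapping windows (more training views per night
# than the non-overlapping inference tiling).
night_windows <- function(night, input_epochs, output_epochs, stride = NULL) {
  n <- length(night$mels)
  plan <- window_plan(n, input_epochs, output_epochs)
  if (!is.null(stride) && stride < output_epochs && n > output_epochs) {
    ctx <- (input_epochs - output_epochs) %/% 2L
    starts <- unique(pmin(seq(0L, n - 1L, by = stride), n - output_epochs))
    plan <- lapply(starts, function(s) {
      out_idx <- s + seq_len(output_epochs)
      in_idx <- pmin(pmax((s - ctx) + seq_len(input_epochs) - 1L, 0L), n - 1L) + 1L
      list(input_idx = in_idx, output_idx = out_idx)
    })
  }
  lapply(plan, function(p) {
    rng <- range(p$input_idx)
    list(input_idx = p$input_idx, output_idx = p$output_idx,
         labels = as.character(night$labels)[p$output_idx],
         night = night, range = rng)
  })
}

# Precomputation for the consistency fast path. Training-time corruption
# mixes in the linear power-mel domain: for additive independent signals
# the expected power spectrum is the sum of the two power spectra, so
# log(mel_clean_power + g^2 * mel_noise_power) equals the log-mel of the
# waveform mixture up to a zero-mean phase cross-term. Clip epoch mels
# and per-epoch waveform powers are computed once, making each corrupted
# view an elementwise operation instead of an STFT. Test-time corruption
# (run_snr_sweep, corrupt()) stays in the waveform domain.
consistency_prep <- function(train_nights, noise, mel_cfg, config,
                             n_variants = 2L) {
  spe <- round(mel_cfg$sample_rate * 30)
  epoch_powers <- function(audio, n) {
    vapply(seq_len(n), function(k)
      mean(audio$samples[((k - 1L) * spe + 1L):(k * spe)]^2), 0)
  }
  nights <- lapply(train_nights, function(nt) {
    n <- length(nt$mels)
    variants <- if (config$pitch_prob > 0) lapply(seq_len(n_variants), function(v) {
      semis <- runif(1, config$pitch_range[1], config$pitch_range[2])
      shifted <- pitch_shift(nt$audio, semis)
      vm <- night_mels(shifted, mel_cfg)
      list(semitones = semis, log = vm,
           lin = lapply(vm, function(m) exp(unclass(m))),
           pw = epoch_powers(shifted, n))
    }) else list()
    list(log = nt$mels,
         lin = lapply(nt$mels, function(m) exp(unclass(m))),
         pw = epoch_powers(nt$audio, n),
         variants = variants)
  })
  eligible <- which(noise$split == "train")
  clips <- list(); clip_of <- integer(0)
  for (i in eligible) {
    segs <- segment_epochs(noise$clips[[i]])
    if (length(segs) == 0L) next
    ms <- lapply(segs, mel_spectrogram, config = mel_cfg)
    clips[[length(clips) + 1L]] <- list(
      lin = lapply(ms, function(m) exp(unclass(m))),
      pw = vapply(segs, mean_power, 0))
  }
  if (length(clips) == 0L)
    stop("no training noise clip is at least one epoch long")
  list(nights = nights, clips = clips, log_epsilon = mel_cfg$log_epsilon)
}

# One corrupted-window view: draw a clip-epoch cover for the window's
# epoch range, scale it to the drawn SNR by mean waveform power, and mix
# in the power-mel domain. `source` is prep$nights[[night]]$variants[[v]]
# or the night itself.
corrupt_window_mels <- function(prep, source, item, snr_db) {
  lo <- item$range[1]; hi <- item$range[2]
  need <- hi - lo + 1L
  cover_lin <- vector("list", 0L); cover_pw <- numeric(0)
  while (length(cover_lin) < need) {
    cl <- prep$clips[[sample.int(length(prep$clips), 1L)]]
    cover_lin <- c(cover_lin, cl$lin)
    cover_pw <- c(cover_pw, cl$pw)
  }
  cover_lin <- cover_lin[seq_len(need)]
  cover_pw <- cover_pw[seq_len(need)]
  ps <- mean(source$pw[lo:hi])
  g2 <- ps / (10^(snr_db / 10) * mean(cover_pw))
  corr <- lapply(seq_len(need), function(k)
    log(source$lin[[lo + k - 1L]] + g2 * cover_lin[[k]]))
  corr[item$input_idx - lo + 1L]
}

#' Train the 14-to-10 detector with home-noise consistency
#'
#' Fine-tunes a pretrained extractor together with the cross-epoch
#' detector. Each iteration draws, per window, one SNR uniformly from
#' `snr_range` and one noise cover from the library, corrupts the clean
#' input, and minimizes the weighted sum of class-weighted cross-entropy
#' (clean branch) and the mean-squared-error consistency loss between the
#' clean and corrupted predictions. Pitch-shift augmentation is applied to
#' the clean input before corruption. The slanted-triangular learning rate
#' and gradual unfreezing of the pretrained extractor are used; training
#' runs for exactly `n_training_epochs` epochs and the checkpoint with the
#' highest validation macro F1 is returned. With `lambda = 0` or
#' `noise = NULL` the run reduces to plain supervised training on clean
#' audio (the control model).
#'
#' @param pretrained An `osa_checkpoint` from [pretrain_1to1()], or `NULL`
#'   (requires `unfreeze = FALSE` in the config).
#' @param train_nights,val_nights Lists of nights (`mels`, `labels`, and
#'   `audio` when corruption or pitch augmentation is active).
#' @param noise A [noise_library()] or `NULL`.
#' @param mel_cfg The [mel_config()] the night mels were computed with
#'   (needed to recompute features of corrupted audio).
#' @param det_config A [detector_config()].
#' @param config A [training_config()].
#' @return An `osa_checkpoint` with per-epoch `history` (losses,
#'   validation macro F1, learning rate) and an `snr_log` attribute of all
#'   drawn SNRs.
#' @export
train_14to10 <- function(pretrained, train_nights, val_nights, noise = NULL,
                         mel_cfg = mel_config(), det_config = detector_config(),
                         config = training_config()) {
  if (length(train_nights) == 0L) stop("no training nights")
  if (is.null(pretrained) && config$unfreeze)
    stop("gradual unfreezing requires a pretrained extractor; ",
         "pass pretrain_1to1() output or set unfreeze = FALSE")
  if (!is.null(pretrained)) det_config <- pretrained$config
  else if (is.null(det_config$norm_center))
    det_config <- fit_input_normalization(det_config, train_nights)
  det <- build_detector(det_config)
  if (!is.null(pretrained)) {
    for (nm in c("Wc", "bc", "Wf", "bf"))
      det$params[[nm]] <- pretrained$params[[nm]]
  }
  # pitch augmentation belongs to the consistency recipe, so a lambda = 0
  # run is exactly the control path (supervised training on clean audio)
  do_consistency <- config$lambda > 0 && !is.null(noise)
  do_pitch <- config$pitch_prob > 0 && do_consistency
  needs_audio <- do_consistency || do_pitch
  if (needs_audio && is.null(train_nights[[1]]$audio))
    stop("consistency training needs nights with an `audio` element")

  # The consistency model is checkpoint-selected on the clean validation
  # nights PLUS noise-added copies of them (fixed covers at 0 dB, the
  # centre of the robustness range), pooled into one macro F1, so the
  # selected checkpoint balances clean accuracy and noise robustness; the
  # control path validates on clean nights only.
  val_for_selection <- val_nights
  noisy_val <- NULL
  if (do_consistency) {
    reps <- 2L                                # two covers per validation night
    vgrid <- expand.grid(night = seq_along(val_nights), rep = seq_len(reps))
    vseeds <- derive_seeds(config$seed + 1L, nrow(vgrid))
    noisy_val <- lapply(seq_len(nrow(vgrid)), function(k) {
      vn <- val_nights[[vgrid$night[k]]]
      if (is.null(vn$audio))
        stop("consistency training needs validation nights with audio")
      corr <- corrupt(vn$audio, noise, 0, seed = vseeds[k])
      list(mels = night_mels(corr, mel_cfg), labels = vn$labels)
    })
    val_for_selection <- c(val_nights, noisy_val)
  }

  items <- unlist(lapply(seq_along(train_nights), function(i) {
    ws <- night_windows(train_nights[[i]],
                        input_epochs = det_config$input_epochs,
                        output_epochs = det_config$output_epochs,
                        stride = config$window_stride)
    lapply(ws, function(w) c(w, list(night_index = i)))
  }), recursive = FALSE)
  n_batches <- ceiling(length(items) / config$batch_windows)
  total_iter <- config$n_training_epochs * n_batches
  seq_stage <- c("U", "bu", "V", "bv")
  vel <- zero_like(det$params)
  history <- data.frame()
  snr_log <- numeric(0)
  best <- list(f1 = -Inf, params = det$params, epoch = 0L)
  iter <- 0L

  with_seed(config$seed, {
    prep <- if (do_consistency)
      consistency_prep(train_nights, noise, mel_cfg, config) else NULL
    for (ep in seq_len(config$n_training_epochs)) {
      trainable <- if (!config$unfreeze || is.null(pretrained)) {
        c(seq_stage, "Wc", "bc", "Wf", "bf")
      } else if (ep == 1L) seq_stage
        else if (ep == 2L) c(seq_stage, "Wf", "bf")
        else c(seq_stage, "Wf", "bf", "Wc", "bc")
      ord <- sample.int(length(items))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_windows))
      ep_ce <- 0; ep_cons <- 0
      for (b in batches) {
        iter <- iter + 1L
        lr <- slanted_triangular_lr(iter, total_iter, config$max_lr,
                                    config$stlr_warmup, config$stlr_ratio)
        clean_list <- vector("list", length(b))
        corr_list <- if (do_consistency) vector("list", length(b)) else NULL
        for (j in seq_along(b)) {
          it <- items[[b[j]]]
          if (do_consistency) {
            src <- prep$nights[[it$night_index]]
            if (do_pitch && length(src$variants) && runif(1) < config$pitch_prob)
              src <- src$variants[[sample.int(length(src$variants), 1L)]]
            snr <- runif(1, config$snr_range[1], config$snr_range[2])
            snr_log <- c(snr_log, snr)
            clean_list[[j]] <- src$log[it$input_idx]
            corr_list[[j]] <- corrupt_window_mels(prep, src, it, snr)
          } else {
            clean_list[[j]] <- it$night$mels[it$input_idx]
          }
        }
        y <- label_int(unlist(lapply(b, function(i) items[[i]]$labels)))
        fw_c <- detector_forward(det, clean_list)
        dlog_c <- ce_grad_logits(fw_c$probs, y, config$weights)
        ce <- weighted_cross_entropy(t(fw_c$probs), osa_classes[y],
                                     config$weights)
        cons <- 0
        if (do_consistency) {
          fw_n <- detector_forward(det, corr_list)
          diff <- fw_c$probs - fw_n$probs
          cons <- mean(diff^2)
          dP <- 2 * diff / length(diff)
          if (!config$consistency_stop_gradient)
            dlog_c <- dlog_c +
              config$lambda * softmax_backprop(fw_c$probs, dP)
          dlog_n <- config$lambda * softmax_backprop(fw_n$probs, -dP)
          g_n <- detector_backward(det, fw_n, dlog_n)
        }
        g <- detector_backward(det, fw_c, dlog_c)
        if (do_consistency)
          for (nm in names(g)) g[[nm]] <- g[[nm]] + g_n[[nm]]
        upd <- sgd_step(det$params, g, vel, lr, config$momentum, trainable,
                        config$clip_norm)
        det$params <- upd$params; vel <- upd$vel
        ep_ce <- ep_ce + ce; ep_cons <- ep_cons + cons
      }
      f1 <- validation_macro_f1(det, val_for_selection)
      history <- rbind(history, data.frame(
        epoch = ep, ce_loss = ep_ce / length(batches),
        consistency_loss = ep_cons / length(batches),
        val_macro_f1 = f1,
        val_clean_f1 = validation_macro_f1(det, val_nights),
        val_noisy_f1 = if (!is.null(noisy_val))
          validation_macro_f1(det, noisy_val) else NA_real_,
        lr = lr))
      if (f1 > best$f1) best <- list(f1 = f1, params = det$params, epoch = ep)
    }
  })
  ck <- structure(list(params = best$params, config = det_config,
                       val_macro_f1 = best$f1, epoch = best$epoch,
                       history = history, snr_log = snr_log,
                       val_clean_f1 = NA_real_, val_noisy_f1 = NA_real_),
                  class = "osa_checkpoint")
  det$params <- best$params
  ck$val_clean_f1 <- validation_macro_f1(det, val_nights)
  if (!is.null(noisy_val))
    ck$val_noisy_f1 <- validation_macro_f1(det, noisy_val)
  ck
}
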