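test_that("weighted cross-entropy matches its closed forms", {
  w <- class_weights()
  onehot <- diag(3)
  expect_equal(weighted_cross_entropy(onehot, osa_classes, w), 0,
               tolerance = 1e-9)
  uniform <- matrix(1 / 3, 1, 3)
  expect_equal(weighted_cross_entropy(uniform, "hypopnea", w),
               2.1 * log(3), tolerance = 1e-9)
  expect_equal(weighted_cross_entropy(uniform, "no_event", w),
               log(3), tolerance = 1e-9)
  expect_equal(weighted_cross_entropy(uniform, "apnea", w),
               1.3 * log(3), tolerance = 1e-9)
  # mean over epochs
  two <- rbind(c(1, 0, 0), c(1 / 3, 1 / 3, 1 / 3))
  expect_equal(weighted_cross_entropy(two, c("no_event", "apnea"), w),
               1.3 * log(3) / 2, tolerance = 1e-9)
  expect_warning(
    expect_true(is.finite(weighted_cross_entropy(rbind(c(0, 1, 0)),
                                                 "no_event", w))),
    "clamped")
})

test_that("consistency loss is the mean squared difference over all elements", {
  expect_equal(consistency_loss(diag(3), diag(3)), 0)
  expect_equal(consistency_loss(rbind(c(0.2, 0.3, 0.5)),
                                rbind(c(0.4, 0.3, 0.3))),
               (0.04 + 0 + 0.04) / 3, tolerance = 1e-9)
  expect_equal(consistency_loss(rbind(c(1, 0, 0)), rbind(c(0, 1, 0))),
               2 / 3, tolerance = 1e-9)
  expect_error(consistency_loss(diag(3), rbind(c(1, 0, 0))), "shapes")
})

test_that("combined loss is the weighted sum and monotone in each term", {
  expect_equal(combined_loss(1.2, 0.7, 0), 1.2)
  expect_equal(combined_loss(1.0, 0.5, 1), 1.5)
  expect_gte(combined_loss(1.1, 0.5, 1), combined_loss(1.0, 0.5, 1))
  expect_gte(combined_loss(1.0, 0.6, 1), combined_loss(1.0, 0.5, 1))
})

test_that("plateau schedule decays after the configured stagnation", {
  # flat history: first decay after epoch 4 (3 stagnant epochs: 2,3,4)
  lrs <- plateau_schedule(c(0.5, 0.5, 0.5, 0.5), 0.01, 10, 3)
  expect_equal(lrs, c(0.01, 0.01, 0.01, 0.01))
  lrs5 <- plateau_schedule(c(0.5, 0.5, 0.5, 0.5, 0.5), 0.01, 10, 3)
  expect_equal(lrs5[5], 0.001)
  # strictly improving: no decay
  expect_equal(plateau_schedule(seq(0.1, 0.9, by = 0.1), 0.01, 10, 3),
               rep(0.01, 9))
  # counter resets after a decay
  lrs8 <- plateau_schedule(rep(0.5, 8), 0.01, 10, 3)
  expect_equal(lrs8, c(rep(0.01, 4), rep(0.001, 3), 1e-4))
})

test_that("slanted-triangular schedule warms up then decays linearly", {
  total <- 100
  lr <- slanted_triangular_lr(1:total, total, max_lr = 0.1, warmup = 0.1,
                              ratio = 32)
  expect_equal(which.max(lr), 10)
  expect_equal(max(lr), 0.1)
  expect_true(all(diff(lr[1:10]) > 0))
  expect_true(all(diff(lr[10:100]) < 0))
  expect_equal(lr[100], 0.1 / 32, tolerance = 1e-9)
})

test_that("the two-step pipeline learns separable synthetic data", {
  mc <- test_mel_config()
  nights <- cached("pipe_nights", prepare_synthetic_cohort(
    8, mc, keep_audio = FALSE, duration_hours = 0.25, seed = 77))
  dc <- detector_config(n_mels = mc$n_mels, seed = 5)
  tc <- training_config(seed = 5, max_lr = 0.05, batch_epochs = 32,
                        val_fraction = 0.2)
  m <- suppressWarnings(osa_train(nights[1:6], noise = NULL, mel_cfg = mc,
                                  det_config = dc, config = tc))
  expect_s3_class(m, "osa_model")
  expect_equal(nrow(m$training$history), 10L)       # fixed 10 training epochs
  # training improves markedly over the untrained ~chance level
  expect_gt(m$val_macro_f1, 0.55)
  # checkpoint selection picks the history maximum
  expect_equal(m$training$val_macro_f1,
               max(m$training$history$val_macro_f1))
  # prediction runs on held-out nights
  pred <- predict(m, nights[[7]])
  expect_equal(nrow(pred), length(nights[[7]]$mels))
})

test_that("training trajectories are bit-identical under a fixed seed", {
  mc <- test_mel_config()
  nights <- cached("pipe_nights", prepare_synthetic_cohort(
    8, mc, keep_audio = FALSE, duration_hours = 0.25, seed = 77))
  dc <- detector_config(n_mels = mc$n_mels, seed = 9)
  tc <- training_config(seed = 9, max_lr = 0.05, n_training_epochs = 3L,
                        val_fraction = 0.2)
  m1 <- suppressWarnings(osa_train(nights[1:5], NULL, mc, dc, tc))
  m2 <- suppressWarnings(osa_train(nights[1:5], NULL, mc, dc, tc))
  expect_identical(m1$training$history, m2$training$history)
  expect_identical(m1$detector$params, m2$detector$params)
})

test_that("consistency training draws SNRs in range and lambda 0 equals the control path", {
  mc <- test_mel_config()
  nights <- cached("cons_nights", prepare_synthetic_cohort(
    5, mc, keep_audio = TRUE, duration_hours = 0.25, seed = 55))
  lib <- test_noise_library()
  dc <- detector_config(n_mels = mc$n_mels, seed = 4)
  tc <- training_config(seed = 4, max_lr = 0.05, n_training_epochs = 2L,
                        batch_windows = 4, val_fraction = 0.2)
  m_cons <- suppressWarnings(osa_train(nights, noise = lib, mel_cfg = mc,
                                       det_config = dc, config = tc))
  expect_true(all(m_cons$training$snr_log >= -20 &
                  m_cons$training$snr_log <= 5))
  expect_gt(length(m_cons$training$snr_log), 0)
  expect_true(all(m_cons$training$history$consistency_loss > 0))

  tc0 <- tc; tc0$lambda <- 0
  m_zero <- suppressWarnings(osa_train(nights, noise = lib, mel_cfg = mc,
                                       det_config = dc, config = tc0))
  m_ctrl <- suppressWarnings(osa_train(nights, noise = NULL, mel_cfg = mc,
                                       det_config = dc, config = tc0))
  expect_identical(m_zero$detector$params, m_ctrl$detector$params)
  expect_equal(m_zero$training$history$ce_loss,
               m_ctrl$training$history$ce_loss, tolerance = 1e-12)
})

test_that("gradual unfreezing requires a pretrained extractor", {
  mc <- test_mel_config()
  nights <- cached("pipe_nights", prepare_synthetic_cohort(
    8, mc, keep_audio = FALSE, duration_hours = 0.25, seed = 77))
  dc <- detector_config(n_mels = mc$n_mels, seed = 2)
  tc <- training_config(seed = 2)
  expect_error(train_14to10(NULL, nights[1:3], nights[4], NULL,
                            mel_cfg = mc, det_config = dc, config = tc),
               "pretrained")
})
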