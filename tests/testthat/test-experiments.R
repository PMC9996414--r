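# Scaled-down robustness experiments: these check mechanics and the
# qualitative shape of the outputs on very small synthetic sets; the
# full-scale behaviour is exercised by the acceptance suite.

exp_setup <- function() {
  mc <- test_mel_config()
  nights <- cached("exp_nights", prepare_synthetic_cohort(
    6, mc, keep_audio = TRUE, duration_hours = 0.25, seed = 91,
    strata_props = c(0, 1, 1, 1)))
  list(mc = mc, nights = nights, lib = test_noise_library())
}

test_that("the SNR sweep pairs covers across SNR and reports every cell", {
  s <- exp_setup()
  dc <- detector_config(n_mels = s$mc$n_mels, seed = 3)
  tc <- training_config(seed = 3, max_lr = 0.05, n_training_epochs = 2L,
                        val_fraction = 0.2)
  m <- suppressWarnings(osa_train(s$nights[1:4], NULL, s$mc, dc, tc))
  sw <- suppressWarnings(run_snr_sweep(
    list(a = m, b = m), s$nights[5:6], s$lib,
    snrs = c(Inf, 0, -30), mel_cfg = s$mc, seed = 7))
  expect_equal(nrow(sw), 6L)
  expect_setequal(unique(sw$model), c("a", "b"))
  # identical models give identical rows
  expect_equal(sw$macro_f1[sw$model == "a"], sw$macro_f1[sw$model == "b"])
  # the clean column equals the model's clean test macro F1
  ref <- unlist(lapply(s$nights[5:6], function(n) as.character(n$labels)))
  prd <- unlist(lapply(s$nights[5:6],
                       function(n) as.character(predict(m, n)$predicted_class)))
  clean_f1 <- suppressWarnings(epoch_metrics(confusion_matrix(ref, prd))$macro_f1)
  expect_equal(sw$macro_f1[sw$model == "a" & is.infinite(sw$snr_db)], clean_f1,
               tolerance = 1e-12)
  # reruns with the same seed are identical
  sw2 <- suppressWarnings(run_snr_sweep(
    list(a = m, b = m), s$nights[5:6], s$lib,
    snrs = c(Inf, 0, -30), mel_cfg = s$mc, seed = 7))
  expect_identical(sw, sw2)
})

test_that("the noise-group matrix has the requested shape", {
  s <- exp_setup()
  groups <- c("speech", "clock", "air_conditioner_fan")
  dc <- detector_config(n_mels = s$mc$n_mels, seed = 3)
  tc <- training_config(seed = 3, max_lr = 0.05, n_training_epochs = 2L,
                        batch_windows = 4, val_fraction = 0.25)
  mat <- suppressWarnings(run_noise_group_matrix(
    s$nights[1:4], s$nights[5], s$nights[6], s$lib, groups = groups,
    snr_db = 0, mel_cfg = s$mc, det_config = dc, config = tc, seed = 5))
  expect_equal(dim(mat), c(4L, 4L))
  expect_equal(rownames(mat), c(groups, "all_groups"))
  expect_equal(colnames(mat), c(groups, "combined"))
  expect_true(all(is.finite(mat)))
  expect_true(all(mat >= 0 & mat <= 1))
})

test_that("the noise-fraction curve spans control to full library", {
  s <- exp_setup()
  dc <- detector_config(n_mels = s$mc$n_mels, seed = 3)
  tc <- training_config(seed = 3, max_lr = 0.05, n_training_epochs = 2L,
                        batch_windows = 4, val_fraction = 0.25)
  cur <- suppressWarnings(run_noise_fraction_curve(
    s$nights[1:4], s$nights[5], s$nights[6], s$lib,
    fractions = c(0, 0.5, 1), snr_db = 0, mel_cfg = s$mc,
    det_config = dc, config = tc, seed = 5))
  expect_equal(cur$fraction, c(0, 0.5, 1))
  expect_equal(cur$n_clips[1], 0L)
  expect_equal(cur$n_clips[3], sum(s$lib$split == "train"))
  expect_true(all(is.finite(cur$macro_f1)))
  # fraction 0 is the control model by definition: identical to a direct
  # control run under the same seeds
  expect_identical(cur$macro_f1[1],
                   suppressWarnings(run_noise_fraction_curve(
                     s$nights[1:4], s$nights[5], s$nights[6], s$lib,
                     fractions = 0, snr_db = 0, mel_cfg = s$mc,
                     det_config = dc, config = tc, seed = 5))$macro_f1[1])
})
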