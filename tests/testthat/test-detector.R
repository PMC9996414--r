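fake_mel <- function(seed, n_mels = 8, frames = 20) {
  set.seed(seed)
  matrix(rnorm(n_mels * frames, -12, 6), n_mels, frames)
}

tiny_cfg <- function(seed = 3) {
  detector_config(input_epochs = 6, output_epochs = 4, n_mels = 8,
                  norm_center = -12, norm_scale = 6, seed = seed)
}

test_that("detector builds, runs and is seed-reproducible", {
  cfg <- tiny_cfg()
  det <- build_detector(cfg)
  win <- lapply(1:6, fake_mel)
  t0 <- Sys.time()
  pred <- predict_window(det, win)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_equal(nrow(pred), 4L)
  expect_identical(predict_window(build_detector(cfg), win), pred)
  # different seed -> different outputs
  det2 <- build_detector(tiny_cfg(seed = 99))
  expect_false(identical(predict_window(det2, win), pred))
})

test_that("window predictions are normalized distributions with argmax class", {
  det <- build_detector(tiny_cfg())
  win <- lapply(11:16, fake_mel)
  pred <- predict_window(det, win)
  p <- as.matrix(pred[, c("p_no_event", "p_apnea", "p_hypopnea")])
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-9)
  expect_true(all(p >= 0))
  expect_equal(as.character(pred$predicted_class),
               osa_classes[apply(p, 1, which.max)])
  expect_equal(pred$confidence, apply(p, 1, max))
  expect_error(predict_window(det, win[1:5]), "exactly 6")
})

test_that("an untrained detector is near-uniform on average over random windows", {
  det <- build_detector(tiny_cfg())
  probs <- matrix(0, 0, 3)
  for (i in 1:100) {
    win <- lapply(i * 10 + (1:6), fake_mel)
    pred <- predict_window(det, win)
    probs <- rbind(probs,
                   as.matrix(pred[, c("p_no_event", "p_apnea", "p_hypopnea")]))
  }
  expect_true(all(abs(colMeans(probs) - 1 / 3) < 0.2))
})

test_that("whole-night prediction stitches windows onto every epoch", {
  cfg <- detector_config(n_mels = 8, norm_center = -12, norm_scale = 6, seed = 5)
  det <- build_detector(cfg)
  for (n in c(10, 25, 30)) {
    mels <- lapply(seq_len(n), fake_mel)
    np <- predict_night(det, mels)
    expect_equal(nrow(np), n)
    expect_equal(np$epoch_index, 0:(n - 1))
    expect_true(all(is.finite(np$confidence)))
  }
  # epochs 16-20 of a 25-epoch night come from the final (shifted) window
  mels <- lapply(seq_len(25), fake_mel)
  np <- predict_night(det, mels)
  wins <- make_windows(mels)
  last <- predict_window(det, wins[[3]])
  expect_equal(np$p_apnea[16:25], last$p_apnea)
  expect_error(predict_night(det, list()), "no epochs")
})

test_that("checkpoints round-trip through the JSON archive", {
  det <- build_detector(tiny_cfg())
  f <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(det, f)
  back <- read_checkpoint(f)
  win <- lapply(1:6, fake_mel)
  expect_equal(predict_window(back, win), predict_window(det, win),
               tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on the combined loss", {
  cfg <- tiny_cfg()
  det <- build_detector(cfg)
  set.seed(42)
  wins <- lapply(1:2, function(i) lapply(i * 7 + (1:6), fake_mel))
  corr <- lapply(1:2, function(i) lapply(i * 31 + (1:6), fake_mel))
  y <- sample(1:3, 8, replace = TRUE)
  w <- class_weights()
  lambda <- 0.7
  loss_of <- function(d) {
    fc <- osadetect:::detector_forward(d, wins)
    fn <- osadetect:::detector_forward(d, corr)
    combined_loss(weighted_cross_entropy(t(fc$probs), osa_classes[y], w),
                  consistency_loss(t(fc$probs), t(fn$probs)), lambda)
  }
  fc <- osadetect:::detector_forward(det, wins)
  fn <- osadetect:::detector_forward(det, corr)
  dlog_c <- osadetect:::ce_grad_logits(fc$probs, y, w)
  dP <- 2 * (fc$probs - fn$probs) / length(fc$probs)
  dlog_c <- dlog_c + lambda * osadetect:::softmax_backprop(fc$probs, dP)
  dlog_n <- lambda * osadetect:::softmax_backprop(fn$probs, -dP)
  g <- osadetect:::detector_backward(det, fc, dlog_c)
  gn <- osadetect:::detector_backward(det, fn, dlog_n)
  for (nm in names(g)) g[[nm]] <- g[[nm]] + gn[[nm]]
  eps <- 1e-6
  set.seed(1)
  for (nm in names(g)) {
    p <- det$params[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      d1 <- det; d1$params[[nm]][i] <- p[i] + eps
      d2 <- det; d2$params[[nm]][i] <- p[i] - eps
      fd <- (loss_of(d1) - loss_of(d2)) / (2 * eps)
      an <- g[[nm]][i]
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-8), 1e-3,
                label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})
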