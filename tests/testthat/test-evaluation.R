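test_that("confusion matrix counts reference x predicted pairs", {
  cm <- confusion_matrix(c("apnea", "apnea", "no_event"),
                         c("apnea", "no_event", "no_event"))
  expect_equal(cm["apnea", "apnea"], 1L)
  expect_equal(cm["apnea", "no_event"], 1L)
  expect_equal(cm["no_event", "no_event"], 1L)
  expect_equal(sum(cm), 3L)
  expect_error(confusion_matrix("apnea", c("apnea", "apnea")), "equal length")
  ident <- confusion_matrix(osa_classes, osa_classes)
  expect_true(all(ident == diag(3)))
})

test_that("epoch metrics match hand-computed values on a fixed matrix", {
  m <- matrix(c(90, 5, 5, 10, 80, 10, 20, 30, 50), 3, 3, byrow = TRUE,
              dimnames = list(reference = osa_classes, predicted = osa_classes))
  class(m) <- c("confusion_matrix", "matrix", "array")
  em <- epoch_metrics(m)
  expect_equal(em$accuracy, 220 / 300, tolerance = 1e-12)
  # per-class F1 by hand: precision/recall per one-vs-rest
  f1 <- function(tp, fp, fn) 2 * tp / (2 * tp + fp + fn)
  macro <- mean(c(f1(90, 30, 10), f1(80, 35, 20), f1(50, 15, 50)))
  expect_equal(em$macro_f1, macro, tolerance = 1e-12)
  expect_equal(unname(em$sensitivity), c(0.9, 0.8, 0.5))
})

test_that("metrics agree with independent references on random confusion matrices", {
  skip_if_not_installed("e1071")
  set.seed(42)
  for (i in 1:100) {
    m <- matrix(rpois(9, lambda = sample(5:60, 1)), 3, 3)
    m <- m + diag(sample(1:30, 3, TRUE))       # keep all classes populated
    dimnames(m) <- list(reference = osa_classes, predicted = osa_classes)
    class(m) <- c("confusion_matrix", "matrix", "array")
    em <- epoch_metrics(m)
    ca <- e1071::classAgreement(unclass(m))
    expect_equal(em$accuracy, ca$diag, tolerance = 1e-9)
    expect_equal(em$cohen_kappa, ca$kappa, tolerance = 1e-9)
    # macro F1 against an independently coded one-vs-rest reduction
    f1s <- vapply(1:3, function(k) {
      tp <- m[k, k]; fp <- sum(m[-k, k]); fn <- sum(m[k, -k])
      2 * tp / (2 * tp + fp + fn)
    }, 0)
    expect_equal(em$macro_f1, mean(f1s), tolerance = 1e-9)
  }
})

test_that("kappa is near zero for predictions independent of the reference", {
  set.seed(7)
  n <- 10000
  ref <- sample(osa_classes, n, replace = TRUE, prob = c(0.6, 0.25, 0.15))
  prd <- sample(osa_classes, n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  em <- epoch_metrics(confusion_matrix(ref, prd))
  expect_lt(abs(em$cohen_kappa), 0.05)
})

test_that("two-class collapse merges the event classes and preserves totals", {
  m <- matrix(c(50, 2, 3, 4, 30, 6, 7, 8, 20), 3, 3, byrow = TRUE,
              dimnames = list(reference = osa_classes, predicted = osa_classes))
  class(m) <- c("confusion_matrix", "matrix", "array")
  two <- collapse_two_class(m)
  expect_equal(sum(two), sum(m))
  expect_equal(two["apnea_hypopnea", "apnea_hypopnea"], 30 + 6 + 8 + 20)
  # hypopnea predicted as apnea becomes correct after the merge
  acc3 <- epoch_metrics(m)$accuracy
  acc2 <- epoch_metrics(two)$accuracy
  expect_gte(acc2, acc3)
  # diagonal stays diagonal
  d <- confusion_matrix(osa_classes, osa_classes)
  expect_true(all(collapse_two_class(d) == diag(2) * c(1, 2)))
})

test_that("collapse never decreases accuracy on random matrices", {
  set.seed(11)
  for (i in 1:50) {
    m <- matrix(rpois(9, 20), 3, 3,
                dimnames = list(reference = osa_classes, predicted = osa_classes))
    class(m) <- c("confusion_matrix", "matrix", "array")
    expect_gte(epoch_metrics(collapse_two_class(m))$accuracy,
               epoch_metrics(m)$accuracy)
  }
})

test_that("screening metrics and AUC behave as specified", {
  sc <- screening(c(4, 10, 20, 40), c(3, 12, 25, 38), 15)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$specificity, 1)
  perfect <- screening(c(3, 10, 22, 40), c(3, 10, 22, 40), 15)
  expect_equal(perfect$auc, 1)
  flat <- screening(c(3, 10, 22, 40), rep(7, 4), 15)
  expect_equal(flat$auc, 0.5)
})

test_that("AUC matches pROC and is invariant under monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (i in 1:40) {
    ref <- runif(30, 0, 50)
    est <- ref + rnorm(30, sd = 10)
    got <- screening(ref, est, 15)$auc
    want <- as.numeric(pROC::auc(pROC::roc(ref >= 15, est, quiet = TRUE,
                                           direction = "<")))
    expect_equal(got, want, tolerance = 1e-9)
    expect_equal(screening(ref, exp(est / 20), 15)$auc, got, tolerance = 1e-12)
  }
})

test_that("Bland-Altman agreement matches hand computation", {
  ba <- bland_altman(c(2, 2, 2), c(1, 2, 3))
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, 1)
  expect_equal(ba$limits_of_agreement, c(-1.96, 1.96))
  expect_equal(ba$mae, 2 / 3)
  expect_false(ba$correlation_defined)          # reference has zero variance

  shift <- bland_altman(c(1, 5, 9), c(3, 7, 11))
  expect_equal(shift$mean_difference, 2)
  expect_equal(shift$sd_difference, 0)
  expect_true(shift$correlation_defined)
  expect_equal(shift$correlation, 1)

  same <- bland_altman(c(1, 5, 9), c(1, 5, 9))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$mae, 0)
})

test_that("agreement statistics match base-R references on random vectors", {
  set.seed(9)
  for (i in 1:30) {
    ref <- runif(25, 0, 60); est <- ref + rnorm(25, 1, 5)
    ba <- bland_altman(ref, est)
    d <- est - ref
    expect_equal(ba$mean_difference, mean(d), tolerance = 1e-12)
    expect_equal(ba$limits_of_agreement,
                 mean(d) + c(-1.96, 1.96) * sd(d), tolerance = 1e-12)
    expect_equal(ba$mae, mean(abs(d)), tolerance = 1e-12)
    expect_equal(ba$correlation, cor(ref, est), tolerance = 1e-12)
  }
})

test_that("confidence summary partitions epochs by correctness", {
  pred <- data.frame(predicted_class = c("apnea", "no_event"),
                     confidence = c(0.8, 0.6))
  cs <- confidence_summary(pred, c("apnea", "apnea"))
  expect_equal(cs$mean_confidence_correct, 0.8)
  expect_equal(cs$mean_confidence_incorrect, 0.6)
  all_right <- confidence_summary(
    data.frame(predicted_class = "apnea", confidence = 0.9), "apnea")
  expect_equal(all_right$mean_confidence_correct, 0.9)
  expect_true(is.na(all_right$mean_confidence_incorrect))
})
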