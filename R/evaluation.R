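# Epoch-level, screening and agreement metrics.

#' Confusion matrix over the epoch classes
#'
#' Rows are the reference class, columns the predicted class, both in
#' [osa_classes] order (or any common factor level set).
#'
#' @param reference,predicted Equal-length label vectors (factor or
#'   character).
#' @param classes Class order; defaults to [osa_classes].
#' @return An integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(reference, predicted, classes = osa_classes) {
  reference <- as.character(reference); predicted <- as.character(predicted)
  if (length(reference) != length(predicted))
    stop("reference and predicted must have equal length")
  bad <- setdiff(unique(c(reference, predicted)), classes)
  if (length(bad)) stop("unknown class labels: ", paste(bad, collapse = ", "))
  cm <- table(factor(reference, levels = classes),
              factor(predicted, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(reference = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' Epoch-level classification metrics
#'
#' Accuracy (trace over total), unweighted macro F1, Cohen's kappa, and
#' one-vs-rest sensitivity (recall) and specificity per class. A class
#' absent from both reference and prediction contributes an F1 of 0 with
#' a warning.
#'
#' @param cm A [confusion_matrix()].
#' @return A list of class `epoch_metrics`: `accuracy`, `macro_f1`,
#'   `cohen_kappa`, `sensitivity`, `specificity`, `f1` (named per class),
#'   `n`.
#' @export
epoch_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix") || (is.matrix(cm) && nrow(cm) == ncol(cm)))
  m <- unclass(cm)
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix")
  k <- nrow(m)
  tp <- diag(m)
  rowt <- rowSums(m); colt <- colSums(m)
  recall <- ifelse(rowt > 0, tp / rowt, NA_real_)
  precision <- ifelse(colt > 0, tp / colt, NA_real_)
  f1 <- ifelse(is.na(recall) & is.na(precision), NA_real_,
               2 * tp / pmax(rowt + colt, 1))
  absent <- rowt == 0 & colt == 0
  if (any(absent)) {
    warning("class absent from both reference and prediction: ",
            paste(rownames(m)[absent], collapse = ", "), "; F1 set to 0")
    f1[absent] <- 0
  }
  specificity <- vapply(seq_len(k), function(i) {
    tn <- n - rowt[i] - colt[i] + tp[i]
    neg <- n - rowt[i]
    if (neg > 0) tn / neg else NA_real_
  }, 0)
  po <- sum(tp) / n
  pe <- sum(rowt * colt) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps) NA_real_ else (po - pe) / (1 - pe)
  structure(list(accuracy = po, macro_f1 = mean(f1),
                 cohen_kappa = kappa,
                 sensitivity = stats::setNames(recall, rownames(m)),
                 specificity = stats::setNames(specificity, rownames(m)),
                 f1 = stats::setNames(f1, rownames(m)), n = n),
            class = "epoch_metrics")
}

#' @export
print.epoch_metrics <- function(x, ...) {
  cat(sprintf("Epoch metrics (n = %d): accuracy %.3f, macro F1 %.3f, kappa %.3f\n",
              x$n, x$accuracy, x$macro_f1, x$cohen_kappa))
  tab <- rbind(sensitivity = x$sensitivity, specificity = x$specificity, f1 = x$f1)
  print(round(tab, 3))
  invisible(x)
}

#' Collapse the 3-class confusion matrix to 2 classes
#'
#' Merges apnea and hypopnea into one `apnea_hypopnea` class by summing
#' their rows and columns; totals are preserved.
#'
#' @param cm A 3-class [confusion_matrix()] in [osa_classes] order.
#' @return A 2x2 `confusion_matrix` (`no_event`, `apnea_hypopnea`).
#' @export
collapse_two_class <- function(cm) {
  m <- unclass(cm)
  stopifnot(nrow(m) == 3L, ncol(m) == 3L)
  out <- matrix(0L, 2L, 2L,
                dimnames = list(reference = c("no_event", "apnea_hypopnea"),
                                predicted = c("no_event", "apnea_hypopnea")))
  out[1, 1] <- m[1, 1]
  out[1, 2] <- m[1, 2] + m[1, 3]
  out[2, 1] <- m[2, 1] + m[3, 1]
  out[2, 2] <- m[2, 2] + m[2, 3] + m[3, 2] + m[3, 3]
  structure(out, class = c("confusion_matrix", "matrix", "array"))
}

#' OSA screening metrics at an AHI cutoff
#'
#' Both reference and estimated AHI are binarized at the cutoff for
#' sensitivity and specificity; the AUC uses the continuous estimated AHI
#' as the score against the binarized reference (rank statistic with
#' midranks for ties).
#'
#' @param reference_ahi,estimated_ahi Numeric vectors of per-night AHI.
#' @param cutoff Cutoff in events/hour (5, 15 or 30 conventionally).
#' @return A list of class `screening_metrics`: `cutoff`, `sensitivity`,
#'   `specificity`, `auc`, `n_positive`, `n_negative`.
#' @export
screening <- function(reference_ahi, estimated_ahi, cutoff) {
  stopifnot(length(reference_ahi) == length(estimated_ahi))
  pos <- reference_ahi >= cutoff
  est_pos <- estimated_ahi >= cutoff
  sens <- if (any(pos)) mean(est_pos[pos]) else NA_real_
  spec <- if (any(!pos)) mean(!est_pos[!pos]) else NA_real_
  auc <- if (any(pos) && any(!pos)) {
    r <- rank(estimated_ahi)                       # midranks for ties
    np <- sum(pos); nn <- sum(!pos)
    (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  } else NA_real_
  structure(list(cutoff = cutoff, sensitivity = sens, specificity = spec,
                 auc = auc, n_positive = sum(pos), n_negative = sum(!pos)),
            class = "screening_metrics")
}

#' @export
print.screening_metrics <- function(x, ...) {
  cat(sprintf("Screening at AHI >= %g: sensitivity %.3f, specificity %.3f, AUC %.3f (%d/%d)\n",
              x$cutoff, x$sensitivity, x$specificity, x$auc,
              x$n_positive, x$n_negative))
  invisible(x)
}

#' Bland-Altman agreement between estimated and reference AHI
#'
#' Differences are `estimated - reference`. Limits of agreement are the
#' mean difference plus/minus 1.96 standard deviations. The Pearson
#' correlation is flagged undefined (NA, `correlation_defined = FALSE`)
#' when either vector has zero variance.
#'
#' @param reference_ahi,estimated_ahi Numeric vectors.
#' @return A list of class `agreement_stats`: `mean_difference`,
#'   `sd_difference`, `limits_of_agreement` (length 2), `mae`,
#'   `correlation`, `correlation_defined`, `n`.
#' @export
bland_altman <- function(reference_ahi, estimated_ahi) {
  stopifnot(length(reference_ahi) == length(estimated_ahi),
            length(reference_ahi) >= 1L)
  d <- estimated_ahi - reference_ahi
  md <- mean(d)
  sdd <- if (length(d) > 1L) sd(d) else 0
  defined <- length(d) > 1L && sd(reference_ahi) > 0 && sd(estimated_ahi) > 0
  structure(list(mean_difference = md, sd_difference = sdd,
                 limits_of_agreement = c(md - 1.96 * sdd, md + 1.96 * sdd),
                 mae = mean(abs(d)),
                 correlation = if (defined) cor(reference_ahi, estimated_ahi)
                               else NA_real_,
                 correlation_defined = defined,
                 n = length(d)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Agreement (n = %d): mean difference %.2f [%.2f, %.2f], MAE %.2f, r = %s\n",
              x$n, x$mean_difference, x$limits_of_agreement[1],
              x$limits_of_agreement[2], x$mae,
              if (x$correlation_defined) sprintf("%.3f", x$correlation)
              else "undefined"))
  invisible(x)
}

#' Mean confidence of correct and incorrect epochs
#'
#' Partitions epochs by correctness of the predicted class and averages
#' the prediction confidence (max probability) in each partition.
#'
#' @param prediction A [predict_night()] data frame (needs
#'   `predicted_class` and `confidence`).
#' @param reference Reference labels, same length.
#' @return List with `mean_confidence_correct`, `mean_confidence_incorrect`
#'   (NA for an empty partition), `n_correct`, `n_incorrect`.
#' @export
confidence_summary <- function(prediction, reference) {
  stopifnot(nrow(prediction) == length(reference))
  ok <- as.character(prediction$predicted_class) == as.character(reference)
  list(mean_confidence_correct = if (any(ok)) mean(prediction$confidence[ok]) else NA_real_,
       mean_confidence_incorrect = if (any(!ok)) mean(prediction$confidence[!ok]) else NA_real_,
       n_correct = sum(ok), n_incorrect = sum(!ok))
}
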