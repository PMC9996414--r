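# Overnight AHI estimation: apneic-epoch rate -> robust linear calibration
# -> severity classification.

#' Apneic-epoch rate of a night
#'
#' Counts epochs predicted apnea or hypopnea and divides by the recording
#' duration in hours.
#'
#' @param prediction A [predict_night()] data frame, or a label vector.
#' @param recording_hours Recording duration in hours (> 0).
#' @return A list of class `apneic_rate`: `apneic_epoch_count`,
#'   `recording_hours`, `rate` (epochs/hour).
#' @export
apneic_rate <- function(prediction, recording_hours) {
  stop_if_not_scalar_number(recording_hours, "recording_hours", 0, strict_min = TRUE)
  labels <- if (is.data.frame(prediction)) prediction$predicted_class else prediction
  count <- sum(as.character(labels) %in% c("apnea", "hypopnea"))
  structure(list(apneic_epoch_count = count,
                 recording_hours = recording_hours,
                 rate = count / recording_hours),
            class = "apneic_rate")
}

#' Calibrate apneic-epoch rate to AHI with a RANSAC linear fit
#'
#' Repeatedly fits a line through random 2-point subsets, scores each
#' candidate by its inlier count under a residual threshold, and refits
#' ordinary least squares on the best consensus set. The default
#' threshold is the median absolute deviation of the residuals of a
#' preliminary least-squares fit.
#'
#' @param rates Per-night apneic-epoch rates (epochs/hour); numeric or a
#'   list of [apneic_rate()] objects.
#' @param reference_ahi Per-night reference AHI (events/hour), same
#'   length, at least 2 nights.
#' @param n_trials Number of random subsets (default 1000).
#' @param threshold Inlier residual threshold; `NULL` for the MAD default.
#' @param seed Integer seed; the fit is deterministic given it.
#' @return An object of class `ahi_regressor` with elements `slope`,
#'   `intercept`, `inlier_mask`, `threshold`, `n_train`, `seed`.
#' @export
fit_ahi_regressor <- function(rates, reference_ahi, n_trials = 1000L,
                              threshold = NULL, seed = 1L) {
  if (is.list(rates)) rates <- vapply(rates, function(r) r$rate, 0)
  x <- as.numeric(rates); y <- as.numeric(reference_ahi)
  if (length(x) != length(y)) stop("rates and reference_ahi differ in length")
  if (length(x) < 2L) stop("need at least 2 nights to fit")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite inputs")
  if (max(x) - min(x) < .Machine$double.eps)
    stop("degenerate fit: all rates are identical")
  n <- length(x)
  if (is.null(threshold)) {
    pre <- stats::lm.fit(cbind(1, x), y)
    threshold <- stats::mad(pre$residuals)
  }
  thr <- max(threshold, 1e-9)
  best <- list(count = -1L, inliers = NULL)
  with_seed(seed, {
    for (t in seq_len(n_trials)) {
      ij <- sample.int(n, 2L)
      dx <- x[ij[2]] - x[ij[1]]
      if (abs(dx) < .Machine$double.eps) next
      slope <- (y[ij[2]] - y[ij[1]]) / dx
      intercept <- y[ij[1]] - slope * x[ij[1]]
      resid <- abs(y - (intercept + slope * x))
      inl <- resid <= thr
      cnt <- sum(inl)
      if (cnt > best$count) best <- list(count = cnt, inliers = inl)
    }
  })
  inl <- best$inliers
  if (is.null(inl) || sum(inl) < 2L || max(x[inl]) - min(x[inl]) < .Machine$double.eps)
    inl <- rep(TRUE, n)                      # fall back to plain least squares
  fit <- stats::lm.fit(cbind(1, x[inl]), y[inl])
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 inlier_mask = inl, threshold = thr,
                 n_train = n, seed = as.integer(seed),
                 rates = x, reference_ahi = y),
            class = "ahi_regressor")
}

#' @export
print.ahi_regressor <- function(x, ...) {
  cat(sprintf("AHI calibration (RANSAC): AHI = %.4f * rate + %.4f\n",
              x$slope, x$intercept))
  cat(sprintf("  %d/%d training nights in the consensus set (threshold %.3g)\n",
              sum(x$inlier_mask), x$n_train, x$threshold))
  invisible(x)
}

#' @export
coef.ahi_regressor <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.ahi_regressor <- function(object, newdata, ...) {
  rate <- if (inherits(newdata, "apneic_rate")) newdata$rate
          else if (is.list(newdata) && !is.data.frame(newdata))
            vapply(newdata, function(r) r$rate, 0)
          else as.numeric(newdata)
  pmax(0, object$slope * rate + object$intercept)
}

#' @export
residuals.ahi_regressor <- function(object, ...) {
  object$reference_ahi - (object$intercept + object$slope * object$rates)
}

#' @export
plot.ahi_regressor <- function(x, ...) {
  graphics::plot(x$rates, x$reference_ahi,
                 col = ifelse(x$inlier_mask, "black", "red"),
                 pch = ifelse(x$inlier_mask, 19, 4),
                 xlab = "apneic epochs per hour",
                 ylab = "reference AHI (events/hour)", ...)
  graphics::abline(x$intercept, x$slope, col = "blue")
  invisible(x)
}

#' Estimate AHI from an apneic-epoch rate
#'
#' Affine prediction `slope * rate + intercept`, floored at 0 events/hour.
#'
#' @param regressor An [fit_ahi_regressor()] object.
#' @param rate An [apneic_rate()] or numeric rate (epochs/hour).
#' @return Estimated AHI in events/hour.
#' @export
estimate_ahi <- function(regressor, rate) {
  stopifnot(inherits(regressor, "ahi_regressor"))
  predict(regressor, rate)
}

#' Persist / restore an AHI regressor as JSON
#'
#' @param regressor An `ahi_regressor`.
#' @param path JSON path.
#' @return `path` (write) or the restored `ahi_regressor` (read).
#' @export
write_ahi_regressor <- function(regressor, path) {
  jsonlite::write_json(list(slope = regressor$slope,
                            intercept = regressor$intercept,
                            threshold = regressor$threshold,
                            seed = regressor$seed,
                            n_train = regressor$n_train),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ahi_regressor
#' @export
read_ahi_regressor <- function(path) {
  j <- jsonlite::fromJSON(path)
  structure(list(slope = j$slope, intercept = j$intercept,
                 inlier_mask = NULL, threshold = j$threshold,
                 n_train = j$n_train, seed = j$seed,
                 rates = NULL, reference_ahi = NULL),
            class = "ahi_regressor")
}

#' Classify OSA severity from an AHI value
#'
#' Cutoffs 5, 15 and 30 events/hour; boundary values belong to the higher
#' class (AHI = 15 is moderate).
#'
#' @param ahi AHI in events/hour (vectorized).
#' @return Factor with levels normal, mild, moderate, severe.
#' @export
classify_severity <- function(ahi) {
  cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
      labels = c("normal", "mild", "moderate", "severe"))
}
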