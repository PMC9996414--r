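# Respiratory-event annotations and 30-second epoch labeling.

#' Construct a table of respiratory events
#'
#' Events are held in a plain data frame with columns `event_type`, `onset`
#' and `duration` (seconds from recording start). Unknown type strings are
#' mapped to `"other"`.
#'
#' @param event_type Character vector; see [osa_event_types].
#' @param onset Numeric vector of onsets in seconds (>= 0).
#' @param duration Numeric vector of durations in seconds (> 0).
#' @return A data frame of class `respiratory_events`, sorted by onset.
#' @export
respiratory_events <- function(event_type = character(),
                               onset = numeric(),
                               duration = numeric()) {
  stopifnot(length(event_type) == length(onset),
            length(onset) == length(duration))
  event_type <- as.character(event_type)
  event_type[!event_type %in% osa_event_types] <- "other"
  onset <- as.numeric(onset); duration <- as.numeric(duration)
  bad <- which(!is.finite(onset) | onset < 0)
  if (length(bad))
    stop("negative or non-finite onset at row ", bad[1])
  bad <- which(!is.finite(duration) | duration <= 0)
  if (length(bad))
    stop("non-positive or non-finite duration at row ", bad[1])
  out <- data.frame(event_type = event_type, onset = onset,
                    duration = duration, stringsAsFactors = FALSE)
  out <- out[order(out$onset, out$duration), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("respiratory_events", "data.frame")
  out
}

#' Read respiratory-event annotations
#'
#' Reads an annotation file in either CSV (header
#' `event_type,onset_sec,duration_sec`) or JSON (array of objects with the
#' same keys) form. Events are returned sorted by onset; unrecognized
#' `event_type` strings map to `"other"`.
#'
#' @param path Path to a `.csv` or `.json` annotation file.
#' @return A [respiratory_events()] data frame.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  is_json <- grepl("\\.json$", path, ignore.case = TRUE)
  if (!is_json) {
    first <- readLines(path, n = 1L)
    is_json <- grepl("^\\s*\\[", first)
  }
  if (is_json) {
    rows <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(rows) == 0L) return(respiratory_events())
    req <- c("event_type", "onset_sec", "duration_sec")
    if (!all(req %in% names(rows)))
      stop("JSON annotations must provide keys: ", paste(req, collapse = ", "))
    df <- rows
  } else {
    df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) stop("cannot parse annotation CSV ",
                                            path, ": ", conditionMessage(e)))
    req <- c("event_type", "onset_sec", "duration_sec")
    if (!all(req %in% names(df)))
      stop("annotation CSV must have header: ", paste(req, collapse = ","))
    for (col in c("onset_sec", "duration_sec")) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]))
      if (length(bad))
        stop(sprintf("malformed value in column '%s' at data line %d of %s",
                     col, bad[1], path))
      df[[col]] <- v
    }
  }
  respiratory_events(df$event_type, df$onset_sec, df$duration_sec)
}

#' Write respiratory-event annotations to CSV
#'
#' @param events A [respiratory_events()] data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- data.frame(event_type = events$event_type,
                   onset_sec = events$onset,
                   duration_sec = events$duration)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Keep only obstructive events
#'
#' Central and mixed apneas (and any `"other"` annotations) are excluded:
#' only obstructive apneas and hypopneas count towards the epoch classes.
#'
#' @param events A [respiratory_events()] data frame.
#' @return The filtered events, same class.
#' @export
filter_obstructive <- function(events) {
  keep <- events$event_type %in% c("obstructive_apnea", "hypopnea")
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define the 30-second epoch grid of a recording
#'
#' Epochs are half-open intervals `[k*L, (k+1)*L)`; a trailing partial
#' segment shorter than `epoch_length` is dropped.
#'
#' @param recording_duration Recording duration in seconds.
#' @param epoch_length Epoch length in seconds (default 30).
#' @return An object of class `epoch_grid`.
#' @export
epoch_grid <- function(recording_duration, epoch_length = 30) {
  stop_if_not_scalar_number(recording_duration, "recording_duration", 0)
  stop_if_not_scalar_number(epoch_length, "epoch_length", 0, strict_min = TRUE)
  structure(list(n_epochs = as.integer(floor(recording_duration / epoch_length)),
                 epoch_length = epoch_length,
                 recording_duration = recording_duration),
            class = "epoch_grid")
}

#' @export
print.epoch_grid <- function(x, ...) {
  cat(sprintf("<epoch_grid: %d epochs of %g s over %g s>\n",
              x$n_epochs, x$epoch_length, x$recording_duration))
  invisible(x)
}

#' Label each 30-second epoch as no-event, apnea or hypopnea
#'
#' Every epoch overlapping at least one (filtered) event receives the class
#' of the event type with the larger score in that epoch; epochs with no
#' overlap are `no_event`. With `overlap = "within_epoch"` (default) the
#' score of a type is its total overlap in seconds inside the epoch,
#' summing over events of that type; with `overlap = "total_duration"` the
#' score is the longest total duration among overlapping events of the
#' type. Equal scores are broken in favour of apnea (the more severe
#' class).
#'
#' @param events A [respiratory_events()] data frame, already passed
#'   through [filter_obstructive()]. Events of excluded types raise an
#'   error.
#' @param grid An [epoch_grid()].
#' @param overlap Score definition, `"within_epoch"` or `"total_duration"`.
#' @return A data frame of class `epoch_labels` with columns `epoch_index`
#'   (0-based), `label` (factor over [osa_classes]), `overlap_apnea` and
#'   `overlap_hypopnea` (seconds of within-epoch overlap per type).
#' @export
label_epochs <- function(events, grid, overlap = c("within_epoch", "total_duration")) {
  overlap <- match.arg(overlap)
  stopifnot(inherits(grid, "epoch_grid"))
  if (nrow(events) && !all(events$event_type %in% c("obstructive_apnea", "hypopnea")))
    stop("label_epochs expects events filtered to obstructive_apnea/hypopnea; ",
         "run filter_obstructive() first")
  n <- grid$n_epochs
  L <- grid$epoch_length
  ov_ap <- numeric(n); ov_hy <- numeric(n)
  sc_ap <- numeric(n); sc_hy <- numeric(n)
  if (n > 0L && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      s <- events$onset[i]; e <- s + events$duration[i]
      k0 <- max(0L, as.integer(floor(s / L)))
      k1 <- min(n - 1L, as.integer(floor((e - 1e-12) / L)))
      if (k1 < k0) next
      ks <- k0:k1
      ov <- pmin(e, (ks + 1) * L) - pmax(s, ks * L)
      ov <- pmax(ov, 0)
      idx <- ks + 1L
      if (events$event_type[i] == "obstructive_apnea") {
        ov_ap[idx] <- ov_ap[idx] + ov
        sc_ap[idx] <- if (overlap == "within_epoch") ov_ap[idx]
                      else pmax(sc_ap[idx], ifelse(ov > 0, events$duration[i], 0))
      } else {
        ov_hy[idx] <- ov_hy[idx] + ov
        sc_hy[idx] <- if (overlap == "within_epoch") ov_hy[idx]
                      else pmax(sc_hy[idx], ifelse(ov > 0, events$duration[i], 0))
      }
    }
  }
  lab <- rep("no_event", n)
  has <- ov_ap > 0 | ov_hy > 0
  # tie (equal scores) goes to apnea, the more severe class
  lab[has & sc_ap >= sc_hy] <- "apnea"
  lab[has & sc_hy > sc_ap] <- "hypopnea"
  lab[has & ov_ap == 0] <- "hypopnea"   # apnea needs actual overlap
  lab[has & ov_hy == 0 & ov_ap > 0] <- "apnea"
  out <- data.frame(epoch_index = seq_len(n) - 1L,
                    label = factor(lab, levels = osa_classes),
                    overlap_apnea = ov_ap,
                    overlap_hypopnea = ov_hy)
  class(out) <- c("epoch_labels", "data.frame")
  out
}
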