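# Accelerometer recordings, annotated activity logs and analysis windows.
#
# Units: acceleration in g, time in seconds. Recordings are kept at their
# native device rate (16 or 25 Hz); nothing is resampled, so feature
# extraction always operates on raw in-window samples.

.activity_labels <- paste0("A", 1:7)

#' The seven activity labels
#'
#' A1 stationary, A2 walking, A3 jogging, A4 sprinting, A5 hitting the ball,
#' A6 standing tackle, A7 dribbling. A1--A4 are the inertial (locomotion)
#' activities, A5--A7 the game activities.
#'
#' @return character vector `c("A1", ..., "A7")`, in canonical order.
#' @export
activity_labels <- function() .activity_labels

#' Construct a validated accelerometer recording
#'
#' @param time sample times in seconds, strictly increasing.
#' @param ax,ay,az per-axis acceleration in g.
#' @param sampling_rate nominal device rate in samples/second; the observed
#'   median inter-sample interval must be within 20 percent of its reciprocal.
#' @param device_id free-text device identifier.
#' @return an `accel_recording`: a data frame with columns `t`, `ax`, `ay`,
#'   `az` and attributes `sampling_rate`, `device_id`.
#' @export
accel_recording <- function(time, ax, ay, az, sampling_rate,
                            device_id = "unknown") {
  n <- length(time)
  if (n < 2L) {
    stop("a recording needs at least 2 samples", call. = FALSE)
  }
  if (length(ax) != n || length(ay) != n || length(az) != n) {
    stop("time and axis vectors must have equal length", call. = FALSE)
  }
  if (anyNA(c(time, ax, ay, az))) {
    stop("recording contains missing values", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive number", call. = FALSE)
  }
  dt <- diff(time)
  bad <- which(dt <= 0)
  if (length(bad)) {
    stop(sprintf("timestamps not strictly increasing: row %d (t = %g) does not advance",
                 bad[1L] + 1L, time[bad[1L] + 1L]), call. = FALSE)
  }
  med <- stats::median(dt)
  if (abs(med - 1 / sampling_rate) > 0.2 / sampling_rate) {
    stop(sprintf(
      "median inter-sample interval %.4gs is inconsistent with sampling_rate %g Hz",
      med, sampling_rate), call. = FALSE)
  }
  structure(
    data.frame(t = as.numeric(time), ax = as.numeric(ax),
               ay = as.numeric(ay), az = as.numeric(az)),
    sampling_rate = sampling_rate, device_id = device_id,
    class = c("accel_recording", "data.frame"))
}

#' Read an accelerometer recording from CSV
#'
#' Expects comma-separated columns `t, ax, ay, az` ('.' decimal mark), with an
#' optional single header row. Rows containing non-numeric fields are dropped
#' with a warning.
#'
#' @param path CSV file path.
#' @param device a [device_profile()] supplying the nominal sampling rate and
#'   device id, or a bare positive number taken as the rate in Hz.
#' @return an `accel_recording`.
#' @export
read_recording <- function(path, device) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (is.numeric(device)) {
    device <- device_profile("custom", sampling_rate = device)
  }
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("t", "ax", "ay", "az"),
                         colClasses = "character", strip.white = TRUE)
  if (nrow(raw) && suppressWarnings(anyNA(as.numeric(unlist(raw[1L, ]))))) {
    raw <- raw[-1L, , drop = FALSE]  # header row
  }
  num <- suppressWarnings(
    data.frame(lapply(raw, as.numeric)))
  ok <- stats::complete.cases(num)
  if (any(!ok)) {
    warning(sprintf("dropped %d row(s) with non-numeric fields", sum(!ok)),
            call. = FALSE)
    num <- num[ok, , drop = FALSE]
  }
  if (nrow(num) < 2L) {
    stop(sprintf("malformed input: %s has fewer than 2 data rows", path),
         call. = FALSE)
  }
  accel_recording(num$t, num$ax, num$ay, num$az,
                  sampling_rate = device$sampling_rate,
                  device_id = device$name)
}

#' Write an accelerometer recording to CSV
#'
#' @param recording an `accel_recording`.
#' @param path output file path.
#' @param digits decimal places kept for every column.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, digits = 6L) {
  stopifnot(inherits(recording, "accel_recording"))
  out <- as.data.frame(lapply(recording, function(col) round(col, digits)))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = c("t", "ax", "ay", "az"), quote = FALSE)
  invisible(path)
}

#' Construct an annotated activity log
#'
#' A log is a nine-second recording with the annotated activity placed at its
#' centre, mirroring how sessions are cut around video-annotated events.
#'
#' @param recording an `accel_recording` spanning 9 seconds (within one sample
#'   period).
#' @param label activity label, one of `"A1"`..`"A7"`.
#' @param activity_center annotation midpoint in seconds (on the recording's
#'   time axis); defaults to the middle of the span.
#' @return an `activity_log`.
#' @export
activity_log <- function(recording, label, activity_center = NULL) {
  stopifnot(inherits(recording, "accel_recording"))
  label <- as.character(label)
  if (length(label) != 1L || !label %in% .activity_labels) {
    stop("`label` must be one of A1..A7", call. = FALSE)
  }
  rate <- attr(recording, "sampling_rate")
  span <- recording$t[nrow(recording)] - recording$t[1L]
  if (abs(span - 9) > 1 / rate + 1e-9) {
    stop(sprintf("log must span 9 seconds (got %.4g s)", span), call. = FALSE)
  }
  if (is.null(activity_center)) {
    activity_center <- recording$t[1L] + span / 2
  }
  if (activity_center < recording$t[1L] ||
      activity_center > recording$t[nrow(recording)]) {
    stop("`activity_center` lies outside the recording span", call. = FALSE)
  }
  structure(list(recording = recording, label = label,
                 activity_center = activity_center),
            class = "activity_log")
}

#' @export
print.activity_log <- function(x, ...) {
  rec <- x$recording
  cat(sprintf(
    "<activity_log> %s: %d samples at %g Hz (device %s), centre %.3g s\n",
    x$label, nrow(rec), attr(rec, "sampling_rate"),
    attr(rec, "device_id"), x$activity_center))
  invisible(x)
}

#' Cut a fixed-length window centred on the annotated activity
#'
#' The window holds `round(length * rate)` samples. Its centre sample is the
#' one nearest the annotation midpoint (index `floor(center * rate + 0.5)`,
#' zero-based), and the window covers indices
#' `[centre - floor(N/2), centre + ceiling(N/2))`, so shorter windows at the
#' same centre are always contiguous subsets of longer ones.
#'
#' @param log an `activity_log`.
#' @param length window length in seconds, in (0, 9].
#' @return an `activity_window`: per-axis sample vectors `x`, `y`, `z`, plus
#'   the label, window length and source rate.
#' @export
segment_window <- function(log, length) {
  stopifnot(inherits(log, "activity_log"))
  if (!is.numeric(length) || length(length) != 1L || length <= 0 ||
      length > 9) {
    stop("`length` must be in (0, 9] seconds", call. = FALSE)
  }
  rec <- log$recording
  rate <- attr(rec, "sampling_rate")
  n <- nrow(rec)
  nw <- as.integer(floor(length * rate + 0.5))
  # round half down so a mid-log annotation lands on sample floor(N/2)
  centre0 <- ceiling((log$activity_center - rec$t[1L]) * rate - 0.5)
  start0 <- centre0 - nw %/% 2L
  if (start0 < 0L || start0 + nw > n) {
    stop(sprintf(
      "window of %g s (%d samples) does not fit inside the log at its centre",
      length, nw), call. = FALSE)
  }
  idx <- seq.int(start0 + 1L, start0 + nw)
  structure(
    list(x = rec$ax[idx], y = rec$ay[idx], z = rec$az[idx],
         label = log$label, length = length, source_rate = rate,
         n = nw),
    class = "activity_window")
}

#' @export
print.activity_window <- function(x, ...) {
  cat(sprintf("<activity_window> %s: %d samples (%g s at %g Hz)\n",
              if (is.null(x$label)) "<unlabelled>" else x$label,
              x$n, x$length, x$source_rate))
  invisible(x)
}

#' Write a collection of activity logs plus their label sidecar
#'
#' Each log is written as `<log_id>.csv` (`t,ax,ay,az`) in `dir`, and a
#' sidecar `labels.csv` records `log_id,label,center_seconds,rate,device`.
#'
#' @param logs list of `activity_log` objects.
#' @param dir output directory, created if needed.
#' @return the sidecar path, invisibly.
#' @export
write_activity_logs <- function(logs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("log_%04d", seq_along(logs))
  meta <- data.frame(
    log_id = ids,
    label = vapply(logs, function(l) l$label, ""),
    center_seconds = vapply(logs, function(l) l$activity_center, 0),
    rate = vapply(logs, function(l) attr(l$recording, "sampling_rate"), 0),
    device = vapply(logs, function(l) attr(l$recording, "device_id"), ""))
  for (i in seq_along(logs)) {
    write_recording(logs[[i]]$recording, file.path(dir, paste0(ids[i], ".csv")))
  }
  sidecar <- file.path(dir, "labels.csv")
  utils::write.csv(meta, sidecar, row.names = FALSE, quote = FALSE)
  invisible(sidecar)
}

#' Read activity logs written by [write_activity_logs()]
#'
#' @param dir directory holding the per-log CSVs and `labels.csv`.
#' @return list of `activity_log` objects.
#' @export
read_activity_logs <- function(dir) {
  sidecar <- file.path(dir, "labels.csv")
  if (!file.exists(sidecar)) {
    stop(sprintf("no labels.csv sidecar in %s", dir), call. = FALSE)
  }
  meta <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    rec <- read_recording(
      file.path(dir, paste0(meta$log_id[i], ".csv")),
      device_profile(meta$device[i], sampling_rate = meta$rate[i]))
    activity_log(rec, meta$label[i], meta$center_seconds[i])
  })
}

#' Flatten windows into a reproducibility CSV
#'
#' One row per window: `id, label, length, rate`, then the x, y and z samples
#' in order. All windows must share the same sample count.
#'
#' @param windows list of `activity_window` objects of equal length.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path) {
  ns <- vapply(windows, function(w) w$n, 0L)
  if (length(unique(ns)) != 1L) {
    stop("all windows must have the same sample count", call. = FALSE)
  }
  flat <- t(vapply(windows, function(w) c(w$x, w$y, w$z),
                   numeric(3L * ns[1L])))
  colnames(flat) <- c(sprintf("x%03d", seq_len(ns[1L])),
                      sprintf("y%03d", seq_len(ns[1L])),
                      sprintf("z%03d", seq_len(ns[1L])))
  out <- data.frame(
    id = sprintf("w_%04d", seq_along(windows)),
    label = vapply(windows, function(w)
      if (is.null(w$label)) NA_character_ else w$label, ""),
    length = vapply(windows, function(w) w$length, 0),
    rate = vapply(windows, function(w) w$source_rate, 0),
    flat, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
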