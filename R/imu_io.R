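#' Uniformly sampled single-channel series
#'
#' Minimal container used throughout the pipeline: a numeric vector plus a
#' sampling rate.  All values must be finite.
#'
#' @param values Numeric vector of samples.
#' @param fs Sampling rate in samples per second (> 0).
#' @return A `series1d` object.
#' @export
series1d <- function(values, fs) {
  values <- as.numeric(values)
  fs <- as.numeric(fs)
  if (length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("series values must be finite", call. = FALSE)
  }
  structure(list(values = values, fs = fs), class = "series1d")
}

as_series1d <- function(x, fs = NULL) {
  if (inherits(x, "series1d")) return(x)
  series1d(x, fs)
}

#' @export
print.series1d <- function(x, ...) {
  cat(sprintf("<series1d> %d samples @ %g Hz (%.2f s)\n",
              length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}

#' Tri-axial inertial recording from a lower-back IMU
#'
#' Holds a synchronously sampled 3-axis accelerometer (m/s^2) and 3-axis
#' gyroscope (degrees/s) stream together with the axis convention.  The
#' axis convention is always declared explicitly -- the package never
#' guesses which physical axis a column represents.
#'
#' @param accel Numeric matrix, n x 3, acceleration in m/s^2.
#' @param gyro Numeric matrix, n x 3, angular velocity in degrees/s, or
#'   `NULL` for accelerometer-only recordings.
#' @param fs Sampling rate, samples/s.
#' @param t0 Start time in seconds (default 0; all event times are
#'   recording-relative).
#' @param ap_axis Column index (1--3) of the anterior-posterior
#'   acceleration channel.
#' @param yaw_axis Column index (1--3) of the vertical (yaw) gyroscope
#'   channel.
#' @return An `inertial_recording` object with fields `accel`, `gyro`,
#'   `fs`, `t0`, `n`, `ap_axis`, `yaw_axis`.
#' @export
inertial_recording <- function(accel, gyro = NULL, fs, t0 = 0,
                               ap_axis = 1L, yaw_axis = 3L) {
  accel <- as.matrix(accel)
  if (ncol(accel) != 3) stop("accel must have 3 columns", call. = FALSE)
  if (anyNA(accel)) stop("accel contains NA", call. = FALSE)
  if (!is.null(gyro)) {
    gyro <- as.matrix(gyro)
    if (ncol(gyro) != 3) stop("gyro must have 3 columns", call. = FALSE)
    if (nrow(gyro) != nrow(accel)) {
      stop("accel and gyro must have the same number of samples",
           call. = FALSE)
    }
    if (anyNA(gyro)) stop("gyro contains NA", call. = FALSE)
  }
  if (!(fs > 0)) stop("fs must be positive", call. = FALSE)
  ap_axis <- as.integer(ap_axis); yaw_axis <- as.integer(yaw_axis)
  stopifnot(ap_axis %in% 1:3, yaw_axis %in% 1:3)
  structure(list(accel = accel, gyro = gyro, fs = as.numeric(fs),
                 t0 = as.numeric(t0), n = nrow(accel),
                 ap_axis = ap_axis, yaw_axis = yaw_axis),
            class = "inertial_recording")
}

#' @export
print.inertial_recording <- function(x, ...) {
  cat(sprintf("<inertial_recording> %d samples @ %g Hz (%.1f s), %s\n",
              x$n, x$fs, x$n / x$fs,
              if (is.null(x$gyro)) "accel only" else "accel + gyro"))
  cat(sprintf("  AP axis: %d, yaw axis: %d, t0 = %g s\n",
              x$ap_axis, x$yaw_axis, x$t0))
  invisible(x)
}

#' Extract the anterior-posterior acceleration as a series
#' @param rec An `inertial_recording`.
#' @return A [series1d()] with the AP channel.
#' @export
ap_series <- function(rec) {
  stopifnot(inherits(rec, "inertial_recording"))
  series1d(rec$accel[, rec$ap_axis], rec$fs)
}

#' Extract the vertical (yaw) angular-velocity channel as a series
#' @param rec An `inertial_recording` with a gyroscope.
#' @return A [series1d()] with the yaw-rate channel in degrees/s.
#' @export
yaw_rate_series <- function(rec) {
  stopifnot(inherits(rec, "inertial_recording"))
  if (is.null(rec$gyro)) stop("recording has no gyroscope data", call. = FALSE)
  series1d(rec$gyro[, rec$yaw_axis], rec$fs)
}

EVENT_TYPES <- c("HS", "TO", "STEP")
EVENT_CONTEXTS <- c("TURNING", "NON_TURNING", "UNLABELED")

#' Ordered list of timestamped gait events
#'
#' Events are heel strikes (`HS`), toe offs (`TO`) or unclassified step
#' occurrences (`STEP`).  In turning-aware analyses each event may carry a
#' movement-context label (`TURNING` / `NON_TURNING`); otherwise the context
#' is `UNLABELED`.  Times must be strictly increasing within each type.
#'
#' @param time Numeric vector of event times in seconds.
#' @param type Character vector (recycled) of event types.
#' @param context Character vector (recycled) of context labels.
#' @return A `gait_events` data frame with columns `time`, `type`,
#'   `context`.
#' @export
gait_events <- function(time = numeric(), type = character(),
                        context = "UNLABELED") {
  n <- length(time)
  type <- rep_len(as.character(type), if (n) n else length(type))
  context <- rep_len(as.character(context), n)
  if (length(type) != n) stop("type length mismatch", call. = FALSE)
  if (n && (anyNA(time) || any(!is.finite(time)))) {
    stop("event times must be finite", call. = FALSE)
  }
  if (!all(type %in% EVENT_TYPES)) {
    stop("unknown event type; expected HS, TO or STEP", call. = FALSE)
  }
  if (!all(context %in% EVENT_CONTEXTS)) {
    stop("unknown context; expected TURNING, NON_TURNING or UNLABELED",
         call. = FALSE)
  }
  df <- data.frame(time = as.numeric(time), type = type, context = context,
                   stringsAsFactors = FALSE)
  df <- df[order(df$time), , drop = FALSE]
  rownames(df) <- NULL
  for (tp in unique(df$type)) {
    tt <- df$time[df$type == tp]
    if (length(tt) > 1 && any(diff(tt) <= 0)) {
      stop("event times must be strictly increasing within type ", tp,
           call. = FALSE)
    }
  }
  class(df) <- c("gait_events", "data.frame")
  df
}

#' Filter a gait event list by type
#' @param events A `gait_events` object.
#' @param type Event type to keep ("HS", "TO" or "STEP").
#' @return Numeric vector of event times.
#' @export
event_times <- function(events, type = NULL) {
  stopifnot(inherits(events, "gait_events") || is.data.frame(events))
  if (is.null(type)) return(events$time)
  events$time[events$type == type]
}

#' Read an inertial recording from delimited text
#'
#' The file must contain six signal columns (three accelerometer, three
#' gyroscope) or three accelerometer columns, named via `cols`, plus either
#' a time column or a declared sampling rate.  Rows containing `NA` in any
#' mapped column are rejected.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param cols Named list mapping roles to column names.  Recognised roles:
#'   `time` (optional), `acc_x`, `acc_y`, `acc_z`, and optionally `gyr_x`,
#'   `gyr_y`, `gyr_z`.
#' @param fs Declared sampling rate (samples/s).  Required when there is no
#'   time column; when both are present they must agree within 1%.
#' @param time_unit Unit of the time column: `"s"` or `"ms"`.
#' @param accel_unit `"ms2"` (m/s^2) or `"g"`; `g` values are multiplied by
#'   9.80665.
#' @param gyro_unit `"dps"` (degrees/s) or `"rads"`; rad/s values are
#'   converted to degrees/s.
#' @param ap_axis,yaw_axis Axis indices (1--3) of the anterior-posterior
#'   accelerometer channel and vertical gyroscope channel, in the order the
#'   `acc_*`/`gyr_*` columns were given.
#' @param sep Field separator (default `","`).
#' @return An [inertial_recording()].
#' @export
read_recording <- function(path, cols = list(acc_x = "acc_x", acc_y = "acc_y",
                                             acc_z = "acc_z", gyr_x = "gyr_x",
                                             gyr_y = "gyr_y", gyr_z = "gyr_z"),
                           fs = NULL, time_unit = c("s", "ms"),
                           accel_unit = c("ms2", "g"),
                           gyro_unit = c("dps", "rads"),
                           ap_axis = 1L, yaw_axis = 3L, sep = ",") {
  time_unit <- match.arg(time_unit)
  accel_unit <- match.arg(accel_unit)
  gyro_unit <- match.arg(gyro_unit)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("acc_x", "acc_y", "acc_z")
  has_gyro <- all(c("gyr_x", "gyr_y", "gyr_z") %in% names(cols))
  if (has_gyro) need <- c(need, "gyr_x", "gyr_y", "gyr_z")
  missing_roles <- setdiff(need, names(cols))
  if (length(missing_roles)) {
    stop("column mapping lacks roles: ", paste(missing_roles, collapse = ", "),
         call. = FALSE)
  }
  wanted <- unlist(cols[c(if ("time" %in% names(cols)) "time", need)])
  absent <- setdiff(wanted, names(df))
  if (length(absent)) {
    stop("missing column(s) in file: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  sig_cols <- unlist(cols[need])
  keep <- stats::complete.cases(df[, wanted, drop = FALSE])
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 2) stop("fewer than 2 valid rows", call. = FALSE)

  t0 <- 0
  if ("time" %in% names(cols)) {
    tt <- as.numeric(df[[cols$time]])
    if (time_unit == "ms") tt <- tt / 1000
    dt <- diff(tt)
    if (any(dt <= 0)) stop("time column is not strictly increasing",
                           call. = FALSE)
    fs_inf <- 1 / stats::median(dt)
    # the CWT assumes contiguous sampling: refuse recordings with gaps
    # longer than 2 sample periods (e.g. left by rejected NaN rows)
    if (any(dt > 2.5 * stats::median(dt))) {
      stop("sampling gap longer than 2 samples; split the recording at ",
           "the gap and process the segments independently", call. = FALSE)
    }
    if (!is.null(fs)) {
      if (abs(fs_inf - fs) / fs > 0.01) {
        stop(sprintf(
          "declared fs (%g) and inferred fs (%.3g) disagree by more than 1%%",
          fs, fs_inf), call. = FALSE)
      }
    } else {
      fs <- fs_inf
    }
    t0 <- tt[1]
  } else if (is.null(fs)) {
    stop("either a time column or a declared fs is required", call. = FALSE)
  }

  accel <- as.matrix(df[, unlist(cols[c("acc_x", "acc_y", "acc_z")])])
  storage.mode(accel) <- "double"
  if (accel_unit == "g") accel <- accel * 9.80665
  gyro <- NULL
  if (has_gyro) {
    gyro <- as.matrix(df[, unlist(cols[c("gyr_x", "gyr_y", "gyr_z")])])
    storage.mode(gyro) <- "double"
    if (gyro_unit == "rads") gyro <- gyro * 180 / pi
  }
  inertial_recording(accel, gyro, fs = fs, t0 = t0,
                     ap_axis = ap_axis, yaw_axis = yaw_axis)
}

#' Write an inertial recording to CSV
#'
#' Columns: `time_s, acc_x, acc_y, acc_z[, gyr_x, gyr_y, gyr_z]` in
#' internal units (m/s^2, degrees/s).
#'
#' @param rec An [inertial_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "inertial_recording"))
  tt <- rec$t0 + (seq_len(rec$n) - 1) / rec$fs
  df <- data.frame(time_s = tt,
                   acc_x = rec$accel[, 1], acc_y = rec$accel[, 2],
                   acc_z = rec$accel[, 3])
  if (!is.null(rec$gyro)) {
    df$gyr_x <- rec$gyro[, 1]; df$gyr_y <- rec$gyro[, 2]
    df$gyr_z <- rec$gyro[, 3]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write gait event lists
#'
#' Event files are CSV with header `time_s,type,context` (`context`
#' optional, defaults to `UNLABELED`).  Writing then reading a list is the
#' identity on values to 1 ms.
#'
#' @param path File path.
#' @return `read_events` returns a [gait_events()] object; `write_events`
#'   returns `path` invisibly.
#' @export
read_events <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
    if (!nrow(df)) return(gait_events())
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!all(c("time_s", "type") %in% names(df))) {
    stop("event file must have columns time_s,type[,context]", call. = FALSE)
  }
  if (nrow(df) == 0) return(gait_events())
  ctx <- if ("context" %in% names(df)) df$context else "UNLABELED"
  gait_events(df$time_s, df$type, ctx)
}

#' @param events A [gait_events()] object.
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  df <- data.frame(time_s = round(events$time, 3),
                   type = events$type, context = events$context)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA)
  } else {
    df$time_s <- sprintf("%.3f", df$time_s)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
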