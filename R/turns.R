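#' @title Turn detection from the yaw channel
#' @description A turn is a change of the yaw angle (rotation about the
#'   vertical axis) with magnitude greater than 90 degrees and a duration
#'   between 0.5 and 10 s.  The yaw angle is obtained by drift-corrected
#'   integration of the vertical angular velocity; candidate episodes are
#'   runs of sustained yaw rate whose endpoint-to-endpoint excursion and
#'   duration are then tested against the definition.
#' @name turn_detection
NULL

#' Yaw angle from vertical angular velocity
#'
#' Removes gyroscope bias by subtracting a running-median baseline of the
#' angular velocity (window `yaw_bias_window_s`, default 60 s), then
#' integrates with the cumulative trapezoid rule.  The angle starts at 0.
#' A running median is used rather than a high-pass filter because a
#' high-pass with a corner slow enough to pass a 10 s turn still makes
#' the integrated angle sag back during multi-second turns, truncating
#' their apparent excursion; a 60 s median is essentially immune to
#' episodes of 10 s or less while tracking slow bias drift.
#'
#' @param gyro_vertical Vertical angular velocity in degrees/s, as a
#'   [series1d()] or numeric vector.
#' @param fs Sampling rate when a bare vector is given.
#' @param drift_correct Apply the baseline correction (default `TRUE`;
#'   disable for already-corrected or synthetic drift-free input).
#' @param params A [pipeline_params()] supplying `yaw_bias_window_s`.
#' @return Yaw angle in degrees as a `series1d`.
#' @export
yaw_angle <- function(gyro_vertical, fs = NULL, drift_correct = TRUE,
                      params = pipeline_params()) {
  s <- as_series1d(gyro_vertical, fs)
  if (drift_correct) {
    k <- min(round(params$yaw_bias_window_s * s$fs), length(s$values))
    if (k %% 2 == 0) k <- k - 1
    if (k >= 3) {
      s <- series1d(s$values - stats::runmed(s$values, k, endrule = "median"),
                    s$fs)
    }
  }
  integrate_cumulative(s)
}

#' Detect turning intervals from a yaw-angle series
#'
#' Candidate episodes are maximal runs where the smoothed yaw rate exceeds
#' `turn_rate_threshold_dps` in magnitude; adjacent same-direction runs
#' separated by less than `turn_merge_gap_s` are merged.  An episode is
#' accepted as a turn when its endpoint-to-endpoint yaw excursion exceeds
#' `turn_min_angle_deg` in magnitude and its duration lies within
#' `[turn_min_dur_s, turn_max_dur_s]`.  Rejected episodes belong wholly to
#' the non-turning context.
#'
#' @param angle Yaw angle in degrees, as produced by [yaw_angle()].
#' @param params A [pipeline_params()] object.
#' @param fs Sampling rate when a bare vector is given.
#' @return A data frame of class `turn_intervals` with columns `start`,
#'   `end` (s) and `yaw_excursion` (signed degrees), time-ordered and
#'   non-overlapping.  Zero rows when no turn is found.
#' @export
detect_turns <- function(angle, params = pipeline_params(), fs = NULL) {
  s <- as_series1d(angle, fs)
  n <- length(s$values)
  tt <- (seq_len(n) - 1) / s$fs
  rate <- c(0, diff(s$values)) * s$fs
  # smooth the rate for run extraction (the excursion itself is always
  # measured on the unsmoothed angle)
  rate_s <- lowpass(series1d(rate, s$fs), min(1.5, s$fs / 4), 2)$values
  active <- abs(rate_s) > params$turn_rate_threshold_dps
  dirn <- sign(rate_s)
  runs <- split_runs(active & dirn > 0)
  pos <- runs[runs$flag, c("from", "to"), drop = FALSE]
  runs <- split_runs(active & dirn < 0)
  neg <- runs[runs$flag, c("from", "to"), drop = FALSE]
  pos$dir <- if (nrow(pos)) 1 else numeric(0)
  neg$dir <- if (nrow(neg)) -1 else numeric(0)
  eps <- rbind(pos, neg)
  if (!nrow(eps)) return(empty_turns())
  eps <- eps[order(eps$from), , drop = FALSE]
  # merge same-direction runs separated by a short gap
  gap <- params$turn_merge_gap_s * s$fs
  merged <- eps[1, , drop = FALSE]
  for (i in seq_len(nrow(eps))[-1]) {
    j <- nrow(merged)
    if (eps$dir[i] == merged$dir[j] && eps$from[i] - merged$to[j] <= gap) {
      merged$to[j] <- eps$to[i]
    } else {
      merged <- rbind(merged, eps[i, , drop = FALSE])
    }
  }
  # extend each episode outward to where the rate dies off (same sign,
  # |rate| > 2 deg/s), so the slow tails of a turn count toward its
  # excursion; never past a neighbouring episode
  nm <- nrow(merged)
  for (i in seq_len(nm)) {
    lo_lim <- if (i > 1) merged$to[i - 1] + 1L else 1L
    hi_lim <- if (i < nm) merged$from[i + 1] - 1L else n
    dd <- merged$dir[i]
    j <- merged$from[i]
    while (j > lo_lim && rate_s[j - 1] * dd > 2) j <- j - 1L
    merged$from[i] <- j
    j <- merged$to[i]
    while (j < hi_lim && rate_s[j + 1] * dd > 2) j <- j + 1L
    merged$to[i] <- j
  }
  exc <- s$values[merged$to] - s$values[merged$from]
  dur <- (merged$to - merged$from) / s$fs
  ok <- abs(exc) > params$turn_min_angle_deg &
    dur >= params$turn_min_dur_s & dur <= params$turn_max_dur_s
  out <- data.frame(start = tt[merged$from[ok]], end = tt[merged$to[ok]],
                    yaw_excursion = exc[ok])
  class(out) <- c("turn_intervals", "data.frame")
  out
}

empty_turns <- function() {
  out <- data.frame(start = numeric(), end = numeric(),
                    yaw_excursion = numeric())
  class(out) <- c("turn_intervals", "data.frame")
  out
}

#' Construct a turn-interval table
#' @param start,end Interval bounds in seconds.
#' @param yaw_excursion Signed yaw excursion in degrees.
#' @return A `turn_intervals` data frame.
#' @export
turn_intervals <- function(start, end, yaw_excursion = NA_real_) {
  stopifnot(length(start) == length(end), all(end > start))
  out <- data.frame(start = as.numeric(start), end = as.numeric(end),
                    yaw_excursion = as.numeric(
                      rep_len(yaw_excursion, length(start))))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("turn_intervals", "data.frame")
  out
}
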