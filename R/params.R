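#' Pipeline parameters for wavelet-based step detection
#'
#' Bundles every tunable constant of the detection pipeline.  The defaults
#' are the published operating point of the method: a 10 Hz second-order
#' Butterworth low-pass, a peak-acceptance threshold of 40% of the mean
#' candidate-peak magnitude, a 0.3 s tolerance when matching detected events
#' to a reference system, and the turn definition (yaw excursion larger than
#' 90 degrees lasting 0.5--10 s).
#'
#' @param lowpass_cutoff_hz Low-pass corner frequency applied to the raw
#'   anterior-posterior (AP) acceleration, in Hz.
#' @param filter_order Butterworth filter order (applied forward-backward,
#'   so the effective magnitude response is squared).
#' @param peak_threshold_fraction Fraction of the mean candidate-peak
#'   magnitude a local extremum must exceed to be kept as a gait event.
#'   Must lie strictly between 0 and 1.
#' @param match_tolerance_s Maximum absolute time difference, in seconds,
#'   for a detected event to count as a true positive against a reference
#'   event.
#' @param turn_min_angle_deg Minimum absolute yaw excursion, in degrees,
#'   for an episode to qualify as a turn.
#' @param turn_min_dur_s,turn_max_dur_s Admissible turn duration window in
#'   seconds.
#' @param dominant_freq_band_hz Length-2 numeric; the frequency band (Hz)
#'   searched for the dominant step frequency.  The default 0.5--3 Hz spans
#'   the human step-frequency range and excludes tremor (4--6 Hz) and
#'   postural drift.
#' @param min_peak_separation_cycles Minimum separation between same-type
#'   candidate peaks, as a fraction of the dominant gait period.  When two
#'   candidates are closer, the one with larger magnitude is kept.
#' @param turn_rate_threshold_dps Smoothed yaw-rate magnitude (degrees/s)
#'   above which a sample belongs to a candidate turn episode.
#' @param turn_merge_gap_s Adjacent same-direction yaw-rate runs separated
#'   by less than this many seconds are merged into one candidate turn.
#' @param yaw_bias_window_s Length (s) of the running-median window
#'   subtracted from the vertical angular velocity before integration, to
#'   suppress gyroscope bias drift without truncating multi-second turns.
#'
#' @return An object of class `pipeline_params` (a validated list).
#' @examples
#' p <- pipeline_params()
#' p$peak_threshold_fraction
#' @export
pipeline_params <- function(lowpass_cutoff_hz = 10,
                            filter_order = 2,
                            peak_threshold_fraction = 0.40,
                            match_tolerance_s = 0.3,
                            turn_min_angle_deg = 90,
                            turn_min_dur_s = 0.5,
                            turn_max_dur_s = 10,
                            dominant_freq_band_hz = c(0.5, 3.0),
                            min_peak_separation_cycles = 0.25,
                            turn_rate_threshold_dps = 15,
                            turn_merge_gap_s = 0.2,
                            yaw_bias_window_s = 60) {
  p <- list(
    lowpass_cutoff_hz = as.numeric(lowpass_cutoff_hz),
    filter_order = as.integer(filter_order),
    peak_threshold_fraction = as.numeric(peak_threshold_fraction),
    match_tolerance_s = as.numeric(match_tolerance_s),
    turn_min_angle_deg = as.numeric(turn_min_angle_deg),
    turn_min_dur_s = as.numeric(turn_min_dur_s),
    turn_max_dur_s = as.numeric(turn_max_dur_s),
    dominant_freq_band_hz = as.numeric(dominant_freq_band_hz),
    min_peak_separation_cycles = as.numeric(min_peak_separation_cycles),
    turn_rate_threshold_dps = as.numeric(turn_rate_threshold_dps),
    turn_merge_gap_s = as.numeric(turn_merge_gap_s),
    yaw_bias_window_s = as.numeric(yaw_bias_window_s)
  )
  validate_pipeline_params(p)
  structure(p, class = "pipeline_params")
}

validate_pipeline_params <- function(p) {
  stopifnot(
    p$lowpass_cutoff_hz > 0,
    p$filter_order >= 1,
    p$peak_threshold_fraction > 0, p$peak_threshold_fraction < 1,
    p$match_tolerance_s >= 0,
    p$turn_min_angle_deg > 0,
    p$turn_min_dur_s > 0,
    p$turn_min_dur_s < p$turn_max_dur_s,
    length(p$dominant_freq_band_hz) == 2,
    p$dominant_freq_band_hz[1] > 0,
    p$dominant_freq_band_hz[1] < p$dominant_freq_band_hz[2]
  )
  invisible(p)
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("<pipeline_params>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Read pipeline parameters from a JSON configuration file
#'
#' Unknown keys are rejected so that typos in a configuration file do not
#' silently fall back to defaults.
#'
#' @param path Path to a JSON file whose keys are a subset of the arguments
#'   of [pipeline_params()].
#' @return A `pipeline_params` object.
#' @export
read_params <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(pipeline_params))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) {
    stop("unknown parameter(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_params, cfg)
}
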