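#' @title Synthetic IMU gait recordings with exact ground truth
#' @description Generates lower-back-IMU-like recordings so the whole
#'   pipeline can be tested without any recorded data.  The AP
#'   acceleration is a sum of cadence-locked harmonics whose phases place
#'   the waveform features at stipulated heel-strike and toe-off times,
#'   plus a short Gaussian heel-strike transient, wide-band noise and an
#'   optional tremor-band tone.  This emulates the quasi-periodicity and
#'   impact transients the detector consumes; it is not a biomechanical
#'   model.
#' @name synthetic_gait
NULL

#' Parameters of the gait simulator
#'
#' Defaults describe the treadmill protocol: 120 s at 100 samples/s,
#' preferred-speed walking near 1.8 steps/s.  `step_time_cv` is the
#' fractional standard deviation of the log-normally distributed step
#' intervals (0.03, typical short-term step-time variability of steady
#' walking).  `hs_impulse_amp` (m/s^2) scales the heel-strike transient,
#' `noise_sd` the additive Gaussian sensor/soft-tissue noise, and
#' `tremor_amp`/`tremor_freq` an optional 4--6 Hz tremor-band tone.
#'
#' @param duration Recording length in seconds (>= 10).
#' @param fs Sampling rate, samples/s.
#' @param cadence Commanded step rate, steps/s, in `[0.5, 3]`.
#' @param step_time_cv Coefficient of variation of step intervals.
#' @param stance_fraction Stance fraction of the stride, in
#'   `[0.55, 0.70]`; fixes the toe-off offset after each heel strike.
#' @param hs_impulse_amp Heel-strike transient amplitude, m/s^2.
#' @param harmonic_amps Amplitudes (m/s^2) of the cadence-locked
#'   fundamental and its harmonics.
#' @param noise_sd Additive white-noise standard deviation, m/s^2.
#' @param tremor_amp,tremor_freq Tremor tone amplitude (m/s^2) and
#'   frequency (Hz).
#' @param turn_script Data frame with columns `start`, `excursion_deg`,
#'   `duration_s` scripting turns (home-like mode only), or `NULL`.  With
#'   a `NULL`/empty script, [simulate_homelike()] generates straight
#'   walking bouts on a regular grid with idle gaps and no yaw turns.
#' @param idle_only If `TRUE`, [simulate_homelike()] generates no walking
#'   at all -- only noise (and tremor, if any): the false-positive stress
#'   test.
#' @param turn_cadence_factor Step-rate multiplier inside turns (> 1:
#'   shorter, quicker steps while turning).
#' @param walk_lead_s Seconds of straight walking simulated before and
#'   after each scripted turn (home-like mode).
#' @param seed Integer seed; identical seeds give identical recordings.
#' @return A `gait_sim_params` list.
#' @export
gait_sim_params <- function(duration = 120, fs = 100, cadence = 1.8,
                            step_time_cv = 0.03, stance_fraction = 0.625,
                            hs_impulse_amp = 1.5,
                            harmonic_amps = c(1.0, 0.5, 0.25),
                            noise_sd = 0.15,
                            tremor_amp = 0, tremor_freq = 5,
                            turn_script = NULL,
                            idle_only = FALSE,
                            turn_cadence_factor = 1.1,
                            walk_lead_s = 4,
                            seed = 1) {
  p <- list(duration = duration, fs = fs, cadence = cadence,
            step_time_cv = step_time_cv, stance_fraction = stance_fraction,
            hs_impulse_amp = hs_impulse_amp, harmonic_amps = harmonic_amps,
            noise_sd = noise_sd, tremor_amp = tremor_amp,
            tremor_freq = tremor_freq, turn_script = turn_script,
            idle_only = isTRUE(idle_only),
            turn_cadence_factor = turn_cadence_factor,
            walk_lead_s = walk_lead_s, seed = as.integer(seed))
  stopifnot(p$duration >= 10, p$fs > 0,
            p$cadence >= 0.5, p$cadence <= 3,
            p$step_time_cv >= 0, p$step_time_cv < 0.5,
            p$stance_fraction >= 0.55, p$stance_fraction <= 0.70,
            p$noise_sd >= 0, p$tremor_amp >= 0)
  if (!is.null(p$turn_script)) {
    ts <- p$turn_script
    stopifnot(all(c("start", "excursion_deg", "duration_s") %in% names(ts)))
    ts <- ts[order(ts$start), , drop = FALSE]
    ends <- ts$start + ts$duration_s
    if (any(ts$start[-1] < ends[-nrow(ts)])) {
      stop("scripted turns overlap", call. = FALSE)
    }
    if (any(ends > duration)) {
      stop("scripted turn extends past the recording", call. = FALSE)
    }
    p$turn_script <- ts
  }
  structure(p, class = "gait_sim_params")
}

#' Deterministic turn script for home-like simulations
#'
#' Places `n_turns` turns at regular intervals over the session, with
#' alternating direction, excursions drawn uniformly from
#' `[min_angle, max_angle]` degrees and durations from
#' `[min_dur, max_dur]` s.
#'
#' @param n_turns Number of turns.
#' @param duration Session duration in seconds.
#' @param min_angle,max_angle Excursion magnitude range, degrees.
#' @param min_dur,max_dur Turn duration range, seconds.
#' @param seed Integer seed.
#' @return A data frame with columns `start`, `excursion_deg`,
#'   `duration_s`.
#' @export
make_turn_script <- function(n_turns, duration,
                             min_angle = 90, max_angle = 180,
                             min_dur = 1, max_dur = 4, seed = 1) {
  stopifnot(n_turns >= 1, duration > n_turns * (max_dur + 10))
  with_sim_rng(seed + 77000L, {
    spacing <- duration / (n_turns + 1)
    start <- spacing * seq_len(n_turns) +
      stats::runif(n_turns, -0.1, 0.1) * spacing
    dur <- stats::runif(n_turns, min_dur, max_dur)
    ang <- stats::runif(n_turns, min_angle + 2, max_angle) *
      rep_len(c(1, -1), n_turns)
    data.frame(start = start, excursion_deg = ang, duration_s = dur)
  })
}

# Evaluate code with a private, restored RNG state.
with_sim_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Heel-strike times over [t_from, t_to] with log-normal intervals.
# rate_fun(t) returns the instantaneous step rate at time t.
draw_hs_times <- function(t_from, t_to, cadence, cv, rate_fun = NULL) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -0.5 * sdlog^2            # unit-mean multiplicative jitter
  hs <- numeric(0)
  t <- t_from
  repeat {
    rate <- if (is.null(rate_fun)) cadence else rate_fun(t)
    dt <- stats::rlnorm(1, meanlog, sdlog) / rate
    if (t + dt > t_to) break
    t <- t + dt
    hs <- c(hs, t)
  }
  hs
}

# Harmonic gait waveform locked to the given heel-strike times.
# Phase is piecewise linear with value k at the k-th heel strike; the
# harmonic phases place the toe-off feature a double-support interval
# (2*stance_fraction - 1)*stride after each heel strike.
gait_waveform <- function(tt, hs, p) {
  if (length(hs) < 2) return(numeric(length(tt)))
  k <- seq_along(hs)
  Tm <- mean(diff(hs))
  phase <- stats::approx(hs, k, xout = tt, rule = 2)$y
  before <- tt < hs[1]
  after <- tt > hs[length(hs)]
  phase[before] <- 1 - (hs[1] - tt[before]) / Tm
  phase[after] <- length(hs) + (tt[after] - hs[length(hs)]) / Tm
  dfrac <- (2 * p$stance_fraction - 1) * 2   # TO offset as phase fraction
  amps <- p$harmonic_amps
  # fundamental peaks at integer phase (heel strike); harmonics >= 2 are
  # phased so their superposition peaks at the toe-off phase offset,
  # where the second-order differentiation (which weights harmonic m by
  # m^2) then places its maxima
  w <- numeric(length(tt))
  for (m in seq_along(amps)) {
    ph <- if (m == 1) 0 else -2 * pi * m * dfrac
    w <- w + amps[m] * cos(2 * pi * m * phase + ph)
  }
  # amplitude envelope: ramp in/out over half a step around the bout
  env <- rep(1, length(tt))
  ramp <- 0.5
  t0 <- hs[1] - 0.25 * Tm; t1 <- hs[length(hs)] + 0.75 * Tm
  env[tt < t0 - ramp | tt > t1 + ramp] <- 0
  sel <- tt >= t0 - ramp & tt < t0
  env[sel] <- 0.5 - 0.5 * cos(pi * (tt[sel] - (t0 - ramp)) / ramp)
  sel <- tt > t1 & tt <= t1 + ramp
  env[sel] <- 0.5 + 0.5 * cos(pi * (tt[sel] - t1) / ramp)
  w * env
}

# Gaussian heel-strike transients (sigma 20 ms) at the given times.
hs_transients <- function(tt, hs, amp, fs) {
  out <- numeric(length(tt))
  sig <- 0.02
  half <- ceiling(4 * sig * fs)
  for (h in hs) {
    i0 <- max(1, round(h * fs) - half)
    i1 <- min(length(tt), round(h * fs) + half)
    idx <- i0:i1
    out[idx] <- out[idx] + amp * exp(-(tt[idx] - h)^2 / (2 * sig^2))
  }
  out
}

to_from_hs <- function(hs, stance_fraction) {
  if (length(hs) < 2) return(numeric(0))
  dfrac <- (2 * stance_fraction - 1) * 2
  iv <- diff(hs)
  hs[-length(hs)] + dfrac * iv
}

#' Simulate a treadmill walking recording
#'
#' Continuous straight walking at the commanded cadence, with exact
#' ground-truth heel-strike and toe-off times.  Identical seeds give
#' bit-identical output.
#'
#' @param params A [gait_sim_params()] object (its `turn_script` must be
#'   `NULL`).
#' @return A list with `recording` (an [inertial_recording()]) and
#'   `truth` (fields `hs_times`, `to_times`, `turn_intervals`, `params`).
#' @export
simulate_treadmill <- function(params = gait_sim_params()) {
  stopifnot(inherits(params, "gait_sim_params"))
  if (!is.null(params$turn_script)) {
    stop("treadmill simulation takes no turn script; use simulate_homelike",
         call. = FALSE)
  }
  p <- params
  with_sim_rng(p$seed, {
    n <- round(p$duration * p$fs)
    tt <- (seq_len(n) - 1) / p$fs
    hs <- draw_hs_times(1.5, p$duration - 1.0, p$cadence, p$step_time_cv)
    ap <- gait_waveform(tt, hs, p) +
      hs_transients(tt, hs, p$hs_impulse_amp, p$fs) +
      stats::rnorm(n, 0, p$noise_sd)
    if (p$tremor_amp > 0) {
      ap <- ap + p$tremor_amp *
        sin(2 * pi * p$tremor_freq * tt + stats::runif(1, 0, 2 * pi))
    }
    phase_v <- stats::approx(hs, seq_along(hs), xout = tt, rule = 2)$y
    vert <- 9.80665 + 0.6 * cos(4 * pi * phase_v) +
      stats::rnorm(n, 0, p$noise_sd)
    ml <- 0.4 * cos(pi * phase_v) + stats::rnorm(n, 0, p$noise_sd)
    gyro <- matrix(stats::rnorm(3 * n, 0, 1.5), ncol = 3)
    rec <- inertial_recording(cbind(ap, ml, vert), gyro, fs = p$fs,
                              ap_axis = 1L, yaw_axis = 3L)
    truth <- list(hs_times = hs,
                  to_times = to_from_hs(hs, p$stance_fraction),
                  turn_intervals = empty_turns(), params = p)
    list(recording = rec, truth = truth)
  })
}

#' Simulate a home-like session with scripted turns and idle gaps
#'
#' Walking bouts are built around the scripted turns (each turn preceded
#' and followed by `walk_lead_s` of straight walking; overlapping bouts
#' merge), separated by idle periods containing only noise and tremor.
#' Step rate increases by `turn_cadence_factor` inside turns.  The yaw
#' gyroscope channel realises each scripted turn as a raised-cosine
#' angular-velocity pulse integrating exactly to the scripted excursion,
#' on top of a small constant bias (exercising drift correction) and
#' noise.
#'
#' @param params A [gait_sim_params()] with a non-`NULL` `turn_script`.
#' @return As [simulate_treadmill()]; `truth$turn_intervals` holds the
#'   scripted turns.
#' @export
simulate_homelike <- function(params) {
  stopifnot(inherits(params, "gait_sim_params"))
  ts <- params$turn_script
  if (is.null(ts)) ts <- data.frame(start = numeric(),
                                    excursion_deg = numeric(),
                                    duration_s = numeric())
  p <- params
  with_sim_rng(p$seed, {
    n <- round(p$duration * p$fs)
    tt <- (seq_len(n) - 1) / p$fs
    tend <- ts$start + ts$duration_s
    if (p$idle_only) {
      bouts <- data.frame(from = numeric(), to = numeric())
    } else if (nrow(ts)) {
      # walking bouts around turns, merged when overlapping
      b0 <- pmax(0.5, ts$start - p$walk_lead_s)
      b1 <- pmin(p$duration - 0.5, tend + p$walk_lead_s)
      bouts <- data.frame(from = b0[1], to = b1[1])
      for (i in seq_len(nrow(ts))[-1]) {
        j <- nrow(bouts)
        if (b0[i] <= bouts$to[j] + 2) bouts$to[j] <- max(bouts$to[j], b1[i])
        else bouts <- rbind(bouts, data.frame(from = b0[i], to = b1[i]))
      }
    } else {
      # no scripted turns: straight-walking bouts on a regular grid
      from <- seq(1, max(1, p$duration - 11), by = 31)
      bouts <- data.frame(from = from,
                          to = pmin(from + 25, p$duration - 0.5))
      bouts <- bouts[bouts$to - bouts$from > 6, , drop = FALSE]
    }
    in_turn <- function(t) {
      out <- logical(length(t))
      for (i in seq_len(nrow(ts))) {
        out <- out | (t >= ts$start[i] & t <= tend[i])
      }
      out
    }
    rate_fun <- function(t) {
      p$cadence * ifelse(in_turn(t), p$turn_cadence_factor, 1)
    }
    ap <- stats::rnorm(n, 0, p$noise_sd)
    hs_all <- numeric(0)
    for (i in seq_len(nrow(bouts))) {
      hs <- draw_hs_times(bouts$from[i] + 1.0, bouts$to[i] - 0.5,
                          p$cadence, p$step_time_cv, rate_fun)
      if (length(hs) < 4) next
      ap <- ap + gait_waveform(tt, hs, p) +
        hs_transients(tt, hs, p$hs_impulse_amp, p$fs)
      hs_all <- c(hs_all, hs)
    }
    if (p$tremor_amp > 0) {
      ap <- ap + p$tremor_amp *
        sin(2 * pi * p$tremor_freq * tt + stats::runif(1, 0, 2 * pi))
    }
    # yaw-rate channel: raised-cosine pulse per scripted turn + bias
    yaw <- stats::rnorm(n, 0, 1.0) + 0.5
    for (i in seq_len(nrow(ts))) {
      sel <- tt >= ts$start[i] & tt <= tend[i]
      u <- (tt[sel] - ts$start[i]) / ts$duration_s[i]
      yaw[sel] <- yaw[sel] + ts$excursion_deg[i] / ts$duration_s[i] *
        (1 - cos(2 * pi * u))
    }
    vert <- 9.80665 + stats::rnorm(n, 0, p$noise_sd)
    ml <- stats::rnorm(n, 0, p$noise_sd)
    gyro <- cbind(stats::rnorm(n, 0, 1.0), stats::rnorm(n, 0, 1.0), yaw)
    rec <- inertial_recording(cbind(ap, ml, vert), gyro, fs = p$fs,
                              ap_axis = 1L, yaw_axis = 3L)
    truth <- list(hs_times = sort(hs_all),
                  to_times = sort(unlist(lapply(
                    split(hs_all, findInterval(hs_all, bouts$from)),
                    to_from_hs, stance_fraction = p$stance_fraction))),
                  turn_intervals = turn_intervals(ts$start, tend,
                                                  ts$excursion_deg),
                  params = p)
    list(recording = rec, truth = truth)
  })
}
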