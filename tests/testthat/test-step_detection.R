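test_that("threshold_peaks implements the 40% mean-magnitude rule", {
  expect_equal(threshold_peaks(c(10, 9, 1), 0.4), c(10, 9))
  expect_equal(threshold_peaks(c(5, 5, 5), 0.4), c(5, 5, 5))
  expect_equal(threshold_peaks(3, 0.4), 3)
  expect_equal(threshold_peaks(numeric(), 0.4), numeric())
  df <- data.frame(magnitude = c(10, 9, 1), index = 1:3)
  expect_equal(threshold_peaks(df, 0.4)$index, 1:2)
  expect_error(threshold_peaks(c(1, 2), 1.5))
})

test_that("detector handles degenerate inputs per contract", {
  expect_error(detect_hs_to(series1d(rep(0, 100), 100)), "10 s")
  # constant-zero AP signal: no dominant frequency -> empty list + warning
  expect_warning(ev <- detect_hs_to(series1d(rep(0, 2000), 100)),
                 "no dominant frequency")
  expect_equal(nrow(ev), 0)
  # long white noise has no dominant frequency either
  set.seed(42)
  expect_warning(ev <- detect_hs_to(series1d(rnorm(12000), 100)),
                 "no dominant frequency")
  expect_equal(nrow(ev), 0)
})

test_that("pure 2 Hz sinusoid yields one HS per cycle, uniformly spaced", {
  ev <- detect_hs_to(tone(2, 60, 100))
  hs <- event_times(ev, "HS")
  expect_gte(length(hs), 118)
  expect_lte(length(hs), 121)
  gaps <- diff(hs)
  expect_lt(max(gaps) - min(gaps), 0.021)  # uniform within ~2 samples
  expect_equal(median(gaps), 0.5, tolerance = 0.01)
})

test_that("synthetic treadmill HS accuracy exceeds 99% (seed 1)", {
  sim <- simulate_treadmill(gait_sim_params(seed = 1))
  ev <- detect_hs_to(sim$recording)
  m <- match_events(event_times(ev, "HS"), sim$truth$hs_times, 0.3)
  expect_gte(100 * m$tp / (m$tp + m$fp + m$fn), 99)
  expect_lt(mean(abs(m$diffs)), 0.05)
})

test_that("amplitude scaling leaves event times unchanged", {
  sim <- simulate_treadmill(gait_sim_params(duration = 60, seed = 7))
  ap <- ap_series(sim$recording)
  ev1 <- detect_hs_to(ap)
  for (c in c(0.5, 3)) {
    evc <- detect_hs_to(series1d(c * ap$values, ap$fs))
    expect_equal(evc$time, ev1$time)
    expect_equal(evc$type, ev1$type)
  }
})

test_that("time shift moves events by the shift (away from edges)", {
  sim <- simulate_treadmill(gait_sim_params(duration = 80, seed = 8))
  ap <- ap_series(sim$recording)
  k <- 150  # 1.5 s
  shifted <- series1d(ap$values[(k + 1):length(ap$values)], ap$fs)
  t1 <- event_times(detect_hs_to(ap), "HS")
  t2 <- event_times(detect_hs_to(shifted), "HS") + k / ap$fs
  # compare on the common interior
  t1 <- t1[t1 > 6 & t1 < 74]
  t2 <- t2[t2 > 6 & t2 < 74]
  m <- match_events(t2, t1, 0.02)
  expect_gte(m$tp / length(t1), 0.98)
  expect_lt(max(abs(m$diffs)), 0.011)
})

test_that("HS/TO alternate with physiological spacing across seeds", {
  for (seed in c(2, 3)) {
    sim <- simulate_treadmill(gait_sim_params(seed = seed))
    ev <- detect_hs_to(sim$recording)
    expect_true(all(rle(ev$type)$lengths == 1))    # strict alternation
    Fa <- attr(ev, "manifest")$dominant_frequency_hz
    expect_gte(min(diff(ev$time)), 0.25 / Fa)
    m <- match_events(event_times(ev, "HS"), sim$truth$hs_times, 0.3)
    expect_lt(mean(abs(m$diffs)), 0.05)
  }
})

test_that("an upside-down sensor is rectified by orientation check", {
  sim <- simulate_treadmill(gait_sim_params(duration = 60, seed = 9))
  ap <- ap_series(sim$recording)
  ev <- detect_hs_to(series1d(-ap$values, ap$fs))
  expect_true(attr(ev, "manifest")$orientation_flipped)
  m <- match_events(event_times(ev, "HS"), sim$truth$hs_times, 0.3)
  expect_gte(100 * m$tp / (m$tp + m$fp + m$fn), 98)
})

test_that("home-like detection labels contexts and counts steps", {
  script <- make_turn_script(8, 220, seed = 2)
  sim <- simulate_homelike(gait_sim_params(duration = 220, fs = 128,
                                           turn_script = script, seed = 2))
  ev <- detect_steps_homelike(sim$recording)
  expect_true(all(ev$type == "STEP"))
  expect_setequal(unique(ev$context), c("TURNING", "NON_TURNING"))
  # per-turn step counts within +-1 of truth for >= 90% of turns,
  # after compensating the constant detection lag of the turning stage
  ti <- sim$truth$turn_intervals
  m <- match_events(event_times(ev), sim$truth$hs_times, 0.3)
  lag <- median(m$diffs)
  ok <- 0
  for (i in seq_len(nrow(ti))) {
    truth_n <- sum(sim$truth$hs_times >= ti$start[i] &
                     sim$truth$hs_times <= ti$end[i])
    det_n <- sum(ev$time - lag >= ti$start[i] - 0.1 &
                   ev$time - lag <= ti$end[i] + 0.1)
    if (abs(det_n - truth_n) <= 1) ok <- ok + 1
  }
  expect_gte(ok / nrow(ti), 0.9)
})

test_that("empty turn list gives all NON_TURNING; full-turn recording all TURNING", {
  sim <- simulate_homelike(gait_sim_params(duration = 120, fs = 128,
                                           seed = 3))
  ev <- detect_steps_homelike(sim$recording, turns = gaitcwt:::empty_turns())
  expect_true(all(ev$context == "NON_TURNING"))
  expect_gt(nrow(ev), 50)
  span <- turn_intervals(0, sim$recording$n / sim$recording$fs)
  ev2 <- detect_steps_homelike(sim$recording, turns = span)
  expect_true(all(ev2$context == "TURNING"))
})

test_that("overlapping turn intervals are rejected", {
  sim <- simulate_homelike(gait_sim_params(duration = 60, fs = 100,
                                           seed = 4))
  bad <- data.frame(start = c(5, 8), end = c(10, 12),
                    yaw_excursion = c(100, -100))
  class(bad) <- c("turn_intervals", "data.frame")
  expect_error(detect_steps_homelike(sim$recording, turns = bad), "overlap")
})
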