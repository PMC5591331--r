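test_that("read_recording parses a small CSV with declared fs", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_tiny_recording_csv(f, n = 3, fs = 100, time_col = FALSE)
  rec <- read_recording(f, cols = list(acc_x = "acc_x", acc_y = "acc_y",
                                       acc_z = "acc_z"), fs = 100)
  expect_s3_class(rec, "inertial_recording")
  expect_equal(rec$n, 3)
  expect_equal(rec$fs, 100)
  expect_null(rec$gyro)
})

test_that("time column in ms yields seconds and the right fs", {
  f <- withr::local_tempfile(fileext = ".csv")
  n <- 50
  df <- data.frame(t_ms = (seq_len(n) - 1) * 10,   # 10 ms step -> 100 Hz
                   ax = rnorm(n), ay = rnorm(n), az = rnorm(n))
  utils::write.csv(df, f, row.names = FALSE)
  rec <- read_recording(f, cols = list(time = "t_ms", acc_x = "ax",
                                       acc_y = "ay", acc_z = "az"),
                        time_unit = "ms")
  # oracle: fs from the median time step
  expect_equal(rec$fs, 1 / median(diff(df$t_ms / 1000)), tolerance = 1e-9)
  expect_equal(rec$fs, 100, tolerance = 1e-6)
})

test_that("format and data errors are raised, with no partial object", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_tiny_recording_csv(f, n = 10)
  expect_error(read_recording(f, cols = list(acc_x = "nope", acc_y = "acc_y",
                                             acc_z = "acc_z"), fs = 100),
               "missing column")
  # declared vs inferred fs mismatch > 1%
  expect_error(read_recording(f, cols = list(time = "time_s", acc_x = "acc_x",
                                             acc_y = "acc_y", acc_z = "acc_z"),
                              fs = 128),
               "disagree")
  # non-monotonic time
  df <- utils::read.csv(f)
  df$time_s[3] <- df$time_s[2]
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_recording(f, cols = list(time = "time_s", acc_x = "acc_x",
                                             acc_y = "acc_y",
                                             acc_z = "acc_z")),
               "not strictly increasing")
})

test_that("NaN rows are rejected; a long gap is refused", {
  f <- withr::local_tempfile(fileext = ".csv")
  n <- 60
  tt <- (seq_len(n) - 1) / 100
  df <- data.frame(time_s = tt, acc_x = rnorm(n), acc_y = rnorm(n),
                   acc_z = rnorm(n))
  df$acc_x[10] <- NA              # single bad row: dropped, gap of 2 ok
  utils::write.csv(df, f, row.names = FALSE)
  rec <- read_recording(f, cols = list(time = "time_s", acc_x = "acc_x",
                                       acc_y = "acc_y", acc_z = "acc_z"))
  expect_equal(rec$n, n - 1)
  df$acc_x[20:25] <- NA           # 6-sample gap: refuse
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_recording(f, cols = list(time = "time_s", acc_x = "acc_x",
                                             acc_y = "acc_y",
                                             acc_z = "acc_z")),
               "gap")
})

test_that("unit conversions are applied per dialect", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(ax = rep(1, 10), ay = 0, az = 0,
                   gx = rep(pi, 10), gy = 0, gz = 0)
  utils::write.csv(df, f, row.names = FALSE)
  rec <- read_recording(f, cols = list(acc_x = "ax", acc_y = "ay",
                                       acc_z = "az", gyr_x = "gx",
                                       gyr_y = "gy", gyr_z = "gz"),
                        fs = 100, accel_unit = "g", gyro_unit = "rads")
  expect_equal(rec$accel[1, 1], 9.80665)
  expect_equal(rec$gyro[1, 1], 180)
})

test_that("event lists round-trip through CSV and JSON at 1 ms", {
  ev <- gait_events(c(0.5, 1.234567, 2.002, 3.5, 4.75), "HS")
  for (ext in c(".csv", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_events(ev, f)
    back <- read_events(f)
    expect_equal(back$time, round(ev$time, 3), tolerance = 5e-4)
    expect_equal(back$type, ev$type)
    expect_equal(back$context, ev$context)
  }
})

test_that("empty event list writes a headed file that reads back empty", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(gait_events(), f)
  expect_match(readLines(f)[1], "time_s")
  expect_equal(nrow(read_events(f)), 0)
})

test_that("event list invariants are enforced", {
  expect_error(gait_events(c(1, 2), c("HS", "XX")), "unknown event type")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,type", "2.0,HS", "1.0,HS", "1.0,HS"), f)
  expect_error(read_events(f), "strictly increasing")
  # equal times across types are fine, within type they are not
  expect_silent(gait_events(c(1, 1), c("HS", "TO")))
})

test_that("recording round-trips through write_recording/read_recording", {
  sim <- simulate_treadmill(gait_sim_params(duration = 12, seed = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(sim$recording, f)
  rec <- read_recording(f, cols = list(time = "time_s", acc_x = "acc_x",
                                       acc_y = "acc_y", acc_z = "acc_z",
                                       gyr_x = "gyr_x", gyr_y = "gyr_y",
                                       gyr_z = "gyr_z"))
  expect_equal(rec$n, sim$recording$n)
  expect_equal(rec$accel, sim$recording$accel, ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("pipeline defaults equal the published constants", {
  p <- pipeline_params()
  expect_equal(p$lowpass_cutoff_hz, 10)
  expect_equal(p$filter_order, 2L)
  expect_equal(p$peak_threshold_fraction, 0.40)
  expect_equal(p$match_tolerance_s, 0.3)
  expect_equal(p$turn_min_angle_deg, 90)
  expect_equal(p$turn_min_dur_s, 0.5)
  expect_equal(p$turn_max_dur_s, 10)
  expect_equal(p$dominant_freq_band_hz, c(0.5, 3.0))
  expect_error(pipeline_params(peak_threshold_fraction = 1.2))
  expect_error(pipeline_params(turn_min_dur_s = 11, turn_max_dur_s = 10))
})

test_that("read_params accepts known keys and rejects unknown ones", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"lowpass_cutoff_hz": 8, "peak_threshold_fraction": 0.3}', f)
  p <- read_params(f)
  expect_equal(p$lowpass_cutoff_hz, 8)
  expect_equal(p$peak_threshold_fraction, 0.3)
  writeLines('{"lowpss_cutoff_hz": 8}', f)
  expect_error(read_params(f), "unknown parameter")
})
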