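# Shared fixtures, built in code.

# a sine-based series
tone <- function(freq, dur, fs, amp = 1, phase = 0) {
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  series1d(amp * sin(2 * pi * freq * tt + phase), fs)
}

# tiny recording CSV on disk; returns the path
write_tiny_recording_csv <- function(path, n = 5, fs = 100,
                                     gyro = TRUE, time_col = TRUE) {
  tt <- (seq_len(n) - 1) / fs
  df <- data.frame(acc_x = sin(tt), acc_y = cos(tt), acc_z = 9.8 + 0 * tt)
  if (gyro) {
    df$gyr_x <- 0 * tt; df$gyr_y <- 0 * tt; df$gyr_z <- 10 + 0 * tt
  }
  if (time_col) df <- cbind(time_s = tt, df)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# yaw-angle series from a piecewise-constant rate spec:
# list of c(rate_dps, duration_s), padded with stillness
angle_from_rates <- function(..., fs = 100, pad = 5) {
  segs <- list(...)
  rate <- c(rep(0, pad * fs),
            unlist(lapply(segs, function(s) rep(s[1], round(s[2] * fs)))),
            rep(0, pad * fs))
  series1d(cumsum(rate) / fs, fs)
}

# brute-force matching oracle: enumerates all monotone one-to-one
# assignments, maximising matches then minimising total |diff|
match_oracle <- function(d, r, tol) {
  d <- sort(d); r <- sort(r)
  nd <- length(d); nr <- length(r)
  best <- c(0, Inf)
  rec <- function(i, j, cnt, tot) {
    if (i > nd || j > nr) {
      if (cnt > best[1] || (cnt == best[1] && tot < best[2])) {
        best <<- c(cnt, tot)
      }
      return(invisible())
    }
    rec(i + 1, j, cnt, tot)
    rec(i, j + 1, cnt, tot)
    if (abs(d[i] - r[j]) < tol) {
      rec(i + 1, j + 1, cnt + 1, tot + abs(d[i] - r[j]))
    }
  }
  if (nd > 0 && nr > 0) rec(1, 1, 0, 0)
  list(tp = best[1], total_diff = best[2])
}

# exhaustive turn oracle: tests every sample-pair window of a yaw-angle
# series against the (>min_angle, [min_dur, max_dur]) rule and keeps
# maximal monotone windows
turn_oracle <- function(angle, min_angle = 90, min_dur = 0.5,
                        max_dur = 10) {
  v <- angle$values; fs <- angle$fs; n <- length(v)
  hits <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dur <- (j - i) / fs
      if (dur < min_dur || dur > max_dur) next
      exc <- v[j] - v[i]
      if (abs(exc) <= min_angle) next
      seg <- v[i:j]
      mono <- if (exc > 0) all(diff(seg) >= -1e-9) else
        all(diff(seg) <= 1e-9)
      if (mono) hits[[length(hits) + 1]] <- c(i, j, exc)
    }
  }
  if (!length(hits)) return(data.frame(from = integer(), to = integer(),
                                       exc = numeric()))
  h <- do.call(rbind, hits)
  # keep maximal windows (not contained in another window)
  keep <- rep(TRUE, nrow(h))
  for (k in seq_len(nrow(h))) {
    if (any(h[, 1] <= h[k, 1] & h[, 2] >= h[k, 2] &
              (h[, 1] < h[k, 1] | h[, 2] > h[k, 2]))) keep[k] <- FALSE
  }
  h <- h[keep, , drop = FALSE]
  data.frame(from = h[, 1], to = h[, 2], exc = h[, 3])
}
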