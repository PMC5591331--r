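#' @title Heel-strike and toe-off detection
#' @description The core detector.  The anterior-posterior (AP)
#'   acceleration is detrended, low-pass filtered (10 Hz, zero-phase
#'   Butterworth), integrated, and differentiated by a single-scale CWT
#'   with a `gaus1` wavelet; local minima of that signal are heel strikes.
#'   The first-order signal is differentiated again with a `gaus2` wavelet;
#'   local maxima of the result are toe offs.  A candidate extremum is kept
#'   only when its magnitude exceeds 40% of the mean magnitude of all
#'   candidates of the same stage.
#' @name step_detection
NULL

# Local extrema of a numeric vector.  polarity "max" returns indices of
# local maxima, "min" of local minima.  Plateaus report their last rising
# sample; endpoints are never extrema.
find_extrema <- function(v, polarity = c("max", "min")) {
  polarity <- match.arg(polarity)
  if (polarity == "min") v <- -v
  d <- diff(v)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2) return(integer())
  sv <- s[nz]
  turn <- which(sv[-length(sv)] > 0 & sv[-1] < 0)
  nz[turn] + 1L
}

# Candidate extrema of a coefficient series as a data frame.
# For minima only negative-valued extrema qualify (magnitude = -value),
# for maxima only positive-valued ones (magnitude = value): a "peak" on
# the wrong side of zero is not a gait event.
candidate_peaks <- function(coef, polarity = c("min", "max")) {
  polarity <- match.arg(polarity)
  v <- coef$values
  idx <- find_extrema(v, if (polarity == "min") "min" else "max")
  val <- v[idx]
  keep <- if (polarity == "min") val < 0 else val > 0
  idx <- idx[keep]; val <- val[keep]
  data.frame(index = idx,
             time = (idx - 1) / coef$fs,
             value = val,
             magnitude = abs(val),
             polarity = polarity,
             stringsAsFactors = FALSE)
}

# Enforce a minimum separation (in samples) between candidates, keeping
# the larger magnitude when two candidates are too close.
enforce_min_separation <- function(cands, min_sep_samples) {
  if (nrow(cands) < 2) return(cands)
  ord <- order(-cands$magnitude, cands$index)
  kept <- logical(nrow(cands))
  kept_idx <- numeric(0)
  for (i in ord) {
    if (!length(kept_idx) ||
        all(abs(kept_idx - cands$index[i]) >= min_sep_samples)) {
      kept[i] <- TRUE
      kept_idx <- c(kept_idx, cands$index[i])
    }
  }
  out <- cands[kept, , drop = FALSE]
  out[order(out$index), , drop = FALSE]
}

#' Retain candidate peaks above a fraction of the mean peak magnitude
#'
#' Implements the relative acceptance rule: a candidate is kept when its
#' magnitude exceeds `fraction` times the mean magnitude of all candidates
#' in the same set.  The rule is scale-free: multiplying the signal by a
#' positive constant does not change which peaks survive.
#'
#' @param cands A data frame with a `magnitude` column (as produced
#'   internally), or a bare numeric vector of magnitudes.
#' @param fraction Threshold fraction in (0, 1); default 0.40.
#' @return The retained subset, same type as the input.
#' @examples
#' threshold_peaks(c(10, 9, 1), 0.4)  # mean 6.67, cut 2.67 -> keep 10, 9
#' @export
threshold_peaks <- function(cands, fraction = 0.40) {
  stopifnot(fraction > 0, fraction < 1)
  mags <- if (is.data.frame(cands)) cands$magnitude else as.numeric(cands)
  if (!length(mags)) return(cands)
  cut <- fraction * mean(mags)
  keep <- mags > cut
  if (is.data.frame(cands)) cands[keep, , drop = FALSE] else cands[keep]
}

# Orientation normalisation: with the stated axis convention the filtered
# AP acceleration carries sharp positive heel-strike transients, giving
# positive skewness.  A sensor mounted backwards inverts the axis; detect
# that from the skewness sign and flip.
orientation_flip_needed <- function(v) {
  m <- mean(v); s <- stats::sd(v)
  if (s == 0) return(FALSE)
  mean((v - m)^3) / s^3 < 0
}

# CWT at scale a, mirror-tiling the input when it is shorter than the
# 10*a samples the strict entry point requires (used for short home-like
# segments).
cwt_padded <- function(s, kind, a) {
  n <- length(s$values)
  need <- ceiling(10 * a)
  if (n >= need) return(cwt_single_scale(s, kind, a))
  v <- s$values
  reps <- 2 * (ceiling(need / n) + 1)    # even tile count per side
  tiles <- lapply(seq_len(2 * reps + 1), function(k) {
    if (k %% 2 == 1) v else rev(v)
  })
  full <- unlist(tiles)
  start_idx <- reps * n + 1              # centre tile, original orientation
  lead <- min(reps * n, need)
  seg <- full[(start_idx - lead):(start_idx + n - 1 + lead)]
  co <- cwt_single_scale(series1d(seg, s$fs), kind, a)
  series1d(co$values[(lead + 1):(lead + n)], s$fs)
}

#' Detect heel strikes and toe offs from AP acceleration
#'
#' Runs the full single-sensor pipeline on an anterior-posterior
#' acceleration trace: detrend, zero-phase low-pass at
#' `params$lowpass_cutoff_hz`, cumulative integration, `gaus1` CWT at the
#' scale matched to the dominant step frequency (minima = heel strikes),
#' then a `gaus2` CWT of the first-order signal (maxima = toe offs).  Both
#' candidate sets are filtered by the 40% mean-peak rule, a physiological
#' refractory separation of `min_peak_separation_cycles` of the gait
#' period, and finally forced to alternate HS/TO by dropping the weaker of
#' two consecutive same-type events.
#'
#' @param ap AP acceleration as a [series1d()], numeric vector (with
#'   `fs`), or an [inertial_recording()] (its AP channel is used).
#' @param params A [pipeline_params()] object.
#' @param fs Sampling rate when `ap` is a bare vector.
#' @return A [gait_events()] object with HS and TO events.  Attribute
#'   `"manifest"` records the dominant frequency, wavelet scales and
#'   whether the axis orientation was flipped.  If no dominant frequency
#'   exists in the search band, an empty event list is returned with a
#'   warning.
#' @export
detect_hs_to <- function(ap, params = pipeline_params(), fs = NULL) {
  if (inherits(ap, "inertial_recording")) ap <- ap_series(ap)
  s <- as_series1d(ap, fs)
  if (length(s$values) / s$fs < 10) {
    stop("recording shorter than 10 s", call. = FALSE)
  }
  filt <- lowpass(linear_detrend(s), params$lowpass_cutoff_hz,
                  params$filter_order)
  Fa <- tryCatch(
    dominant_frequency(filt, params$dominant_freq_band_hz),
    gaitcwt_no_dominant_frequency = function(e) NA_real_)
  if (is.na(Fa)) {
    warning("no dominant frequency in band; returning empty event list")
    out <- gait_events()
    attr(out, "manifest") <- list(status = "no_dominant_frequency")
    return(out)
  }
  flip <- orientation_flip_needed(filt$values)
  if (flip) filt$values <- -filt$values
  y <- integrate_cumulative(filt)
  delta <- 1 / s$fs
  a1 <- scale_from_frequency(wavelet_center_frequency("gaus1"), Fa, delta)
  d1 <- cwt_single_scale(y, "gaus1", a1)
  sep <- params$min_peak_separation_cycles / Fa * s$fs
  hs <- candidate_peaks(d1, "min")
  hs <- enforce_min_separation(hs, sep)
  hs <- threshold_peaks(hs, params$peak_threshold_fraction)
  a2 <- scale_from_frequency(wavelet_center_frequency("gaus2"), Fa, delta)
  d2 <- cwt_single_scale(d1, "gaus2", a2)
  to <- candidate_peaks(d2, "max")
  to <- enforce_min_separation(to, sep)
  to <- threshold_peaks(to, params$peak_threshold_fraction)
  ev <- rbind(
    if (nrow(hs)) data.frame(time = hs$time, type = "HS",
                             magnitude = hs$magnitude),
    if (nrow(to)) data.frame(time = to$time, type = "TO",
                             magnitude = to$magnitude))
  ev <- enforce_alternation(ev)
  out <- gait_events(ev$time, ev$type)
  attr(out, "manifest") <- list(
    dominant_frequency_hz = Fa,
    scale_gaus1 = a1, scale_gaus2 = a2,
    wavelets = c("gaus1", "gaus2"),
    orientation_flipped = flip)
  out
}

# Force HS/TO alternation: among consecutive same-type events keep the
# one with the larger magnitude.
enforce_alternation <- function(ev) {
  if (is.null(ev) || nrow(ev) < 2) {
    return(ev %||% data.frame(time = numeric(), type = character(),
                              magnitude = numeric()))
  }
  ev <- ev[order(ev$time), , drop = FALSE]
  repeat {
    same <- which(ev$type[-1] == ev$type[-nrow(ev)])
    if (!length(same)) break
    drop <- vapply(same, function(i) {
      if (ev$magnitude[i] >= ev$magnitude[i + 1]) i + 1L else i
    }, integer(1))
    ev <- ev[-unique(drop), , drop = FALSE]
  }
  ev
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Turning-aware step detection for home-like recordings
#'
#' Splits the recording into turning and non-turning segments (from
#' supplied or freshly detected turn intervals) and runs step detection
#' per segment with a `gaus2` mother wavelet inside turns and a `db2`
#' wavelet outside -- the wavelet shapes that match the integrated AP
#' acceleration of turning vs. straight steps.  Only step-occurrence
#' events (type `"STEP"`) are emitted, labelled `TURNING` or
#' `NON_TURNING`.  The dominant frequency and the 40% mean-peak threshold
#' are computed per context group (all turning segments pooled, all
#' non-turning segments pooled), mirroring the split of the dataset into
#' a turning and a non-turning part.
#'
#' @param rec An [inertial_recording()] with accelerometer (and, unless
#'   `turns` is supplied, gyroscope) data.
#' @param turns A data frame of turn intervals (columns `start`, `end`) as
#'   returned by [detect_turns()], or `NULL` to detect them from the yaw
#'   channel.
#' @param params A [pipeline_params()] object.
#' @return A [gait_events()] object of `STEP` events with context labels
#'   and a `"manifest"` attribute.
#' @export
detect_steps_homelike <- function(rec, turns = NULL,
                                  params = pipeline_params()) {
  stopifnot(inherits(rec, "inertial_recording"))
  if (is.null(turns)) {
    ang <- yaw_angle(yaw_rate_series(rec), params = params)
    turns <- detect_turns(ang, params)
  }
  if (nrow(turns)) {
    turns <- turns[order(turns$start), , drop = FALSE]
    if (any(turns$end[-nrow(turns)] > turns$start[-1])) {
      stop("turn intervals overlap", call. = FALSE)
    }
    if (any(turns$start < 0) || any(turns$end > rec$n / rec$fs)) {
      stop("turn intervals outside recording span", call. = FALSE)
    }
  }
  fs <- rec$fs
  n <- rec$n
  tt <- (seq_len(n) - 1) / fs
  turning <- rep(FALSE, n)
  for (i in seq_len(nrow(turns))) {
    turning[tt >= turns$start[i] & tt <= turns$end[i]] <- TRUE
  }
  segs <- split_runs(turning)

  s <- ap_series(rec)
  filt <- lowpass(linear_detrend(s), params$lowpass_cutoff_hz,
                  params$filter_order)
  if (orientation_flip_needed(filt$values)) filt$values <- -filt$values

  ctx_of <- function(flag) if (flag) "TURNING" else "NON_TURNING"
  wavelet_of <- function(flag) if (flag) "gaus2" else "db2"
  margin <- round(2 * fs)         # context margin around short segments
  delta <- 1 / fs

  # group dominant frequency per context (pooled periodograms)
  Fa_ctx <- c(TURNING = NA_real_, NON_TURNING = NA_real_)
  for (ctx_flag in c(TRUE, FALSE)) {
    sub <- segs[segs$flag == ctx_flag, , drop = FALSE]
    vals <- lapply(seq_len(nrow(sub)), function(i) {
      filt$values[sub$from[i]:sub$to[i]]
    })
    Fa_ctx[ctx_of(ctx_flag)] <- pooled_dominant_frequency(
      vals, fs, params$dominant_freq_band_hz)
  }
  # fall back to the other context's estimate when one group has no
  # usable spectrum (e.g. no turns at all)
  if (is.na(Fa_ctx["TURNING"])) Fa_ctx["TURNING"] <- Fa_ctx["NON_TURNING"]
  if (is.na(Fa_ctx["NON_TURNING"])) Fa_ctx["NON_TURNING"] <- Fa_ctx["TURNING"]
  if (all(is.na(Fa_ctx))) {
    warning("no dominant frequency in any segment; returning empty list")
    out <- gait_events()
    attr(out, "manifest") <- list(status = "no_dominant_frequency")
    return(out)
  }

  # per-segment candidates, pooled per context for the threshold
  all_cands <- list()
  for (i in seq_len(nrow(segs))) {
    from <- segs$from[i]; to <- segs$to[i]; flag <- segs$flag[i]
    ctx <- ctx_of(flag)
    Fa <- Fa_ctx[[ctx]]
    kind <- wavelet_of(flag)
    a <- scale_from_frequency(wavelet_center_frequency(kind), Fa, delta)
    lo <- max(1L, from - margin); hi <- min(n, to + margin)
    seg <- series1d(filt$values[lo:hi], fs)
    y <- integrate_cumulative(seg)
    co <- cwt_padded(y, kind, a)
    cands <- candidate_peaks(co, "max")
    # map back to absolute sample indices; keep only those inside the core
    cands$index <- cands$index + lo - 1L
    cands <- cands[cands$index >= from & cands$index <= to, , drop = FALSE]
    if (!nrow(cands)) next
    cands$time <- (cands$index - 1) / fs
    cands <- enforce_min_separation(
      cands, params$min_peak_separation_cycles / Fa * fs)
    cands$context <- ctx
    all_cands[[length(all_cands) + 1]] <- cands
  }
  cands <- do.call(rbind, all_cands)
  if (is.null(cands) || !nrow(cands)) {
    out <- gait_events()
  } else {
    kept <- do.call(rbind, lapply(split(cands, cands$context),
                                  threshold_peaks,
                                  fraction = params$peak_threshold_fraction))
    kept <- kept[order(kept$index), , drop = FALSE]
    out <- gait_events(kept$time, "STEP", kept$context)
  }
  attr(out, "manifest") <- list(
    dominant_frequency_hz = as.list(Fa_ctx),
    wavelets = c(TURNING = "gaus2", NON_TURNING = "db2"),
    scales = list(
      TURNING = scale_from_frequency(wavelet_center_frequency("gaus2"),
                                     Fa_ctx[["TURNING"]], delta),
      NON_TURNING = scale_from_frequency(wavelet_center_frequency("db2"),
                                         Fa_ctx[["NON_TURNING"]], delta)),
    n_turns = nrow(turns))
  out
}

# Runs of a logical vector as a data frame (from, to, flag).
split_runs <- function(flag) {
  r <- rle(flag)
  to <- cumsum(r$lengths)
  data.frame(from = c(1L, utils::head(to, -1) + 1L), to = to,
             flag = r$values)
}

# Dominant frequency pooled over several contiguous pieces: each piece
# contributes a Hann-windowed, zero-padded periodogram on a shared grid;
# the duration-weighted average power is searched in the band with the
# same 3x-median flatness guard as dominant_frequency().
pooled_dominant_frequency <- function(pieces, fs, band) {
  pieces <- pieces[vapply(pieces, length, 1L) >= round(2 * fs)]
  if (!length(pieces)) return(NA_real_)
  nfft <- 2^ceiling(log2(max(8 * fs, max(vapply(pieces, length, 1L)))))
  acc <- numeric(nfft)
  wsum <- 0
  for (v in pieces) {
    m <- length(v)
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, m - 1) / (m - 1))
    seg <- (v - mean(v)) * w
    acc <- acc + Mod(stats::fft(c(seg, numeric(nfft - m))))^2 / sum(w^2)
    wsum <- wsum + m
  }
  nf <- floor(nfft / 2) + 1
  freq <- (seq_len(nf) - 1) * fs / nfft
  power <- acc[seq_len(nf)]
  sel <- freq >= band[1] & freq <= band[2]
  pw <- power[sel]
  if (!length(pw) || max(pw) < 3 * stats::median(pw)) return(NA_real_)
  freq[sel][which.max(pw)]
}
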