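#' @title Single-scale continuous wavelet transform engine
#' @description Dominant-frequency estimation, scale selection and the
#'   single-scale CWT used as a smoothed differentiator.  The transform
#'   follows the standard numerical CWT algorithm: the wavelet's
#'   antiderivative is sampled at the requested scale, convolved with the
#'   signal, and differenced, giving coefficients
#'   \eqn{C(a,b) = a^{-1/2} \int x(t)\,\psi((t-b)/a)\,dt} on the sample
#'   grid.  Supported mother wavelets are the first and second derivative
#'   of a Gaussian (`gaus1`, `gaus2`) and the Daubechies 2-vanishing-moment
#'   wavelet (`db2`).
#' @name wavelet_engine
NULL

WAVELET_NAMES <- c("gaus1", "gaus2", "db2")

# Published per-sample center-frequency constants (argmax of |FFT(psi)|
# over the wavelet's natural support; reproduced by a test).
WAVELET_CENTER_FREQ <- c(gaus1 = 0.2, gaus2 = 0.3, db2 = 2 / 3)

#' Center frequency of a supported mother wavelet
#'
#' The dimensionless per-sample center frequency \eqn{F_c} used in the
#' scale equation \eqn{a = F_c / (F_a \Delta)}.
#'
#' @param name One of `"gaus1"`, `"gaus2"`, `"db2"`.
#' @return A positive scalar.
#' @export
wavelet_center_frequency <- function(name) {
  name <- match.arg(name, WAVELET_NAMES)
  unname(WAVELET_CENTER_FREQ[name])
}

# --- wavelet function grids -------------------------------------------------

# Daubechies-2 reconstruction low-pass filter (sums to sqrt(2)).
db2_rec_lo <- function() {
  s3 <- sqrt(3)
  c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
}

# Wavelet function psi on a dyadic grid over [0, 3] via the cascade
# (inverse-DWT of a unit detail coefficient).
db2_wavefun <- function(level = 10) {
  h <- db2_rec_lo()
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)   # quadrature mirror filter
  up2 <- function(v) {
    out <- numeric(2 * length(v) - 1)
    out[seq(1, length(out), by = 2)] <- v
    out
  }
  step_rec <- function(v, f) {
    u <- up2(v)
    as.numeric(stats::convolve(u, rev(f), type = "open"))
  }
  coef <- step_rec(1, g)
  for (i in seq_len(level - 1)) coef <- step_rec(coef, h)
  psi <- coef * sqrt(2)^level
  dx <- (L - 1) / (length(psi) - 1)     # support width L-1 = 3
  x <- seq(0, L - 1, by = dx)
  psi <- psi / sqrt(sum(psi^2) * dx)    # unit L2 norm
  list(x = x, psi = psi)
}

gaus_wavefun <- function(order, npts = 1024) {
  x <- seq(-5, 5, length.out = npts)
  # gaus2 uses the positive-centre (Mexican-hat/Ricker) normalisation
  # -(d^2/dx^2) exp(-x^2): with it the second-stage maxima fall on the
  # mid-cycle (toe-off) feature rather than on the heel-strike feature.
  raw <- switch(as.character(order),
                "1" = -2 * x * exp(-x^2),
                "2" = (2 - 4 * x^2) * exp(-x^2),
                stop("unsupported Gaussian derivative order"))
  dx <- x[2] - x[1]
  list(x = x, psi = raw / sqrt(sum(raw^2) * dx))
}

wavelet_cache <- new.env(parent = emptyenv())

# psi grid, its antiderivative and metadata for a named wavelet (cached).
wavelet_fun <- function(name) {
  name <- match.arg(name, WAVELET_NAMES)
  if (!is.null(wavelet_cache[[name]])) return(wavelet_cache[[name]])
  wf <- switch(name,
               gaus1 = gaus_wavefun(1),
               gaus2 = gaus_wavefun(2),
               db2 = db2_wavefun(10))
  dx <- wf$x[2] - wf$x[1]
  wv <- list(name = name, x = wf$x, psi = wf$psi, dx = dx,
             int_psi = cumsum(wf$psi) * dx,
             center_frequency = wavelet_center_frequency(name))
  wavelet_cache[[name]] <- wv
  wv
}

# --- dominant frequency -----------------------------------------------------

# Welch power spectral density: Hann window, 50% overlap, zero-padded FFT.
welch_psd <- function(v, fs, seg_s = 10, pad_factor = 8) {
  n <- length(v)
  nper <- min(n, round(seg_s * fs))
  step <- max(1, floor(nper / 2))
  starts <- seq(1, n - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))
  nfft <- 2^ceiling(log2(nper * pad_factor))
  acc <- numeric(nfft)
  for (s0 in starts) {
    seg <- v[s0:(s0 + nper - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(c(seg, numeric(nfft - nper))))^2
  }
  nf <- floor(nfft / 2) + 1
  list(freq = (seq_len(nf) - 1) * fs / nfft,
       power = acc[seq_len(nf)] / (length(starts) * sum(w^2) * fs))
}

#' Dominant frequency of a series within a band
#'
#' Estimates the power spectral density with Welch's method (about 10 s
#' Hann segments, 50% overlap, zero-padded FFT) and returns the frequency
#' of maximum power inside `band`.  If the in-band spectrum is flat -- the
#' peak power is less than 3 times the in-band median power -- no dominant
#' frequency exists and an error of class `gaitcwt_no_dominant_frequency`
#' is raised.
#'
#' @param x A [series1d()] or numeric vector.
#' @param band Length-2 numeric, search band in Hz.
#' @param fs Sampling rate, used only when `x` is a bare vector.
#' @return Dominant frequency in Hz.
#' @export
dominant_frequency <- function(x, band = c(0.5, 3.0), fs = NULL) {
  s <- as_series1d(x, fs)
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  dur <- length(s$values) / s$fs
  if (dur < 4 / band[1]) {
    stop("series too short for dominant-frequency estimation (need ",
         sprintf("%.1f", 4 / band[1]), " s)", call. = FALSE)
  }
  sp <- welch_psd(s$values, s$fs)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  pw <- sp$power[sel]
  fq <- sp$freq[sel]
  if (!length(pw) || !(max(pw) > 3 * stats::median(pw))) {
    stop(structure(class = c("gaitcwt_no_dominant_frequency",
                             "error", "condition"),
                   list(message = "no dominant frequency in band",
                        call = sys.call(-1))))
  }
  fq[which.max(pw)]
}

#' Convert a dominant frequency to a wavelet scale
#'
#' Implements the scale equation \eqn{a = F_c / (F_a \Delta)}: the scale at
#' which the wavelet's pseudo-frequency equals the dominant frequency
#' \eqn{F_a}, given the wavelet center frequency \eqn{F_c} and the sampling
#' period \eqn{\Delta = 1/f_s} in seconds.
#'
#' @param Fc Wavelet center frequency (dimensionless, per sample).
#' @param Fa Dominant frequency in Hz.
#' @param delta Sampling period in seconds.
#' @return The scale `a` in samples.
#' @seealso [pseudo_frequency()] for the inverse conversion.
#' @export
scale_from_frequency <- function(Fc, Fa, delta) {
  if (!(Fc > 0 && Fa > 0 && delta > 0)) {
    stop("Fc, Fa and delta must all be positive", call. = FALSE)
  }
  Fc / (Fa * delta)
}

#' Pseudo-frequency corresponding to a wavelet scale
#' @param Fc Wavelet center frequency (per sample).
#' @param a Scale in samples.
#' @param delta Sampling period in seconds.
#' @return Pseudo-frequency in Hz.
#' @export
pseudo_frequency <- function(Fc, a, delta) {
  if (!(Fc > 0 && a > 0 && delta > 0)) {
    stop("Fc, a and delta must all be positive", call. = FALSE)
  }
  Fc / (a * delta)
}

#' Continuous wavelet transform at a single scale
#'
#' Computes CWT coefficients at one scale by convolving the signal with the
#' sampled antiderivative of the mother wavelet and differencing (the
#' classic discretised-integral algorithm).  For `gaus1` the output is
#' proportional to a band-limited first derivative of the signal (smoothed
#' at the scale), with the sign convention that an upward-sloping signal
#' yields negative coefficients; for `gaus2` a second derivative.  Edges
#' are handled by symmetric signal extension of `2*a` samples, trimmed
#' after the transform, so boundary extrema are not reported as events.
#'
#' @param x A [series1d()] or numeric vector.
#' @param kind Mother wavelet: `"gaus1"`, `"gaus2"` or `"db2"`.
#' @param a Scale in samples (>= 1); the series must be at least `10*a`
#'   samples long.
#' @param fs Sampling rate, used only when `x` is a bare vector.
#' @return A `series1d` of coefficients, same length as the input.
#' @export
cwt_single_scale <- function(x, kind, a, fs = NULL) {
  s <- as_series1d(x, fs)
  wv <- wavelet_fun(kind)
  if (a < 1) stop("scale must be >= 1 sample", call. = FALSE)
  n <- length(s$values)
  if (n < 10 * a) {
    stop(sprintf("series too short (%d samples) for scale %.1f (need %d)",
                 n, a, ceiling(10 * a)), call. = FALSE)
  }
  m <- ceiling(2 * a)
  v <- s$values
  ext <- c(rev(v[seq_len(m)]), v, rev(v[(n - m + 1):n]))
  npts <- floor(a * (wv$x[length(wv$x)] - wv$x[1])) + 1
  idx <- floor(seq(0, npts - 1) / (a * wv$dx)) + 1
  idx <- idx[idx <= length(wv$int_psi)]
  kern <- rev(wv$int_psi[idx])
  cv <- as.numeric(stats::convolve(ext, rev(kern), type = "open"))
  coef <- -sqrt(a) * diff(cv)
  d <- (length(coef) - length(ext)) / 2
  coef <- coef[(floor(d) + 1):(length(coef) - ceiling(d))]
  series1d(coef[(m + 1):(m + n)], s$fs)
}
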