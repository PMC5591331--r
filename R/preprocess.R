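#' @title Signal preprocessing front end
#' @description Linear detrending, zero-phase Butterworth filtering and
#'   cumulative trapezoidal integration of the anterior-posterior
#'   acceleration, applied in that order before the wavelet stage.
#' @name preprocess
NULL

#' Remove the least-squares line from a series
#'
#' @param x A [series1d()] (or numeric vector plus `fs`).
#' @param fs Sampling rate, used only when `x` is a bare vector.
#' @return A `series1d` whose best-fit line has zero slope and intercept.
#' @export
linear_detrend <- function(x, fs = NULL) {
  s <- as_series1d(x, fs)
  n <- length(s$values)
  if (n < 2) stop("need at least 2 samples to detrend", call. = FALSE)
  i <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, i), s$values)
  series1d(unname(fit$residuals), s$fs)
}

# Butterworth IIR design via bilinear transform.
# Returns list(b, a) for the given order and corner (Hz).
butter_design <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop("cutoff must lie in (0, fs/2)", call. = FALSE)
  }
  n <- as.integer(order)
  Wn <- cutoff_hz / (fs / 2)
  # analog prototype poles on the unit circle, Re < 0
  k <- seq_len(n)
  pa <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  fs2 <- 4                          # internal bilinear rate (scipy convention)
  warped <- 2 * fs2 * tan(pi * Wn / 2) / 2
  if (type == "low") {
    p <- warped * pa
    z <- complex(0)
    kk <- warped^n
  } else {
    p <- warped / pa
    z <- rep(0 + 0i, n)
    kk <- 1                          # prod(-pa) = 1 for Butterworth
  }
  # bilinear transform s -> 2*fs2*(z-1)/(z+1)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- if (length(z)) (fs2 + z) / (fs2 - z) else complex(0)
  zd <- c(zd, rep(-1 + 0i, n - length(z)))
  kd <- kk * Re(prod(fs2 - z) / prod(fs2 - p))
  poly_from_roots <- function(r) {
    p <- 1 + 0i
    for (ri in r) p <- c(p, 0) - c(0, p * ri)
    p
  }
  b <- Re(kd * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a / a[1])
}

# Direct-form IIR filter (single pass).
iir_filter <- function(b, a, x) {
  n <- length(x)
  nb <- length(b)
  xpad <- c(rep(0, nb - 1), x)
  bx <- stats::filter(xpad, b, method = "convolution", sides = 1)
  bx <- as.numeric(bx)[nb:(nb - 1 + n)]
  if (length(a) > 1) {
    as.numeric(stats::filter(bx, -a[-1], method = "recursive"))
  } else bx
}

# Zero-phase (forward-backward) filtering with odd-reflection padding.
filtfilt_pad <- function(b, a, x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1)
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  xe <- c(pre, x, post)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' The filter is applied forward and backward so that event times are not
#' delayed by the filter's group delay; the effective magnitude response is
#' therefore the squared Butterworth response
#' \eqn{|H(f)|^2 = 1 / (1 + (f/f_c)^{2\,order})}.  Edges are handled by
#' odd-symmetric reflection padding of at least three filter time constants.
#'
#' @param x A [series1d()] or numeric vector.
#' @param cutoff_hz Corner frequency in Hz; must be below the Nyquist
#'   frequency.
#' @param order Butterworth order of each pass (default 2).
#' @param fs Sampling rate, used only when `x` is a bare vector.
#' @return Filtered `series1d`, same length as the input.
#' @export
lowpass <- function(x, cutoff_hz, order = 2, fs = NULL) {
  s <- as_series1d(x, fs)
  des <- butter_design(order, cutoff_hz, s$fs, "low")
  # padding must absorb the zero-state startup transient on both passes
  padlen <- max(3 * (length(des$a) - 1), ceiling(9 * s$fs / cutoff_hz))
  series1d(filtfilt_pad(des$b, des$a, s$values, padlen), s$fs)
}

#' Zero-phase Butterworth high-pass filter
#'
#' Used for gyroscope drift removal before yaw-angle integration.
#'
#' @inheritParams lowpass
#' @return Filtered `series1d`.
#' @export
highpass <- function(x, cutoff_hz, order = 2, fs = NULL) {
  s <- as_series1d(x, fs)
  des <- butter_design(order, cutoff_hz, s$fs, "high")
  padlen <- max(3 * (length(des$a) - 1), ceiling(9 * s$fs / cutoff_hz))
  padlen <- min(padlen, length(s$values) - 1)
  series1d(filtfilt_pad(des$b, des$a, s$values, padlen), s$fs)
}

#' Cumulative trapezoidal integral of a series
#'
#' The integration constant is fixed so that the first output sample is 0;
#' only the shape of the integrated signal matters downstream.
#'
#' @param x A [series1d()] or numeric vector.
#' @param fs Sampling rate, used only when `x` is a bare vector.
#' @return A `series1d` in units of the input times seconds.
#' @export
integrate_cumulative <- function(x, fs = NULL) {
  s <- as_series1d(x, fs)
  v <- s$values
  n <- length(v)
  out <- c(0, cumsum((v[-1] + v[-n]) / 2) / s$fs)
  series1d(out, s$fs)
}
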