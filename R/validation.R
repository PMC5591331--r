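#' @title Agreement statistics against a gold standard
#' @description Event matching with a time tolerance, contingency-table
#'   metrics (sensitivity, specificity, accuracy, predictive values,
#'   Cohen's kappa), Bland-Altman limits of agreement and the two-rater
#'   intraclass correlation.
#' @name validation_metrics
NULL

#' Match detected events to reference events
#'
#' Finds the globally optimal one-to-one assignment between two
#' time-sorted event lists: among assignments with the maximum number of
#' pairs whose absolute time difference is below `tolerance`, the one with
#' the smallest total absolute difference is chosen (dynamic programming
#' over the two sorted sequences; the optimal assignment is monotone).
#' Unmatched detected events are false positives, unmatched reference
#' events false negatives.
#'
#' @param detected,reference Numeric vectors of event times (s), or
#'   [gait_events()] objects (pass `type` to select one event type).
#' @param tolerance Matching tolerance in seconds (default 0.3); a pair
#'   qualifies when `|detected - reference| < tolerance`.
#' @param type Event type to extract when event lists are supplied.
#' @return A list of class `match_result`: `pairs` (data frame with
#'   `detected`, `reference`, `diff`), `tp`, `fp`, `fn`, `diffs`.
#' @export
match_events <- function(detected, reference, tolerance = 0.3, type = NULL) {
  if (tolerance < 0) stop("tolerance must be non-negative", call. = FALSE)
  d <- if (is.data.frame(detected)) event_times(detected, type) else
    as.numeric(detected)
  r <- if (is.data.frame(reference)) event_times(reference, type) else
    as.numeric(reference)
  d <- sort(d); r <- sort(r)
  n <- length(d); m <- length(r)
  if (n == 0 || m == 0) {
    return(new_match_result(
      data.frame(detected = numeric(), reference = numeric(),
                 diff = numeric()), n, m))
  }
  K <- 1e6  # one match outweighs any achievable total |diff|
  F <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    md <- abs(d[i] - r)
    sc <- ifelse(md < tolerance, K - md, -Inf)
    # best of: skip detected (F[i, j+1]) or match i with j (F[i, j] + sc);
    # skipping a reference event is the running maximum along j
    row <- pmax(F[i, -1], F[i, -(m + 1)] + sc)
    F[i + 1, -1] <- cummax(row)
  }
  # traceback
  pairs_d <- numeric(0); pairs_r <- numeric(0)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    md <- abs(d[i] - r[j])
    # identical arithmetic to the forward pass (associativity matters)
    if (md < tolerance && F[i + 1, j + 1] == F[i, j] + (K - md)) {
      pairs_d <- c(d[i], pairs_d); pairs_r <- c(r[j], pairs_r)
      i <- i - 1; j <- j - 1
    } else if (F[i + 1, j + 1] == F[i, j + 1]) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  new_match_result(
    data.frame(detected = pairs_d, reference = pairs_r,
               diff = pairs_d - pairs_r), n, m)
}

new_match_result <- function(pairs, n_det, n_ref) {
  tp <- nrow(pairs)
  structure(list(pairs = pairs, tp = tp, fp = n_det - tp, fn = n_ref - tp,
                 diffs = pairs$diff),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d", x$tp, x$fp, x$fn))
  if (x$tp) {
    cat(sprintf("; mean diff %.3f s, sd %.3f s",
                mean(x$diffs), stats::sd(x$diffs)))
  }
  cat("\n")
  invisible(x)
}

#' Contingency counts for step-detection validation
#'
#' @param tp,fp,fn,tn Non-negative integer counts.  True negatives are
#'   operationalised as candidate extrema rejected by the 40% threshold
#'   that do not correspond to a true step.
#' @return A `contingency_counts` object.
#' @export
contingency_counts <- function(tp, fp, fn, tn = 0) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(v) == 0) stop("at least one count must be positive", call. = FALSE)
  structure(as.list(v), class = "contingency_counts")
}

#' Agreement metrics from a 2x2 contingency table
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/total`, positive and negative predictive values, and Cohen's
#' kappa `(po - pe)/(1 - pe)` with observed agreement `po = accuracy` and
#' chance agreement `pe` from the table marginals.  All values are
#' returned as percentages at full precision; use [percent_display()] for
#' integer formatting.  A metric whose denominator is zero is `NA`
#' (undefined), never 0.
#'
#' @param counts A [contingency_counts()] object, or the `tp` count when
#'   the four counts are given separately.
#' @param fp,fn,tn Remaining counts when given separately.
#' @return A named list of class `agreement_stats` with elements `kappa`,
#'   `accuracy`, `sensitivity`, `specificity`, `npv`, `ppv` (percent).
#' @examples
#' contingency_metrics(contingency_counts(50, 0, 0, 50))
#' @export
contingency_metrics <- function(counts, fp = NULL, fn = NULL, tn = NULL) {
  if (!inherits(counts, "contingency_counts")) {
    counts <- contingency_counts(counts, fp, fn, tn)
  }
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  tot <- tp + fp + fn + tn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  po <- (tp + tn) / tot
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / tot^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else if (po == 1) 1 else NA_real_
  structure(list(
    kappa = 100 * kappa,
    accuracy = 100 * po,
    sensitivity = 100 * safe_div(tp, tp + fn),
    specificity = 100 * safe_div(tn, tn + fp),
    npv = 100 * safe_div(tn, tn + fn),
    ppv = 100 * safe_div(tp, tp + fp)
  ), class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat("<agreement_stats> (%)\n")
  for (nm in names(x)) {
    cat(sprintf("  %-12s %s (%.2f)\n", nm, percent_display(x[[nm]]), x[[nm]]))
  }
  invisible(x)
}

#' Display rounding for percentage tables
#'
#' Rounds a percentage to an integer the way the validation tables are
#' formatted: first to one decimal place, then to an integer, both half
#' away from zero.  The two-stage ("double") rounding matters at values
#' such as 93.48, which print as 94 (93.48 -> 93.5 -> 94).
#'
#' @param x Numeric vector of percentages.
#' @return Integer-valued numeric vector (`NA` preserved).
#' @export
percent_display <- function(x) {
  rha <- function(v, digits) {
    f <- 10^digits
    sign(v) * floor(abs(v) * f + 0.5) / f
  }
  out <- rha(rha(x, 1), 0)
  out
}

#' Accuracy for the laboratory (treadmill) validation design
#'
#' The treadmill protocol has no true negatives: every detected event is
#' either a true or a false positive, so accuracy is
#' `tp / (tp + fp + fn) * 100` with `tp = n_detected - fp`.
#'
#' @param n_detected Total number of events the detector reported.
#' @param fp Number of detected events with no reference event within
#'   tolerance.
#' @param fn Number of reference events missed.
#' @return Accuracy in percent (full precision).
#' @export
lab_accuracy <- function(n_detected, fp, fn) {
  if (fp > n_detected) stop("fp cannot exceed n_detected", call. = FALSE)
  tp <- n_detected - fp
  if (tp < 0) stop("negative true-positive count", call. = FALSE)
  100 * tp / (tp + fp + fn)
}

#' Bland-Altman mean difference and 95% limits of agreement
#'
#' @param diffs Numeric vector of paired differences (detected minus
#'   reference), length >= 2.
#' @return A list with `mean`, `loa_low`, `loa_high` (mean -/+ 1.96 times
#'   the n-1 standard deviation) and `sd`.
#' @export
bland_altman <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2) stop("need at least 2 differences", call. = FALSE)
  m <- mean(diffs); s <- stats::sd(diffs)
  list(mean = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s, sd = s)
}

#' Two-rater intraclass correlation (absolute agreement, single measure)
#'
#' ICC(2,1): two-way random effects, absolute agreement, single rater.
#' Used for agreement of per-bout step counts between two observers.
#'
#' @param ratings_a,ratings_b Equal-length numeric vectors (n >= 3), one
#'   rating per subject and rater.
#' @return The ICC estimate.
#' @export
icc_two_raters <- function(ratings_a, ratings_b) {
  a <- as.numeric(ratings_a); b <- as.numeric(ratings_b)
  n <- length(a)
  if (length(b) != n || n < 3) {
    stop("need equal-length vectors with at least 3 subjects", call. = FALSE)
  }
  k <- 2
  x <- cbind(a, b)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (den == 0) {
    stop("zero variance in both raters; ICC undefined", call. = FALSE)
  }
  (msr - mse) / den
}
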