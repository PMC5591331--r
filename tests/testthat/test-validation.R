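test_that("match_events applies the tolerance rule", {
  m <- match_events(c(1.1, 2.5), c(1.0, 2.0), 0.3)
  expect_equal(m$tp, 1); expect_equal(m$fp, 1); expect_equal(m$fn, 1)
  expect_equal(m$diffs, 0.1)
  # identical lists
  m <- match_events(1:5, 1:5, 0.3)
  expect_equal(m$tp, 5); expect_equal(m$diffs, rep(0, 5))
  # two candidates for one reference: one tp, one fp
  m <- match_events(c(0.95, 1.05), 1.0, 0.3)
  expect_equal(m$tp, 1); expect_equal(m$fp, 1)
  expect_equal(abs(m$diffs), 0.05)
  # empty inputs
  m <- match_events(numeric(), c(1, 2), 0.3)
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 0, 2))
  expect_error(match_events(1, 1, -0.1), "non-negative")
})

test_that("match_events equals the exhaustive oracle on small instances", {
  set.seed(101)
  for (rep in 1:60) {
    d <- sort(runif(sample(0:10, 1), 0, 6))
    r <- sort(runif(sample(0:10, 1), 0, 6))
    m <- match_events(d, r, 0.4)
    orc <- match_oracle(d, r, 0.4)
    expect_equal(m$tp, orc$tp)
    if (m$tp > 0) {
      expect_equal(sum(abs(m$diffs)), orc$total_diff, tolerance = 1e-9)
    }
  }
})

test_that("match_events is symmetric with FP and FN exchanged", {
  set.seed(55)
  d <- sort(runif(40, 0, 30)); r <- sort(runif(35, 0, 30))
  m1 <- match_events(d, r, 0.3)
  m2 <- match_events(r, d, 0.3)
  expect_equal(m1$tp, m2$tp)
  expect_equal(m1$fp, m2$fn)
  expect_equal(m1$fn, m2$fp)
  expect_equal(sort(abs(m1$diffs)), sort(abs(m2$diffs)))
})

test_that("contingency metrics match hand-computed cases", {
  # perfect agreement
  s <- contingency_metrics(contingency_counts(50, 0, 0, 50))
  for (v in unlist(s)) expect_equal(v, 100)
  # chance agreement: kappa 0
  s <- contingency_metrics(contingency_counts(25, 25, 25, 25))
  expect_equal(s$kappa, 0)
  expect_equal(s$accuracy, 50)
  # the published turning-episode row for the PD cohort
  s <- contingency_metrics(contingency_counts(3257, 227, 361, 1083))
  expect_equal(percent_display(s$kappa), 70)
  expect_equal(percent_display(s$accuracy), 88)
  expect_equal(percent_display(s$sensitivity), 90)
  expect_equal(percent_display(s$specificity), 83)
  expect_equal(percent_display(s$npv), 75)
  expect_equal(percent_display(s$ppv), 94)
  # undefined metrics are NA, not 0
  s <- contingency_metrics(contingency_counts(10, 0, 0, 0))
  expect_true(is.na(s$specificity))
  expect_true(is.na(s$npv))
  expect_error(contingency_counts(-1, 0, 0, 0))
})

test_that("kappa never exceeds accuracy on random tables", {
  set.seed(7)
  for (i in 1:200) {
    v <- sample(0:500, 4, replace = TRUE)
    if (sum(v) == 0) next
    s <- contingency_metrics(contingency_counts(v[1], v[2], v[3], v[4]))
    if (!is.na(s$kappa)) expect_lte(s$kappa, s$accuracy + 1e-9)
  }
})

test_that("lab_accuracy reproduces the treadmill design", {
  expect_equal(percent_display(lab_accuracy(2729, 9, 10)), 99)
  expect_equal(lab_accuracy(2729, 9, 10), 99.30759, tolerance = 1e-4)
  expect_equal(percent_display(lab_accuracy(2732, 5, 12)), 99)
  expect_equal(lab_accuracy(2732, 5, 12), 99.38159, tolerance = 1e-4)
  expect_equal(lab_accuracy(100, 0, 0), 100)
  expect_error(lab_accuracy(5, 9, 0), "exceed")
})

test_that("bland_altman computes mean and 1.96-sd limits", {
  expect_equal(bland_altman(c(0, 0, 0))$loa_high, 0)
  ba <- bland_altman(c(0.1, -0.1))
  expect_equal(ba$mean, 0)
  expect_equal(ba$loa_high, 1.96 * sd(c(0.1, -0.1)), tolerance = 1e-9)
  expect_equal(ba$loa_high, 0.2772, tolerance = 1e-3)
  # Monte-Carlo vs closed form 1.96 sigma
  set.seed(12)
  ba <- bland_altman(rnorm(1e4, 0, 0.05))
  expect_gte(ba$loa_high, 0.095)
  expect_lte(ba$loa_high, 0.101)
  expect_error(bland_altman(0.1), "at least 2")
})

test_that("two-rater ICC(2,1) matches an ANOVA-table oracle", {
  expect_equal(icc_two_raters(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  # oracle: mean squares from R's anova on the long-format model
  icc_oracle <- function(a, b) {
    n <- length(a)
    dat <- data.frame(y = c(a, b),
                      subj = factor(rep(seq_len(n), 2)),
                      rater = factor(rep(1:2, each = n)))
    # suppressWarnings: the constant-offset case is a perfect fit and
    # anova.lm warns about its F test, which the oracle does not use
    ms <- suppressWarnings(anova(lm(y ~ subj + rater, dat)))$"Mean Sq"
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
  }
  set.seed(30)
  a <- rnorm(20, 10, 3)
  b <- a + 2                      # constant offset: bias term lowers ICC
  expect_equal(icc_two_raters(a, b), icc_oracle(a, b), tolerance = 1e-9)
  expect_lt(icc_two_raters(a, b), 1)
  b2 <- a + rnorm(20, 0, 1)
  expect_equal(icc_two_raters(a, b2), icc_oracle(a, b2), tolerance = 1e-9)
  # independent raters: ICC near 0
  set.seed(31)
  x <- rnorm(1000); y <- rnorm(1000)
  expect_lt(abs(icc_two_raters(x, y)), 0.1)
  expect_error(icc_two_raters(1:2, 1:2), "at least 3")
  expect_error(icc_two_raters(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("percent_display applies table-style two-stage rounding", {
  expect_equal(percent_display(93.485), 94)   # 93.485 -> 93.5 -> 94
  expect_equal(percent_display(68.495), 69)
  expect_equal(percent_display(93.44), 93)
  expect_equal(percent_display(-1.25), -1)
  expect_true(is.na(percent_display(NA_real_)))
})
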