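test_that("2x2 metrics reproduce the worked single-positive example", {
  t <- two_by_two(tp = 1, fp = 0, fn = 3, tn = 960)
  m <- metrics_from_table(t)
  expect_equal(m[["sensitivity"]], 0.25)
  expect_equal(m[["specificity"]], 1)
  expect_equal(m[["npv"]], 960 / 963)
  expect_equal(m[["ppv"]], 1)
})

test_that("perfect classifiers score 1 on all four metrics", {
  m <- metrics_from_table(two_by_two(5, 0, 0, 7))
  expect_equal(unname(m), rep(1, 4))
})

test_that("an enriched PPV sample supports PPV only", {
  t <- two_by_two(38, 24, 0, 0)
  expect_equal(metrics_from_table(t, metrics = "ppv")[["ppv"]], 38 / 62)
  # no gold negatives reviewed: NPV denominator is zero
  expect_error(metrics_from_table(t, metrics = "npv"), "npv")
  expect_error(metrics_from_table(t), "npv")
})

test_that("Sn * (tp + fn) = tp exactly on integer tables", {
  set.seed(9)
  for (i in 1:25) {
    counts <- rpois(4, 8) + c(1, 0, 1, 1)  # keep denominators positive
    t <- two_by_two(counts[1], counts[2], counts[3], counts[4])
    m <- metrics_from_table(t)
    expect_equal(m[["sensitivity"]] * (t$tp + t$fn), t$tp)
  }
})

test_that("Wald half-widths reproduce the study's printed +/- values", {
  expect_equal(wald_interval(1, 4)$half_width, 0.4243447, tolerance = 1e-6)
  expect_equal(wald_interval(960, 963)$half_width, 0.003519694,
               tolerance = 1e-6)
  expect_equal(wald_interval(38, 62)$half_width, 0.1212434,
               tolerance = 1e-6)
  # degenerate proportions: half-width exactly 0
  expect_equal(wald_interval(0, 20)$half_width, 0)
  expect_equal(wald_interval(20, 20)$half_width, 0)
})

test_that("Wald interval is symmetric about p-hat before clipping", {
  e <- wald_interval(30, 100)
  expect_equal(e$upper - e$p_hat, e$p_hat - e$lower)
  expect_equal(e$upper - e$p_hat, e$half_width)
})

test_that("Wilson CC endpoints match the score-equation root-finder", {
  for (case in list(c(1, 4), c(38, 62), c(0, 10), c(10, 10), c(3, 7))) {
    est <- wilson_cc_interval(case[1], case[2])
    oracle <- wilson_cc_oracle(case[1], case[2])
    expect_equal(est$lower, oracle[["lower"]], tolerance = 1e-6)
    expect_equal(est$upper, oracle[["upper"]], tolerance = 1e-6)
  }
  # frozen endpoints for the two study proportions
  expect_equal(wilson_cc_interval(1, 4)$lower, 0.01319116, tolerance = 1e-6)
  expect_equal(wilson_cc_interval(1, 4)$upper, 0.78057345, tolerance = 1e-6)
  expect_equal(wilson_cc_interval(38, 62)$lower, 0.48047577, tolerance = 1e-6)
  expect_equal(wilson_cc_interval(38, 62)$upper, 0.73130714, tolerance = 1e-6)
})

test_that("interval invariants hold across k, n and confidence levels", {
  for (n in c(1, 4, 11, 30)) {
    for (k in 0:n) {
      w <- wald_interval(k, n)
      s <- wilson_cc_interval(k, n)
      expect_lte(w$lower, w$upper)
      expect_lte(s$lower, s$upper)
      # Wilson CC always contains the point estimate
      expect_lte(s$lower, k / n)
      expect_gte(s$upper, k / n)
      expect_true(s$lower >= 0 && s$upper <= 1)
      # shrinking confidence shrinks width
      s90 <- wilson_cc_interval(k, n, conf_level = 0.90)
      expect_lte(s90$upper - s90$lower, s$upper - s$lower)
      w90 <- wald_interval(k, n, conf_level = 0.90)
      expect_lte(w90$half_width, w$half_width)
    }
  }
  expect_equal(wilson_cc_interval(0, 10)$lower, 0)
  expect_equal(wilson_cc_interval(10, 10)$upper, 1)
})

test_that("kappa handles perfect agreement, a worked table, and the null", {
  # perfect agreement with both labels present
  p <- pairs_from_counts(4, 0, 0, 6)
  expect_equal(cohen_kappa(p$label_a, p$label_b)$kappa, 1)
  # direct-formula worked example: a=4, b=1, c=1, d=4
  p <- pairs_from_counts(4, 1, 1, 4)
  k <- cohen_kappa(p$label_a, p$label_b)
  expect_equal(k$p_o, 0.8)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0.6)
  # independent raters: kappa within 3 large-sample SEs of 0
  set.seed(31)
  n <- 10000
  a <- runif(n) < 0.5
  b <- runif(n) < 0.5
  expect_lt(abs(cohen_kappa(a, b)$kappa), 3 / sqrt(n))
})

test_that("kappa is undefined when both raters are constant and identical", {
  expect_error(cohen_kappa(rep(TRUE, 5), rep(TRUE, 5)), "undefined")
  expect_error(cohen_kappa(rep(FALSE, 3), rep(FALSE, 3)), "undefined")
  # constant but opposite raters: defined, and zero
  expect_equal(cohen_kappa(rep(TRUE, 4), rep(FALSE, 4))$kappa, 0)
})

test_that("flipping an agreeing pair to disagreement lowers kappa", {
  set.seed(12)
  for (i in 1:10) {
    a <- sum(sample(1:5, 1)); b <- sample(0:3, 1)
    c_ <- sample(0:3, 1); d <- sample(2:6, 1)
    p <- pairs_from_counts(a, b, c_, d)
    k0 <- cohen_kappa(p$label_a, p$label_b)$kappa
    p2 <- pairs_from_counts(a - 1, b + 1, c_, d)
    if (a - 1 + d > 0) {
      k1 <- tryCatch(cohen_kappa(p2$label_a, p2$label_b)$kappa,
                     error = function(e) -Inf)
      expect_lt(k1, k0)
    }
  }
})

test_that("sample-size formulas reproduce planning values", {
  expect_equal(sample_size_ppv(0.80, 0.10)$n_required, 62L)
  expect_equal(sample_size_ppv(0.50, 0.10)$n_required, 97L)
  expect_equal(sample_size_ppv(0.80, 0.20)$n_required, 16L)
  plan <- sample_size_sn_sp(0.40, 0.90, 0.10, 0.10)
  expect_equal(plan$n_sn, 922L)
  expect_equal(plan$n_sp, 39L)
  expect_equal(plan$n_required, 922L)
})

test_that("sample-size limits and monotonicity hold", {
  # prevalence -> 1: the Sn component approaches the plain proportion size
  near1 <- sample_size_sn_sp(0.40, 0.90, 1 - 1e-12, 0.10)
  expect_equal(near1$n_sn, sample_size_ppv(0.40, 0.10)$n_required)
  # symmetric inputs give equal components
  sym <- sample_size_sn_sp(0.50, 0.50, 0.5, 0.10)
  expect_equal(sym$n_sn, sym$n_sp)
  # non-increasing in d, non-decreasing in confidence
  expect_gte(sample_size_ppv(0.7, 0.05)$n_required,
             sample_size_ppv(0.7, 0.10)$n_required)
  expect_gte(sample_size_ppv(0.7, 0.10, 0.99)$n_required,
             sample_size_ppv(0.7, 0.10, 0.95)$n_required)
  expect_gte(sample_size_sn_sp(0.4, 0.9, 0.1, 0.05)$n_required,
             sample_size_sn_sp(0.4, 0.9, 0.1, 0.10)$n_required)
})

test_that("percentage formatting rounds for display only", {
  expect_equal(format_percent(0.25), "25.0%")
  expect_equal(format_percent(960 / 963), "99.7%")
  expect_equal(format_percent(0.003519694), "0.4%")
  expect_equal(format_percent(208 / 326702, digits = 2), "0.06%")
})
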