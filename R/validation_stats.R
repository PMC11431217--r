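#' Build a 2x2 diagnostic classification table
#'
#' Cross-classifies algorithm positivity (test) against the gold-standard
#' chart-review label (reference): true positives, false positives, false
#' negatives, true negatives.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class `two_by_two`.
#' @examples
#' two_by_two(tp = 1, fp = 0, fn = 3, tn = 960)
#' @export
two_by_two <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("tp, fp, fn, tn must be non-negative integers.", call. = FALSE)
  }
  if (sum(counts) < 1) {
    stop("The 2x2 table must contain at least one observation.", call. = FALSE)
  }
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(c("algorithm+", "algorithm-"),
                              c("gold+", "gold-")))
  cat("<two_by_two> n =", sum(unlist(x)), "\n")
  print(m)
  invisible(x)
}

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`. A metric
#' whose denominator is zero is undefined; requesting it is an error
#' (the function never silently substitutes 0), so callers working with
#' an enriched sample can request only the metrics their design supports.
#'
#' @param t A `two_by_two`.
#' @param metrics Which metrics to compute; any subset of
#'   `c("sensitivity", "specificity", "ppv", "npv")`.
#' @return Named numeric vector of proportions.
#' @examples
#' metrics_from_table(two_by_two(1, 0, 3, 960))
#' metrics_from_table(two_by_two(38, 24, 0, 0), metrics = "ppv")
#' @export
metrics_from_table <- function(t,
                               metrics = c("sensitivity", "specificity",
                                           "ppv", "npv")) {
  stopifnot(inherits(t, "two_by_two"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  denom <- c(sensitivity = t$tp + t$fn, specificity = t$tn + t$fp,
             ppv = t$tp + t$fp, npv = t$tn + t$fn)
  numer <- c(sensitivity = t$tp, specificity = t$tn, ppv = t$tp, npv = t$tn)
  zero <- metrics[denom[metrics] == 0]
  if (length(zero)) {
    stop("Undefined metric(s) with zero denominator: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  numer[metrics] / denom[metrics]
}

new_proportion_estimate <- function(p_hat, n, conf_level, method,
                                    lower, upper, half_width = NA_real_) {
  structure(
    list(p_hat = p_hat, n = as.integer(n), conf_level = conf_level,
         method = method, lower = lower, upper = upper,
         half_width = half_width),
    class = "proportion_estimate"
  )
}

#' @export
print.proportion_estimate <- function(x, digits = 1, ...) {
  cat(sprintf("<proportion_estimate> %s, n = %d\n", x$method, x$n))
  if (x$method == "wald") {
    cat(sprintf("  %s ± %s (%.0f%% CI: %s to %s)\n",
                format_percent(x$p_hat, digits),
                format_percent(x$half_width, digits),
                100 * x$conf_level,
                format_percent(x$lower, digits),
                format_percent(x$upper, digits)))
  } else {
    cat(sprintf("  %s (%.0f%% CI: %s to %s)\n",
                format_percent(x$p_hat, digits), 100 * x$conf_level,
                format_percent(x$lower, digits),
                format_percent(x$upper, digits)))
  }
  invisible(x)
}

check_k_n <- function(k, n) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n)) {
    stop("Require integer counts with 0 <= k <= n and n >= 1.",
         call. = FALSE)
  }
}

#' Wald (normal-approximation) confidence interval for a proportion
#'
#' The simple asymptotic interval `p-hat +/- z * sqrt(p-hat (1 - p-hat)/n)`,
#' reported with its half-width because diagnostic validation studies
#' conventionally present estimates as "point +/- half-width". Degenerate
#' proportions (k = 0 or k = n) give half-width 0. Bounds are clipped to
#' [0, 1] after the symmetric interval is formed.
#'
#' @param k Number of successes.
#' @param n Denominator.
#' @param conf_level Confidence level (default 0.95).
#' @return A `proportion_estimate` with `method = "wald"`.
#' @examples
#' wald_interval(1, 4)        # 25.0 +/- 42.4%
#' wald_interval(960, 963)    # 99.7 +/- 0.4%
#' @export
wald_interval <- function(k, n, conf_level = 0.95) {
  check_k_n(k, n)
  stopifnot(conf_level > 0, conf_level < 1)
  p <- k / n
  z <- stats::qnorm((1 + conf_level) / 2)
  hw <- z * sqrt(p * (1 - p) / n)
  new_proportion_estimate(
    p_hat = p, n = n, conf_level = conf_level, method = "wald",
    lower = max(0, p - hw), upper = min(1, p + hw), half_width = hw
  )
}

#' Continuity-corrected Wilson score interval for a proportion
#'
#' The efficient-score interval with continuity correction: the bounds
#' solve `|p-hat - p| - 1/(2n) = z * sqrt(p (1 - p)/n)`, evaluated here in
#' closed form. By convention the lower bound is 0 when k = 0 and the
#' upper bound is 1 when k = n. Unlike the Wald interval it is asymmetric,
#' always contains `k/n`, and behaves sensibly for extreme proportions and
#' small n — which is why it is the preferred reporting interval for rare
#' conditions such as heat illness.
#'
#' @inheritParams wald_interval
#' @return A `proportion_estimate` with `method = "wilson_cc"` and
#'   `half_width = NA` (the interval is asymmetric).
#' @references Newcombe, R.G. (1998) Two-sided confidence intervals for
#'   the single proportion: comparison of seven methods.
#'   *Statistics in Medicine* 17, 857-872.
#' @examples
#' wilson_cc_interval(1, 4)
#' wilson_cc_interval(0, 10)  # lower bound exactly 0
#' @export
wilson_cc_interval <- function(k, n, conf_level = 0.95) {
  check_k_n(k, n)
  stopifnot(conf_level > 0, conf_level < 1)
  p <- k / n
  z <- stats::qnorm((1 + conf_level) / 2)
  lower <- if (k == 0) 0 else {
    max(0, (2 * n * p + z^2 - 1 -
              z * sqrt(pmax(0, z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1)))) /
          (2 * (n + z^2)))
  }
  upper <- if (k == n) 1 else {
    min(1, (2 * n * p + z^2 + 1 +
              z * sqrt(pmax(0, z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1)))) /
          (2 * (n + z^2)))
  }
  new_proportion_estimate(
    p_hat = p, n = n, conf_level = conf_level, method = "wilson_cc",
    lower = lower, upper = upper
  )
}

#' Unweighted Cohen's kappa for two raters, two categories
#'
#' Chance-corrected agreement between two reviewers who each assigned a
#' binary label (gold-standard positive or negative) to the same charts:
#' `kappa = (p_o - p_e) / (1 - p_e)`, with observed agreement `p_o` and
#' expected-by-chance agreement `p_e` from the marginal label frequencies.
#' Kappa is undefined when `p_e = 1`, i.e. both raters used a single,
#' identical label for every chart — chance agreement then explains
#' everything and the data carry no information about reliability.
#'
#' @param label_a,label_b Logical vectors of the two raters' labels,
#'   equal length, at least one pair.
#' @return An object of class `kappa_result` with fields `n_pairs`,
#'   `p_o`, `p_e` and `kappa`.
#' @examples
#' cohen_kappa(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE, FALSE))
#' @export
cohen_kappa <- function(label_a, label_b) {
  stopifnot(is.logical(label_a), is.logical(label_b),
            length(label_a) == length(label_b))
  if (length(label_a) < 1L) {
    stop("Kappa requires at least one pair of labels.", call. = FALSE)
  }
  if (anyNA(label_a) || anyNA(label_b)) {
    stop("Labels must not contain NA.", call. = FALSE)
  }
  n <- length(label_a)
  a <- sum(label_a & label_b)          # both positive
  b <- sum(label_a & !label_b)
  c_ <- sum(!label_a & label_b)
  d <- sum(!label_a & !label_b)        # both negative
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  if (p_e >= 1 - 1e-12) {
    stop("Kappa is undefined: both raters assigned a single identical ",
         "label to every chart (expected agreement = 1).", call. = FALSE)
  }
  structure(
    list(n_pairs = n, p_o = p_o, p_e = p_e,
         kappa = (p_o - p_e) / (1 - p_e)),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "<kappa_result> n_pairs = %d, p_o = %.3f, p_e = %.3f, kappa = %.3f\n",
    x$n_pairs, x$p_o, x$p_e, x$kappa))
  invisible(x)
}

#' Sample size to estimate a positive predictive value
#'
#' Closed-form sample size for estimating a proportion (here the PPV of a
#' case-finding algorithm, among algorithm-positive charts) to within a
#' desired precision `d` at a given confidence level:
#' `n = ceil(z^2 P (1 - P) / d^2)`.
#'
#' @param estimated_ppv Anticipated PPV, in (0, 1).
#' @param precision_d Desired half-width of the confidence interval.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `sample_size_plan` with the inputs and
#'   `n_required`.
#' @references Hajian-Tilaki, K. (2014) Sample size estimation in
#'   diagnostic test studies of biomedical informatics.
#'   *Journal of Biomedical Informatics* 48, 193-204.
#' @examples
#' sample_size_ppv(0.80, 0.10)   # 62 charts
#' @export
sample_size_ppv <- function(estimated_ppv, precision_d, conf_level = 0.95) {
  stopifnot(estimated_ppv > 0, estimated_ppv < 1, precision_d > 0,
            conf_level > 0, conf_level < 1)
  z <- stats::qnorm((1 + conf_level) / 2)
  n <- ceiling(z^2 * estimated_ppv * (1 - estimated_ppv) / precision_d^2)
  structure(
    list(target = "ppv", estimated_ppv = estimated_ppv,
         precision_d = precision_d, conf_level = conf_level,
         n_required = n),
    class = "sample_size_plan"
  )
}

#' Sample size to estimate sensitivity and specificity
#'
#' Sensitivity is estimated only from true cases and specificity only from
#' true non-cases, so the required total review sample inflates each
#' proportion-type size by the expected prevalence:
#' `n_sn = ceil(z^2 Sn (1 - Sn) / (d^2 prev))` and
#' `n_sp = ceil(z^2 Sp (1 - Sp) / (d^2 (1 - prev)))`; the study must
#' satisfy both, so `n_required = max(n_sn, n_sp)`. Both components are
#' reported.
#'
#' @param estimated_sn,estimated_sp Anticipated sensitivity and
#'   specificity, each in (0, 1).
#' @param expected_prevalence Anticipated prevalence of true cases in the
#'   review sample, in (0, 1).
#' @param precision_d Desired half-width of the confidence interval.
#' @param conf_level Confidence level (default 0.95).
#' @return A `sample_size_plan` with `n_sn`, `n_sp` and
#'   `n_required = max(n_sn, n_sp)`.
#' @inherit sample_size_ppv references
#' @examples
#' sample_size_sn_sp(0.40, 0.90, 0.10, 0.10)
#' @export
sample_size_sn_sp <- function(estimated_sn, estimated_sp,
                              expected_prevalence, precision_d,
                              conf_level = 0.95) {
  stopifnot(estimated_sn > 0, estimated_sn < 1,
            estimated_sp > 0, estimated_sp < 1,
            expected_prevalence > 0, expected_prevalence < 1,
            precision_d > 0, conf_level > 0, conf_level < 1)
  z <- stats::qnorm((1 + conf_level) / 2)
  n_sn <- ceiling(z^2 * estimated_sn * (1 - estimated_sn) /
                    (precision_d^2 * expected_prevalence))
  n_sp <- ceiling(z^2 * estimated_sp * (1 - estimated_sp) /
                    (precision_d^2 * (1 - expected_prevalence)))
  structure(
    list(target = "sensitivity_specificity",
         estimated_sn = estimated_sn, estimated_sp = estimated_sp,
         expected_prevalence = expected_prevalence,
         precision_d = precision_d, conf_level = conf_level,
         n_sn = n_sn, n_sp = n_sp,
         n_required = max(n_sn, n_sp)),
    class = "sample_size_plan"
  )
}

#' @export
print.sample_size_plan <- function(x, ...) {
  cat("<sample_size_plan>", x$target, "\n")
  if (x$target == "ppv") {
    cat(sprintf("  estimated PPV %.2f, precision %.2f, conf %.2f\n",
                x$estimated_ppv, x$precision_d, x$conf_level))
  } else {
    cat(sprintf(
      "  Sn %.2f, Sp %.2f, prevalence %.2f, precision %.2f, conf %.2f\n",
      x$estimated_sn, x$estimated_sp, x$expected_prevalence,
      x$precision_d, x$conf_level))
    cat(sprintf("  n_sn = %.0f, n_sp = %.0f\n", x$n_sn, x$n_sp))
  }
  cat("  n_required =", x$n_required, "\n")
  invisible(x)
}

#' Format a proportion as a percentage string
#'
#' Display helper used throughout reports: proportions are shown as
#' percentages rounded (round-half-even, as in base `round()`) to a fixed
#' number of decimals. Internal computation always retains full precision.
#'
#' @param p Numeric vector of proportions.
#' @param digits Decimal places (default 1; cohort-level positivity is
#'   conventionally shown with 2).
#' @return Character vector like `"25.0%"`.
#' @examples
#' format_percent(1 / 4)
#' format_percent(208 / 326702, digits = 2)
#' @export
format_percent <- function(p, digits = 1) {
  paste0(formatC(round(100 * p, digits), format = "f", digits = digits), "%")
}
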