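# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: the Wilson oracle solves the
# continuity-corrected score equations by root-finding instead of the
# closed form, and the kappa oracle works from 2x2 agreement counts
# instead of label pairs.

# Bounds solve |p_hat - p| - 1/(2n) = z * sqrt(p (1 - p) / n).
wilson_cc_oracle <- function(k, n, conf_level = 0.95) {
  p_hat <- k / n
  z <- qnorm((1 + conf_level) / 2)
  f_lower <- function(p) p_hat - 1 / (2 * n) - p - z * sqrt(p * (1 - p) / n)
  f_upper <- function(p) p - p_hat - 1 / (2 * n) - z * sqrt(p * (1 - p) / n)
  lower <- if (k == 0) 0 else uniroot(f_lower, c(0, p_hat), tol = 1e-12)$root
  upper <- if (k == n) 1 else uniroot(f_upper, c(p_hat, 1), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# Unweighted two-rater kappa straight from agreement counts
# (a = both positive, d = both negative).
kappa_from_counts <- function(a, b, c, d) {
  n <- a + b + c + d
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  (p_o - p_e) / (1 - p_e)
}

# Expand agreement counts into label-pair vectors for cohen_kappa().
pairs_from_counts <- function(a, b, c, d) {
  list(
    label_a = rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c, d)),
    label_b = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d))
  )
}

# A small, non-rare synthetic world where every design is feasible:
# high prevalence and a fairly accurate coder.
small_world <- function(n = 4000, seed = 71, ...) {
  args <- list(n_encounters = n, p_true_ahi = 0.20,
               p_algo_code_given_ahi = 0.80,
               p_algo_code_given_not_ahi = 0.05, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generator_config, args)
}
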