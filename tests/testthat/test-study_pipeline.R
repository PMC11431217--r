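test_that("fixed thresholds classify every temperature exactly once", {
  cls <- classify_day_fixed(c(19.9, 20, 30.5, 31, 35, -2))
  expect_equal(as.character(cls),
               c("cool", "moderate", "moderate", "hot", "hot", "cool"))
  # the verbally unassigned 30-31 band lands in moderate
  expect_equal(as.character(classify_day_fixed(30.9)), "moderate")
})

test_that("quartile classification uses closed interquartile bounds", {
  w <- tibble::tibble(
    date = seq(as.Date("2016-05-01"), by = "day", length.out = 8),
    tmax_c = c(0, 20, 20, 20, 20, 20, 20, 100)
  )
  cls <- classify_days_quartile(w)$day_class
  # Q1 = Q3 = 20 here: values equal to a quartile are moderate
  expect_equal(as.character(cls),
               c("cool", rep("moderate", 6), "hot"))

  same <- tibble::tibble(date = w$date, tmax_c = rep(25, 8))
  expect_true(all(classify_days_quartile(same)$day_class == "moderate"))

  expect_error(
    classify_days_quartile(tibble::tibble(date = w$date[1:3],
                                          tmax_c = c(1, 2, 3))),
    "at least 4 days")
})

test_that("quartile classes of iid days approach 25/50/25 percent", {
  set.seed(14)
  w <- tibble::tibble(
    date = seq(as.Date("2017-05-01"), by = "day", length.out = 100),
    tmax_c = runif(100, 10, 35)
  )
  frac <- prop.table(table(classify_days_quartile(w)$day_class))
  expect_lt(abs(frac[["cool"]] - 0.25), 0.05)
  expect_lt(abs(frac[["moderate"]] - 0.50), 0.05)
  expect_lt(abs(frac[["hot"]] - 0.25), 0.05)
})

test_that("positivity rate counts algorithm-positive encounters", {
  enc <- tibble::tibble(id = c("a", "b", "c", "d"),
                        codes = c("T670", "J45", "N179;J45", "W92"))
  expect_equal(positivity_rate(enc, ahi_code_set()), 0.5)
  nothing <- code_set("none", includes = "Q99")
  expect_equal(positivity_rate(enc, nothing), 0)
  # generator with certain coding for everyone: positivity 1
  cfg <- small_world(n = 300, p_algo_code_given_ahi = 1,
                     p_algo_code_given_not_ahi = 1)
  expect_equal(positivity_rate(generate_cohort(cfg)$encounters,
                               ahi_code_set()), 1)
})

test_that("a perfectly coded cohort yields PPV = Sn = Sp = NPV = 1", {
  cfg <- small_world(n = 4000, seed = 19,
                     p_algo_code_given_ahi = 1, p_algo_code_given_not_ahi = 0)
  cohort <- generate_cohort(cfg)
  rep <- run_validation_study(
    cohort$encounters, reviews_from_cohort(cohort$encounters),
    study_design(n_ppv_sample = 50, n_random_sample = 500, seed = 2),
    weather = cohort$weather
  )
  est <- rbind(rep$stage_a$estimates, rep$stage_b$estimates)
  expect_true(all(est$estimate == 1))
  expect_setequal(unique(est$quantity),
                  c("ppv", "sensitivity", "specificity", "npv"))
})

test_that("the single-positive worked table renders the printed report", {
  est <- validity_estimates(two_by_two(1, 0, 3, 960))
  wald <- est[est$method == "wald", ]
  get <- function(q, col) wald[wald$quantity == q, ][[col]]
  expect_equal(format_percent(get("sensitivity", "estimate")), "25.0%")
  expect_equal(format_percent(get("specificity", "estimate")), "100.0%")
  expect_equal(format_percent(get("npv", "estimate")), "99.7%")
  expect_equal(format_percent(get("sensitivity", "half_width")), "42.4%")
  expect_equal(format_percent(get("specificity", "half_width")), "0.0%")
  expect_equal(format_percent(get("npv", "half_width")), "0.4%")
})

test_that("stage B cross-classification sums to the sample size and stays
           separate from stage A", {
  cfg <- small_world(n = 6000, seed = 23)
  cohort <- generate_cohort(cfg)
  rep <- run_validation_study(
    cohort$encounters, reviews_from_cohort(cohort$encounters),
    study_design(n_ppv_sample = 40, n_random_sample = 700, seed = 9)
  )
  t <- rep$stage_b$table
  expect_equal(t$tp + t$fp + t$fn + t$tn, 700L)
  # PPV comes only from stage A, Sn/Sp/NPV only from stage B
  expect_equal(unique(rep$stage_a$estimates$quantity), "ppv")
  expect_false("ppv" %in% rep$stage_b$estimates$quantity)
  expect_equal(rep$n_kappa_pairs, round(0.2 * 700))
})

test_that("stratified metrics are suppressed without gold positives and
           emitted when every stratum has one", {
  # rare-disease world: the random sample holds no gold positives
  rare <- generate_cohort(generator_config(n_encounters = 20000, seed = 3))
  rep_rare <- run_validation_study(
    rare$encounters, reviews_from_cohort(rare$encounters),
    study_design(n_ppv_sample = 2, n_random_sample = 400, seed = 7),
    weather = rare$weather
  )
  expect_match(rep_rare$strata_note, "suppressed")
  expect_false("sensitivity" %in% names(rep_rare$strata))

  # common-disease world: positives land in every temperature stratum
  common <- generate_cohort(small_world(n = 8000, seed = 29))
  rep_common <- run_validation_study(
    common$encounters, reviews_from_cohort(common$encounters),
    study_design(n_ppv_sample = 40, n_random_sample = 2000, seed = 11),
    weather = common$weather
  )
  expect_match(rep_common$strata_note, "emitted")
  expect_equal(sum(rep_common$strata$n), 2000L)
  expect_true(all(rep_common$strata$n_gold_positive >= 1))
  expect_true(all(rep_common$strata$sensitivity >= 0 &
                    rep_common$strata$sensitivity <= 1))
})

test_that("infeasible designs and missing reviews fail loudly", {
  cohort <- generate_cohort(small_world(n = 500, seed = 31))
  enc <- cohort$encounters
  rev <- reviews_from_cohort(enc)
  expect_error(
    run_validation_study(enc, rev,
                         study_design(n_ppv_sample = 100000, seed = 1)),
    "infeasible")
  expect_error(
    run_validation_study(enc, rev,
                         study_design(n_ppv_sample = 5,
                                      n_random_sample = 10000, seed = 1)),
    "infeasible")
  expect_error(
    run_validation_study(enc, rev[1:10, ],
                         study_design(n_ppv_sample = 5,
                                      n_random_sample = 400, seed = 1)),
    "No chart review")
})

test_that("report files are written and reproducible under a seed", {
  cohort <- generate_cohort(small_world(n = 3000, seed = 37))
  design <- study_design(n_ppv_sample = 30, n_random_sample = 600, seed = 13)
  run <- function() {
    run_validation_study(cohort$encounters,
                         reviews_from_cohort(cohort$encounters),
                         design, weather = cohort$weather)
  }
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_validity_report(run(), d1)
  write_validity_report(run(), d2)
  for (f in c("report.csv", "two_by_two.csv", "strata.csv", "report.txt")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_true(file.exists(file.path(d1, "report.txt")))
})
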