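#' Default per-year temperature parameters
#'
#' Median and interquartile range of the daily maximum temperature,
#' May-September, for the five study years at a single southwestern
#' Ontario airport weather station. Used as the default calibration of
#' the synthetic weather generator.
#'
#' @return A tibble with columns `year`, `median_c`, `iqr_c`.
#' @export
default_temp_params <- function() {
  tibble::tibble(
    year = 2014:2018,
    median_c = c(24.2, 24.5, 26.1, 24.3, 25.7),
    iqr_c = c(6.1, 4.5, 5.7, 6.6, 6.0)
  )
}

# Common non-heat ED diagnosis codes used to pad encounters. None of
# these extends an AHI include prefix, so background codes can never
# make an encounter algorithm-positive.
default_background_pool <- function() {
  c("J45", "J069", "I10", "K529", "A09", "R104", "R074", "M545",
    "S934", "L039", "N390", "H669", "J189", "K358", "T784", "F329",
    "G439", "R42", "B349", "S0990")
}

# Concrete codes the generator assigns when an encounter is coded with
# the AHI algorithm (one representative per frequently used category).
default_ahi_assignment_pool <- function() {
  c("X30", "X32", "T670", "T671", "T672", "T675", "T676", "T677",
    "E860", "N179", "R508", "R509", "M628", "E875", "R55")
}

#' Configuration of the synthetic ED cohort generator
#'
#' The generator produces an emergency-department encounter population
#' with a latent acute-heat-illness (AHI) truth, imperfect ICD-10 code
#' assignment, chart documentation of heat exposure and complaints, and
#' a daily maximum-temperature series. The defaults reproduce, in
#' expectation, the headline quantities of a five-summer validation
#' study at a two-site Canadian ED (about 327,000 encounters):
#' an algorithm-positivity rate of 0.06%, a latent coding sensitivity of
#' 0.25, and a PPV near 61% — which together imply a true AHI prevalence
#' of about 0.00156. See the methods vignette for why these three, and
#' not the random-sample gold-positive count, anchor the calibration.
#'
#' @param n_encounters Number of encounters (default 326702).
#' @param years Study years (default 2014-2018).
#' @param p_true_ahi Latent prevalence of true AHI among encounters.
#' @param p_algo_code_given_ahi Probability a true AHI receives at least
#'   one algorithm code (the latent sensitivity; default 0.25).
#' @param p_algo_code_given_not_ahi Probability a non-AHI encounter
#'   receives an algorithm code (latent false-positive rate).
#' @param p_exposure_documented_given_ahi,p_exposure_documented_given_not_ahi
#'   Probability the chart documents patient-reported heat exposure.
#' @param p_complaint_documented_given_ahi,p_complaint_documented_given_not_ahi
#'   Probability the chart documents at least one heat-related complaint.
#' @param background_code_pool Non-AHI ICD-10 codes used to pad charts.
#' @param ahi_code_pool Concrete AHI codes assigned to algorithm-coded
#'   encounters.
#' @param temp_params Per-year temperature calibration, as returned by
#'   [default_temp_params()].
#' @param temp_link_beta Log-odds increase in AHI risk per degree C of
#'   daily maximum temperature above the yearly median. Default 0
#'   (temperature-independent risk); positive values concentrate true
#'   AHIs on warmer days.
#' @param seed Master seed; every component derives its own substream
#'   from it, so generation is fully reproducible.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_encounters = 326702,
                             years = 2014:2018,
                             p_true_ahi = 0.00156,
                             p_algo_code_given_ahi = 0.25,
                             p_algo_code_given_not_ahi = 0.000247,
                             p_exposure_documented_given_ahi = 1,
                             p_exposure_documented_given_not_ahi = 0,
                             p_complaint_documented_given_ahi = 1,
                             p_complaint_documented_given_not_ahi = 0.3,
                             background_code_pool = default_background_pool(),
                             ahi_code_pool = default_ahi_assignment_pool(),
                             temp_params = default_temp_params(),
                             temp_link_beta = 0,
                             seed = 1L) {
  cfg <- list(
    n_encounters = n_encounters, years = as.integer(years),
    p_true_ahi = p_true_ahi,
    p_algo_code_given_ahi = p_algo_code_given_ahi,
    p_algo_code_given_not_ahi = p_algo_code_given_not_ahi,
    p_exposure_documented_given_ahi = p_exposure_documented_given_ahi,
    p_exposure_documented_given_not_ahi = p_exposure_documented_given_not_ahi,
    p_complaint_documented_given_ahi = p_complaint_documented_given_ahi,
    p_complaint_documented_given_not_ahi = p_complaint_documented_given_not_ahi,
    background_code_pool = normalize_code(background_code_pool),
    ahi_code_pool = normalize_code(ahi_code_pool),
    temp_params = temp_params, temp_link_beta = temp_link_beta,
    seed = as.integer(seed)
  )
  probs <- grep("^p_", names(cfg), value = TRUE)
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("`", p, "` must be a single probability in [0, 1].", call. = FALSE)
    }
  }
  if (!is.numeric(cfg$n_encounters) || cfg$n_encounters < 1) {
    stop("`n_encounters` must be a positive integer.", call. = FALSE)
  }
  if (length(cfg$background_code_pool) == 0L) {
    stop("`background_code_pool` must not be empty.", call. = FALSE)
  }
  missing_years <- setdiff(cfg$years, temp_params$year)
  if (length(missing_years)) {
    stop("`temp_params` has no row for year(s): ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

# Deterministic substream seed from a master seed and a component label.
# Kept well below 2^31 so it is always a valid integer seed.
derive_seed <- function(seed, label) {
  chars <- utf8ToInt(label)
  h <- sum(chars * seq_along(chars))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

season_dates <- function(year) {
  seq(as.Date(sprintf("%d-05-01", year)),
      as.Date(sprintf("%d-09-30", year)), by = "day")
}

#' Generate a synthetic daily maximum-temperature series
#'
#' One value per calendar day, May 1 to September 30, drawn from a
#' normal location-scale family with location the target median and
#' scale `iqr / 1.349` (the normal IQR-to-SD conversion), so the sample
#' median and IQR match the per-year calibration targets up to sampling
#' noise over the 153-day season.
#'
#' @param year Calendar year.
#' @param median_c Target median of daily maxima, degrees C.
#' @param iqr_c Target interquartile range, degrees C (> 0).
#' @param seed Integer seed.
#' @return A tibble with columns `date`, `tmax_c` (one row per day).
#' @examples
#' w <- generate_temperature_series(2016, 26.1, 5.7, seed = 7)
#' nrow(w)          # 153 days
#' median(w$tmax_c)
#' @export
generate_temperature_series <- function(year, median_c, iqr_c, seed) {
  stopifnot(is.numeric(iqr_c), iqr_c > 0)
  dates <- season_dates(year)
  tmax <- withr::with_seed(
    derive_seed(seed, paste0("weather-", year)),
    stats::rnorm(length(dates), mean = median_c, sd = iqr_c / 1.349)
  )
  tibble::tibble(date = dates, tmax_c = round(tmax, 1))
}

#' Generate the weather series for a set of study years
#'
#' @param years Integer vector of years.
#' @param temp_params Tibble with `year`, `median_c`, `iqr_c` covering
#'   every requested year.
#' @param seed Master seed.
#' @return A tibble with `date`, `tmax_c`, all years stacked.
#' @export
generate_weather <- function(years, temp_params = default_temp_params(),
                             seed = 1L) {
  missing_years <- setdiff(years, temp_params$year)
  if (length(missing_years)) {
    stop("No temperature parameters for year(s): ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  out <- lapply(years, function(y) {
    row <- temp_params[temp_params$year == y, ]
    generate_temperature_series(y, row$median_c[1], row$iqr_c[1], seed)
  })
  do.call(rbind, out)
}

#' Generate a synthetic ED cohort with latent AHI truth
#'
#' Draws, per encounter: a visit date uniform over the May-September
#' season of a uniformly chosen study year; a latent true-AHI indicator
#' (Bernoulli at `p_true_ahi`, optionally tilted towards warmer days via
#' `temp_link_beta`); an algorithm-code indicator conditional on truth;
#' an assigned ICD-10 code list (an AHI code when algorithm-coded, plus
#' background codes — every encounter carries at least one code);
#' cosmetic demographics (age, sex, five-level triage score,
#' disposition) matched to the marginal frequencies of a large ED
#' population; and chart-documentation fields (heat exposure documented,
#' heat-related complaint list) conditional on truth. Each component
#' uses its own seed substream derived from the master seed, so adding a
#' field never perturbs earlier draws and generation is byte-reproducible.
#'
#' The latent truth column is synthetic ground truth for calibration
#' checks only; estimators in this package never read it — gold-standard
#' labels are always derived from the chart-documentation fields via
#' [label_chart()].
#'
#' @param config A [generator_config()].
#' @return A list with elements `encounters` (tibble: `id`, `date`,
#'   `codes` semicolon-delimited, `age`, `sex`, `ctas`, `disposition`,
#'   `exposure_documented`, `complaints`, `latent_true_ahi`) and
#'   `weather` (tibble: `date`, `tmax_c`).
#' @examples
#' cohort <- generate_cohort(generator_config(n_encounters = 2000, seed = 3))
#' mean(cohort$encounters$latent_true_ahi)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- as.integer(config$n_encounters)
  seed <- config$seed

  weather <- generate_weather(config$years, config$temp_params, seed)

  dates <- withr::with_seed(derive_seed(seed, "dates"), {
    yr <- sample(config$years, n, replace = TRUE)
    offs <- sample.int(153L, n, replace = TRUE) - 1L
    as.Date(sprintf("%d-05-01", yr)) + offs
  })

  truth <- withr::with_seed(derive_seed(seed, "truth"), {
    if (config$temp_link_beta == 0) {
      stats::runif(n) < config$p_true_ahi
    } else {
      tmax <- weather$tmax_c[match(dates, weather$date)]
      med <- stats::ave(weather$tmax_c,
                        format(weather$date, "%Y"),
                        FUN = stats::median)[match(dates, weather$date)]
      p <- stats::plogis(stats::qlogis(config$p_true_ahi) +
                           config$temp_link_beta * (tmax - med))
      stats::runif(n) < p
    }
  })

  algo_coded <- withr::with_seed(derive_seed(seed, "coding"), {
    p <- ifelse(truth, config$p_algo_code_given_ahi,
                config$p_algo_code_given_not_ahi)
    stats::runif(n) < p
  })

  codes <- withr::with_seed(derive_seed(seed, "codes"), {
    bg1 <- sample(config$background_code_pool, n, replace = TRUE)
    bg2 <- sample(config$background_code_pool, n, replace = TRUE)
    two_bg <- stats::runif(n) < 0.45 & bg1 != bg2
    base <- ifelse(two_bg, paste(bg1, bg2, sep = ";"), bg1)
    ahi_code <- sample(config$ahi_code_pool, n, replace = TRUE)
    ifelse(algo_coded, paste(ahi_code, base, sep = ";"), base)
  })

  demo <- withr::with_seed(derive_seed(seed, "demographics"), {
    age <- pmin(pmax(round(stats::rnorm(n, 41.7, 26.5)), 0), 102)
    sex <- sample(c("female", "male"), n, replace = TRUE,
                  prob = c(0.511, 0.489))
    ctas <- sample(1:5, n, replace = TRUE,
                   prob = c(38, 241, 444, 224, 11) / 958)
    disposition <- sample(c("discharged", "admitted", "left-AMA"), n,
                          replace = TRUE, prob = c(729, 167, 64) / 960)
    list(age = age, sex = sex, ctas = ctas, disposition = disposition)
  })

  vocab <- default_complaint_vocabulary()
  docs <- withr::with_seed(derive_seed(seed, "documentation"), {
    p_exp <- ifelse(truth, config$p_exposure_documented_given_ahi,
                    config$p_exposure_documented_given_not_ahi)
    p_comp <- ifelse(truth, config$p_complaint_documented_given_ahi,
                     config$p_complaint_documented_given_not_ahi)
    exposure <- stats::runif(n) < p_exp
    has_complaint <- stats::runif(n) < p_comp
    c1 <- sample(vocab, n, replace = TRUE)
    c2 <- sample(vocab, n, replace = TRUE)
    second <- truth & stats::runif(n) < 0.5 & c1 != c2
    complaints <- ifelse(has_complaint,
                         ifelse(second, paste(c1, c2, sep = ";"), c1), "")
    list(exposure = exposure, complaints = complaints)
  })

  encounters <- tibble::tibble(
    id = sprintf("E%07d", seq_len(n)),
    date = dates,
    codes = codes,
    age = demo$age,
    sex = demo$sex,
    ctas = demo$ctas,
    disposition = demo$disposition,
    exposure_documented = docs$exposure,
    complaints = docs$complaints,
    latent_true_ahi = truth
  )
  list(encounters = encounters, weather = weather)
}

#' Derive a chart-review table from a synthetic cohort
#'
#' Repackages the chart-documentation fields of the encounter table as a
#' review table (one row per encounter and reviewer), the format the
#' validation pipeline consumes.
#'
#' @param encounters Encounter tibble from [generate_cohort()].
#' @param reviewer_id Reviewer identifier (default `"r1"`).
#' @return Tibble with `encounter_id`, `reviewer_id`,
#'   `exposure_documented`, `complaints`.
#' @export
reviews_from_cohort <- function(encounters, reviewer_id = "r1") {
  tibble::tibble(
    encounter_id = encounters$id,
    reviewer_id = reviewer_id,
    exposure_documented = encounters$exposure_documented,
    complaints = encounters$complaints
  )
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `encounters.csv`, `weather.csv` and `reviews.csv` into `dir`
#' (created if needed), in the column layouts read back by
#' [read_encounters()], [read_weather()] and [read_reviews()]. Output is
#' byte-identical across runs with the same cohort.
#'
#' @param cohort List from [generate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$encounters, file.path(dir, "encounters.csv"))
  readr::write_csv(cohort$weather, file.path(dir, "weather.csv"))
  readr::write_csv(reviews_from_cohort(cohort$encounters),
                   file.path(dir, "reviews.csv"))
  invisible(dir)
}
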