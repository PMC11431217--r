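#' Two-stage validation study design
#'
#' Parameters of the chart-review validation design: an enriched stage-A
#' sample of algorithm-positive charts sized for the PPV, and a stage-B
#' simple random sample of the whole coded cohort sized for sensitivity,
#' specificity and NPV. A fraction of stage-B charts is abstracted in
#' duplicate for the inter-rater kappa. Defaults mirror a published
#' two-site ED validation: 62 algorithm-positive charts, 964 random
#' charts, 20% duplicate abstraction, 95% confidence.
#'
#' @param n_ppv_sample Stage-A sample size (algorithm-positive charts).
#' @param n_random_sample Stage-B sample size (random charts).
#' @param duplicate_fraction Fraction of stage-B charts reviewed in
#'   duplicate.
#' @param conf_level Confidence level for all intervals.
#' @param reviewer_flip_prob Per-reviewer mislabeling probability used
#'   when duplicate abstraction is simulated (default 0.02).
#' @param day_class_scheme Day-classification scheme for the optional
#'   temperature strata: `"fixed"` (cool < 20, moderate 20 to < 31,
#'   hot >= 31 degrees C) or `"quartile"` (per-year quartile bands).
#' @param seed Master seed for the sampling and duplicate-abstraction
#'   substreams.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_ppv_sample = 62L, n_random_sample = 964L,
                         duplicate_fraction = 0.20, conf_level = 0.95,
                         reviewer_flip_prob = 0.02,
                         day_class_scheme = c("fixed", "quartile"),
                         seed = 1L) {
  day_class_scheme <- match.arg(day_class_scheme)
  stopifnot(n_ppv_sample >= 1, n_random_sample >= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1,
            conf_level > 0, conf_level < 1,
            reviewer_flip_prob >= 0, reviewer_flip_prob <= 1)
  structure(
    list(n_ppv_sample = as.integer(n_ppv_sample),
         n_random_sample = as.integer(n_random_sample),
         duplicate_fraction = duplicate_fraction,
         conf_level = conf_level,
         reviewer_flip_prob = reviewer_flip_prob,
         day_class_scheme = day_class_scheme,
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Classify days by fixed temperature thresholds
#'
#' Ontario heat-warning convention: hot days reach a daily maximum of at
#' least 31 degrees C, cool days stay below 20, and everything between
#' (including the 30-31 band, which the verbal definition leaves
#' unassigned) is moderate, so every finite temperature receives exactly
#' one class.
#'
#' @param tmax_c Numeric vector of daily maximum temperatures, degrees C.
#' @return Factor with levels `cool`, `moderate`, `hot`.
#' @examples
#' classify_day_fixed(c(19.9, 30.5, 31))
#' @export
classify_day_fixed <- function(tmax_c) {
  stopifnot(all(is.finite(tmax_c)))
  cut(tmax_c, breaks = c(-Inf, 20, 31, Inf), right = FALSE,
      labels = c("cool", "moderate", "hot"))
}

#' Classify days by per-year temperature quartiles
#'
#' Within each calendar year, days below the first quartile of the daily
#' maxima are cool, days above the third quartile are hot, and days in
#' the closed interquartile interval (boundaries included) are moderate.
#' Quartiles use linear interpolation between order statistics
#' (`quantile()` type 7).
#'
#' @param weather Tibble with `date` and `tmax_c`; at least 4 days per
#'   year.
#' @return `weather` with a `day_class` factor column (`cool`,
#'   `moderate`, `hot`) appended.
#' @export
classify_days_quartile <- function(weather) {
  stopifnot(all(c("date", "tmax_c") %in% names(weather)),
            all(is.finite(weather$tmax_c)))
  yr <- format(weather$date, "%Y")
  n_per_year <- table(yr)
  if (any(n_per_year < 4)) {
    stop("Quartile day classification needs at least 4 days per year; ",
         "year(s) with fewer: ",
         paste(names(n_per_year)[n_per_year < 4], collapse = ", "),
         call. = FALSE)
  }
  cls <- character(nrow(weather))
  for (y in unique(yr)) {
    sel <- yr == y
    q <- stats::quantile(weather$tmax_c[sel], c(0.25, 0.75), type = 7,
                         names = FALSE)
    x <- weather$tmax_c[sel]
    cls[sel] <- ifelse(x < q[1], "cool", ifelse(x > q[2], "hot", "moderate"))
  }
  weather$day_class <- factor(cls, levels = c("cool", "moderate", "hot"))
  weather
}

#' Cohort algorithm-positivity rate
#'
#' Fraction of encounters assigned at least one code of the case-finding
#' algorithm.
#'
#' @param encounters Encounter tibble with a `codes` column.
#' @param codeset A `code_set`.
#' @return A single proportion.
#' @examples
#' \dontrun{
#' positivity_rate(encounters, ahi_code_set())  # e.g. 0.000637 ~ "0.06%"
#' }
#' @export
positivity_rate <- function(encounters, codeset) {
  stopifnot(nrow(encounters) >= 1)
  flagged <- flag_encounters(encounters, codeset)
  mean(flagged$algorithm_positive)
}

# Both interval methods for one proportion, as tidy rows.
estimate_rows <- function(quantity, k, n, conf_level) {
  rows <- lapply(list(wald_interval(k, n, conf_level),
                      wilson_cc_interval(k, n, conf_level)),
                 function(e) {
                   tibble::tibble(
                     quantity = quantity, method = e$method, k = k, n = n,
                     estimate = e$p_hat, lower = e$lower, upper = e$upper,
                     half_width = e$half_width
                   )
                 })
  do.call(rbind, rows)
}

#' Interval estimates for the metrics a 2x2 table supports
#'
#' Computes sensitivity, specificity, PPV and NPV (where their
#' denominators are positive) from a 2x2 table, each with both the Wald
#' and the continuity-corrected Wilson interval, as a tidy table.
#' Metrics with zero denominator are omitted rather than reported as 0.
#'
#' @param t A `two_by_two`.
#' @param conf_level Confidence level.
#' @param metrics Metrics to attempt.
#' @return Tibble with columns `quantity`, `method`, `k`, `n`,
#'   `estimate`, `lower`, `upper`, `half_width`.
#' @examples
#' validity_estimates(two_by_two(1, 0, 3, 960))
#' @export
validity_estimates <- function(t, conf_level = 0.95,
                               metrics = c("sensitivity", "specificity",
                                           "ppv", "npv")) {
  stopifnot(inherits(t, "two_by_two"))
  num <- list(sensitivity = c(t$tp, t$tp + t$fn),
              specificity = c(t$tn, t$tn + t$fp),
              ppv = c(t$tp, t$tp + t$fp),
              npv = c(t$tn, t$tn + t$fn))
  out <- list()
  for (m in metrics) {
    kn <- num[[m]]
    if (kn[2] > 0) {
      out[[m]] <- estimate_rows(m, kn[1], kn[2], conf_level)
    }
  }
  do.call(rbind, out)
}

# Gold-standard label per encounter id from a review table: the first
# reviewer (lowest reviewer_id) is authoritative; additional reviewers
# only ever feed the kappa.
gold_labels_from_reviews <- function(reviews, vocabulary) {
  ord <- order(reviews$encounter_id, reviews$reviewer_id)
  reviews <- reviews[ord, ]
  first <- !duplicated(reviews$encounter_id)
  labels <- label_chart(reviews$exposure_documented[first],
                        reviews$complaints[first], vocabulary)
  names(labels) <- reviews$encounter_id[first]
  labels
}

#' Run the two-stage validation study
#'
#' Orchestrates the full validation analysis on an encounter table plus
#' chart reviews:
#'
#' * flags algorithm-positive encounters with the code set and computes
#'   the cohort positivity rate;
#' * stage A — draws a simple random sample (without replacement) of
#'   algorithm-positive encounters and estimates the PPV as the fraction
#'   meeting the gold standard;
#' * stage B — draws an independent simple random sample of the whole
#'   cohort, cross-classifies algorithm positivity against the gold
#'   standard into a 2x2 table, and estimates sensitivity, specificity
#'   and NPV (PPV is never pooled across stages: it comes from stage A
#'   only, the stage-B metrics from stage B only);
#' * simulates duplicate abstraction on the configured fraction of the
#'   stage-B sample and computes the inter-rater kappa;
#' * when `weather` is supplied, classifies each stage-B chart's visit
#'   day (fixed thresholds or per-year quartiles) and builds per-stratum
#'   2x2 tables. Stratified metrics are emitted only when every stratum
#'   contains at least one gold-standard positive; otherwise the report
#'   records the suppression — with a handful of true cases, stratified
#'   validity is not estimable and should not be reported.
#'
#' All sampling runs on substreams derived from `design$seed`, so the
#' whole report is reproducible.
#'
#' @param encounters Encounter tibble (`id`, `date`, `codes`, ...).
#' @param reviews Review tibble (`encounter_id`, `reviewer_id`,
#'   `exposure_documented`, `complaints`) covering at least every
#'   sampled encounter.
#' @param design A [study_design()].
#' @param codeset A `code_set` (default the bundled AHI algorithm).
#' @param weather Optional weather tibble (`date`, `tmax_c`).
#' @param vocabulary Complaint vocabulary for gold-standard labeling.
#' @return An object of class `validity_report`.
#' @export
run_validation_study <- function(encounters, reviews, design,
                                 codeset = ahi_code_set(),
                                 weather = NULL,
                                 vocabulary = default_complaint_vocabulary()) {
  stopifnot(inherits(design, "study_design"), nrow(encounters) >= 1)
  flagged <- flag_encounters(encounters, codeset)
  n_cohort <- nrow(flagged)
  pos_ids <- flagged$id[flagged$algorithm_positive]
  positivity <- length(pos_ids) / n_cohort

  if (length(pos_ids) < design$n_ppv_sample) {
    stop("Design infeasible: stage A needs ", design$n_ppv_sample,
         " algorithm-positive encounters but the cohort contains only ",
         length(pos_ids), ".", call. = FALSE)
  }
  if (n_cohort < design$n_random_sample) {
    stop("Design infeasible: stage B needs ", design$n_random_sample,
         " encounters but the cohort contains only ", n_cohort, ".",
         call. = FALSE)
  }

  gold <- gold_labels_from_reviews(reviews, vocabulary)
  lookup_gold <- function(ids) {
    missing <- setdiff(ids, names(gold))
    if (length(missing)) {
      stop("No chart review for sampled encounter(s): ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) sprintf(" (and %d more)",
                                            length(missing) - 5),
           call. = FALSE)
    }
    unname(gold[ids])
  }

  # Stage A: enriched algorithm-positive sample -> PPV.
  stage_a_ids <- withr::with_seed(
    derive_seed(design$seed, "stage-a"),
    pos_ids[sample.int(length(pos_ids), design$n_ppv_sample)]
  )
  gold_a <- lookup_gold(stage_a_ids)
  stage_a <- list(
    n = design$n_ppv_sample,
    k_gold_positive = sum(gold_a),
    estimates = estimate_rows("ppv", sum(gold_a), design$n_ppv_sample,
                              design$conf_level)
  )

  # Stage B: random sample of the whole coded cohort -> 2x2.
  stage_b_idx <- withr::with_seed(
    derive_seed(design$seed, "stage-b"),
    sample.int(n_cohort, design$n_random_sample)
  )
  b <- flagged[stage_b_idx, ]
  gold_b <- lookup_gold(b$id)
  tab <- two_by_two(
    tp = sum(b$algorithm_positive & gold_b),
    fp = sum(b$algorithm_positive & !gold_b),
    fn = sum(!b$algorithm_positive & gold_b),
    tn = sum(!b$algorithm_positive & !gold_b)
  )
  stage_b <- list(
    n = design$n_random_sample,
    table = tab,
    estimates = validity_estimates(tab, design$conf_level,
                                   metrics = c("sensitivity", "specificity",
                                               "npv"))
  )

  # Inter-rater reliability on the duplicated stage-B fraction.
  pairs <- simulate_dual_abstraction(gold_b, design$reviewer_flip_prob,
                                     design$duplicate_fraction,
                                     seed = derive_seed(design$seed, "kappa"))
  kappa <- tryCatch(cohen_kappa(pairs$label_a, pairs$label_b),
                    error = function(e) NULL)
  kappa_note <- if (is.null(kappa)) {
    if (nrow(pairs) == 0) {
      "no duplicate reviews requested"
    } else {
      "kappa undefined: both reviewers used a single identical label"
    }
  } else {
    NA_character_
  }

  # Temperature strata of the stage-B sample.
  strata <- NULL
  strata_note <- "no weather series supplied; strata not computed"
  if (!is.null(weather)) {
    day_class <- if (design$day_class_scheme == "fixed") {
      stats::setNames(classify_day_fixed(weather$tmax_c),
                      as.character(weather$date))
    } else {
      w <- classify_days_quartile(weather)
      stats::setNames(w$day_class, as.character(w$date))
    }
    cls <- day_class[as.character(b$date)]
    if (anyNA(cls)) {
      stop("Weather series does not cover every sampled encounter date.",
           call. = FALSE)
    }
    strata <- do.call(rbind, lapply(levels(cls), function(lv) {
      sel <- cls == lv
      tibble::tibble(
        day_class = lv,
        n = sum(sel),
        tp = sum(b$algorithm_positive[sel] & gold_b[sel]),
        fp = sum(b$algorithm_positive[sel] & !gold_b[sel]),
        fn = sum(!b$algorithm_positive[sel] & gold_b[sel]),
        tn = sum(!b$algorithm_positive[sel] & !gold_b[sel])
      )
    }))
    strata$n_gold_positive <- strata$tp + strata$fn
    if (all(strata$n_gold_positive >= 1)) {
      strata_note <- "all strata have gold positives; stratified metrics emitted"
      strata$sensitivity <- strata$tp / (strata$tp + strata$fn)
    } else {
      strata_note <- paste(
        "stratified validity suppressed: no gold-standard positives in",
        paste(strata$day_class[strata$n_gold_positive == 0], collapse = ", "),
        "days")
    }
  }

  structure(
    list(design = design, codeset_name = codeset$name,
         n_cohort = n_cohort, n_algorithm_positive = length(pos_ids),
         positivity = positivity,
         stage_a = stage_a, stage_b = stage_b,
         kappa = kappa, kappa_note = kappa_note, n_kappa_pairs = nrow(pairs),
         strata = strata, strata_note = strata_note),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  cat("== Validation of coding algorithm '", x$codeset_name, "' ==\n",
      sep = "")
  cat(sprintf("Cohort: %d encounters; %d algorithm-positive (%s)\n",
              x$n_cohort, x$n_algorithm_positive,
              format_percent(x$positivity, 2)))
  cat(sprintf("Stage A (PPV): n = %d, gold-positive = %d\n",
              x$stage_a$n, x$stage_a$k_gold_positive))
  cat(sprintf("Stage B (Sn/Sp/NPV): n = %d; 2x2 [tp %d, fp %d, fn %d, tn %d]\n",
              x$stage_b$n, x$stage_b$table$tp, x$stage_b$table$fp,
              x$stage_b$table$fn, x$stage_b$table$tn))
  est <- rbind(x$stage_a$estimates, x$stage_b$estimates)
  for (i in seq_len(nrow(est))) {
    e <- est[i, ]
    cat(sprintf("  %-11s [%-9s] %s (%s to %s)\n", e$quantity, e$method,
                format_percent(e$estimate), format_percent(e$lower),
                format_percent(e$upper)))
  }
  if (!is.null(x$kappa)) {
    cat(sprintf("Inter-rater kappa: %.2f on %d duplicated pairs\n",
                x$kappa$kappa, x$kappa$n_pairs))
  } else {
    cat("Inter-rater kappa: not computed (", x$kappa_note, ")\n", sep = "")
  }
  cat("Strata: ", x$strata_note, "\n", sep = "")
  invisible(x)
}

#' Write a validity report to files
#'
#' Writes `report.txt` (human-readable, including the seed and package
#' version), `report.csv` (tidy estimates), `two_by_two.csv` and
#' `strata.csv` into `dir`.
#'
#' @param report A `validity_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_validity_report <- function(report, dir) {
  stopifnot(inherits(report, "validity_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  est <- rbind(report$stage_a$estimates, report$stage_b$estimates)
  est$stage <- rep(c("A", "B"),
                   c(nrow(report$stage_a$estimates),
                     nrow(report$stage_b$estimates)))
  readr::write_csv(est, file.path(dir, "report.csv"))

  t <- report$stage_b$table
  readr::write_csv(
    tibble::tibble(tp = t$tp, fp = t$fp, fn = t$fn, tn = t$tn),
    file.path(dir, "two_by_two.csv")
  )

  if (!is.null(report$strata)) {
    readr::write_csv(report$strata, file.path(dir, "strata.csv"))
  } else {
    readr::write_csv(
      tibble::tibble(day_class = character(), note = character()),
      file.path(dir, "strata.csv")
    )
  }

  txt <- c(
    paste0("heatvalid ", as.character(utils::packageVersion("heatvalid")),
           " validity report"),
    paste0("seed: ", report$design$seed),
    paste0("codeset: ", report$codeset_name),
    utils::capture.output(print(report))
  )
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
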