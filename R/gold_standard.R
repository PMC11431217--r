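#' The default heat-related complaint vocabulary
#'
#' Controlled vocabulary of chart-documented complaints that count
#' towards the gold-standard AHI definition. The clinical list is
#' open-ended in practice; a closed default set keeps labeling testable,
#' and users can extend it via [read_complaint_vocabulary()] or by
#' passing their own vector to [label_chart()].
#'
#' @return Character vector of lowercase canonical complaint terms.
#' @export
default_complaint_vocabulary <- function() {
  c("syncope", "heat stroke", "loss of consciousness", "muscle cramps",
    "pain", "exhaustion", "fatigue", "edema")
}

#' Read a complaint vocabulary file
#'
#' One term per line; blank lines ignored; terms are lowercased.
#'
#' @param path Path to a plain-text vocabulary file.
#' @return Character vector of terms.
#' @export
read_complaint_vocabulary <- function(path) {
  terms <- tolower(trimws(readLines(path, warn = FALSE)))
  terms <- unique(terms[nzchar(terms)])
  if (length(terms) == 0L) {
    stop("Vocabulary file ", path, " contains no terms.", call. = FALSE)
  }
  terms
}

#' Apply the gold-standard AHI definition to chart reviews
#'
#' A chart is gold-standard positive for acute heat illness when the
#' reviewer found BOTH healthcare-provider documentation of
#' patient-reported heat exposure AND at least one documented
#' heat-related complaint. Either conjunct alone is insufficient: a
#' syncope chart without documented heat exposure, or documented
#' exposure without any complaint, is negative.
#'
#' @param exposure_documented Logical vector: heat exposure documented.
#' @param complaints Complaint lists, either a character vector of
#'   semicolon-delimited terms (`""` for none) or a list of character
#'   vectors. Terms outside the vocabulary are an error.
#' @param vocabulary Allowed complaint terms
#'   (default [default_complaint_vocabulary()]).
#' @return Logical vector of gold-standard labels.
#' @examples
#' label_chart(TRUE, "syncope")
#' label_chart(c(TRUE, FALSE), c("", "heat stroke;fatigue"))
#' @export
label_chart <- function(exposure_documented, complaints,
                        vocabulary = default_complaint_vocabulary()) {
  stopifnot(is.logical(exposure_documented))
  if (is.character(complaints)) {
    parts <- strsplit(tolower(ifelse(is.na(complaints), "", complaints)),
                      ";", fixed = TRUE)
  } else {
    stopifnot(is.list(complaints))
    parts <- lapply(complaints, tolower)
  }
  stopifnot(length(parts) == length(exposure_documented))
  # flatten once: per-row loops over trimws/tolower dominate runtime on
  # cohort-sized inputs
  flat <- trimws(unlist(parts, use.names = FALSE))
  row_of <- rep.int(seq_along(parts), lengths(parts))
  keep <- nzchar(flat)
  unknown <- setdiff(unique(flat[keep]), vocabulary)
  if (length(unknown)) {
    stop("Unknown complaint term(s): ",
         paste(sprintf("\"%s\"", unknown), collapse = ", "),
         ". Extend the vocabulary to accept them.", call. = FALSE)
  }
  n_terms <- tabulate(row_of[keep], nbins = length(parts))
  exposure_documented & n_terms > 0L
}

#' Simulate blinded duplicate chart abstraction
#'
#' Emulates the reliability arm of a chart-review study: a simple random
#' fraction of the reviewed charts is abstracted independently by two
#' reviewers, each of whom reports the true gold-standard label with
#' probability `1 - flip_prob` (labeling errors are independent between
#' reviewers and across charts). The resulting label pairs feed the
#' inter-rater kappa; they are not used for the accuracy estimates.
#'
#' @param truth Logical vector of true gold-standard labels for the
#'   reviewed charts.
#' @param flip_prob Per-reviewer probability of recording the wrong
#'   label.
#' @param duplicate_fraction Fraction of charts reviewed in duplicate
#'   (default 0.20); the subset size is `round(duplicate_fraction * n)`.
#' @param seed Integer seed.
#' @return Tibble with `index` (position in `truth`), `label_a`,
#'   `label_b`. Zero rows when `truth` is empty or the fraction is 0.
#' @examples
#' simulate_dual_abstraction(rep(c(TRUE, FALSE), 50), 0.02, 0.2, seed = 1)
#' @export
simulate_dual_abstraction <- function(truth, flip_prob,
                                      duplicate_fraction = 0.2, seed) {
  stopifnot(is.logical(truth),
            flip_prob >= 0, flip_prob <= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1)
  n <- length(truth)
  m <- round(duplicate_fraction * n)
  if (n == 0L || m == 0L) {
    return(tibble::tibble(index = integer(), label_a = logical(),
                          label_b = logical()))
  }
  withr::with_seed(derive_seed(seed, "dual-abstraction"), {
    idx <- sort(sample.int(n, m))
    flip_a <- stats::runif(m) < flip_prob
    flip_b <- stats::runif(m) < flip_prob
    tibble::tibble(
      index = idx,
      label_a = xor(truth[idx], flip_a),
      label_b = xor(truth[idx], flip_b)
    )
  })
}
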