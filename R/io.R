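#' Read study input tables
#'
#' Typed CSV readers for the three study inputs. Encounter tables have
#' one row per ED encounter with semicolon-delimited ICD-10 codes;
#' review tables one row per (encounter, reviewer); weather tables one
#' row per date with the daily maximum temperature in degrees Celsius.
#' Dates are ISO-8601. Missing optional columns are tolerated; the
#' columns each pipeline step needs are validated where used.
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @name study_io
NULL

#' @rdname study_io
#' @export
read_encounters <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          id = readr::col_character(),
                          date = readr::col_date(),
                          codes = readr::col_character(),
                          .default = readr::col_guess()
                        ))
  required <- c("id", "date", "codes")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("Encounter file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$codes[is.na(df$codes)] <- ""
  df
}

#' @rdname study_io
#' @export
read_reviews <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          encounter_id = readr::col_character(),
                          reviewer_id = readr::col_character(),
                          exposure_documented = readr::col_logical(),
                          complaints = readr::col_character()
                        ))
  required <- c("encounter_id", "reviewer_id", "exposure_documented",
                "complaints")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("Review file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$complaints[is.na(df$complaints)] <- ""
  df
}

#' @rdname study_io
#' @export
read_weather <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          date = readr::col_date(),
                          tmax_c = readr::col_double()
                        ))
  missing <- setdiff(c("date", "tmax_c"), names(df))
  if (length(missing)) {
    stop("Weather file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$date)) {
    stop("Weather file has more than one row for some date(s).",
         call. = FALSE)
  }
  if (any(!is.finite(df$tmax_c))) {
    stop("Weather file contains non-finite temperatures.", call. = FALSE)
  }
  df
}
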