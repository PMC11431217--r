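#' Normalize raw ICD-10 code strings
#'
#' Administrative extracts record ICD-10 codes with inconsistent case,
#' decimal points and stray whitespace (`"T67.0"`, `" n17 "`). Matching
#' against a code set requires a canonical form: uppercase, all dots and
#' whitespace removed. Normalization is idempotent.
#'
#' @param raw Character vector of raw code strings.
#' @return Character vector of normalized codes: a leading letter followed
#'   by two digits and up to four further alphanumerics.
#' @examples
#' normalize_code(c("T67.0", "n17", "T670"))
#' @export
normalize_code <- function(raw) {
  if (!is.character(raw)) {
    stop("`raw` must be a character vector of ICD-10 codes.", call. = FALSE)
  }
  out <- toupper(gsub("[.[:space:]]", "", raw))
  bad <- is.na(out) | !grepl("^[A-Z][0-9]{2}[A-Z0-9]{0,4}$", out)
  if (any(bad)) {
    stop(
      "Malformed ICD-10 code(s): ",
      paste(sprintf("\"%s\"", raw[bad]), collapse = ", "),
      ". Expected a letter, two digits, then up to four alphanumerics.",
      call. = FALSE
    )
  }
  out
}

#' Construct a diagnosis code set
#'
#' A code set is a named collection of normalized ICD-10 code *prefixes*
#' used as a case-finding algorithm: an encounter is algorithm-positive
#' when any of its assigned codes extends one of the `includes` entries.
#' Category-level entries (e.g. `"N17"`) therefore capture all their
#' subcodes (`"N170"` ... `"N179"`). The `excludes` slot documents codes
#' that were deliberately left out of the algorithm; it is descriptive
#' only and never vetoes a match on an included code.
#'
#' @param name Short name for the set.
#' @param includes Character vector of code prefixes that define positivity.
#' @param excludes Character vector of code prefixes documented as excluded.
#' @return An object of class `code_set`.
#' @seealso [ahi_code_set()] for the bundled acute heat illness algorithm.
#' @export
code_set <- function(name, includes, excludes = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  includes <- unique(normalize_code(includes))
  excludes <- if (length(excludes)) unique(normalize_code(excludes)) else character()
  if (length(includes) == 0L) {
    stop("A code set needs at least one include entry.", call. = FALSE)
  }
  overlap <- intersect(includes, excludes)
  if (length(overlap)) {
    stop(
      "Codes cannot be both included and excluded: ",
      paste(overlap, collapse = ", "), call. = FALSE
    )
  }
  structure(
    list(name = name, includes = includes, excludes = excludes),
    class = "code_set"
  )
}

#' @export
print.code_set <- function(x, ...) {
  cat("<code_set> ", x$name, "\n", sep = "")
  cat("  includes (", length(x$includes), "): ",
      paste(x$includes, collapse = ", "), "\n", sep = "")
  if (length(x$excludes)) {
    cat("  excludes (", length(x$excludes), "): ",
        paste(x$excludes, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' The acute heat illness (AHI) ICD-10 coding algorithm
#'
#' Returns the expanded AHI code set used to flag emergency-department
#' encounters for acute heat illness: direct heat-exposure and
#' heat-illness codes (X30, X32, T670-T679) plus consequence codes
#' (volume depletion, acute kidney injury, hyperthermic fever,
#' rhabdomyolysis, electrolyte disorders, syncope and collapse).
#' W92 (excessive heat of man-made origin, e.g. saunas or occupational
#' sources) is documented as excluded: the algorithm targets
#' environmentally caused heat illness.
#'
#' The set ships as a JSON registry file under
#' `system.file("extdata", "codesets", "ahi.json", package = "heatvalid")`.
#'
#' @return A `code_set` with 23 include prefixes and one exclude (W92).
#' @examples
#' ahi <- ahi_code_set()
#' code_matches(ahi, "T670")
#' @export
ahi_code_set <- function() {
  path <- system.file("extdata", "codesets", "ahi.json",
                      package = "heatvalid", mustWork = TRUE)
  read_code_set(path)
}

#' Read and write code-set registry files
#'
#' Code sets are stored as small JSON documents with fields `name`,
#' `includes` and `excludes`, so that alternative algorithms can be
#' supplied without changing code.
#'
#' @param path Path to a JSON registry file.
#' @return `read_code_set()` returns a `code_set`;
#'   `write_code_set()` returns `path` invisibly.
#' @export
read_code_set <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("name", "includes")) {
    if (is.null(doc[[field]])) {
      stop("Code-set file ", path, " is missing field `", field, "`.",
           call. = FALSE)
    }
  }
  code_set(doc$name, doc$includes,
           if (is.null(doc$excludes)) character() else doc$excludes)
}

#' @rdname read_code_set
#' @param x A `code_set`.
#' @export
write_code_set <- function(x, path) {
  stopifnot(inherits(x, "code_set"))
  jsonlite::write_json(
    list(name = x$name, includes = x$includes, excludes = x$excludes),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Does a code match a code set?
#'
#' A normalized code matches when some include entry is a prefix of it,
#' so category entries capture all their subcodes. Excluded entries are
#' documentation only and play no role in matching.
#'
#' @param codeset A `code_set`.
#' @param code Character vector of normalized codes.
#' @return Logical vector, one element per code.
#' @examples
#' code_matches(ahi_code_set(), c("T670", "N179", "Z000"))
#' @export
code_matches <- function(codeset, code) {
  stopifnot(inherits(codeset, "code_set"))
  if (length(code) == 0L) return(logical(0))
  code <- normalize_code(code)
  vapply(
    code,
    function(cd) any(startsWith(cd, codeset$includes)),
    logical(1), USE.NAMES = FALSE
  )
}

#' Is an encounter algorithm-positive?
#'
#' An encounter is flagged when at least one of its assigned codes, in
#' any diagnostic field, matches the code set. An encounter with no
#' codes is negative.
#'
#' @param codeset A `code_set`.
#' @param codes Character vector of the encounter's normalized codes
#'   (possibly empty).
#' @return A single logical.
#' @examples
#' encounter_is_algorithm_positive(ahi_code_set(), c("J45", "T675"))
#' encounter_is_algorithm_positive(ahi_code_set(), "W92")
#' @export
encounter_is_algorithm_positive <- function(codeset, codes) {
  if (length(codes) == 0L) return(FALSE)
  any(code_matches(codeset, codes))
}

#' Flag algorithm-positive encounters in a table
#'
#' Applies [encounter_is_algorithm_positive()] to each row of an
#' encounter table whose `codes` column holds semicolon-delimited code
#' strings, appending a logical `algorithm_positive` column.
#'
#' @param encounters Data frame with a character `codes` column
#'   (semicolon-delimited; empty string means no codes).
#' @param codeset A `code_set`.
#' @return `encounters` with an `algorithm_positive` column appended.
#' @export
flag_encounters <- function(encounters, codeset) {
  stopifnot(is.data.frame(encounters), "codes" %in% names(encounters))
  code_lists <- split_codes(encounters$codes)
  # Match each distinct code once, then fold back per encounter: large
  # cohorts carry few distinct codes, so this is far cheaper than a
  # per-row loop and provably equivalent to
  # encounter_is_algorithm_positive() row by row.
  all_codes <- unlist(code_lists, use.names = FALSE)
  row_of <- rep.int(seq_along(code_lists), lengths(code_lists))
  positive <- logical(length(code_lists))
  if (length(all_codes)) {
    uniq <- unique(all_codes)
    uniq_match <- code_matches(codeset, uniq)
    hit <- uniq_match[match(all_codes, uniq)]
    positive[unique(row_of[hit])] <- TRUE
  }
  encounters$algorithm_positive <- positive
  encounters
}

# "A;B;C" -> c("A","B","C"); "" or NA -> character(0)
split_codes <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE), function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}
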