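# CSV schemas. All files are UTF-8 with mandatory header rows; positions
# are signed integers; accuracies are percent with 2 decimal places; the
# reported span column is the only value rounded (1 d.p.).

TRIALS_COLS <- c("participant_id", "age_group", "complexity", "block",
                 "center", "stim1", "stim2", "stim3",
                 "correct1", "correct2", "correct3")

#' Read and write trial tables
#'
#' One row per trigram presentation. Reading validates the schema against
#' a design and reports offending row numbers.
#'
#' @param path File path.
#' @param design A `vs_design` used for validation.
#' @param trials Trial table (extra columns such as responses are dropped
#'   on write).
#' @return `read_trials_csv()` returns the validated trial data frame;
#'   `write_trials_csv()` returns `path` invisibly.
#' @export
read_trials_csv <- function(path, design = default_design()) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  missing_cols <- setdiff(TRIALS_COLS, names(trials))
  if (length(missing_cols)) {
    stop("`", path, "` is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_trials(trials, design)
  trials[TRIALS_COLS]
}

#' @rdname read_trials_csv
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials[TRIALS_COLS], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write profile tables
#'
#' One row per participant x complexity x scored position; accuracies are
#' serialized with two decimal places.
#'
#' @param profiles Profile table from [build_profiles()].
#' @param path File path.
#' @return `read_profiles_csv()` returns the profile data frame;
#'   `write_profiles_csv()` returns `path` invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  out <- profiles
  out$accuracy_pct <- round(out$accuracy_pct, 2)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read and write span tables
#'
#' The reported `span_chars` column is rounded to one decimal place on
#' write (the convention for reporting span sizes); all other columns keep
#' full precision to four decimals.
#'
#' @param spans Span table from [estimate_spans()].
#' @param path File path.
#' @return `read_spans_csv()` returns the span data frame;
#'   `write_spans_csv()` returns `path` invisibly.
#' @export
write_spans_csv <- function(spans, path) {
  out <- spans
  out$span_chars <- round(out$span_chars, 1)
  for (col in c("r_squared", "left_extent", "right_extent", "asymmetry",
                "span_bits")) {
    out[[col]] <- round(out[[col]], 4)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_spans_csv
#' @export
read_spans_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read and write sentence-reading tables
#'
#' @param records Reading table (`participant_id`, `sentence_id`,
#'   `n_characters`, `reading_time_s`).
#' @param path File path.
#' @return `read_reading_csv()` returns the reading data frame;
#'   `write_reading_csv()` returns `path` invisibly.
#' @export
write_reading_csv <- function(records, path) {
  cols <- c("participant_id", "sentence_id", "n_characters",
            "reading_time_s")
  utils::write.csv(records[cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_reading_csv
#' @export
read_reading_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
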