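#' Convert sentence-reading records to characters-per-minute speeds
#'
#' Each sentence contributes a speed of `60 * n_characters / reading_time_s`
#' characters per minute. Per participant, speeds are aggregated either as
#' the mean of per-sentence speeds (default) or as total characters over
#' total time; the two differ whenever sentence lengths or times vary, so
#' the mode used is recorded on the result.
#'
#' @param records Data frame with columns `participant_id`, `sentence_id`,
#'   `n_characters` (>= 1) and `reading_time_s` (> 0, seconds).
#' @param method `"mean_of_speeds"` or `"total_ratio"`.
#' @return Data frame with columns `participant_id` and `cpm`, one row per
#'   participant, with the aggregation mode in attribute `"method"`.
#' @export
compute_reading_speed <- function(records,
                                  method = c("mean_of_speeds",
                                             "total_ratio")) {
  method <- match.arg(method)
  required <- c("participant_id", "n_characters", "reading_time_s")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("reading table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) stop("reading table is empty", call. = FALSE)
  bad <- which(!(records$reading_time_s > 0) | records$n_characters < 1)
  if (length(bad)) {
    stop("invalid reading records (non-positive time or empty sentence) ",
         "at rows ", paste(utils::head(bad, 10L), collapse = ", "),
         call. = FALSE)
  }
  pid <- factor(records$participant_id)
  cpm <- if (method == "mean_of_speeds") {
    tapply(60 * records$n_characters / records$reading_time_s, pid, mean)
  } else {
    60 * tapply(records$n_characters, pid, sum) /
      tapply(records$reading_time_s, pid, sum)
  }
  structure(data.frame(participant_id = levels(pid),
                       cpm = as.numeric(cpm),
                       stringsAsFactors = FALSE),
            method = method)
}

#' Pair span estimates with reading speeds for correlation
#'
#' Builds the paired table consumed by [pearson_r()]. With
#' `pooling = "participant_mean"` each participant contributes one pair:
#' span averaged across complexity levels against reading speed. With
#' `pooling = "per_complexity"` the pairs are the spans at one named
#' complexity level. Participants present in only one of the two tables
#' are listed in a warning and dropped.
#'
#' @param spans Span table as produced by [estimate_spans()].
#' @param speeds Speed table as produced by [compute_reading_speed()].
#' @param pooling `"participant_mean"` or `"per_complexity"`.
#' @param complexity Complexity level to keep when
#'   `pooling = "per_complexity"`.
#' @return Data frame with columns `participant_id`, `span` and `cpm`.
#' @export
span_speed_join <- function(spans, speeds,
                            pooling = c("participant_mean",
                                        "per_complexity"),
                            complexity = NULL) {
  pooling <- match.arg(pooling)
  unmatched <- c(setdiff(spans$participant_id, speeds$participant_id),
                 setdiff(speeds$participant_id, spans$participant_id))
  if (length(unmatched)) {
    warning("excluding unmatched participants: ",
            paste(unique(unmatched), collapse = ", "), call. = FALSE)
  }
  if (pooling == "participant_mean") {
    pid <- factor(spans$participant_id)
    agg <- data.frame(participant_id = levels(pid),
                      span = as.numeric(tapply(spans$span_chars, pid, mean)),
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(complexity)) {
      stop("`complexity` must name a level when pooling per complexity",
           call. = FALSE)
    }
    sub <- spans[spans$complexity == complexity, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("no spans at complexity level `", complexity, "`", call. = FALSE)
    }
    agg <- data.frame(participant_id = sub$participant_id,
                      span = sub$span_chars, stringsAsFactors = FALSE)
  }
  merged <- merge(agg, speeds[c("participant_id", "cpm")],
                  by = "participant_id")
  merged[order(merged$participant_id), , drop = FALSE]
}
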