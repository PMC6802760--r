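log_msg <- function(verbose, ...) {
  if (verbose) message(...)
}

#' Generate a synthetic dataset on disk
#'
#' Simulates a cohort under `config` and writes `trials.csv`,
#' `reading.csv` and `manifest.json` (the full configuration plus derived
#' seeds) into `out_dir`, creating the directory if needed. Re-running
#' with the same manifest reproduces byte-identical files.
#'
#' @param config A `vs_generator_config`.
#' @param out_dir Output directory.
#' @param design A `vs_design`.
#' @param verbose Log progress messages.
#' @return Invisibly, a named list of the written paths.
#' @export
run_simulate <- function(config = generator_config(), out_dir = ".",
                         design = default_design(), verbose = TRUE) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    log_msg(verbose, "created output directory ", out_dir)
  }
  cohort <- simulate_cohort(config, design)
  paths <- list(trials = file.path(out_dir, "trials.csv"),
                reading = file.path(out_dir, "reading.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_trials_csv(cohort$trials, paths$trials)
  write_reading_csv(cohort$reading, paths$reading)
  jsonlite::write_json(cohort$manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_msg(verbose, "simulated ", nrow(cohort$trials), " trials and ",
          nrow(cohort$reading), " reading records for ",
          length(unique(cohort$trials$participant_id)), " participants")
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Scores trials into profiles, fits and selects profile curves, extracts
#' spans in characters and bits, runs the mixed ANOVA and the pairwise
#' age contrasts, and (when reading records are supplied) computes reading
#' speeds and span-speed correlations averaged across complexity levels
#' and per level. Results are written as CSV/JSON plus a plain-text report
#' mirroring the usual span-study tables.
#'
#' @param trials Trial table or path to a trials CSV.
#' @param reading Optional reading table or path to a reading CSV.
#' @param out_dir Output directory (created if missing).
#' @param design A `vs_design`.
#' @param criterion Span accuracy criterion (percent).
#' @param delta_r2 Model-selection threshold for [select_best_fit()].
#' @param gg_correct Apply the Greenhouse-Geisser correction in the ANOVA.
#' @param speed_method Aggregation mode for [compute_reading_speed()].
#' @param set_size Stimulus set size.
#' @param verbose Log stage progress.
#' @return Invisibly, a list with `profiles`, `spans`, `anova_chars`,
#'   `anova_bits`, `pairwise_chars`, `center_role`, `asymmetry_summary`,
#'   `speeds` and `correlations` (the latter two `NULL` without reading
#'   data).
#' @export
run_analyze <- function(trials, reading = NULL, out_dir = ".",
                        design = default_design(), criterion = 80,
                        delta_r2 = 0.01, gg_correct = TRUE,
                        speed_method = "mean_of_speeds", set_size = 26,
                        verbose = TRUE) {
  if (is.character(trials)) trials <- read_trials_csv(trials, design)
  if (is.character(reading)) reading <- read_reading_csv(reading)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  log_msg(verbose, "scoring ", nrow(trials), " trials")
  profiles <- build_profiles(trials, design)
  write_profiles_csv(profiles, file.path(out_dir, "profiles.csv"))
  log_msg(verbose, "built ", nrow(profiles), " profile rows (",
          length(unique(profiles$participant_id)), " participants)")

  spans <- estimate_spans(profiles, criterion = criterion,
                          delta_r2 = delta_r2, set_size = set_size)
  write_spans_csv(spans, file.path(out_dir, "spans.csv"))
  log_msg(verbose, "estimated ", nrow(spans), " spans (",
          sum(spans$model == "double"), " dual-Gaussian fits, ",
          sum(spans$span_chars == 0), " zero spans)")

  anova_chars <- mixed_anova(spans, dv = "span_chars",
                             within_levels = design$complexity_levels,
                             gg_correct = gg_correct)
  anova_bits <- mixed_anova(spans, dv = "span_bits",
                            within_levels = design$complexity_levels,
                            gg_correct = gg_correct)
  pairwise_chars <- pairwise_age_by_complexity(
    spans, dv = "span_chars", within_levels = design$complexity_levels)
  center_role <- center_role_accuracy(trials, design)

  asym <- spans[!is.na(spans$asymmetry), , drop = FALSE]
  asym_means <- tapply(asym$asymmetry, asym$age_group, mean)
  asymmetry_summary <- data.frame(
    age_group = names(asym_means),
    mean_asymmetry = as.numeric(asym_means),
    n = as.integer(table(asym$age_group)[names(asym_means)]),
    stringsAsFactors = FALSE)

  speeds <- NULL
  correlations <- NULL
  if (!is.null(reading)) {
    speeds <- compute_reading_speed(reading, method = speed_method)
    log_msg(verbose, "computed reading speeds for ", nrow(speeds),
            " participants (", speed_method, ")")
    corr_of <- function(pairs) {
      ct <- pearson_r(pairs$span, pairs$cpm)
      data.frame(r = ct$r, p = ct$p, n = ct$n)
    }
    correlations <- rbind(
      cbind(pooling = "participant_mean",
            corr_of(span_speed_join(spans, speeds, "participant_mean"))),
      do.call(rbind, lapply(design$complexity_levels, function(lv) {
        cbind(pooling = lv,
              corr_of(span_speed_join(spans, speeds, "per_complexity",
                                      complexity = lv)))
      })))
  }

  results <- list(profiles = profiles, spans = spans,
                  anova_chars = anova_chars, anova_bits = anova_bits,
                  pairwise_chars = pairwise_chars,
                  center_role = center_role,
                  asymmetry_summary = asymmetry_summary,
                  speeds = speeds, correlations = correlations)

  stats_json <- list(
    criterion = criterion, delta_r2 = delta_r2,
    gg_correct = gg_correct,
    anova_span_chars = as.data.frame(anova_chars),
    anova_span_bits = as.data.frame(anova_bits),
    pairwise_span_chars = pairwise_chars,
    asymmetry_summary = asymmetry_summary,
    correlations = correlations)
  jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(format_report(results), file.path(out_dir, "report.txt"))
  log_msg(verbose, "wrote profiles.csv, spans.csv, stats.json, report.txt",
          " to ", out_dir)
  invisible(results)
}

# Plain-text report mirroring the usual layout of span-study results
# tables: cell means, ANOVA table, pairwise contrasts, correlations.
format_report <- function(results) {
  spans <- results$spans
  lines <- character(0)
  add <- function(...) lines <<- c(lines, paste0(...))
  add("Visual span analysis report")
  add(strrep("=", 60))
  add("")
  add("Mean span size by age group and complexity")
  cm <- stats::aggregate(cbind(span_chars, span_bits) ~
                           age_group + complexity, data = spans, mean)
  se <- stats::aggregate(span_chars ~ age_group + complexity, data = spans,
                         function(v) stats::sd(v) / sqrt(length(v)))
  cm$se_chars <- se$span_chars
  for (i in seq_len(nrow(cm))) {
    add(sprintf("  %-6s %-7s  %5.1f chars (SE %.1f)   %5.1f bits",
                cm$age_group[i], cm$complexity[i], cm$span_chars[i],
                cm$se_chars[i], cm$span_bits[i]))
  }
  add("")
  add("Mixed ANOVA, span in characters")
  a <- as.data.frame(results$anova_chars)
  for (i in seq_len(nrow(a))) {
    add(sprintf("  %-28s F(%.2f, %.2f) = %6.2f, p = %-8.3g eta_p^2 = %.3f",
                a$effect[i], a$df_num[i], a$df_den[i], a$F[i], a$p[i],
                a$partial_eta_sq[i]))
  }
  add("")
  add("Pairwise age contrasts by complexity (Bonferroni)")
  pw <- results$pairwise_chars
  for (i in seq_len(nrow(pw))) {
    add(sprintf("  %-7s t(%d) = %5.2f, p_adj = %-8.3g d = %5.2f",
                pw$complexity[i], as.integer(pw$df[i]), pw$t[i],
                pw$p_adj[i], pw$cohens_d[i]))
  }
  if (!is.null(results$correlations)) {
    add("")
    add("Span-reading speed Pearson correlations")
    co <- results$correlations
    for (i in seq_len(nrow(co))) {
      add(sprintf("  %-16s r = %5.2f, p = %-8.3g (n = %d)", co$pooling[i],
                  co$r[i], co$p[i], co$n[i]))
    }
  }
  lines
}
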