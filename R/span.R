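# Locate the outermost crossings of fitted(x) = criterion on [-9, 9] by a
# 0.001-position grid scan followed by root refinement. Returns c(xl, xr),
# or NULL when the curve never reaches the criterion.
criterion_crossings <- function(fit, criterion) {
  xs <- seq(-9, 9, by = 0.001)
  ys <- gaussian_curve(xs, fit$par)
  imax <- which.max(ys)
  if (ys[imax] < criterion) return(NULL)
  f <- function(x) gaussian_curve(x, fit$par) - criterion

  refine <- function(a, b) {
    fa <- f(a); fb <- f(b)
    if (abs(fa) < 1e-9) return(a)
    if (abs(fb) < 1e-9) return(b)
    stats::uniroot(f, c(a, b), tol = 1e-10)$root
  }
  # leftmost root left of the maximum (upward crossing nearest -9)
  if (ys[1L] >= criterion) {
    xl <- xs[1L]
  } else {
    i <- which(ys[seq_len(imax - 1L)] < criterion &
               ys[seq_len(imax - 1L) + 1L] >= criterion)[1L]
    xl <- refine(xs[i], xs[i + 1L])
  }
  # rightmost root right of the maximum (downward crossing nearest +9)
  n <- length(xs)
  if (ys[n] >= criterion) {
    xr <- xs[n]
  } else {
    cand <- which(ys[imax:(n - 1L)] >= criterion &
                  ys[(imax + 1L):n] < criterion)
    i <- imax - 1L + cand[length(cand)]
    xr <- refine(xs[i], xs[i + 1L])
  }
  c(xl, xr)
}

#' Span size of a fitted profile at an accuracy criterion
#'
#' The span is the width of the fitted curve at the criterion accuracy
#' (default 80%): the distance between the outermost points, left and right
#' of the curve maximum, at which the fitted accuracy equals the criterion.
#' Left and right extents are measured from the central fixation position 0
#' (clamped at 0 when both crossings fall on the same side), and their
#' difference gives the rightward asymmetry. When the fitted curve never
#' reaches the criterion anywhere on [-9, 9] a span of zero is recorded and
#' the asymmetry is undefined (`NA`).
#'
#' @param fit A `vs_fit` object.
#' @param criterion Accuracy criterion in percent, in (0, 100).
#'
#' @return A `vs_span` object: `span_chars`, `left_extent`, `right_extent`,
#'   `asymmetry`, `criterion`, and the crossing positions `x_left`,
#'   `x_right` (`NA` for a zero span).
#' @examples
#' f <- profile_fit("single", c(A = 100, mu = 0, sigma = 3))
#' compute_span(f)  # 2 * 3 * sqrt(2 * log(100 / 80)) = 4.01 positions
#' @export
compute_span <- function(fit, criterion = 80) {
  stopifnot(inherits(fit, "vs_fit"))
  if (!is.numeric(criterion) || length(criterion) != 1L ||
      criterion <= 0 || criterion >= 100) {
    stop("`criterion` must be a single percentage in (0, 100)", call. = FALSE)
  }
  cr <- criterion_crossings(fit, criterion)
  if (is.null(cr)) {
    est <- list(span_chars = 0, left_extent = 0, right_extent = 0,
                asymmetry = NA_real_, criterion = criterion,
                x_left = NA_real_, x_right = NA_real_, model = fit$model)
  } else {
    left_extent <- max(0, -cr[1L])
    right_extent <- max(0, cr[2L])
    est <- list(span_chars = cr[2L] - cr[1L],
                left_extent = left_extent,
                right_extent = right_extent,
                asymmetry = right_extent - left_extent,
                criterion = criterion,
                x_left = cr[1L], x_right = cr[2L], model = fit$model)
  }
  structure(est, class = "vs_span")
}

#' @export
print.vs_span <- function(x, ...) {
  cat("Visual span at ", x$criterion, "% criterion: ",
      formatC(x$span_chars, format = "f", digits = 1), " characters\n",
      sep = "")
  if (x$span_chars > 0) {
    cat("  left extent ", round(x$left_extent, 2), ", right extent ",
        round(x$right_extent, 2), " (asymmetry ",
        sprintf("%+.2f", x$asymmetry), ")\n", sep = "")
  } else {
    cat("  criterion not reached at any position\n")
  }
  invisible(x)
}

#' Rightward asymmetry of a span estimate
#'
#' Right extent minus left extent, both measured from the central fixation
#' position; positive values mean the span reaches further rightward. For a
#' zero span the asymmetry is undefined and `NA` is returned with a
#' `"flagged"` attribute so such cases can be excluded from group summaries.
#'
#' @param estimate A `vs_span` object.
#' @return Asymmetry in character positions (possibly `NA`).
#' @export
span_asymmetry <- function(estimate) {
  stopifnot(inherits(estimate, "vs_span"))
  if (estimate$span_chars <= 0) {
    return(structure(NA_real_, flagged = "zero span"))
  }
  estimate$right_extent - estimate$left_extent
}

#' Information transmitted by recognition at one character position
#'
#' Mutual information (bits) between stimulus and response for a
#' recognition channel that reports the correct character with probability
#' `p` and otherwise confuses it uniformly with the other `set_size - 1`
#' characters: `I(p) = log2(N) + p log2 p + (1 - p) log2((1 - p)/(N - 1))`.
#' `p` is clamped to `[1/set_size, 1]` before evaluation, so chance-level
#' accuracy transmits 0 bits and perfect accuracy `log2(set_size)` bits
#' (4.7 bits for a 26-character set).
#'
#' @param p Proportion(s) correct in `[0, 1]`.
#' @param set_size Number of characters in the stimulus set (>= 2).
#' @return Bits transmitted, vectorised over `p`.
#' @export
info_transmitted <- function(p, set_size = 26) {
  if (!is.numeric(set_size) || length(set_size) != 1L || set_size < 2) {
    stop("`set_size` must be a single count >= 2", call. = FALSE)
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  n <- set_size
  p <- pmin(pmax(p, 1 / n), 1)
  miss <- ifelse(p == 1, 0, (1 - p) * log2((1 - p) / (n - 1)))
  log2(n) + p * log2(p) + miss
}

#' Span size in bits of information
#'
#' Sums the information transmitted at each scored position of a profile,
#' using the raw (not fitted) accuracies. A profile at ceiling everywhere
#' yields `15 * log2(set_size)` (about 70.5 bits for a 26-character set);
#' a profile at chance yields 0 bits.
#'
#' @param profile Data frame with columns `position` and `accuracy_pct`
#'   covering every scored position exactly once.
#' @param set_size Number of characters in the stimulus set.
#' @return Total bits transmitted across positions.
#' @export
span_bits <- function(profile, set_size = 26) {
  if (anyDuplicated(profile$position)) {
    stop("profile has duplicated positions", call. = FALSE)
  }
  if (anyNA(profile$accuracy_pct)) {
    stop("profile has missing accuracies", call. = FALSE)
  }
  sum(info_transmitted(profile$accuracy_pct / 100, set_size))
}

#' Estimate spans for every profile in a profile table
#'
#' For each participant x complexity profile: fits the single and dual
#' Gaussian models, selects between them ([select_best_fit()]), extracts
#' the span at the criterion ([compute_span()]), and computes the span in
#' bits from the raw accuracies ([span_bits()]).
#'
#' @param profiles Profile table as produced by [build_profiles()].
#' @param criterion Accuracy criterion in percent.
#' @param delta_r2 Model-selection threshold passed to [select_best_fit()].
#' @param set_size Stimulus set size for the bits measure.
#'
#' @return A data frame with one row per participant x complexity:
#'   `participant_id`, `age_group`, `complexity`, `model`, `r_squared`,
#'   `span_chars`, `left_extent`, `right_extent`, `asymmetry`, `span_bits`,
#'   `criterion`. Values are full precision; rounding to one decimal place
#'   happens only when a span table is written to file.
#' @export
estimate_spans <- function(profiles, criterion = 80, delta_r2 = 0.01,
                           set_size = 26) {
  combos <- unique(profiles[c("participant_id", "complexity")])
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    prof <- profiles[profiles$participant_id == combos$participant_id[i] &
                     profiles$complexity == combos$complexity[i], ,
                     drop = FALSE]
    prof <- prof[order(prof$position), , drop = FALSE]
    fs <- fit_gaussian(prof, "single")
    fd <- fit_gaussian(prof, "double")
    sel <- select_best_fit(fs, fd, delta_r2 = delta_r2,
                           criterion = criterion)
    sp <- compute_span(sel, criterion = criterion)
    rows[[i]] <- data.frame(
      participant_id = combos$participant_id[i],
      age_group = prof$age_group[1L],
      complexity = combos$complexity[i],
      model = sel$model,
      r_squared = sel$r_squared,
      span_chars = sp$span_chars,
      left_extent = sp$left_extent,
      right_extent = sp$right_extent,
      asymmetry = sp$asymmetry,
      span_bits = span_bits(prof, set_size),
      criterion = criterion,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
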