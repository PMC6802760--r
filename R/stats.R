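# Reshape a long span table into a subjects x levels matrix plus group
# vector, enforcing the complete balanced split-plot layout.
spantable_matrix <- function(data, dv, participant, between, within,
                             within_levels = NULL) {
  for (col in c(dv, participant, between, within)) {
    if (!col %in% names(data)) {
      stop("span table is missing column `", col, "`", call. = FALSE)
    }
  }
  lev <- within_levels %||% unique(as.character(data[[within]]))
  pid <- factor(data[[participant]])
  wf <- factor(as.character(data[[within]]), levels = lev)
  if (anyNA(wf)) stop("unknown within-factor level in span table", call. = FALSE)
  k <- nlevels(wf)
  n_s <- nlevels(pid)
  counts <- table(pid, wf)
  if (any(counts != 1L)) {
    bad <- which(counts != 1L, arr.ind = TRUE)[1L, ]
    stop("incomplete design: participant ", levels(pid)[bad[1L]],
         " has ", counts[bad[1L], bad[2L]], " values at level ",
         lev[bad[2L]], " (expected exactly 1)", call. = FALSE)
  }
  y <- matrix(NA_real_, n_s, k, dimnames = list(levels(pid), lev))
  y[cbind(as.integer(pid), as.integer(wf))] <- data[[dv]]
  grp_of <- tapply(as.character(data[[between]]), pid, function(g) {
    u <- unique(g)
    if (length(u) != 1L) stop("participant assigned to multiple groups",
                              call. = FALSE)
    u
  })
  grp <- factor(unname(unlist(grp_of)))
  n_g <- table(grp)
  if (any(n_g < 2L)) {
    stop("degenerate design: fewer than 2 participants in group ",
         names(n_g)[which(n_g < 2L)[1L]], call. = FALSE)
  }
  if (length(unique(n_g)) != 1L) {
    stop("unbalanced design: group sizes ",
         paste(n_g, collapse = ", "), " differ", call. = FALSE)
  }
  list(y = y, grp = grp, k = k, n = unname(n_g[1L]), a = nlevels(grp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# repeated measures, via an orthonormal contrast basis.
gg_epsilon <- function(y, grp) {
  k <- ncol(y)
  covs <- lapply(split.data.frame(y, grp), stats::cov)
  ns <- table(grp)
  S <- Reduce(`+`, Map(function(s, n) (n - 1) * s, covs, as.list(ns))) /
    (nrow(y) - length(ns))
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  M <- t(C) %*% S %*% C
  eps <- sum(diag(M))^2 / ((k - 1) * sum(M^2))
  min(1, max(1 / (k - 1), eps))
}

#' Mixed-design (split-plot) ANOVA on a span table
#'
#' Two-way ANOVA with one between-subjects factor (age group) and one
#' within-subjects factor (pattern complexity) on a complete balanced span
#' table: the between effect is tested against the subjects-within-groups
#' mean square, the within effect and interaction against the
#' subject-by-within residual. Partial eta-squared is reported per effect,
#' and the Greenhouse-Geisser epsilon (estimated from the pooled
#' within-group covariance of the repeated measures) can be applied to the
#' within-effect degrees of freedom to guard against sphericity violations.
#'
#' @param data Long data frame with one row per participant x within-level.
#' @param dv Name of the response column (e.g. `"span_chars"`).
#' @param participant,between,within Names of the identifier, group and
#'   repeated-measures columns.
#' @param within_levels Optional explicit ordering of the within levels.
#' @param gg_correct If `TRUE`, within-effect degrees of freedom are
#'   multiplied by the Greenhouse-Geisser epsilon and p-values recomputed
#'   on the corrected df.
#'
#' @return A `vs_anova` object: a data frame with one row per effect
#'   (between, within, interaction) and columns `effect`, `df_num`,
#'   `df_den`, `F`, `p`, `partial_eta_sq`, `gg_epsilon` (`NA` for the
#'   between effect). Sum-of-squares components are attached as attributes.
#' @export
mixed_anova <- function(data, dv = "span_chars",
                        participant = "participant_id",
                        between = "age_group", within = "complexity",
                        within_levels = NULL, gg_correct = FALSE) {
  m <- spantable_matrix(data, dv, participant, between, within, within_levels)
  y <- m$y; grp <- m$grp; k <- m$k; n <- m$n; a <- m$a
  grand <- mean(y)
  m_subj <- rowMeans(y)
  m_grp <- tapply(m_subj, grp, mean)
  m_lev <- colMeans(y)
  m_cell <- apply(y, 2, function(col) tapply(col, grp, mean))  # a x k

  ss_total <- sum((y - grand)^2)
  ss_bs <- k * sum((m_subj - grand)^2)
  ss_a <- n * k * sum((m_grp - grand)^2)
  ss_subj <- ss_bs - ss_a
  ss_b <- a * n * sum((m_lev - grand)^2)
  inter <- sweep(sweep(m_cell, 1, m_grp, "-"), 2, m_lev, "-") + grand
  ss_ab <- n * sum(inter^2)
  ss_err <- ss_total - ss_bs - ss_b - ss_ab

  df_a <- a - 1; df_subj <- a * (n - 1)
  df_b <- k - 1; df_ab <- (a - 1) * (k - 1); df_err <- a * (n - 1) * (k - 1)

  eps <- gg_epsilon(y, grp)
  f_a <- (ss_a / df_a) / (ss_subj / df_subj)
  f_b <- (ss_b / df_b) / (ss_err / df_err)
  f_ab <- (ss_ab / df_ab) / (ss_err / df_err)

  mult <- if (gg_correct) eps else 1
  tab <- data.frame(
    effect = c(between, within, paste0(between, ":", within)),
    df_num = c(df_a, df_b * mult, df_ab * mult),
    df_den = c(df_subj, df_err * mult, df_err * mult),
    F = c(f_a, f_b, f_ab),
    p = c(stats::pf(f_a, df_a, df_subj, lower.tail = FALSE),
          stats::pf(f_b, df_b * mult, df_err * mult, lower.tail = FALSE),
          stats::pf(f_ab, df_ab * mult, df_err * mult, lower.tail = FALSE)),
    partial_eta_sq = c(ss_a / (ss_a + ss_subj),
                       ss_b / (ss_b + ss_err),
                       ss_ab / (ss_ab + ss_err)),
    gg_epsilon = c(NA_real_, eps, eps),
    stringsAsFactors = FALSE)
  structure(tab, class = c("vs_anova", "data.frame"),
            ss = c(between = ss_a, subjects = ss_subj, within = ss_b,
                   interaction = ss_ab, error = ss_err, total = ss_total),
            gg_correct = gg_correct, dv = dv)
}

#' @export
print.vs_anova <- function(x, ...) {
  cat("Mixed-design ANOVA on `", attr(x, "dv"), "`",
      if (isTRUE(attr(x, "gg_correct"))) " (Greenhouse-Geisser corrected)",
      "\n", sep = "")
  df <- as.data.frame(x)
  df$df_num <- round(df$df_num, 2)
  df$df_den <- round(df$df_den, 2)
  df$F <- round(df$F, 2)
  df$p <- signif(df$p, 3)
  df$partial_eta_sq <- round(df$partial_eta_sq, 3)
  df$gg_epsilon <- round(df$gg_epsilon, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Age-group contrasts at each complexity level
#'
#' Independent-samples Welch-free (pooled-variance) t-tests comparing the
#' two age groups at each within-factor level, with pooled-SD Cohen's d and
#' Bonferroni adjustment over the set of levels. The contrast is oriented
#' `young - older` when those labels are present, otherwise second group
#' minus first in factor order.
#'
#' @inheritParams mixed_anova
#' @return A data frame with one row per complexity level: `complexity`,
#'   `contrast`, `t`, `df`, `p`, `p_adj`, `cohens_d`, `flag` (`NA` or a
#'   note, e.g. when the pooled variance is zero and d is undefined).
#' @export
pairwise_age_by_complexity <- function(data, dv = "span_chars",
                                       participant = "participant_id",
                                       between = "age_group",
                                       within = "complexity",
                                       within_levels = NULL) {
  m <- spantable_matrix(data, dv, participant, between, within, within_levels)
  groups <- levels(m$grp)
  if (all(c("young", "older") %in% groups)) {
    g1 <- "young"; g2 <- "older"
  } else {
    g1 <- groups[2L]; g2 <- groups[1L]
  }
  lev <- colnames(m$y)
  rows <- vector("list", length(lev))
  for (j in seq_along(lev)) {
    y1 <- m$y[m$grp == g1, j]
    y2 <- m$y[m$grp == g2, j]
    n1 <- length(y1); n2 <- length(y2)
    sp2 <- ((n1 - 1) * stats::var(y1) + (n2 - 1) * stats::var(y2)) /
      (n1 + n2 - 2)
    if (sp2 > 0) {
      tt <- stats::t.test(y1, y2, var.equal = TRUE)
      rows[[j]] <- data.frame(
        complexity = lev[j],
        contrast = paste(g1, "-", g2),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, p_adj = NA_real_,
        cohens_d = (mean(y1) - mean(y2)) / sqrt(sp2),
        flag = NA_character_, stringsAsFactors = FALSE)
    } else {
      rows[[j]] <- data.frame(
        complexity = lev[j], contrast = paste(g1, "-", g2),
        t = if (mean(y1) == mean(y2)) 0 else NA_real_,
        df = n1 + n2 - 2,
        p = if (mean(y1) == mean(y2)) 1 else NA_real_,
        p_adj = NA_real_, cohens_d = NA_real_,
        flag = "zero pooled variance", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, length(lev) * out$p)
  rownames(out) <- NULL
  out
}

#' Pearson correlation with two-tailed p-value
#'
#' Product-moment correlation between two paired vectors, with the p-value
#' from the usual t transform (as in [stats::cor.test()], which performs
#' the computation).
#'
#' @param x,y Numeric vectors of equal length (n >= 3), each with non-zero
#'   variance.
#' @return A list of class `vs_cor`: `r`, `p`, `n`, `df`, `t`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length",
                                   call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 n = length(x), df = unname(ct$parameter),
                 t = unname(ct$statistic)),
            class = "vs_cor")
}

#' @export
print.vs_cor <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, t(%d) = %.2f, p = %.4g)\n",
              x$r, x$n, x$df, x$t, x$p))
  invisible(x)
}
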