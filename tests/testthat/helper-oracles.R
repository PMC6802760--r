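# Independent oracles used to check the package's numerical routines.
# They deliberately avoid the code paths they verify.

# Coarse grid search for the best single-Gaussian r^2 on a profile.
grid_fit_r2 <- function(profile) {
  x <- profile$position
  y <- profile$accuracy_pct
  sst <- sum((y - mean(y))^2)
  best <- -Inf
  for (A in seq(5, 110, by = 5)) {
    for (mu in -7:7) {
      for (sigma in seq(0.5, 10, by = 0.5)) {
        ssr <- sum((y - A * exp(-(x - mu)^2 / (2 * sigma^2)))^2)
        r2 <- 1 - ssr / sst
        if (r2 > best) best <- r2
      }
    }
  }
  best
}

# Dense threshold-scan span oracle: outermost grid points at or above the
# criterion, at 0.001-position resolution.
grid_span <- function(par, criterion = 80, step = 0.001) {
  xs <- seq(-9, 9, by = step)
  ys <- par[[1L]] * exp(-(xs - par[[2L]])^2 / (2 * par[[3L]]^2))
  if (length(par) == 6L) {
    ys <- ys + par[[4L]] * exp(-(xs - par[[5L]])^2 / (2 * par[[6L]]^2))
  }
  above <- which(ys >= criterion)
  if (!length(above)) return(0)
  xs[above[length(above)]] - xs[above[1L]]
}

# Direct evaluation of the Gaussian curve formulas for building test data.
gaussian_curve_for_test <- function(x, par) {
  y <- par[[1L]] * exp(-(x - par[[2L]])^2 / (2 * par[[3L]]^2))
  if (length(par) == 6L) {
    y <- y + par[[4L]] * exp(-(x - par[[5L]])^2 / (2 * par[[6L]]^2))
  }
  y
}

# Mutual information of the uniform-confusion recognition channel,
# computed from the explicit N x N stimulus-response joint distribution.
mi_confusion <- function(p, n = 26) {
  joint <- matrix((1 - p) / (n * (n - 1)), n, n)
  diag(joint) <- p / n
  ps <- rowSums(joint)
  pr <- colSums(joint)
  cells <- joint * log2(joint / outer(ps, pr))
  sum(cells[joint > 0])
}

# A deterministic full session in which every response is correct:
# all (complexity x block x center x rep) combinations, stimuli fixed.
all_correct_trials <- function(design, participant_id = "p1",
                               age_group = "young") {
  g <- expand.grid(rep = seq_len(design$reps_per_center_per_block),
                   center = design$centers,
                   block = seq_len(design$blocks_per_level),
                   complexity = design$complexity_levels,
                   stringsAsFactors = FALSE)
  data.frame(participant_id = participant_id, age_group = age_group,
             complexity = g$complexity, block = g$block, center = g$center,
             stim1 = 1L, stim2 = 2L, stim3 = 3L,
             correct1 = 1L, correct2 = 1L, correct3 = 1L,
             stringsAsFactors = FALSE)
}

# Profile data frame from a function of position.
make_profile <- function(f, positions = -7:7) {
  data.frame(position = positions, accuracy_pct = f(positions))
}

# Long span table with known values for ANOVA tests.
make_span_table <- function(n_per_group = 4, seed = 1,
                            means = c(low = 7, medium = 6.5, high = 4),
                            age_effect = c(young = 0.5, older = -0.5),
                            sd = 1) {
  set.seed(seed)
  rows <- list()
  for (g in names(age_effect)) {
    for (i in seq_len(n_per_group)) {
      for (lv in names(means)) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = paste0(g, i), age_group = g, complexity = lv,
          span_chars = stats::rnorm(1, means[[lv]] + age_effect[[g]], sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
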