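test_that("mixed ANOVA agrees with the aov Error-strata reference", {
  tab <- make_span_table(n_per_group = 5, seed = 11)
  res <- mixed_anova(tab, within_levels = c("low", "medium", "high"))

  ref_dat <- data.frame(y = tab$span_chars,
                        g = factor(tab$age_group),
                        w = factor(tab$complexity,
                                   c("low", "medium", "high")),
                        s = factor(tab$participant_id))
  ref <- summary(stats::aov(y ~ g * w + Error(s), data = ref_dat))
  between <- ref[["Error: s"]][[1]]
  within <- ref[["Error: Within"]][[1]]

  expect_equal(res$F[1], between["g", "F value"], tolerance = 1e-6)
  expect_equal(res$p[1], between["g", "Pr(>F)"], tolerance = 1e-6)
  expect_equal(res$F[2], within["w", "F value"], tolerance = 1e-6)
  expect_equal(res$p[2], within["w", "Pr(>F)"], tolerance = 1e-6)
  expect_equal(res$F[3], within["g:w", "F value"], tolerance = 1e-6)
  expect_equal(res$p[3], within["g:w", "Pr(>F)"], tolerance = 1e-6)
  expect_equal(res$df_num, c(1, 2, 2))
  expect_equal(res$df_den, c(8, 16, 16))
  # partial eta^2 identity with F and df
  expect_equal(res$partial_eta_sq,
               res$F * res$df_num / (res$F * res$df_num + res$df_den),
               tolerance = 1e-10)
})

test_that("Greenhouse-Geisser epsilon matches the car reference", {
  tab <- make_span_table(n_per_group = 6, seed = 12)
  res <- mixed_anova(tab, within_levels = c("low", "medium", "high"),
                     gg_correct = TRUE)
  wide <- reshape(tab, idvar = c("participant_id", "age_group"),
                  timevar = "complexity", direction = "wide")
  mod <- stats::lm(cbind(span_chars.low, span_chars.medium,
                         span_chars.high) ~ age_group, data = wide)
  av <- car::Anova(mod, idata = data.frame(lvl = factor(1:3)),
                   idesign = ~lvl, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  eps_ref <- s$pval.adjustments[, "GG eps"]
  expect_equal(unname(res$gg_epsilon[2]), unname(eps_ref["lvl"]),
               tolerance = 1e-6)
  # corrected p equals F on epsilon-scaled df
  expect_equal(res$p[2],
               pf(res$F[2], res$df_num[2], res$df_den[2],
                  lower.tail = FALSE), tolerance = 1e-12)
})

test_that("epsilon is bounded and the sums of squares partition exactly", {
  set.seed(31)
  for (i in 1:10) {
    tab <- make_span_table(n_per_group = sample(3:8, 1), seed = i,
                           sd = runif(1, 0.5, 3))
    res <- mixed_anova(tab, within_levels = c("low", "medium", "high"))
    eps <- res$gg_epsilon[2]
    expect_gte(eps, 0.5)
    expect_lte(eps, 1)
    ss <- attr(res, "ss")
    expect_equal(ss[["total"]],
                 ss[["between"]] + ss[["subjects"]] + ss[["within"]] +
                   ss[["interaction"]] + ss[["error"]], tolerance = 1e-8)
  }
})

test_that("ANOVA is invariant to relabeling and detects a null age effect", {
  tab <- make_span_table(n_per_group = 4, seed = 13)
  res <- mixed_anova(tab, within_levels = c("low", "medium", "high"))
  relab <- tab
  relab$participant_id <- paste0("zz_", relab$participant_id)
  res2 <- mixed_anova(relab, within_levels = c("low", "medium", "high"))
  expect_equal(res$F, res2$F, tolerance = 1e-12)
  # reordering within-factor levels leaves every F unchanged
  res3 <- mixed_anova(tab, within_levels = c("high", "low", "medium"))
  expect_equal(res$F, res3$F, tolerance = 1e-10)

  # two groups with literally identical data: no between-group variance
  one <- tab[tab$age_group == "young", ]
  clone <- one
  clone$age_group <- "older"
  clone$participant_id <- paste0("c_", clone$participant_id)
  res4 <- mixed_anova(rbind(one, clone),
                      within_levels = c("low", "medium", "high"))
  expect_equal(res4$F[1], 0, tolerance = 1e-12)
})

test_that("degenerate ANOVA inputs raise informative errors", {
  tab <- make_span_table(n_per_group = 4, seed = 14)
  expect_error(mixed_anova(tab[-1, ]), "incomplete design")
  tiny <- tab[tab$participant_id %in% c("young1", "older1"), ]
  expect_error(mixed_anova(tiny), "degenerate")
  lop <- tab[tab$participant_id != "young1", ]
  expect_error(mixed_anova(lop), "unbalanced")
})

test_that("pairwise age contrasts match hand-worked values", {
  # one-level table: young {3, 5} vs older {1, 2}
  tab <- data.frame(
    participant_id = c("y1", "y2", "o1", "o2"),
    age_group = c("young", "young", "older", "older"),
    complexity = "high",
    span_chars = c(3, 5, 1, 2), stringsAsFactors = FALSE)
  pw <- pairwise_age_by_complexity(tab, within_levels = "high")
  # pooled var = (0.5 * 1 + 0.5 * 2) / 2 ... = (2 + 0.5)/2 = 1.25
  sp <- sqrt((stats::var(c(3, 5)) + stats::var(c(1, 2))) / 2)
  expect_equal(pw$t, 2.5 / (sp * sqrt(1)), tolerance = 1e-12)
  expect_equal(pw$cohens_d, 2.5 / sp, tolerance = 1e-12)
  expect_equal(pw$df, 2)
  expect_identical(pw$contrast, "young - older")
})

test_that("identical groups give t = 0 and Bonferroni stays capped", {
  tab <- make_span_table(n_per_group = 4, seed = 15, age_effect =
                           c(young = 0, older = 0), sd = 1)
  wide_y <- tab[tab$age_group == "young", ]
  mirrored <- wide_y
  mirrored$age_group <- "older"
  mirrored$participant_id <- paste0("m_", mirrored$participant_id)
  pw <- pairwise_age_by_complexity(rbind(wide_y, mirrored),
                                   within_levels = c("low", "medium",
                                                     "high"))
  expect_equal(pw$t, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(pw$cohens_d, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(pw$p_adj, pmin(1, 3 * pw$p))
  expect_true(all(pw$p_adj <= 1))
})

test_that("zero pooled variance flags an undefined effect size", {
  tab <- data.frame(
    participant_id = c("y1", "y2", "o1", "o2"),
    age_group = c("young", "young", "older", "older"),
    complexity = "low",
    span_chars = c(4, 4, 2, 2), stringsAsFactors = FALSE)
  pw <- pairwise_age_by_complexity(tab, within_levels = "low")
  expect_true(is.na(pw$cohens_d))
  expect_identical(pw$flag, "zero pooled variance")
})

test_that("group contrast magnitude is as expected under reference moments", {
  # two n = 21 groups at the high-complexity cell means with SD ~ 1.83
  # (SE 0.4): |t| concentrates near 4.4
  set.seed(77)
  ts <- replicate(300, {
    y <- rnorm(21, 5.5, 1.83)
    o <- rnorm(21, 3.1, 1.83)
    tab <- data.frame(
      participant_id = c(paste0("y", 1:21), paste0("o", 1:21)),
      age_group = rep(c("young", "older"), each = 21),
      complexity = "high", span_chars = c(y, o),
      stringsAsFactors = FALSE)
    pairwise_age_by_complexity(tab, within_levels = "high")$t
  })
  expect_equal(mean(abs(ts)), 4.4, tolerance = 0.1)
})

test_that("pearson_r matches hand-computed correlations", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x + 10)$r, -1, tolerance = 1e-12)
  y <- c(2, 1, 4, 3, 6)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_r(x, y)
  expect_equal(res$r, hand, tolerance = 1e-12)
  expect_equal(res$n, 5)
  # p from the t transform
  tt <- hand * sqrt(3 / (1 - hand^2))
  expect_equal(res$p, 2 * pt(abs(tt), 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(pearson_r(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})
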