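test_that("the generator is reproducible from its seed", {
  cfg <- generator_config(seed = 5, n_per_group = 2)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$reading, b$reading)
  expect_identical(a$participants, b$participants)
  # a different seed changes the data
  c2 <- simulate_cohort(generator_config(seed = 6, n_per_group = 2))
  expect_false(identical(a$trials$correct1, c2$trials$correct1))
})

test_that("zero between-participant spread collapses onto the cell means", {
  cfg <- generator_config(seed = 5, n_per_group = 3, between = list(
    sigma_cv = c(low = 0, medium = 0, high = 0),
    peak_logit_sd = c(low = 0, medium = 0, high = 0), shift_sd = 0))
  prt <- sample_participants(cfg)
  m <- merge(prt, cfg$cells, by = c("age_group", "complexity"),
             suffixes = c("", ".cell"))
  expect_equal(m$peak, m$peak.cell, tolerance = 1e-12)
  expect_equal(m$sigma_left, m$sigma_left.cell, tolerance = 1e-12)
  expect_equal(m$peak_shift, m$peak_shift.cell, tolerance = 1e-12)
})

test_that("latent accuracy has the stated shape", {
  prm <- list(peak = 0.95, sigma_left = 3, sigma_right = 4,
              peak_shift = 0.5, middle_penalty = 0.8)
  chance <- 1 / 26
  expect_equal(latent_accuracy(prm, 0.5, "first"), 0.95)
  expect_lt(latent_accuracy(prm, 9, "first"), 0.95)
  expect_equal(latent_accuracy(prm, 200, "first"), chance, tolerance = 1e-9)
  # middle penalty scales the above-chance component
  f0 <- latent_accuracy(prm, 0, "first")
  m0 <- latent_accuracy(prm, 0, "middle")
  expect_equal((m0 - chance) / (f0 - chance), 0.8, tolerance = 1e-12)
  # asymmetric spread: accuracy falls slower to the right of the peak
  expect_gt(latent_accuracy(prm, 0.5 + 3, "first"),
            latent_accuracy(prm, 0.5 - 3, "first"))
})

test_that("closed-form true span matches a numeric scan of the latent curve", {
  chance <- 1 / 26
  cells <- generator_config()$cells
  for (i in seq_len(nrow(cells))) {
    prm <- as.list(cells[i, ])
    xs <- seq(-12, 12, by = 1e-4)
    acc <- (latent_accuracy(prm, xs, "first") +
            latent_accuracy(prm, xs, "middle") +
            latent_accuracy(prm, xs, "last")) / 3
    above <- xs[acc >= 0.8]
    ts <- true_span(prm$peak, prm$sigma_left, prm$sigma_right,
                    prm$peak_shift, prm$middle_penalty)
    expect_equal(ts$span_chars, max(above) - min(above), tolerance = 1e-3)
  }
})

test_that("default cohorts realize the calibrated group-mean spans", {
  # average over three cohorts per target to tame sampling error
  targets <- data.frame(
    age_group = rep(c("older", "young"), each = 3),
    complexity = rep(c("low", "medium", "high"), 2),
    span = c(7.1, 6.4, 3.1, 7.2, 6.5, 5.5), stringsAsFactors = FALSE)
  prt <- do.call(rbind, lapply(1:3, function(s) {
    sample_participants(generator_config(seed = s))
  }))
  got <- aggregate(true_span_chars ~ age_group + complexity, prt, mean)
  m <- merge(got, targets)
  expect_true(all(abs(m$true_span_chars - m$span) <= 0.5))
})

test_that("sessions follow the design and pass validation", {
  design <- default_design()
  cfg <- generator_config(seed = 10, n_per_group = 1)
  prt <- sample_participants(cfg)
  one <- prt[prt$participant_id == "older_01", ]
  ses <- simulate_session(one, design, seed = 99)
  expect_equal(nrow(ses), 459)
  expect_silent(visualspan:::validate_trials(ses, design))
  # balanced: every center appears 27 times per complexity
  expect_true(all(table(ses$complexity, ses$center) == 9))
  # same participant and seed: byte-identical trial list
  expect_identical(simulate_session(one, design, seed = 99), ses)
  # responses equal the stimulus iff correct
  expect_true(all((ses$resp1 == ses$stim1) == (ses$correct1 == 1)))
  expect_true(all((ses$resp2 == ses$stim2) == (ses$correct2 == 1)))
})

test_that("empirical accuracies track the latent curve", {
  design <- default_design()
  cfg <- generator_config(seed = 30, n_per_group = 1, between = list(
    sigma_cv = c(low = 0, medium = 0, high = 0),
    peak_logit_sd = c(low = 0, medium = 0, high = 0), shift_sd = 0))
  prt <- sample_participants(cfg)
  one <- prt[prt$participant_id == "young_01", ]
  trials <- do.call(rbind, lapply(1:20, function(s) {
    ses <- simulate_session(one, design, seed = 1000 + s)
    ses$participant_id <- paste0("r", s)
    ses
  }))
  prof <- build_profiles(trials, design)
  hi <- prof[prof$complexity == "high", ]
  agg <- aggregate(accuracy_pct ~ position, hi, mean)
  prm <- as.list(one[one$complexity == "high", ])
  expected <- vapply(agg$position, function(x) {
    100 * mean(c(latent_accuracy(prm, x, "first"),
                 latent_accuracy(prm, x, "middle"),
                 latent_accuracy(prm, x, "last")))
  }, numeric(1))
  # 20 sessions x 27 obs: binomial SE < 1%; allow 4 SE
  se <- 100 * sqrt(expected / 100 * (1 - expected / 100) / (27 * 20))
  expect_true(all(abs(agg$accuracy_pct - expected) < pmax(4 * se, 2)))
})

test_that("a harsher middle penalty lowers middle-role accuracy", {
  design <- default_design()
  acc_mid <- function(mp, seed) {
    cells <- visualspan:::default_cells()
    cells$middle_penalty <- mp
    cfg <- generator_config(seed = seed, n_per_group = 2, cells = cells)
    co <- simulate_cohort(cfg)
    cra <- center_role_accuracy(co$trials, design)
    mean(cra$accuracy_pct[cra$role == "middle"])
  }
  expect_gt(acc_mid(0.95, 40), acc_mid(0.45, 40))
})

test_that("reading records reflect the span-speed model", {
  cfg0 <- generator_config(seed = 3, n_per_group = 4,
                           reading = list(beta1 = 0, noise_sd = 0))
  prt <- sample_participants(cfg0)
  ids <- unique(prt$participant_id)
  speeds <- vapply(ids, function(id) {
    rec <- simulate_reading(prt[prt$participant_id == id, ], cfg0,
                            seed = 77)
    compute_reading_speed(rec)$cpm
  }, numeric(1))
  expect_true(all(abs(speeds - 250) < 1e-9))
  # positive slope, no noise: speed ranks follow true span ranks
  cfg1 <- generator_config(seed = 3, n_per_group = 4,
                           reading = list(noise_sd = 0))
  mean_span <- tapply(prt$true_span_chars, prt$participant_id, mean)
  speeds1 <- vapply(ids, function(id) {
    rec <- simulate_reading(prt[prt$participant_id == id, ], cfg1,
                            seed = 77)
    compute_reading_speed(rec)$cpm
  }, numeric(1))
  expect_equal(cor(mean_span[ids], speeds1, method = "spearman"), 1)
  # sentence lengths stay in the configured range
  rec <- simulate_reading(prt[prt$participant_id == ids[1], ],
                          generator_config(seed = 3), seed = 5)
  expect_true(all(rec$n_characters >= 17 & rec$n_characters <= 25))
  expect_equal(nrow(rec), 20)
})

test_that("invalid generator configurations name the offending field", {
  expect_error(generator_config(n_per_group = 0), "n_per_group")
  expect_error(generator_config(reading = list(noise_sd = -1)), "noise_sd")
  cells <- visualspan:::default_cells()
  cells$peak[1] <- 1.2
  expect_error(generator_config(cells = cells), "peak")
  cells2 <- visualspan:::default_cells()
  cells2$sigma_left[2] <- -1
  expect_error(generator_config(cells = cells2), "sigma_left")
  expect_error(generator_config(cells = cells2[, -3]), "peak")
})
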