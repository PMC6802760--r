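# Default latent profile parameters per age group x complexity cell.
# Peaks and middle-character penalties reproduce the reference accuracies
# at fixation (first/last vs middle roles); the sigma pairs are solved in
# closed form so that the role-averaged latent profile has the target
# 80%-criterion span and rightward asymmetry for each cell (see the
# methods vignette for the derivation).
default_cells <- function() {
  data.frame(
    age_group = rep(c("older", "young"), each = 3L),
    complexity = rep(c("low", "medium", "high"), 2L),
    peak = c(0.970, 0.970, 0.955, 0.970, 0.970, 0.960),
    sigma_left = c(5.5365, 4.9707, 3.0160, 5.4153, 4.8495, 4.3512),
    sigma_right = c(5.9406, 5.3749, 3.5451, 6.2235, 5.6578, 5.2215),
    peak_shift = c(0, 0, 0, 0, 0, 0),
    middle_penalty = c(0.970, 0.970, 0.7872, 0.970, 0.970, 0.9240),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles every constant the generator uses: cohort size, the latent
#' profile parameters of each age-group x complexity cell, the
#' between-participant spread of those parameters, and the linear model
#' relating reading speed to span. All randomness downstream flows from
#' `seed`.
#'
#' @param seed Integer master seed.
#' @param n_per_group Participants per age group.
#' @param cells Data frame of per-cell latent parameters (columns
#'   `age_group`, `complexity`, `peak`, `sigma_left`, `sigma_right`,
#'   `peak_shift`, `middle_penalty`); defaults to the calibrated values.
#' @param between List of between-participant spreads: `sigma_cv`
#'   (coefficient of variation of a mean-one lognormal factor on both
#'   sigmas, named per complexity), `peak_logit_sd` (SD of a logit-scale
#'   perturbation of the peak, named per complexity), `shift_sd` (SD in
#'   positions of the peak-location jitter).
#' @param reading List with `beta0` (cpm intercept), `beta1` (cpm per span
#'   position), `noise_sd` (cpm), `n_sentences`, `len_range` (inclusive
#'   sentence-length range in characters) and `floor_cpm` (minimum target
#'   speed).
#' @param set_size Stimulus set size per complexity level.
#' @return A `vs_generator_config` object.
#' @export
generator_config <- function(seed = 1L, n_per_group = 21L, cells = NULL,
                             between = NULL, reading = NULL,
                             set_size = 26L) {
  cells <- cells %||% default_cells()
  between_default <- list(
    sigma_cv = c(low = 0.08, medium = 0.08, high = 0.30),
    peak_logit_sd = c(low = 0.30, medium = 0.30, high = 0.50),
    shift_sd = 0.15)
  between <- utils::modifyList(between_default, between %||% list())
  reading_default <- list(beta0 = 250, beta1 = 40, noise_sd = 30,
                          n_sentences = 20L, len_range = c(17L, 25L),
                          floor_cpm = 60)
  reading <- utils::modifyList(reading_default, reading %||% list())

  need <- c("age_group", "complexity", "peak", "sigma_left", "sigma_right",
            "peak_shift", "middle_penalty")
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    stop("invalid config: `cells` is missing field ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  chance <- 1 / set_size
  check <- function(ok, field) {
    if (!all(ok)) stop("invalid config: field `", field, "` out of range",
                       call. = FALSE)
  }
  check(length(seed) == 1L && is.finite(seed) &&
          abs(seed) < .Machine$integer.max, "seed")
  check(length(n_per_group) == 1L && n_per_group >= 1, "n_per_group")
  check(set_size >= 2, "set_size")
  check(cells$peak > chance & cells$peak <= 1, "peak")
  check(cells$sigma_left > 0, "sigma_left")
  check(cells$sigma_right > 0, "sigma_right")
  check(cells$middle_penalty > 0 & cells$middle_penalty <= 1,
        "middle_penalty")
  lev <- unique(cells$complexity)
  check(all(lev %in% names(between$sigma_cv)), "between$sigma_cv")
  check(all(lev %in% names(between$peak_logit_sd)), "between$peak_logit_sd")
  check(between$shift_sd >= 0, "between$shift_sd")
  check(between$sigma_cv >= 0, "between$sigma_cv")
  check(between$peak_logit_sd >= 0, "between$peak_logit_sd")
  check(reading$noise_sd >= 0, "reading$noise_sd")
  check(reading$n_sentences >= 1, "reading$n_sentences")
  check(reading$len_range[1L] >= 1 &&
          reading$len_range[2L] >= reading$len_range[1L],
        "reading$len_range")
  check(reading$floor_cpm > 0, "reading$floor_cpm")

  structure(list(seed = as.integer(seed),
                 n_per_group = as.integer(n_per_group),
                 cells = cells, between = between, reading = reading,
                 set_size = as.integer(set_size)),
            class = "vs_generator_config")
}

#' @export
print.vs_generator_config <- function(x, ...) {
  cat("Synthetic cohort generator (seed ", x$seed, ", ",
      x$n_per_group, " per group, set size ", x$set_size, ")\n", sep = "")
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Latent recognition accuracy at a display position
#'
#' The latent accuracy function is an asymmetric Gaussian on a guessing
#' floor: `chance + (peak - chance) * exp(-(x - shift)^2 / (2 sigma^2))`,
#' with `sigma = sigma_left` left of the peak and `sigma_right` right of
#' it. For the doubly-flanked middle trigram character the above-chance
#' component is multiplied by `middle_penalty`, modelling the stronger
#' crowding of a character with flankers on both sides. Results are clamped
#' to `[chance, 1]`.
#'
#' @param params List-like with fields `peak`, `sigma_left`, `sigma_right`,
#'   `peak_shift`, `middle_penalty` (e.g. one row of
#'   [sample_participants()]).
#' @param x Display position(s), real-valued.
#' @param role Trigram role of the character: `"first"`, `"middle"` or
#'   `"last"` (recycled against `x`).
#' @param set_size Stimulus set size; the guessing floor is `1/set_size`.
#' @return Probability of correct report, vectorised over `x`.
#' @export
latent_accuracy <- function(params, x, role = "first", set_size = 26) {
  chance <- 1 / set_size
  sigma <- ifelse(x < params$peak_shift, params$sigma_left,
                  params$sigma_right)
  base <- chance + (params$peak - chance) *
    exp(-(x - params$peak_shift)^2 / (2 * sigma^2))
  fac <- ifelse(role == "middle", params$middle_penalty, 1)
  pmin(1, pmax(chance, chance + (base - chance) * fac))
}

#' Closed-form span of a latent accuracy profile
#'
#' The generator's ground truth. Observed profiles average the three
#' trigram roles (each scored position receives equal numbers of first,
#' middle and last characters under the balanced design), so the
#' role-averaged above-chance amplitude is `(peak - chance) (2 + delta)/3`
#' with `delta` the middle penalty. Solving the asymmetric Gaussian for
#' the criterion accuracy gives half-widths `sigma_left * w` and
#' `sigma_right * w` with `w = sqrt(2 log(amp / (crit - chance)))`.
#'
#' @param peak,sigma_left,sigma_right,peak_shift,middle_penalty Latent
#'   parameters (vectorised).
#' @param set_size Stimulus set size.
#' @param criterion Accuracy criterion in percent.
#' @return Data frame with `span_chars`, `left_extent`, `right_extent`,
#'   `asymmetry` (extents from position 0, clamped at 0; zero span when the
#'   role-averaged peak does not reach the criterion, with `NA` asymmetry).
#' @export
true_span <- function(peak, sigma_left, sigma_right, peak_shift = 0,
                      middle_penalty = 1, set_size = 26, criterion = 80) {
  chance <- 1 / set_size
  crit <- criterion / 100
  amp <- (peak - chance) * (2 + middle_penalty) / 3
  reached <- (chance + amp) > crit
  w <- rep(NA_real_, length(amp))
  w[reached] <- sqrt(2 * log(amp[reached] / (crit - chance)))
  xl <- peak_shift - sigma_left * w
  xr <- peak_shift + sigma_right * w
  out <- data.frame(
    span_chars = ifelse(reached, xr - xl, 0),
    left_extent = ifelse(reached, pmax(0, -xl), 0),
    right_extent = ifelse(reached, pmax(0, xr), 0),
    asymmetry = NA_real_)
  out$asymmetry <- ifelse(reached, out$right_extent - out$left_extent,
                          NA_real_)
  out
}

#' Draw a cohort of latent participants
#'
#' Participant-level parameters are the cell means perturbed by
#' independent draws per participant x complexity: a mean-one lognormal
#' factor on both sigmas, a logit-scale shift of the peak, and a Gaussian
#' jitter of the peak location. The realized closed-form span
#' ([true_span()]) is attached per row as the recovery target.
#'
#' @param config A `vs_generator_config`.
#' @return Data frame with one row per participant x complexity:
#'   identifiers, realized latent parameters, and `true_span_chars`,
#'   `true_left`, `true_right`.
#' @export
sample_participants <- function(config) {
  stopifnot(inherits(config, "vs_generator_config"))
  set.seed(config$seed)
  groups <- unique(config$cells$age_group)
  lev <- unique(config$cells$complexity)
  bt <- config$between
  rows <- vector("list", length(groups) * config$n_per_group)
  r <- 0L
  for (g in groups) {
    for (i in seq_len(config$n_per_group)) {
      pid <- sprintf("%s_%02d", g, i)
      cell_rows <- vector("list", length(lev))
      for (j in seq_along(lev)) {
        cell <- config$cells[config$cells$age_group == g &
                             config$cells$complexity == lev[j], ]
        cv <- bt$sigma_cv[[lev[j]]]
        sc <- exp(stats::rnorm(1L, -cv^2 / 2, cv))
        pk <- stats::plogis(stats::qlogis(cell$peak) +
                              stats::rnorm(1L, 0, bt$peak_logit_sd[[lev[j]]]))
        sh <- cell$peak_shift + stats::rnorm(1L, 0, bt$shift_sd)
        cell_rows[[j]] <- data.frame(
          participant_id = pid, age_group = g, complexity = lev[j],
          peak = pk, sigma_left = cell$sigma_left * sc,
          sigma_right = cell$sigma_right * sc, peak_shift = sh,
          middle_penalty = cell$middle_penalty, stringsAsFactors = FALSE)
      }
      r <- r + 1L
      rows[[r]] <- do.call(rbind, cell_rows)
    }
  }
  out <- do.call(rbind, rows)
  ts <- true_span(out$peak, out$sigma_left, out$sigma_right, out$peak_shift,
                  out$middle_penalty, set_size = config$set_size)
  out$true_span_chars <- ts$span_chars
  out$true_left <- ts$left_extent
  out$true_right <- ts$right_extent
  rownames(out) <- NULL
  out
}

# Deterministic per-participant sub-seed derived from the master seed.
derive_seed <- function(base, i, stream) {
  as.integer((abs(as.numeric(base)) * 10007 + i * 131 + stream * 7919) %%
               2147483587)
}

#' Simulate one participant's trigram session
#'
#' Generates the full blocked session the design prescribes (459 trials
#' under the default design): for every complexity x block x center x
#' repetition, a trigram of three distinct characters drawn uniformly from
#' the complexity set, each reported correctly with probability
#' [latent_accuracy()] at its display position and role. Incorrect reports
#' draw a response uniformly from the remaining characters (kept for
#' realism; scoring uses the correctness flags). Trial order is randomized
#' within block.
#'
#' @param participant Rows of [sample_participants()] for one participant
#'   (one row per complexity level).
#' @param design A `vs_design`.
#' @param seed Integer seed; the same participant and seed reproduce the
#'   identical trial list.
#' @param set_size Stimulus set size.
#' @return Data frame of trials: `participant_id`, `age_group`,
#'   `complexity`, `block`, `center`, `stim1..3`, `resp1..3`,
#'   `correct1..3`.
#' @export
simulate_session <- function(participant, design, seed, set_size = 26) {
  stopifnot(inherits(design, "vs_design"))
  if (length(unique(participant$participant_id)) != 1L) {
    stop("`participant` must contain rows for a single participant",
         call. = FALSE)
  }
  set.seed(seed)
  lev <- design$complexity_levels
  centers <- design$centers
  nb <- design$blocks_per_level
  nr <- design$reps_per_center_per_block
  per_block <- length(centers) * nr

  chunks <- vector("list", length(lev))
  for (j in seq_along(lev)) {
    prm <- participant[participant$complexity == lev[j], ]
    if (nrow(prm) != 1L) {
      stop("participant lacks parameters for complexity ", lev[j],
           call. = FALSE)
    }
    blocks <- vector("list", nb)
    for (b in seq_len(nb)) {
      ctr <- rep(centers, each = nr)[sample.int(per_block)]
      n <- length(ctr)
      stim <- t(vapply(seq_len(n),
                       function(i) sample.int(set_size, 3L),
                       integer(3L)))
      pos <- cbind(ctr - 1L, ctr, ctr + 1L)
      p <- cbind(latent_accuracy(prm, pos[, 1L], "first", set_size),
                 latent_accuracy(prm, pos[, 2L], "middle", set_size),
                 latent_accuracy(prm, pos[, 3L], "last", set_size))
      correct <- matrix(stats::runif(3L * n) < p, n, 3L)
      # uniform confusion: draw from the other set_size - 1 characters
      resp <- stim
      nw <- sum(!correct)
      if (nw > 0L) {
        raw <- sample.int(set_size - 1L, nw, replace = TRUE)
        resp[!correct] <- raw + (raw >= stim[!correct])
      }
      blocks[[b]] <- data.frame(
        participant_id = prm$participant_id, age_group = prm$age_group,
        complexity = lev[j], block = b, center = ctr,
        stim1 = stim[, 1L], stim2 = stim[, 2L], stim3 = stim[, 3L],
        resp1 = resp[, 1L], resp2 = resp[, 2L], resp3 = resp[, 3L],
        correct1 = as.integer(correct[, 1L]),
        correct2 = as.integer(correct[, 2L]),
        correct3 = as.integer(correct[, 3L]),
        stringsAsFactors = FALSE)
    }
    chunks[[j]] <- do.call(rbind, blocks)
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  out
}

#' Simulate one participant's sentence-reading records
#'
#' The participant's target reading speed is linear in their mean
#' closed-form span across complexity levels
#' (`beta0 + beta1 * mean span + N(0, noise_sd)`, floored at `floor_cpm`).
#' Sentence lengths are uniform over `len_range`; each sentence's reading
#' time is `60 * length / speed` seconds.
#'
#' @inheritParams simulate_session
#' @param config A `vs_generator_config` (its `reading` component is used).
#' @return Data frame with columns `participant_id`, `sentence_id`,
#'   `n_characters`, `reading_time_s`.
#' @export
simulate_reading <- function(participant, config, seed) {
  stopifnot(inherits(config, "vs_generator_config"))
  set.seed(seed)
  rd <- config$reading
  speed <- max(rd$floor_cpm,
               rd$beta0 + rd$beta1 * mean(participant$true_span_chars) +
                 stats::rnorm(1L, 0, rd$noise_sd))
  len <- sample(seq.int(rd$len_range[1L], rd$len_range[2L]),
                rd$n_sentences, replace = TRUE)
  data.frame(participant_id = participant$participant_id[1L],
             sentence_id = seq_len(rd$n_sentences),
             n_characters = len,
             reading_time_s = 60 * len / speed,
             stringsAsFactors = FALSE)
}

#' Simulate a full cohort: trials, reading records and manifest
#'
#' Draws the latent cohort, then one trigram session and one reading
#' session per participant, using per-participant seeds derived
#' deterministically from the master seed so the whole dataset is
#' reproducible from the configuration alone.
#'
#' @param config A `vs_generator_config`.
#' @param design A `vs_design`; defaults to [default_design()].
#' @return A list with elements `participants` (latent parameters and true
#'   spans), `trials`, `reading`, and `manifest` (config echo plus the
#'   derived seeds).
#' @export
simulate_cohort <- function(config = generator_config(),
                            design = default_design()) {
  stopifnot(inherits(config, "vs_generator_config"))
  participants <- sample_participants(config)
  ids <- unique(participants$participant_id)
  trials <- vector("list", length(ids))
  reading <- vector("list", length(ids))
  seeds <- data.frame(participant_id = ids,
                      trial_seed = derive_seed(config$seed,
                                               seq_along(ids), 1L),
                      reading_seed = derive_seed(config$seed,
                                                 seq_along(ids), 2L),
                      stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    prt <- participants[participants$participant_id == ids[i], ]
    trials[[i]] <- simulate_session(prt, design, seeds$trial_seed[i],
                                    config$set_size)
    reading[[i]] <- simulate_reading(prt, config, seeds$reading_seed[i])
  }
  list(participants = participants,
       trials = do.call(rbind, trials),
       reading = do.call(rbind, reading),
       manifest = list(seed = config$seed,
                       n_per_group = config$n_per_group,
                       set_size = config$set_size,
                       cells = config$cells,
                       between = config$between,
                       reading = config$reading,
                       participant_seeds = seeds,
                       design_trials = n_trials(design)))
}
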