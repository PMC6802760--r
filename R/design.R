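# Role offsets of the three trigram characters relative to the trigram center.
ROLE_OFFSETS <- c(first = -1L, middle = 0L, last = 1L)

#' Describe a trigram-task session design
#'
#' A session design records where trigrams can be centered, how the session
#' is blocked, and which display positions are scored. A trigram centered at
#' position `c` places its first, middle and last characters at `c - 1`,
#' `c` and `c + 1`; characters landing outside `scored_range` are shown but
#' never scored.
#'
#' @param centers Integer vector of allowed trigram center positions. Must be
#'   contiguous and symmetric about 0.
#' @param n_complexity_levels Number of pattern-complexity stimulus sets.
#' @param blocks_per_level Blocks presented per complexity level.
#' @param reps_per_center_per_block How often each center is used per block.
#' @param set_size Number of characters in each complexity set; the guessing
#'   rate is `1 / set_size`.
#' @param scored_range Length-2 integer vector, the inclusive interval of
#'   display positions at which recognition accuracy is assessed.
#' @param complexity_levels Labels of the complexity levels, in order.
#'
#' @return An object of class `vs_design`.
#' @seealso [default_design()] for the standard session.
#' @export
session_design <- function(centers = -8:8,
                           n_complexity_levels = 3L,
                           blocks_per_level = 3L,
                           reps_per_center_per_block = 3L,
                           set_size = 26L,
                           scored_range = c(-7L, 7L),
                           complexity_levels = c("low", "medium", "high")) {
  centers <- sort(as.integer(centers))
  if (anyDuplicated(centers)) {
    stop("`centers` must not contain duplicates", call. = FALSE)
  }
  if (length(centers) < 1L || any(diff(centers) != 1L)) {
    stop("`centers` must be a contiguous run of integers", call. = FALSE)
  }
  if (!identical(centers, sort(-centers))) {
    stop("`centers` must be symmetric about position 0", call. = FALSE)
  }
  scored_range <- as.integer(scored_range)
  if (length(scored_range) != 2L || scored_range[1L] > scored_range[2L]) {
    stop("`scored_range` must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  if (set_size < 2L) stop("`set_size` must be at least 2", call. = FALSE)
  if (length(complexity_levels) != n_complexity_levels) {
    stop("`complexity_levels` must have length `n_complexity_levels`",
         call. = FALSE)
  }
  scored <- seq.int(scored_range[1L], scored_range[2L])
  covered <- unique(as.vector(outer(centers, ROLE_OFFSETS, `+`)))
  if (!all(scored %in% covered)) {
    stop("scored positions ", paste(setdiff(scored, covered), collapse = ", "),
         " are not reachable by any (center, role) pair", call. = FALSE)
  }
  structure(
    list(centers = centers,
         n_complexity_levels = as.integer(n_complexity_levels),
         blocks_per_level = as.integer(blocks_per_level),
         reps_per_center_per_block = as.integer(reps_per_center_per_block),
         set_size = as.integer(set_size),
         scored_range = scored_range,
         complexity_levels = as.character(complexity_levels)),
    class = "vs_design")
}

#' The default trigram session design
#'
#' Seventeen trigram centers (-8 ... +8), three complexity levels presented
#' in three blocks each, with every center used three times per block:
#' 17 x 3 x 3 x 3 = 459 trials per participant. Characters can fall at
#' positions -9 ... +9 but only -7 ... +7 are scored, so positions beyond
#' +-7 receive stimuli without contributing observations.
#'
#' @return A `vs_design` object.
#' @export
default_design <- function() session_design()

#' Total number of trials a design prescribes per participant
#'
#' @param design A `vs_design` object.
#' @return Integer trial count.
#' @export
n_trials <- function(design) {
  stopifnot(inherits(design, "vs_design"))
  length(design$centers) * design$n_complexity_levels *
    design$blocks_per_level * design$reps_per_center_per_block
}

#' @export
print.vs_design <- function(x, ...) {
  cat("Trigram session design\n")
  cat("  centers:      ", x$centers[1L], "...", x$centers[length(x$centers)],
      " (", length(x$centers), " centers)\n", sep = "")
  cat("  complexity:   ", paste(x$complexity_levels, collapse = ", "), "\n",
      sep = "")
  cat("  blocks/level: ", x$blocks_per_level, ", reps/center/block: ",
      x$reps_per_center_per_block, "\n", sep = "")
  cat("  scored range: ", x$scored_range[1L], " ... ", x$scored_range[2L],
      "\n", sep = "")
  cat("  set size:     ", x$set_size, " (chance ",
      round(100 / x$set_size, 1), "%)\n", sep = "")
  cat("  trials/participant: ", n_trials(x), "\n", sep = "")
  invisible(x)
}

#' Score one trigram trial
#'
#' Each character of the trigram is scored 1 (reported correctly) or 0 at
#' the display position it occupied; characters falling outside the design's
#' scored range are dropped.
#'
#' @param trial A list or one-row data frame with fields `center` (integer
#'   trigram center) and either `correct` (three 0/1 flags, first/middle/last)
#'   or columns `correct1`, `correct2`, `correct3`.
#' @param design A `vs_design` object governing the trial.
#'
#' @return A data frame with columns `position`, `score` (0/1) and `role`
#'   (`"first"`, `"middle"`, `"last"`), one row per scored character.
#' @examples
#' d <- default_design()
#' # center -3, left character missed: 0 at -4, 1 at -3 and -2
#' score_trial(list(center = -3, correct = c(0, 1, 1)), d)
#' @export
score_trial <- function(trial, design) {
  stopifnot(inherits(design, "vs_design"))
  if (is.data.frame(trial)) {
    if (nrow(trial) != 1L) stop("`trial` must be a single trial", call. = FALSE)
    trial <- as.list(trial)
  }
  correct <- if (!is.null(trial$correct)) trial$correct
             else c(trial$correct1, trial$correct2, trial$correct3)
  center <- as.integer(trial$center)
  if (length(center) != 1L || !center %in% design$centers) {
    stop("invalid trial: center ", center, " is not a design center",
         call. = FALSE)
  }
  if (length(correct) != 3L || !all(correct %in% c(0, 1))) {
    stop("invalid trial: `correct` must be three 0/1 flags", call. = FALSE)
  }
  position <- center + ROLE_OFFSETS
  keep <- position >= design$scored_range[1L] & position <= design$scored_range[2L]
  data.frame(position = unname(position[keep]),
             score = as.integer(correct[keep]),
             role = names(ROLE_OFFSETS)[keep],
             stringsAsFactors = FALSE)
}

# Basic schema and range validation of a trial table. Reports offending row
# numbers so malformed input files can be located.
validate_trials <- function(trials, design) {
  required <- c("participant_id", "age_group", "complexity", "block",
                "center", "correct1", "correct2", "correct3")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(trials) == 0L) {
    stop("trial table is empty", call. = FALSE)
  }
  bad_rows <- function(ok, what) {
    if (!all(ok)) {
      rows <- which(!ok)
      stop("invalid trials (", what, ") at row",
           if (length(rows) > 1L) "s" else "", " ",
           paste(utils::head(rows, 10L), collapse = ", "),
           if (length(rows) > 10L) " ..." else "", call. = FALSE)
    }
  }
  bad_rows(trials$center %in% design$centers, "center outside design")
  bad_rows(trials$complexity %in% design$complexity_levels,
           "unknown complexity level")
  for (k in 1:3) {
    bad_rows(trials[[paste0("correct", k)]] %in% c(0, 1),
             paste0("correct", k, " not 0/1"))
  }
  stim_cols <- paste0("stim", 1:3)
  if (all(stim_cols %in% names(trials))) {
    s <- trials[stim_cols]
    bad_rows(s[[1]] >= 1 & s[[1]] <= design$set_size &
             s[[2]] >= 1 & s[[2]] <= design$set_size &
             s[[3]] >= 1 & s[[3]] <= design$set_size,
             "stimulus index outside character set")
    bad_rows(s[[1]] != s[[2]] & s[[1]] != s[[3]] & s[[2]] != s[[3]],
             "repeated character within trigram")
  }
  invisible(trials)
}

#' Score a table of trigram trials
#'
#' Vectorised version of [score_trial()]: expands every trial into one row
#' per stimulus character, keeps those landing in the design's scored range,
#' and carries participant, age-group and complexity labels along.
#'
#' @param trials Data frame of trials with columns `participant_id`,
#'   `age_group`, `complexity`, `block`, `center`, `correct1..3` (and
#'   optionally `stim1..3`).
#' @param design A `vs_design` object.
#'
#' @return A long data frame with columns `participant_id`, `age_group`,
#'   `complexity`, `position`, `role` and `score`.
#' @export
score_trials <- function(trials, design) {
  stopifnot(inherits(design, "vs_design"))
  validate_trials(trials, design)
  n <- nrow(trials)
  roles <- names(ROLE_OFFSETS)
  long <- data.frame(
    participant_id = rep(as.character(trials$participant_id), 3L),
    age_group = rep(as.character(trials$age_group), 3L),
    complexity = rep(as.character(trials$complexity), 3L),
    position = c(trials$center - 1L, trials$center, trials$center + 1L),
    role = rep(roles, each = n),
    score = as.integer(c(trials$correct1, trials$correct2, trials$correct3)),
    stringsAsFactors = FALSE)
  keep <- long$position >= design$scored_range[1L] &
          long$position <= design$scored_range[2L]
  long[keep, , drop = FALSE]
}

#' Build per-position accuracy profiles
#'
#' Aggregates scored characters into a visual-span profile for every
#' participant x complexity combination present in the trial table:
#' percent-correct accuracy and observation count at each scored position.
#' Under the default balanced design every scored position accumulates 27
#' observations per complexity level.
#'
#' @inheritParams score_trials
#' @return A data frame with one row per participant x complexity x position:
#'   columns `participant_id`, `age_group`, `complexity`, `position`,
#'   `n_obs`, `accuracy_pct`.
#' @export
build_profiles <- function(trials, design) {
  long <- score_trials(trials, design)
  if (nrow(long) == 0L) {
    stop("incomplete profile: no scored observations", call. = FALSE)
  }
  positions <- seq.int(design$scored_range[1L], design$scored_range[2L])
  npos <- length(positions)

  pid <- factor(long$participant_id)
  cpx <- factor(long$complexity, levels = design$complexity_levels)
  pos_i <- match(long$position, positions)
  ncpx <- nlevels(cpx)

  # combined cell index: participant-major, then complexity, then position
  idx <- ((as.integer(pid) - 1L) * ncpx + (as.integer(cpx) - 1L)) * npos + pos_i
  n_obs <- numeric(nlevels(pid) * ncpx * npos)
  n_cor <- n_obs
  tab_n <- rowsum(rep(1L, nrow(long)), idx)
  tab_c <- rowsum(long$score, idx)
  ii <- as.integer(rownames(tab_n))
  n_obs[ii] <- tab_n[, 1L]
  n_cor[ii] <- tab_c[, 1L]

  # participant x complexity combinations actually observed
  combo_seen <- unique((as.integer(pid) - 1L) * ncpx + as.integer(cpx))
  out <- NULL
  age_of <- tapply(long$age_group, pid, function(a) a[[1L]])
  rows <- vector("list", length(combo_seen))
  combo_seen <- sort(combo_seen)
  for (j in seq_along(combo_seen)) {
    cb <- combo_seen[j]
    p_i <- (cb - 1L) %/% ncpx + 1L
    c_i <- (cb - 1L) %% ncpx + 1L
    cell <- (cb - 1L) * npos + seq_len(npos)
    if (any(n_obs[cell] == 0L)) {
      stop("incomplete profile for participant ", levels(pid)[p_i],
           ", complexity ", design$complexity_levels[c_i],
           ": no observations at position",
           if (sum(n_obs[cell] == 0L) > 1L) "s" else "", " ",
           paste(positions[n_obs[cell] == 0L], collapse = ", "),
           call. = FALSE)
    }
    rows[[j]] <- data.frame(
      participant_id = levels(pid)[p_i],
      age_group = unname(age_of[[p_i]]),
      complexity = design$complexity_levels[c_i],
      position = positions,
      n_obs = as.integer(n_obs[cell]),
      accuracy_pct = 100 * n_cor[cell] / n_obs[cell],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Accuracy at the fixation position by trigram role
#'
#' Only trigrams centered at -1, 0 or +1 place a character at position 0,
#' as the last, middle or first trigram character respectively. Comparing
#' accuracy across these roles separates crowding of the doubly-flanked
#' middle character from recognition of the outer characters at matched
#' eccentricity.
#'
#' @inheritParams score_trials
#' @return A data frame with one row per age group x complexity x role:
#'   `n` observations and `accuracy_pct` (percent correct; `NA` for empty
#'   cells, which are undefined rather than zero).
#' @export
center_role_accuracy <- function(trials, design) {
  long <- score_trials(trials, design)
  at0 <- long[long$position == 0L, , drop = FALSE]
  groups <- unique(as.character(trials$age_group))
  grid <- expand.grid(role = names(ROLE_OFFSETS),
                      complexity = design$complexity_levels,
                      age_group = groups,
                      stringsAsFactors = FALSE)[, 3:1]
  key <- function(a, c, r) paste(a, c, r, sep = "\r")
  kk <- key(at0$age_group, at0$complexity, at0$role)
  n <- tapply(at0$score, kk, length)
  s <- tapply(at0$score, kk, sum)
  gk <- key(grid$age_group, grid$complexity, grid$role)
  grid$n <- as.integer(ifelse(is.na(n[gk]), 0L, n[gk]))
  grid$accuracy_pct <- ifelse(grid$n > 0L, 100 * s[gk] / n[gk], NA_real_)
  rownames(grid) <- NULL
  grid
}
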