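# Experiment designs: 2x2 (Difficulty x Feedback) task conditions, six task
# pairings per block, and dot-count stimuli for the three experiments.

# Stimulus constants: one box is always half-filled; the other carries a
# fixed dot surplus per difficulty level (experiment 1 used +58 for easy,
# experiments 2 and 3 +60; difficult is +24 throughout).
N_REFERENCE_DOTS <- 313L
N_GRID_POSITIONS <- 625L
DOT_SURPLUS <- list(
  exp1 = c(easy = 58L, difficult = 24L),
  exp2 = c(easy = 60L, difficult = 24L),
  exp3 = c(easy = 60L, difficult = 24L)
)

EXPERIMENT_IDS <- c("exp1", "exp2", "exp3")
DIFFICULTY_LEVELS <- c("easy", "difficult")
FEEDBACK_MODES <- c("feedback", "none", "confidence_rating")

#' Default evidence-strength (signal) calibration
#'
#' Signals are calibrated so that an observer with choice sensitivity
#' `k_ch = 1` attains the design's target accuracies of 0.85 (easy) and
#' 0.70 (difficult): signal = qnorm(target accuracy).
#'
#' @param easy,difficult target accuracies for the two difficulty levels.
#' @return named numeric vector with elements `easy` and `difficult`.
#' @examples
#' default_signals()  # c(easy = 1.0364, difficult = 0.5244)
#' @export
default_signals <- function(easy = 0.85, difficult = 0.70) {
  c(easy = calibrate_signal(easy, 1), difficult = calibrate_signal(difficult, 1))
}

#' Construct a task condition
#'
#' A task is one cell of the Difficulty x Feedback factorial: it is easy or
#' difficult (via its evidence strength `signal`) and provides feedback,
#' no feedback, or requires a trial-by-trial confidence rating (experiment 3
#' replaces the no-feedback mode by confidence rating).
#'
#' @param difficulty "easy" or "difficult".
#' @param feedback_mode "feedback", "none" or "confidence_rating".
#' @param signal positive evidence strength; default from
#'   \code{\link{default_signals}}.
#' @param color_id opaque label for the task's colour cue.
#' @return an object of class `task_condition`.
#' @export
task_condition <- function(difficulty, feedback_mode,
                           signal = default_signals()[[difficulty]],
                           color_id = NA_character_) {
  difficulty <- match.arg(difficulty, DIFFICULTY_LEVELS)
  feedback_mode <- match.arg(feedback_mode, FEEDBACK_MODES)
  if (!is.numeric(signal) || length(signal) != 1L || !is.finite(signal) ||
      signal <= 0) {
    stop("invalid-condition: `signal` must be a positive real", call. = FALSE)
  }
  structure(
    list(difficulty = difficulty, feedback_mode = feedback_mode,
         signal = as.numeric(signal), color_id = color_id),
    class = "task_condition"
  )
}

#' @export
format.task_condition <- function(x, ...) {
  sprintf("<task %s/%s signal=%.4f>", x$difficulty, x$feedback_mode, x$signal)
}

#' @export
print.task_condition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

condition_label <- function(cond) paste(cond$difficulty, cond$feedback_mode, sep = "-")

#' Enumerate the task pairings of a factorial design
#'
#' Crosses the difficulty levels with the feedback modes and returns all
#' unordered pairs of distinct conditions. The standard 2 x 2 design yields
#' six pairings per learning block.
#'
#' @param difficulty_levels character vector of difficulty levels.
#' @param feedback_modes character vector of feedback modes.
#' @param signals named signal calibration (per difficulty level).
#' @return list of length-2 lists of `task_condition`s.
#' @examples
#' length(enumerate_pairings())  # 6
#' @export
enumerate_pairings <- function(difficulty_levels = c("easy", "difficult"),
                               feedback_modes = c("feedback", "none"),
                               signals = default_signals()) {
  if (length(difficulty_levels) == 0L || length(feedback_modes) == 0L) {
    stop("invalid-design: factor sets must be non-empty", call. = FALSE)
  }
  difficulty_levels <- unique(difficulty_levels)
  feedback_modes <- unique(feedback_modes)
  grid <- expand.grid(difficulty = difficulty_levels, feedback_mode = feedback_modes,
                      stringsAsFactors = FALSE)
  conds <- lapply(seq_len(nrow(grid)), function(i) {
    task_condition(grid$difficulty[i], grid$feedback_mode[i],
                   signal = signals[[grid$difficulty[i]]])
  })
  n <- length(conds)
  if (n < 2L) return(list())
  pairs <- utils::combn(n, 2L, simplify = FALSE)
  lapply(pairs, function(ij) list(conds[[ij[1L]]], conds[[ij[2L]]]))
}

# Balanced pseudo-random trial order: random permutation of the task-label
# multiset, so each task contributes exactly trials_per_task trials.
interleave_tasks <- function(trials_per_task) {
  sample(rep(c(1L, 2L), each = trials_per_task))
}

# Per-task balanced sides: within each task, half the targets appear left
# and half right (per-task balance implies the per-block balance as well).
balanced_sides <- function(trial_order) {
  side <- character(length(trial_order))
  for (task in c(1L, 2L)) {
    idx <- which(trial_order == task)
    n <- length(idx)
    side[idx] <- sample(rep(c("left", "right"), length.out = n))
  }
  side
}

make_block <- function(block_id, pairing, pairing_id, trials_per_task) {
  trial_order <- interleave_tasks(trials_per_task)
  data.frame(
    block = block_id,
    trial = seq_along(trial_order),
    task_index = trial_order,
    pairing = pairing_id,
    trials_per_task = trials_per_task,
    difficulty = vapply(trial_order, function(t) pairing[[t]]$difficulty, ""),
    feedback_mode = vapply(trial_order, function(t) pairing[[t]]$feedback_mode, ""),
    target_side = balanced_sides(trial_order),
    stringsAsFactors = FALSE
  )
}

#' Build the trial-level design of one experiment
#'
#' Experiment 1: the six pairings of the 2 x 2 (Difficulty x Feedback)
#' design, each repeated twice, with 12 trials per task (24-trial blocks;
#' 288 trials in total). Experiments 2 and 3: the six pairings crossed with
#' block durations of 2, 4, 6, 8 or 10 trials per task, each combination
#' once (30 blocks, 360 trials). In experiment 3 the no-feedback mode is
#' replaced by trial-by-trial confidence rating. Block order, trial
#' interleaving and target sides are pseudo-random but balanced, and fully
#' determined by `seed`.
#'
#' @param experiment_id "exp1", "exp2" or "exp3".
#' @param seed integer seed.
#' @param signals named signal calibration (per difficulty level).
#' @return an object of class `design_spec`: list with `experiment_id`,
#'   `pairings` (list of condition pairs), `blocks` (list of per-block
#'   metadata) and `trials` (one row per trial).
#' @examples
#' d <- build_design("exp2", seed = 1)
#' nrow(d$trials)  # 360
#' @export
build_design <- function(experiment_id, seed = 1L, signals = default_signals()) {
  experiment_id <- match.arg(experiment_id, EXPERIMENT_IDS)
  feedback_modes <- if (experiment_id == "exp3") {
    c("feedback", "confidence_rating")
  } else {
    c("feedback", "none")
  }
  pairings <- enumerate_pairings(c("easy", "difficult"), feedback_modes, signals)

  with_seed(seed, {
    if (experiment_id == "exp1") {
      slots <- data.frame(pairing = rep(seq_along(pairings), times = 2L),
                          trials_per_task = 12L)
    } else {
      slots <- expand.grid(pairing = seq_along(pairings),
                           trials_per_task = c(2L, 4L, 6L, 8L, 10L))
    }
    slots <- slots[sample(nrow(slots)), , drop = FALSE]
    trials <- vector("list", nrow(slots))
    blocks <- vector("list", nrow(slots))
    for (b in seq_len(nrow(slots))) {
      p_id <- slots$pairing[b]
      tpt <- slots$trials_per_task[b]
      trials[[b]] <- make_block(b, pairings[[p_id]], p_id, tpt)
      blocks[[b]] <- list(block = b, pairing = p_id,
                          trials_per_task = tpt,
                          conditions = pairings[[p_id]])
    }
    structure(
      list(experiment_id = experiment_id,
           pairings = pairings,
           blocks = blocks,
           trials = do.call(rbind, trials)),
      class = "design_spec"
    )
  })
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design %s: %d blocks, %d trials, %d pairings>\n",
              x$experiment_id, length(x$blocks), nrow(x$trials),
              length(x$pairings)))
  invisible(x)
}

#' Generate a dot-count stimulus
#'
#' One box is always half-filled (313 dots out of 625 grid positions); the
#' target box contains 313 plus a fixed surplus: +24 dots in the difficult
#' conditions of all experiments, +58 (easy, experiment 1) or +60 (easy,
#' experiments 2/3). Spatial dot placements are materialised only on
#' request, as seeded uniform random subsets of the grid positions.
#'
#' @param condition a `task_condition` (or its difficulty string).
#' @param experiment_id "exp1", "exp2" or "exp3".
#' @param target_side "left" or "right".
#' @param seed integer seed for dot placement; NULL skips placement.
#' @param place_dots logical; also sample dot position indices.
#' @return list of class `stimulus_spec` with fields `n_reference_dots`,
#'   `n_target_dots`, `target_side`, `grid_positions`, and (if placed)
#'   `reference_positions`, `target_positions`.
#' @examples
#' generate_stimulus(task_condition("difficult", "none"), "exp1", "left")
#' @export
generate_stimulus <- function(condition, experiment_id, target_side,
                              seed = NULL, place_dots = !is.null(seed)) {
  difficulty <- if (inherits(condition, "task_condition")) {
    condition$difficulty
  } else {
    match.arg(condition, DIFFICULTY_LEVELS)
  }
  experiment_id <- match.arg(experiment_id, EXPERIMENT_IDS)
  target_side <- match.arg(target_side, c("left", "right"))
  n_target <- N_REFERENCE_DOTS + DOT_SURPLUS[[experiment_id]][[difficulty]]
  out <- list(n_reference_dots = N_REFERENCE_DOTS,
              n_target_dots = n_target,
              target_side = target_side,
              grid_positions = N_GRID_POSITIONS)
  if (place_dots) {
    out[c("reference_positions", "target_positions")] <- with_seed(seed, list(
      sort(sample.int(N_GRID_POSITIONS, N_REFERENCE_DOTS)),
      sort(sample.int(N_GRID_POSITIONS, n_target))
    ))
  }
  structure(out, class = "stimulus_spec")
}

#' Export a design as a trial-level CSV
#'
#' One row per trial with columns block, trial, task_index, difficulty,
#' feedback_mode, target_side, n_reference_dots, n_target_dots.
#'
#' @param design a `design_spec`.
#' @param path output file path.
#' @return the exported data.frame, invisibly.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "design_spec"))
  surplus <- DOT_SURPLUS[[design$experiment_id]]
  df <- design$trials[, c("block", "trial", "task_index", "difficulty",
                          "feedback_mode", "target_side")]
  df$n_reference_dots <- N_REFERENCE_DOTS
  df$n_target_dots <- N_REFERENCE_DOTS + unname(surplus[df$difficulty])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Describe a design's factor structure as a YAML config
#'
#' @param design a `design_spec`.
#' @param path output file path.
#' @return the config list, invisibly.
#' @export
write_design_yaml <- function(design, path) {
  stopifnot(inherits(design, "design_spec"))
  cfg <- list(
    experiment_id = design$experiment_id,
    difficulty_levels = DIFFICULTY_LEVELS,
    feedback_modes = unique(unlist(lapply(design$pairings, function(p)
      c(p[[1L]]$feedback_mode, p[[2L]]$feedback_mode)))),
    n_blocks = length(design$blocks),
    trials_per_task = sort(unique(vapply(design$blocks, `[[`, 0L,
                                         "trials_per_task"))),
    n_reference_dots = N_REFERENCE_DOTS,
    grid_positions = N_GRID_POSITIONS,
    dot_surplus = as.list(DOT_SURPLUS[[design$experiment_id]]),
    signals = {
      conds <- unlist(design$pairings, recursive = FALSE)
      sig <- vapply(conds, `[[`, 0, "signal")
      names(sig) <- vapply(conds, `[[`, "", "difficulty")
      as.list(sig[!duplicated(names(sig))])
    }
  )
  yaml::write_yaml(cfg, path)
  invisible(cfg)
}
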