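# Synthetic cohorts: simulated subjects run through the exp1/exp2/exp3
# designs, plus the trial/block CSV schema (read/write with validation).
#
# Trial CSV schema (one row per trial):
#   subject, block, trial, task_index, difficulty, feedback_mode,
#   target_side, choice, correct, rt_ms, confidence, feedback_shown
# `confidence` is on the 50-100 reporting scale and empty except on
# confidence-rating trials. Block CSV schema (one row per block): subject,
# block, pairing, duration, then task-A/task-B summaries (a_*/b_* columns,
# task A = the condition listed first in the pairing definition),
# task_choice (1 = task A chosen) and p_choose_a.

TRIAL_COLUMNS <- c("subject", "block", "trial", "task_index", "difficulty",
                   "feedback_mode", "target_side", "choice", "correct",
                   "rt_ms", "confidence", "feedback_shown")

#' Specification of a simulated cohort
#'
#' Population distributions of the subject parameters: `k_ch` and `k_conf`
#' are lognormal across subjects (positivity preserved); the remaining
#' parameters are shared. Defaults put median sensitivities at 1, so
#' cohort accuracies bracket the designs' 70/85% calibration targets.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param experiment_id "exp1", "exp2" or "exp3".
#' @param k_ch_meanlog,k_ch_sdlog lognormal parameters of k_ch.
#' @param k_conf_meanlog,k_conf_sdlog lognormal parameters of k_conf.
#' @param prior_a,prior_b learner prior pseudo-counts (shared).
#' @param policy_temperature end-of-block policy temperature (shared).
#' @param seed master seed; per-subject child seeds are derived from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, experiment_id,
                        k_ch_meanlog = 0, k_ch_sdlog = 0.25,
                        k_conf_meanlog = 0, k_conf_sdlog = 0.25,
                        prior_a = 1, prior_b = 1,
                        policy_temperature = 1, seed = 1L) {
  stopifnot(n_subjects >= 1L, k_ch_sdlog >= 0, k_conf_sdlog >= 0)
  experiment_id <- match.arg(experiment_id, EXPERIMENT_IDS)
  structure(
    list(n_subjects = as.integer(n_subjects), experiment_id = experiment_id,
         k_ch_meanlog = k_ch_meanlog, k_ch_sdlog = k_ch_sdlog,
         k_conf_meanlog = k_conf_meanlog, k_conf_sdlog = k_conf_sdlog,
         prior_a = prior_a, prior_b = prior_b,
         policy_temperature = policy_temperature, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Deterministic child-seed derivation: subject i of master seed m gets
# (m + 7919 * i) mod (2^31 - 1). Documented so cohorts are reproducible
# and subjects independent.
child_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 7919 * index) %% 2147483647)
}

#' Simulate one subject through a design
#'
#' Runs \code{\link{run_block}} over every block of the design. Internal
#' confidence (0.5-1) is rescaled to the 50-100 reporting scale and
#' reported only on confidence-rating trials; end-of-block ability ratings
#' are produced for experiment-1 designs.
#'
#' @param params a `subject_params`.
#' @param design a `design_spec`.
#' @param subject subject identifier.
#' @param seed integer seed (defaults to `params$seed`).
#' @return list with `trials` and `blocks` data.frames in the CSV schema.
#' @export
simulate_subject <- function(params, design, subject = "s1",
                             seed = params$seed) {
  stopifnot(inherits(params, "subject_params"), inherits(design, "design_spec"))
  with_ratings <- design$experiment_id == "exp1"
  with_seed(seed, {
    trial_list <- vector("list", length(design$blocks))
    block_list <- vector("list", length(design$blocks))
    for (b in seq_along(design$blocks)) {
      blk <- design$blocks[[b]]
      bt <- design$trials[design$trials$block == blk$block, , drop = FALSE]
      res <- run_block(params, blk, bt, with_ratings = with_ratings)
      tr <- res$trials
      tr$confidence <- ifelse(tr$feedback_mode == "confidence_rating",
                              100 * tr$confidence, NA_real_)
      trial_list[[b]] <- data.frame(
        subject = subject,
        tr[, c("block", "trial", "task_index", "difficulty", "feedback_mode",
               "target_side", "choice", "correct", "rt_ms", "confidence",
               "feedback_shown")],
        stringsAsFactors = FALSE)
      block_list[[b]] <- data.frame(subject = subject, res$record,
                                    stringsAsFactors = FALSE)
    }
    list(trials = do.call(rbind, trial_list),
         blocks = do.call(rbind, block_list))
  })
}

#' Simulate a complete cohort
#'
#' Draws per-subject parameters from the population distributions of a
#' `cohort_spec` (truncated to valid ranges), derives per-subject child
#' seeds deterministically from the master seed, simulates every subject
#' through a freshly randomised design, and returns an `spe_dataset`.
#'
#' @param spec a `cohort_spec`.
#' @param signals design signal calibration.
#' @return object of class `spe_dataset`: list with `trials`, `blocks`,
#'   `experiment_id`, `subject_params` (the drawn parameter table) and
#'   `spec`.
#' @export
simulate_cohort <- function(spec, signals = default_signals()) {
  stopifnot(inherits(spec, "cohort_spec"))
  draws <- with_seed(spec$seed, data.frame(
    subject = sprintf("s%02d", seq_len(spec$n_subjects)),
    k_ch = stats::rlnorm(spec$n_subjects, spec$k_ch_meanlog, spec$k_ch_sdlog),
    k_conf = stats::rlnorm(spec$n_subjects, spec$k_conf_meanlog,
                           spec$k_conf_sdlog),
    seed = child_seed(spec$seed, seq_len(spec$n_subjects)),
    stringsAsFactors = FALSE))
  trial_list <- vector("list", spec$n_subjects)
  block_list <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    params <- subject_params(
      k_ch = draws$k_ch[i], k_conf = draws$k_conf[i],
      prior_a = spec$prior_a, prior_b = spec$prior_b,
      policy_temperature = spec$policy_temperature, seed = draws$seed[i])
    design <- build_design(spec$experiment_id, seed = draws$seed[i],
                           signals = signals)
    res <- simulate_subject(params, design, subject = draws$subject[i],
                            seed = draws$seed[i])
    trial_list[[i]] <- res$trials
    block_list[[i]] <- res$blocks
  }
  structure(
    list(trials = do.call(rbind, trial_list),
         blocks = do.call(rbind, block_list),
         experiment_id = spec$experiment_id,
         subject_params = draws, spec = spec),
    class = "spe_dataset"
  )
}

#' @export
print.spe_dataset <- function(x, ...) {
  cat(sprintf("<spe_dataset %s: %d subjects, %d trials, %d blocks>\n",
              x$experiment_id, length(unique(x$trials$subject)),
              nrow(x$trials), if (is.null(x$blocks)) 0L else nrow(x$blocks)))
  invisible(x)
}

validate_trials <- function(trials, experiment_id = NULL) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(trials$correct %in% c(TRUE, FALSE)))
  if (length(bad)) {
    stop("schema error: non-binary `correct` in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  mism <- which((trials$choice == trials$target_side) != trials$correct)
  if (length(mism)) {
    stop("schema error: `correct` inconsistent with choice/target_side in row(s) ",
         paste(utils::head(mism, 5L), collapse = ", "), call. = FALSE)
  }
  bad_rt <- which(!(trials$rt_ms > 0))
  if (length(bad_rt)) {
    stop("schema error: non-positive rt_ms in row(s) ",
         paste(utils::head(bad_rt, 5L), collapse = ", "), call. = FALSE)
  }
  conf <- trials$confidence
  bad_conf <- which(!is.na(conf) & (conf < 50 | conf > 100))
  if (length(bad_conf)) {
    stop("range error: confidence outside [50, 100] in row(s) ",
         paste(utils::head(bad_conf, 5L), collapse = ", "), call. = FALSE)
  }
  need_conf <- which(trials$feedback_mode == "confidence_rating" & is.na(conf))
  if (length(need_conf)) {
    stop("schema error: missing confidence on confidence-rating trial row(s) ",
         paste(utils::head(need_conf, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(trials)
}

#' Write a dataset to CSV files
#'
#' Writes `trials.csv` (and `blocks.csv` when block records are present)
#' under `path`. Comma-separated, UTF-8, header row, "." decimal; missing
#' confidence is encoded as an empty field.
#'
#' @param dataset an `spe_dataset`.
#' @param path output directory (created if needed).
#' @return the file paths, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spe_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tf <- file.path(path, "trials.csv")
  utils::write.csv(dataset$trials, tf, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  files <- tf
  if (!is.null(dataset$blocks)) {
    bf <- file.path(path, "blocks.csv")
    utils::write.csv(dataset$blocks, bf, row.names = FALSE, na = "",
                     quote = FALSE, fileEncoding = "UTF-8")
    files <- c(files, bf)
  }
  meta <- file.path(path, "dataset.json")
  jsonlite::write_json(
    list(experiment_id = dataset$experiment_id,
         n_subjects = length(unique(dataset$trials$subject)),
         spec = if (!is.null(dataset$spec)) unclass(dataset$spec),
         subject_params = dataset$subject_params),
    meta, auto_unbox = TRUE, digits = NA)
  invisible(c(files, meta))
}

#' Read a dataset from CSV files
#'
#' Reads `trials.csv` (+ optional `blocks.csv`, `dataset.json`) from a
#' directory, validating the trial schema (column presence, binary
#' correctness consistent with choice/target side, positive RTs,
#' confidence within [50, 100] and present on confidence-rating trials).
#'
#' @param path directory written by \code{\link{write_dataset}} (or a
#'   direct path to a trials CSV file).
#' @return an `spe_dataset`.
#' @export
read_dataset <- function(path) {
  tf <- if (dir.exists(path)) file.path(path, "trials.csv") else path
  if (!file.exists(tf)) stop("no trials.csv found at ", path, call. = FALSE)
  trials <- utils::read.csv(tf, stringsAsFactors = FALSE)
  if ("correct" %in% names(trials)) trials$correct <- as.logical(trials$correct)
  validate_trials(trials)
  blocks <- NULL
  experiment_id <- NULL
  if (dir.exists(path)) {
    bf <- file.path(path, "blocks.csv")
    if (file.exists(bf)) blocks <- utils::read.csv(bf, stringsAsFactors = FALSE)
    mf <- file.path(path, "dataset.json")
    if (file.exists(mf)) {
      experiment_id <- jsonlite::read_json(mf)$experiment_id
    }
  }
  if (is.null(experiment_id)) {
    experiment_id <- if ("confidence_rating" %in% trials$feedback_mode)
      "exp3" else if (max(trials$block) > 12L) "exp2" else "exp1"
  }
  structure(
    list(trials = trials, blocks = blocks, experiment_id = experiment_id,
         subject_params = NULL, spec = NULL),
    class = "spe_dataset"
  )
}

#' Read a cohort specification from a YAML config
#'
#' @param path YAML file with fields matching \code{\link{cohort_spec}}
#'   arguments.
#' @return a `cohort_spec`.
#' @export
read_cohort_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(cohort_spec, cfg)
}
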