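# Dataset-level analysis orchestration: per-subject condition summaries,
# task-choice frequencies, block-pair features for the choice regression,
# and the full pipeline in one call.

#' Per-subject condition means of a trial-level measure
#'
#' @param trials trial-level data.frame.
#' @param measure column to average ("correct", "rt_ms", "confidence").
#' @return data.frame subject x difficulty x feedback with `value`
#'   (feedback is "feedback" vs "absent", pooling the no-feedback and
#'   confidence-rating modes, which both lack external feedback).
#' @export
condition_means <- function(trials, measure = "correct") {
  stopifnot(measure %in% names(trials))
  fb <- ifelse(trials$feedback_mode == "feedback", "feedback", "absent")
  out <- stats::aggregate(
    list(value = as.numeric(trials[[measure]])),
    by = list(subject = trials$subject, difficulty = trials$difficulty,
              feedback = fb),
    FUN = mean, na.rm = TRUE)
  out[order(out$subject, out$difficulty, out$feedback), , drop = FALSE]
}

#' Per-subject task-choice frequency by condition
#'
#' Each block contributes one observation to each of its two task
#' conditions: 1 for the chosen task, 0 for the unchosen. Frequencies are
#' the per-subject means over the blocks in which a condition appeared.
#'
#' @param blocks block-level data.frame.
#' @return data.frame subject x difficulty x feedback with `value`.
#' @export
task_choice_frequency <- function(blocks) {
  long <- rbind(
    data.frame(subject = blocks$subject, difficulty = blocks$a_difficulty,
               feedback_mode = blocks$a_feedback_mode,
               chosen = as.numeric(blocks$task_choice == 1L)),
    data.frame(subject = blocks$subject, difficulty = blocks$b_difficulty,
               feedback_mode = blocks$b_feedback_mode,
               chosen = as.numeric(blocks$task_choice == 0L)))
  fb <- ifelse(long$feedback_mode == "feedback", "feedback", "absent")
  out <- stats::aggregate(
    list(value = long$chosen),
    by = list(subject = long$subject, difficulty = long$difficulty,
              feedback = fb),
    FUN = mean)
  out[order(out$subject, out$difficulty, out$feedback), , drop = FALSE]
}

#' Block-pair features for the task-choice regression
#'
#' Per block: accDiff, rtDiff and (when available) confDiff, computed as
#' task A minus task B (task A = the condition listed first in the pairing
#' definition), plus the binary choice (1 = task A chosen). For
#' experiment-3 style regressions restrict to blocks where both tasks were
#' confidence-rated with `both_confidence = TRUE`.
#'
#' @param blocks block-level data.frame.
#' @param both_confidence keep only blocks whose two tasks both carry
#'   confidence ratings.
#' @return data.frame with subject, pairing, duration, accDiff, rtDiff,
#'   confDiff, choice.
#' @export
block_pair_features <- function(blocks, both_confidence = FALSE) {
  keep <- if (both_confidence) {
    blocks$a_feedback_mode == "confidence_rating" &
      blocks$b_feedback_mode == "confidence_rating"
  } else {
    rep(TRUE, nrow(blocks))
  }
  b <- blocks[keep, , drop = FALSE]
  data.frame(
    subject = b$subject, pairing = b$pairing, duration = b$duration,
    accDiff = b$a_acc - b$b_acc,
    rtDiff = b$a_rt - b$b_rt,
    confDiff = b$a_conf - b$b_conf,
    choice = b$task_choice,
    stringsAsFactors = FALSE)
}

#' Run the full statistical pipeline on a dataset
#'
#' Applies the exclusion screen and RT trimming, then computes the core
#' analyses of the block-design paradigm: 2 x 2 repeated-measures ANOVAs
#' on accuracy, RT and task-choice frequency (the latter arcsine
#' transformed), JZS Bayes-factor paired t-tests of the feedback null on
#' accuracy within each difficulty level, and — when the design provides
#' them — rating consistency (experiment 1), duration effects and
#' performance splits (experiments 2/3), and the confidence regression
#' with BIC comparison against the reduced accuracy+RT model
#' (experiment 3).
#'
#' @param dataset an `spe_dataset`.
#' @param exclude apply the subject exclusion screen first.
#' @return list of results; see Details in the vignette.
#' @export
analyze_dataset <- function(dataset, exclude = TRUE) {
  out <- list(experiment_id = dataset$experiment_id)
  if (exclude) {
    scr <- exclude_subjects(dataset)
    out$exclusions <- scr$report
    dataset <- scr$dataset
  }
  trim <- trim_rt_outliers(dataset$trials)
  out$rt_removed_fraction <- trim$removed_fraction
  trials <- trim$trials
  blocks <- dataset$blocks

  acc <- condition_means(trials, "correct")
  rt <- condition_means(trials, "rt_ms")
  out$anova_accuracy <- anova_2x2_rm(acc)
  out$anova_rt <- anova_2x2_rm(rt)
  out$anova_choice <- anova_2x2_rm(task_choice_frequency(blocks),
                                   transform = "arcsine_sqrt")

  # Feedback null on accuracy, within each difficulty level
  out$bf_feedback_accuracy <- lapply(DIFFICULTY_LEVELS, function(d) {
    sub <- acc[acc$difficulty == d, ]
    wide <- merge(sub[sub$feedback == "feedback", c("subject", "value")],
                  sub[sub$feedback == "absent", c("subject", "value")],
                  by = "subject", suffixes = c("_fb", "_nofb"))
    paired_t_bf(wide$value_fb, wide$value_nofb)
  })
  names(out$bf_feedback_accuracy) <- DIFFICULTY_LEVELS

  if (dataset$experiment_id == "exp1" && any(!is.na(blocks$a_rating))) {
    out$anova_ratings <- anova_2x2_rm(
      {
        long <- rbind(
          data.frame(subject = blocks$subject, difficulty = blocks$a_difficulty,
                     feedback_mode = blocks$a_feedback_mode,
                     rating = blocks$a_rating),
          data.frame(subject = blocks$subject, difficulty = blocks$b_difficulty,
                     feedback_mode = blocks$b_feedback_mode,
                     rating = blocks$b_rating))
        fb <- ifelse(long$feedback_mode == "feedback", "feedback", "absent")
        stats::aggregate(list(value = long$rating),
                         by = list(subject = long$subject,
                                   difficulty = long$difficulty, feedback = fb),
                         FUN = mean)
      }, zscore = "rank_normal")
    out$consistency <- choice_rating_consistency(blocks)
    out$recency <- recency_regression(list(trials = trials, blocks = blocks))
  }

  if (dataset$experiment_id %in% c("exp2", "exp3")) {
    out$duration <- duration_effect(blocks)
    out$splits <- split_blocks(blocks, "performance_diff")
  }

  if (dataset$experiment_id == "exp3") {
    feats <- block_pair_features(blocks, both_confidence = TRUE)
    if (nrow(feats) > 0L && stats::sd(feats$choice) > 0) {
      out$choice_regression_full <- fixed_effect_regression(
        feats, "choice", c("accDiff", "rtDiff", "confDiff"), "logistic")
      out$choice_regression_reduced <- fixed_effect_regression(
        feats, "choice", c("accDiff", "rtDiff"), "logistic")
      out$bic_full <- out$choice_regression_full$bic
      out$bic_reduced <- out$choice_regression_reduced$bic
    }
    conf_trials <- trials[!is.na(trials$confidence), , drop = FALSE]
    if (nrow(conf_trials) > 0L) {
      eff <- lapply(split(conf_trials, conf_trials$subject), function(tr) {
        tryCatch(metacog_efficiency(tr)$efficiency, error = function(e) NA_real_,
                 warning = function(w) NA_real_)
      })
      out$metacog_efficiency <- data.frame(
        subject = names(eff), efficiency = unlist(eff), row.names = NULL,
        stringsAsFactors = FALSE)
    }
  }
  out
}
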