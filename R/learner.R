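# Bayesian SPE learner: a discretised posterior belief over each task's
# accuracy theta, updated from external feedback (hard Bernoulli evidence)
# or from local decision confidence treated as soft (Jeffrey-style)
# evidence; end-of-block task choices and ability ratings are read out from
# the posteriors.
#
# The belief is a probability mass vector over an equally spaced grid on
# [0, 1]. Masses fold in trapezoid quadrature weights (endpoints
# half-weighted), which keeps grid moments in agreement with conjugate Beta
# closed forms to ~1e-5 at the default 201 points.

BELIEF_GRID_POINTS <- 201L

#' Initialise a belief over task accuracy
#'
#' Weights proportional to the Beta(prior_a, prior_b) density on an equally
#' spaced grid, with trapezoid quadrature weights, normalised to sum to 1.
#'
#' @param params a `subject_params`, or NULL when `prior_a`/`prior_b` are
#'   given directly.
#' @param prior_a,prior_b positive Beta pseudo-counts.
#' @param n_points number of grid points (default 201).
#' @return object of class `belief_grid`: list with `theta` (grid values)
#'   and `weights` (probability masses).
#' @examples
#' b <- init_belief(prior_a = 1, prior_b = 1)
#' belief_mean(b)  # 0.5
#' @export
init_belief <- function(params = NULL, prior_a = 1, prior_b = 1,
                        n_points = BELIEF_GRID_POINTS) {
  if (inherits(params, "subject_params")) {
    prior_a <- params$prior_a
    prior_b <- params$prior_b
  }
  if (prior_a <= 0 || prior_b <= 0) {
    stop("prior pseudo-counts must be positive", call. = FALSE)
  }
  theta <- seq(0, 1, length.out = n_points)
  dens <- stats::dbeta(theta, prior_a, prior_b)
  dens[!is.finite(dens)] <- 0  # open-interval Beta densities (a or b < 1)
  quad <- rep(1, n_points)
  quad[c(1L, n_points)] <- 0.5
  w <- dens * quad
  structure(list(theta = theta, weights = w / sum(w)), class = "belief_grid")
}

#' @export
print.belief_grid <- function(x, ...) {
  cat(sprintf("<belief grid: %d points, mean=%.4f sd=%.4f>\n",
              length(x$theta), belief_mean(x), belief_sd(x)))
  invisible(x)
}

#' Posterior mean of a belief grid
#' @param belief a `belief_grid`.
#' @return E[theta].
#' @export
belief_mean <- function(belief) sum(belief$theta * belief$weights)

#' Posterior standard deviation of a belief grid
#' @param belief a `belief_grid`.
#' @return sd(theta).
#' @export
belief_sd <- function(belief) {
  m <- belief_mean(belief)
  sqrt(max(sum((belief$theta - m)^2 * belief$weights), 0))
}

renormalize <- function(belief, lik) {
  w <- belief$weights * lik
  total <- sum(w)
  if (total <= 0 || !is.finite(total)) {
    stop("all-zero mass: update is incompatible with the belief's support",
         call. = FALSE)
  }
  belief$weights <- w / total
  belief
}

#' Update a belief from external feedback
#'
#' Bernoulli likelihood: weights multiplied pointwise by theta (correct) or
#' 1 - theta (error), then renormalised.
#'
#' @param belief a `belief_grid`.
#' @param outcome logical; TRUE = correct feedback.
#' @return updated `belief_grid`.
#' @export
update_feedback <- function(belief, outcome) {
  stopifnot(inherits(belief, "belief_grid"), is.logical(outcome) ||
              outcome %in% c(0, 1))
  lik <- if (isTRUE(as.logical(outcome))) belief$theta else 1 - belief$theta
  renormalize(belief, lik)
}

#' Update a belief from local confidence (soft evidence)
#'
#' Soft (Jeffrey-style) update in which the trial's correctness is observed
#' only through the confidence c that the choice was correct. With the
#' default `reference = 0.5` the weights are multiplied pointwise by
#' c * theta + (1 - c) * (1 - theta) and renormalised: c = 0.5 leaves the
#' belief unchanged and c = 1 reduces to correct feedback.
#'
#' `reference` sets the accuracy level at which confidence is uninformative.
#' The general likelihood is (c / p) * theta + ((1 - c) / (1 - p)) *
#' (1 - theta) with p = reference, which is the marginal likelihood of the
#' underlying evidence sample for a calibrated confidence observer whose
#' expected accuracy is p (the two densities of confidence given a correct
#' or an error trial enter only through the calibration ratios c / p and
#' (1 - c) / (1 - p)). At p = 0.5 this reduces exactly to the mixture rule
#' above, which treats any above-chance confidence as evidence for high
#' accuracy; the block simulator instead passes the observer's expected
#' accuracy for the task, so that confidence below expectation (typically
#' on error trials) pulls the belief down. See the methods vignette.
#'
#' Confidence below 0.5 is rejected: the perceptual module reports
#' confidence in the chosen option, which is never below chance.
#'
#' @param belief a `belief_grid`.
#' @param confidence value in [0.5, 1].
#' @param reference accuracy at which confidence carries no information,
#'   in (0, 1); default 0.5 (chance).
#' @return updated `belief_grid`.
#' @export
update_confidence <- function(belief, confidence, reference = 0.5) {
  stopifnot(inherits(belief, "belief_grid"))
  if (!is.numeric(confidence) || confidence < 0.5 || confidence > 1) {
    stop("confidence must lie in [0.5, 1]", call. = FALSE)
  }
  if (!is.numeric(reference) || reference <= 0 || reference >= 1) {
    stop("reference must lie in (0, 1)", call. = FALSE)
  }
  lik <- (confidence / reference) * belief$theta +
    ((1 - confidence) / (1 - reference)) * (1 - belief$theta)
  renormalize(belief, lik)
}

#' End-of-block task choice from two beliefs
#'
#' Computes p = P(theta_A > theta_B) + 0.5 P(theta_A = theta_B) over the
#' two independent grids, then chooses task A with probability
#' p^(1/T) / (p^(1/T) + (1-p)^(1/T)) (T = `policy_temperature`): T = 1 is
#' probability matching on p, T -> 0 is argmax.
#'
#' @param belief_a,belief_b `belief_grid`s on identical grids.
#' @param policy_temperature non-negative temperature.
#' @return list with `choice` ("A"/"B"), `p_a_better` (the posterior
#'   probability that A is the better task) and `p_choose_a` (the choice
#'   probability after the policy).
#' @export
choose_task <- function(belief_a, belief_b, policy_temperature = 1) {
  stopifnot(inherits(belief_a, "belief_grid"), inherits(belief_b, "belief_grid"))
  if (length(belief_a$theta) != length(belief_b$theta) ||
      any(belief_a$theta != belief_b$theta)) {
    stop("incompatible beliefs: grids differ", call. = FALSE)
  }
  wa <- belief_a$weights
  wb <- belief_b$weights
  # P(A > B) via the cumulative mass of B strictly below each grid point,
  # plus half the tied mass.
  cb <- cumsum(wb)
  below <- c(0, cb[-length(cb)])
  p <- sum(wa * (below + 0.5 * wb))
  p_choose <- if (policy_temperature == 0) {
    as.numeric(p > 0.5) + 0.5 * (p == 0.5)
  } else {
    la <- p^(1 / policy_temperature)
    lb <- (1 - p)^(1 / policy_temperature)
    la / (la + lb)
  }
  choice <- if (stats::runif(1) < p_choose) "A" else "B"
  list(choice = choice, p_a_better = p, p_choose_a = p_choose)
}

#' End-of-block ability rating from a belief
#'
#' Maps the posterior mean accuracy onto the 50-100 reporting scale
#' ("chance" to "perfect"): 100 * max(mean, 0.5), clipped to [50, 100].
#'
#' @param belief a `belief_grid`.
#' @return rating in [50, 100].
#' @export
rate_task <- function(belief) {
  stopifnot(inherits(belief, "belief_grid"))
  min(max(100 * belief_mean(belief), 50), 100)
}

#' Simulate one learning block
#'
#' Runs the perceptual module on each trial of the block and feeds the
#' learner: the cued task's belief is updated via \code{update_feedback}
#' on feedback tasks and via \code{update_confidence} with the trial's
#' internal confidence on no-feedback and confidence-rating tasks. Beliefs
#' are initialised afresh at block start (each block features two new
#' tasks). Ends with a task choice and, when `with_ratings`, per-task
#' ability ratings.
#'
#' @param params a `subject_params`.
#' @param block one element of `design$blocks` (conditions + trial count).
#' @param block_trials the block's rows of `design$trials`.
#' @param with_ratings include end-of-block ability ratings (experiment 1).
#' @param keep_trajectory return per-trial posterior summaries.
#' @return list with `trials` (trial outcomes), `record` (one-row
#'   data.frame block summary) and optionally `trajectory`.
#' @export
run_block <- function(params, block, block_trials, with_ratings = FALSE,
                      keep_trajectory = FALSE) {
  conds <- block$conditions
  sig <- vapply(conds, `[[`, 0, "signal")[block_trials$task_index]
  sim <- simulate_trial(params, signal = sig,
                        target_side = block_trials$target_side,
                        difficulty = block_trials$difficulty,
                        feedback_mode = block_trials$feedback_mode)
  trials <- cbind(block_trials,
                  sim[, c("evidence", "choice", "correct", "confidence",
                          "rt_ms", "feedback_shown")])

  beliefs <- list(init_belief(params), init_belief(params))
  n <- nrow(trials)
  traj <- if (keep_trajectory) {
    data.frame(trial = seq_len(n), task_index = trials$task_index,
               post_mean = NA_real_, post_sd = NA_real_)
  }
  # confidence is evaluated against the task's difficulty-based expectation:
  # the accuracy a reference observer (unit sensitivity) attains at the
  # task's evidence strength. Task difficulty is perceptually observable
  # (the dot difference), own ability is not — it is what is being learned.
  expected_acc <- stats::pnorm(vapply(conds, `[[`, 0, "signal"))
  for (i in seq_len(n)) {
    t_idx <- trials$task_index[i]
    if (trials$feedback_mode[i] == "feedback") {
      beliefs[[t_idx]] <- update_feedback(beliefs[[t_idx]], trials$correct[i])
    } else {
      beliefs[[t_idx]] <- update_confidence(beliefs[[t_idx]],
                                            trials$confidence[i],
                                            reference = expected_acc[t_idx])
    }
    if (keep_trajectory) {
      traj$post_mean[i] <- belief_mean(beliefs[[t_idx]])
      traj$post_sd[i] <- belief_sd(beliefs[[t_idx]])
    }
  }

  pick <- choose_task(beliefs[[1L]], beliefs[[2L]], params$policy_temperature)
  task_stat <- function(t_idx, col) mean(trials[[col]][trials$task_index == t_idx])
  record <- data.frame(
    block = block$block, pairing = block$pairing,
    duration = block$trials_per_task,
    a_difficulty = conds[[1L]]$difficulty,
    a_feedback_mode = conds[[1L]]$feedback_mode,
    b_difficulty = conds[[2L]]$difficulty,
    b_feedback_mode = conds[[2L]]$feedback_mode,
    a_acc = task_stat(1L, "correct"), b_acc = task_stat(2L, "correct"),
    a_rt = task_stat(1L, "rt_ms"), b_rt = task_stat(2L, "rt_ms"),
    a_conf = task_stat(1L, "confidence"), b_conf = task_stat(2L, "confidence"),
    a_post_mean = belief_mean(beliefs[[1L]]),
    a_post_sd = belief_sd(beliefs[[1L]]),
    b_post_mean = belief_mean(beliefs[[2L]]),
    b_post_sd = belief_sd(beliefs[[2L]]),
    task_choice = as.integer(pick$choice == "A"),
    p_choose_a = pick$p_choose_a,
    a_rating = if (with_ratings) rate_task(beliefs[[1L]]) else NA_real_,
    b_rating = if (with_ratings) rate_task(beliefs[[2L]]) else NA_real_,
    stringsAsFactors = FALSE
  )
  out <- list(trials = trials, record = record, beliefs = beliefs)
  if (keep_trajectory) out$trajectory <- traj
  out
}
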