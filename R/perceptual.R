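# Signal-detection perceptual module: internal evidence, choice, confidence
# and response time for a single trial, plus maximum-likelihood recovery of
# the sensitivity parameters from trial data.
#
# Evidence on a trial is x ~ N(s * k_ch * signal, 1), with s = +1 when the
# target is on the right and -1 when it is on the left (evidence variance is
# fixed at 1; all scaling lives in k * signal). The choice is the sign of x.
# Confidence is the posterior probability that the chosen side is correct
# for an observer whose assumed sensitivity is k_conf:
#   confidence = 1 / (1 + exp(-2 * k_conf * signal * |x|))
# which allows confidence sensitivity to differ from choice sensitivity.

#' Generative parameters of one simulated subject
#'
#' @param k_ch positive choice sensitivity multiplier.
#' @param k_conf positive confidence sensitivity multiplier.
#' @param prior_a,prior_b positive Beta pseudo-counts of the SPE learner's
#'   prior over task accuracy (default flat).
#' @param policy_temperature non-negative; 1 = probability matching on
#'   P(theta_A > theta_B) at end-of-block choice, 0 = argmax.
#' @param rt_location_easy,rt_location_difficult log-ms locations of the
#'   lognormal RT model; defaults target population mean RTs of 672 ms
#'   (easy) and 707 ms (difficult).
#' @param rt_scale positive lognormal scale (log-ms sd).
#' @param lapse_rate probability of a uniform random choice (default 0,
#'   i.e. no lapses).
#' @param seed integer subject-level seed.
#' @return object of class `subject_params`.
#' @export
subject_params <- function(k_ch = 1, k_conf = 1,
                           prior_a = 1, prior_b = 1,
                           policy_temperature = 1,
                           rt_scale = 0.3,
                           rt_location_easy = log(672) - rt_scale^2 / 2,
                           rt_location_difficult = log(707) - rt_scale^2 / 2,
                           lapse_rate = 0,
                           seed = NA_integer_) {
  stopifnot(k_ch > 0, k_conf > 0, prior_a > 0, prior_b > 0,
            rt_scale > 0 || rt_scale == 0, policy_temperature >= 0,
            lapse_rate >= 0, lapse_rate < 1)
  structure(
    list(k_ch = k_ch, k_conf = k_conf,
         prior_a = prior_a, prior_b = prior_b,
         policy_temperature = policy_temperature,
         rt_location_easy = rt_location_easy,
         rt_location_difficult = rt_location_difficult,
         rt_scale = rt_scale, lapse_rate = lapse_rate,
         seed = seed),
    class = "subject_params"
  )
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf("<subject k_ch=%.3f k_conf=%.3f prior=Beta(%g,%g) temp=%g>\n",
              x$k_ch, x$k_conf, x$prior_a, x$prior_b, x$policy_temperature))
  invisible(x)
}

#' Confidence mapping of the perceptual module
#'
#' Posterior probability that the chosen side is correct, for an observer
#' with confidence sensitivity `k_conf` observing absolute evidence
#' `abs_evidence` at evidence strength `signal`.
#'
#' @param abs_evidence non-negative |x|.
#' @param k_conf positive confidence sensitivity.
#' @param signal positive evidence strength.
#' @return confidence in [0.5, 1).
#' @examples
#' confidence_map(0, 1, 1)  # 0.5 at zero evidence
#' @export
confidence_map <- function(abs_evidence, k_conf, signal) {
  stats::plogis(2 * k_conf * signal * abs_evidence)
}

#' Simulate one or more trials of the perceptual module
#'
#' Draws internal evidence, choice, correctness, confidence and RT. All
#' arguments except `params` may be vectors (recycled to the longest).
#'
#' @param params a `subject_params`.
#' @param condition a `task_condition`, or NULL if `signal`/`difficulty`
#'   are given directly.
#' @param target_side "left"/"right" (vector allowed).
#' @param signal,difficulty,feedback_mode trial condition fields, taken from
#'   `condition` when supplied.
#' @param n number of trials (defaults to the longest vector argument).
#' @return data.frame with columns evidence, choice, correct, confidence,
#'   rt_ms, feedback_shown (one row per trial).
#' @examples
#' p <- subject_params(seed = 1)
#' with_seed(1, simulate_trial(p, task_condition("easy", "feedback"), "left"))
#' @export
simulate_trial <- function(params, condition = NULL, target_side = "right",
                           signal = NULL, difficulty = NULL,
                           feedback_mode = NULL, n = NULL) {
  if (!is.null(condition)) {
    stopifnot(inherits(condition, "task_condition"))
    signal <- condition$signal
    difficulty <- condition$difficulty
    feedback_mode <- condition$feedback_mode
  }
  if (is.null(signal) || any(!is.finite(signal)) || any(signal <= 0)) {
    stop("invalid-condition: signal must be positive", call. = FALSE)
  }
  if (is.null(feedback_mode)) feedback_mode <- "none"
  if (is.null(n)) n <- max(length(signal), length(target_side),
                           length(difficulty))
  signal <- rep_len(signal, n)
  target_side <- rep_len(target_side, n)
  difficulty <- rep_len(if (is.null(difficulty)) NA_character_ else difficulty, n)
  feedback_mode <- rep_len(feedback_mode, n)

  s <- ifelse(target_side == "right", 1, -1)
  x <- stats::rnorm(n, mean = s * params$k_ch * signal, sd = 1)
  choice <- ifelse(x > 0, "right", "left")
  if (params$lapse_rate > 0) {
    lapse <- stats::runif(n) < params$lapse_rate
    choice[lapse] <- sample(c("left", "right"), sum(lapse), replace = TRUE)
  }
  correct <- choice == target_side
  confidence <- confidence_map(abs(x), params$k_conf, signal)
  loc <- ifelse(!is.na(difficulty) & difficulty == "difficult",
                params$rt_location_difficult, params$rt_location_easy)
  rt_ms <- if (params$rt_scale > 0) {
    stats::rlnorm(n, meanlog = loc, sdlog = params$rt_scale)
  } else {
    exp(loc)
  }
  feedback_shown <- ifelse(feedback_mode == "feedback",
                           ifelse(correct, "correct", "incorrect"), "none")
  data.frame(signal = signal, difficulty = difficulty,
             target_side = target_side, evidence = x, choice = choice,
             correct = correct, confidence = confidence, rt_ms = rt_ms,
             feedback_shown = feedback_shown,
             stringsAsFactors = FALSE)
}

#' Closed-form choice accuracy of the perceptual module
#'
#' @param params a `subject_params` (or a numeric `k_ch`).
#' @param condition a `task_condition` (or a numeric `signal`).
#' @return Phi(k_ch * signal), the large-sample accuracy.
#' @examples
#' choice_accuracy(1, 1.0364)  # 0.85
#' @export
choice_accuracy <- function(params, condition) {
  k_ch <- if (inherits(params, "subject_params")) params$k_ch else params
  signal <- if (inherits(condition, "task_condition")) condition$signal else condition
  if (any(signal <= 0)) stop("invalid-condition: signal must be positive",
                             call. = FALSE)
  stats::pnorm(k_ch * signal)
}

#' Calibrate an evidence strength to a target accuracy
#'
#' Inverse of \code{\link{choice_accuracy}}: qnorm(target) / k_ch.
#'
#' @param target_accuracy accuracy in (0.5, 1).
#' @param k_ch positive choice sensitivity (default 1).
#' @return the signal achieving the target accuracy.
#' @examples
#' calibrate_signal(0.85)  # 1.0364
#' @export
calibrate_signal <- function(target_accuracy, k_ch = 1) {
  if (any(target_accuracy <= 0.5) || any(target_accuracy >= 1)) {
    stop("target_accuracy must lie in (0.5, 1)", call. = FALSE)
  }
  stats::qnorm(target_accuracy) / k_ch
}

#' Sample response times
#'
#' Lognormal RT model with a difficulty-specific location and shared scale;
#' the model is independent of the trial's evidence given difficulty and
#' exists to provide the rtDiff regressor with realistic structure
#' (easy trials faster than difficult).
#'
#' @param params a `subject_params`.
#' @param condition a `task_condition` (or a difficulty string).
#' @param n number of draws.
#' @return RTs in ms.
#' @export
sample_rt <- function(params, condition, n = 1L) {
  difficulty <- if (inherits(condition, "task_condition")) {
    condition$difficulty
  } else {
    match.arg(condition, DIFFICULTY_LEVELS)
  }
  loc <- if (difficulty == "difficult") params$rt_location_difficult else
    params$rt_location_easy
  if (params$rt_scale == 0) return(rep(exp(loc), n))
  stats::rlnorm(n, meanlog = loc, sdlog = params$rt_scale)
}

CONF_EPS <- 1e-4

#' Maximum-likelihood recovery of the perceptual sensitivities
#'
#' `k_ch` maximises the Bernoulli likelihood of correctness,
#' prod Phi(k_ch s)^correct (1 - Phi)^(1-correct), across signal levels.
#' `k_conf` maximises the confidence likelihood obtained by
#' change-of-variables from the evidence: the reported confidence implies
#' |x| = logit(confidence) / (2 k_conf signal); the likelihood is the
#' Gaussian density of the signed evidence given stimulus side (mean
#' +/- k_ch_hat * signal) at the implied value, times the Jacobian
#' 1 / (2 k_conf signal c (1-c)). Confidence values at the scale bounds are
#' clipped to [0.5 + 1e-4, 1 - 1e-4] before inversion.
#'
#' @param trials data.frame with columns `correct` (logical/0-1) and
#'   `signal` (or `difficulty`, mapped through `signals`); for the
#'   confidence fit also `confidence` (in [0.5, 1] or [50, 100]),
#'   `choice` and `target_side`.
#' @param signals named difficulty -> signal map used when the table has no
#'   `signal` column.
#' @param bounds optimisation box for both sensitivities.
#' @return list with `k_ch`, `k_conf` (NA if no usable confidence),
#'   `loglik_choice`, `loglik_conf`, `convergence`, `boundary` flags.
#' @export
fit_perceptual_params <- function(trials, signals = default_signals(),
                                  bounds = c(1e-4, 1e3)) {
  if (!("signal" %in% names(trials))) {
    if (!("difficulty" %in% names(trials))) {
      stop("trials need a `signal` or `difficulty` column", call. = FALSE)
    }
    trials$signal <- unname(signals[trials$difficulty])
  }
  correct <- as.logical(trials$correct)
  sig <- trials$signal
  if (length(unique(sig)) < 2L) {
    warning("single signal level: k_ch identified only up to the signal scale")
  }

  nll_choice <- function(log_k) {
    p <- stats::pnorm(exp(log_k) * sig)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(ifelse(correct, log(p), log1p(-p)))
  }
  if (all(correct) || !any(correct)) {
    # likelihood monotone in k: no interior maximum
    warning("all-correct or all-error data: k_ch estimate at box constraint")
    k_ch_hat <- if (all(correct)) bounds[2L] else bounds[1L]
    opt_ch <- list(minimum = log(k_ch_hat), objective = nll_choice(log(k_ch_hat)))
    boundary_ch <- TRUE
  } else {
    opt_ch <- stats::optimize(nll_choice, log(bounds))
    k_ch_hat <- exp(opt_ch$minimum)
    boundary_ch <- opt_ch$minimum <= log(bounds[1L]) + 1e-2 ||
      opt_ch$minimum >= log(bounds[2L]) - 1e-2
    if (boundary_ch) warning("k_ch estimate at box constraint")
  }

  k_conf_hat <- NA_real_
  ll_conf <- NA_real_
  boundary_conf <- FALSE
  if ("confidence" %in% names(trials) && any(!is.na(trials$confidence))) {
    keep <- !is.na(trials$confidence)
    conf <- trials$confidence[keep]
    if (max(conf) > 1) conf <- conf / 100  # reporting scale 50-100
    conf <- pmin(pmax(conf, 0.5 + CONF_EPS), 1 - CONF_EPS)
    sgn <- ifelse(trials$choice[keep] == "right", 1, -1)
    mu <- ifelse(trials$target_side[keep] == "right", 1, -1) *
      k_ch_hat * trials$signal[keep]
    sig_c <- trials$signal[keep]
    lq <- stats::qlogis(conf)
    nll_conf <- function(log_k) {
      k <- exp(log_k)
      absx <- lq / (2 * k * sig_c)
      x <- sgn * absx
      # Jacobian of conf -> |x|: 1 / (2 k signal c (1-c))
      -sum(stats::dnorm(x, mean = mu, sd = 1, log = TRUE) -
             log(2 * k * sig_c * conf * (1 - conf)))
    }
    opt_cf <- stats::optimize(nll_conf, log(bounds))
    k_conf_hat <- exp(opt_cf$minimum)
    ll_conf <- -opt_cf$objective
    boundary_conf <- opt_cf$minimum <= log(bounds[1L]) + 1e-2 ||
      opt_cf$minimum >= log(bounds[2L]) - 1e-2
    if (boundary_conf) warning("k_conf estimate at box constraint")
  }

  list(k_ch = k_ch_hat, k_conf = k_conf_hat,
       loglik_choice = -opt_ch$objective, loglik_conf = ll_conf,
       convergence = TRUE,
       boundary = c(k_ch = boundary_ch, k_conf = boundary_conf))
}
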