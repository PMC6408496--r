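# Type-1 and type-2 signal-detection metrics: d', maximum-likelihood
# meta-d', metacognitive efficiency (meta-d'/d') and AUROC2.
#
# Convention: the two boxes map to SDT stimulus classes S1 = target left,
# S2 = target right; the "response" is the chosen side. Confidence is
# discretised into bins (subject-level quantile bins by default) before
# meta-d' fitting. Zero hit/false-alarm cells are handled by the log-linear
# correction (add 0.5 to each cell of the collapsed 2x2 table), so results
# are reproducible bit-for-bit.

#' Tabulate type-2 confidence counts
#'
#' Builds the 2 (stimulus side) x 2 (response side) x n_bins confidence
#' count table consumed by the meta-d' fit. Continuous confidence is binned
#' by subject-level quantiles (default) or by fixed edges; when the
#' confidence distribution is too degenerate to support the requested
#' number of bins the table collapses to fewer bins with a warning.
#'
#' @param trials data.frame with columns `target_side`, `choice`,
#'   `confidence` (0.5-1 or 50-100 scale).
#' @param n_bins number of confidence bins (>= 2).
#' @param binning "quantile" or "fixed".
#' @param edges bin edges for fixed binning (length n_bins + 1).
#' @return object of class `type2_counts`: list with `counts`
#'   (2 x 2 x n_bins array, dimnames stimulus/response/bin) and `n_bins`.
#' @export
tabulate_type2 <- function(trials, n_bins = 4L, binning = c("quantile", "fixed"),
                           edges = NULL) {
  binning <- match.arg(binning)
  stopifnot(n_bins >= 2L)
  conf <- trials$confidence
  if (length(conf) && max(conf, na.rm = TRUE) > 1) conf <- conf / 100
  n <- nrow(trials)
  if (n == 0L) {
    counts <- array(0L, dim = c(2L, 2L, n_bins),
                    dimnames = list(stimulus = c("S1", "S2"),
                                    response = c("R1", "R2"),
                                    bin = seq_len(n_bins)))
    return(structure(list(counts = counts, n_bins = n_bins, breaks = NULL),
                     class = "type2_counts"))
  }
  if (binning == "quantile") {
    breaks <- unique(stats::quantile(conf, probs = seq(0, 1, length.out = n_bins + 1),
                                     na.rm = TRUE, names = FALSE))
    if (length(breaks) < 3L) {
      warning("degenerate confidence distribution: collapsed to fewer bins")
      breaks <- unique(c(min(conf), stats::median(conf), max(conf)))
      if (length(breaks) < 2L) breaks <- c(breaks, breaks + 1e-9)
    } else if (length(breaks) < n_bins + 1L) {
      warning("degenerate confidence distribution: collapsed to fewer bins")
    }
  } else {
    if (is.null(edges)) stop("fixed binning requires `edges`", call. = FALSE)
    breaks <- edges
  }
  bin <- cut(conf, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  k <- length(breaks) - 1L
  stim <- factor(ifelse(trials$target_side == "right", "S2", "S1"),
                 levels = c("S1", "S2"))
  resp <- factor(ifelse(trials$choice == "right", "R2", "R1"),
                 levels = c("R1", "R2"))
  counts <- table(stimulus = stim, response = resp,
                  bin = factor(bin, levels = seq_len(k)))
  counts <- array(as.integer(counts), dim = c(2L, 2L, k),
                  dimnames = list(stimulus = c("S1", "S2"),
                                  response = c("R1", "R2"),
                                  bin = seq_len(k)))
  structure(list(counts = counts, n_bins = k, breaks = breaks),
            class = "type2_counts")
}

#' @export
print.type2_counts <- function(x, ...) {
  cat(sprintf("<type-2 counts: %d bins, %d trials>\n", x$n_bins,
              sum(x$counts)))
  invisible(x)
}

# Collapse a type-2 table to the 2x2 stimulus x response table, applying
# the log-linear correction when any marginal rate is 0 or 1.
collapsed_rates <- function(counts) {
  tab <- apply(counts$counts, c(1L, 2L), sum)
  if (any(rowSums(tab) == 0)) {
    stop("undefined-d': a stimulus class is absent", call. = FALSE)
  }
  if (any(tab == 0)) tab <- tab + 0.5
  hr <- tab["S2", "R2"] / sum(tab["S2", ])   # P(respond right | target right)
  far <- tab["S1", "R2"] / sum(tab["S1", ])  # P(respond right | target left)
  list(hr = hr, far = far)
}

#' Type-1 sensitivity and criterion
#'
#' d' = z(hit rate) - z(false-alarm rate) and c = -(z(H) + z(F)) / 2, with
#' the log-linear correction (add 0.5 to each cell) applied when any cell
#' of the collapsed table is zero.
#'
#' @param counts a `type2_counts` (or anything \code{\link{tabulate_type2}}
#'   accepts, forwarded with 2 bins).
#' @return list with `d_prime`, `criterion`, `hit_rate`, `fa_rate`.
#' @examples
#' # H = 0.85, F = 0.15 -> d' = 2.0728
#' @export
compute_dprime <- function(counts) {
  if (!inherits(counts, "type2_counts")) counts <- tabulate_type2(counts, 2L)
  r <- collapsed_rates(counts)
  list(d_prime = stats::qnorm(r$hr) - stats::qnorm(r$far),
       criterion = -0.5 * (stats::qnorm(r$hr) + stats::qnorm(r$far)),
       hit_rate = r$hr, fa_rate = r$far)
}

# Predicted type-2 probabilities P(bin | stimulus, response) under the
# meta-d' model: evidence ~ N(-/+ meta_d/2, 1), type-1 criterion at
# meta_c = meta_d * (c1 / d1), type-2 criteria around it.
meta_d_type2_probs <- function(meta_d, t2c_rS1, t2c_rS2, c_ratio) {
  meta_c <- meta_d * c_ratio
  k <- length(t2c_rS1) + 1L
  mu <- c(S1 = -meta_d / 2, S2 = meta_d / 2)
  out <- array(NA_real_, dim = c(2L, 2L, k))
  bounds_l <- c(-Inf, t2c_rS1, meta_c)  # response R1 region, ascending
  bounds_r <- c(meta_c, t2c_rS2, Inf)   # response R2 region, ascending
  for (s in 1:2) {
    pl <- diff(stats::pnorm(bounds_l - mu[s]))
    pr <- diff(stats::pnorm(bounds_r - mu[s]))
    # leftmost R1 interval = highest confidence; rightmost R2 = highest
    out[s, 1L, ] <- rev(pl) / sum(pl)
    out[s, 2L, ] <- pr / sum(pr)
  }
  out
}

meta_d_nll <- function(par, counts, c_ratio) {
  k <- dim(counts)[3L]
  meta_d <- par[1L]
  meta_c <- meta_d * c_ratio
  t2c_rS1 <- meta_c - rev(cumsum(exp(par[2:k])))
  t2c_rS2 <- meta_c + cumsum(exp(par[(k + 1L):(2L * k - 1L)]))
  p <- meta_d_type2_probs(meta_d, t2c_rS1, t2c_rS2, c_ratio)
  -sum(counts * log(pmax(p, 1e-12)))
}

#' Maximum-likelihood meta-d'
#'
#' Fits meta-d' under the standard equal-variance type-2 SDT model: the
#' type-1 criterion is held at its empirical relative position
#' (meta-c = meta-d' * c/d') and the type-2 criteria are free, maximising
#' the multinomial likelihood of the confidence-bin counts conditional on
#' stimulus and response.
#'
#' @param counts a `type2_counts`.
#' @param lower,upper box for meta-d'.
#' @return list with `meta_d`, `d_prime`, `criterion`, `efficiency`
#'   (meta-d'/d'), `loglik`, `convergence`, `t2_criteria`.
#' @export
fit_meta_d <- function(counts, lower = -5, upper = 10) {
  stopifnot(inherits(counts, "type2_counts"))
  k <- counts$n_bins
  if (k < 2L) {
    warning("degenerate confidence (single effective bin): meta-d' = 0")
    t1 <- compute_dprime(counts)
    return(list(meta_d = 0, d_prime = t1$d_prime, criterion = t1$criterion,
                efficiency = 0, loglik = NA_real_, convergence = TRUE,
                t2_criteria = NULL))
  }
  t1 <- compute_dprime(counts)
  if (abs(t1$d_prime) < 1e-10) {
    stop("efficiency undefined: d' is zero", call. = FALSE)
  }
  c_ratio <- t1$criterion / t1$d_prime
  init <- c(t1$d_prime, rep(log(0.5), 2L * k - 2L))
  fit <- stats::optim(init, meta_d_nll, counts = counts$counts,
                      c_ratio = c_ratio, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-10))
  # polish with a second start to guard against simplex stalls
  fit2 <- stats::optim(fit$par, meta_d_nll, counts = counts$counts,
                       c_ratio = c_ratio, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-10))
  if (fit2$value < fit$value) fit <- fit2
  meta_d <- min(max(fit$par[1L], lower), upper)
  meta_c <- meta_d * c_ratio
  list(meta_d = meta_d, d_prime = t1$d_prime, criterion = t1$criterion,
       efficiency = meta_d / t1$d_prime, loglik = -fit$value,
       convergence = fit$convergence == 0,
       t2_criteria = list(
         rS1 = meta_c - rev(cumsum(exp(fit$par[2:k]))),
         rS2 = meta_c + cumsum(exp(fit$par[(k + 1L):(2L * k - 1L)]))))
}

#' Area under the type-2 ROC
#'
#' Probability that a randomly drawn correct trial carries higher
#' confidence than a randomly drawn error trial, ties counting one half
#' (equivalent to trapezoidal integration of the type-2 ROC). Computed via
#' midranks.
#'
#' @param correctness logical/0-1 vector.
#' @param confidence numeric vector, same length.
#' @return AUROC2 in [0, 1].
#' @examples
#' auroc2(c(1, 1, 0, 0), c(0.9, 0.8, 0.8, 0.6))  # 0.875
#' @export
auroc2 <- function(correctness, confidence) {
  stopifnot(length(correctness) == length(confidence))
  correct <- as.logical(correctness)
  n1 <- sum(correct)
  n0 <- sum(!correct)
  if (n1 == 0L || n0 == 0L) {
    stop("AUROC2 undefined: need at least one correct and one error trial",
         call. = FALSE)
  }
  r <- rank(confidence)  # midranks handle ties as 1/2
  (sum(r[correct]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Metacognitive efficiency of a trial set
#'
#' meta-d'/d' computed separately per difficulty level (the meta-d'
#' framework assumes constant signal strength) and averaged, plus the
#' pooled AUROC2. A missing difficulty level yields a partial result with
#' `partial = TRUE`.
#'
#' @param trials data.frame with `difficulty`, `target_side`, `choice`,
#'   `correct`, `confidence`.
#' @param n_bins confidence bins for the meta-d' fit.
#' @return object of class `metacog_result`: list with `efficiency`
#'   (averaged), `auroc2`, `by_difficulty` (per-level data.frame),
#'   `partial`.
#' @export
metacog_efficiency <- function(trials, n_bins = 4L) {
  levels_present <- intersect(DIFFICULTY_LEVELS, unique(trials$difficulty))
  partial <- length(levels_present) < length(DIFFICULTY_LEVELS)
  if (partial) warning("difficulty level missing: partial efficiency result")
  per <- lapply(levels_present, function(d) {
    sub <- trials[trials$difficulty == d, , drop = FALSE]
    cnt <- tabulate_type2(sub, n_bins)
    fit <- fit_meta_d(cnt)
    data.frame(difficulty = d, d_prime = fit$d_prime, meta_d = fit$meta_d,
               efficiency = fit$efficiency, n_trials = nrow(sub),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(
    list(efficiency = mean(per$efficiency),
         auroc2 = auroc2(trials$correct, trials$confidence),
         by_difficulty = per, partial = partial),
    class = "metacog_result"
  )
}

#' @export
print.metacog_result <- function(x, ...) {
  cat(sprintf("<metacognition: efficiency=%.3f auroc2=%.3f%s>\n",
              x$efficiency, x$auroc2, if (x$partial) " (partial)" else ""))
  invisible(x)
}
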