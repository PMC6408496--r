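# Statistical pipeline: subject exclusions, RT trimming, repeated-measures
# ANOVA with transforms, JZS Bayes-factor paired t-tests, fixed-effect
# regressions with BIC comparison and sequential orthogonalisation, block
# splits, duration and recency regressions, choice/rating consistency and
# between-subject correlations.

#' Apply the subject-level exclusion screen
#'
#' Removes subjects (i) whose overall accuracy is not above chance — a
#' one-sided binomial test of correct-trial count against 0.5 at alpha —
#' (ii) who always select the same confidence/ability rating (zero
#' variance), and (iii), when a comprehension table is supplied
#' (experiment-3 style), whose "perfect" comprehension rating is not at
#' least `comprehension_gap` points above their "chance" rating.
#'
#' @param dataset an `spe_dataset` (see \code{\link{simulate_cohort}}).
#' @param alpha significance level of the above-chance binomial test.
#' @param comprehension optional data.frame with columns `subject`,
#'   `chance_rating`, `perfect_rating`.
#' @param comprehension_gap required separation on the rating scale.
#' @return list with `dataset` (kept subjects) and `report` (data.frame of
#'   excluded subjects and the rule each triggered).
#' @export
exclude_subjects <- function(dataset, alpha = 0.05, comprehension = NULL,
                             comprehension_gap = 10) {
  trials <- dataset$trials
  blocks <- dataset$blocks
  if (is.null(trials) || nrow(trials) == 0L) stop("empty dataset", call. = FALSE)
  subjects <- unique(trials$subject)
  rules <- list()
  for (s in subjects) {
    tr <- trials[trials$subject == s, , drop = FALSE]
    n_correct <- sum(tr$correct)
    p <- stats::binom.test(n_correct, nrow(tr), p = 0.5,
                           alternative = "greater")$p.value
    if (p >= alpha) {
      rules[[length(rules) + 1L]] <- data.frame(
        subject = s, rule = "chance_responding", stringsAsFactors = FALSE)
    }
    ratings <- c(tr$confidence[!is.na(tr$confidence)])
    if (!is.null(blocks)) {
      bl <- blocks[blocks$subject == s, , drop = FALSE]
      if ("a_rating" %in% names(bl)) {
        ratings <- c(ratings, bl$a_rating[!is.na(bl$a_rating)],
                     bl$b_rating[!is.na(bl$b_rating)])
      }
    }
    if (length(ratings) > 1L && stats::sd(ratings) == 0) {
      rules[[length(rules) + 1L]] <- data.frame(
        subject = s, rule = "constant_rating", stringsAsFactors = FALSE)
    }
    if (!is.null(comprehension)) {
      row <- comprehension[comprehension$subject == s, , drop = FALSE]
      if (nrow(row) == 1L &&
          row$perfect_rating - row$chance_rating < comprehension_gap) {
        rules[[length(rules) + 1L]] <- data.frame(
          subject = s, rule = "comprehension_failure", stringsAsFactors = FALSE)
      }
    }
  }
  report <- if (length(rules)) do.call(rbind, rules) else
    data.frame(subject = character(), rule = character(),
               stringsAsFactors = FALSE)
  drop <- unique(report$subject)
  kept <- dataset
  kept$trials <- trials[!(trials$subject %in% drop), , drop = FALSE]
  if (!is.null(blocks)) {
    kept$blocks <- blocks[!(blocks$subject %in% drop), , drop = FALSE]
  }
  list(dataset = kept, report = report)
}

#' Trim RT outliers
#'
#' Single-pass removal of trials whose RT lies beyond `n_sd` standard
#' deviations from the mean, computed per subject. Subjects with fewer
#' than 3 trials are left untrimmed with a warning.
#'
#' @param trials trial-level data.frame with `subject` and `rt_ms`.
#' @param n_sd trimming threshold in standard deviations.
#' @return list with `trials` (kept rows) and `removed_fraction`.
#' @export
trim_rt_outliers <- function(trials, n_sd = 3) {
  keep <- rep(TRUE, nrow(trials))
  for (s in unique(trials$subject)) {
    idx <- which(trials$subject == s)
    if (length(idx) < 3L) {
      warning("fewer than 3 trials for a subject: no trimming applied")
      next
    }
    rt <- trials$rt_ms[idx]
    sdev <- stats::sd(rt)
    if (sdev == 0) next
    keep[idx] <- abs(rt - mean(rt)) <= n_sd * sdev
  }
  list(trials = trials[keep, , drop = FALSE],
       removed_fraction = mean(!keep))
}

# Rank-to-normal (van der Waerden) transform within a vector.
rank_normal <- function(x) stats::qnorm((rank(x) - 0.5) / length(x))

#' 2 x 2 repeated-measures ANOVA
#'
#' Classical two-way repeated-measures ANOVA (subject as random factor) on
#' one value per subject per cell of the Difficulty x Feedback design.
#' Proportions can be arcsine-square-root transformed
#' (asin(sqrt(p))) beforehand; ratings can be z-scored per subject
#' non-parametrically (rank-to-normal transform).
#'
#' @param data data.frame with columns `subject`, `difficulty`, `feedback`
#'   and `value` — exactly one row per subject x cell.
#' @param transform "none" or "arcsine_sqrt".
#' @param zscore "none" or "rank_normal" (applied per subject, after any
#'   transform).
#' @return data.frame with one row per effect (Difficulty, Feedback,
#'   interaction): F, df1, df2, p.
#' @export
anova_2x2_rm <- function(data, transform = c("none", "arcsine_sqrt"),
                         zscore = c("none", "rank_normal")) {
  transform <- match.arg(transform)
  zscore <- match.arg(zscore)
  need <- c("subject", "difficulty", "feedback", "value")
  stopifnot(all(need %in% names(data)))
  tab <- table(data$subject, data$difficulty, data$feedback)
  if (any(tab != 1L)) {
    stop("unbalanced design: need exactly one value per subject per cell",
         call. = FALSE)
  }
  y <- data$value
  if (transform == "arcsine_sqrt") {
    if (any(y < 0 | y > 1)) stop("arcsine transform requires proportions",
                                 call. = FALSE)
    y <- asin(sqrt(y))
  }
  if (zscore == "rank_normal") {
    y <- stats::ave(y, data$subject, FUN = rank_normal)
  }
  d <- data.frame(subject = factor(data$subject),
                  difficulty = factor(data$difficulty),
                  feedback = factor(data$feedback),
                  value = y)
  fit <- stats::aov(value ~ difficulty * feedback +
                      Error(subject / (difficulty * feedback)), data = d)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tabs <- sm[[stratum]][[1L]]
    i <- grep(term, trimws(rownames(tabs)), fixed = TRUE)[1L]
    j <- grep("Residuals", trimws(rownames(tabs)), fixed = TRUE)[1L]
    f <- tabs[i, "F value"]
    p <- tabs[i, "Pr(>F)"]
    if (tabs[i, "Sum Sq"] < 1e-12) {  # null effect: report F = 0 even when
      f <- 0                          # the error stratum is also degenerate
      p <- 1
    }
    data.frame(effect = term, F = f,
               df1 = tabs[i, "Df"], df2 = tabs[j, "Df"],
               p = p, stringsAsFactors = FALSE)
  }
  out <- rbind(pull("Error: subject:difficulty", "difficulty"),
               pull("Error: subject:feedback", "feedback"),
               pull("Error: subject:difficulty:feedback", "difficulty:feedback"))
  rownames(out) <- NULL
  out
}

# JZS marginal likelihood of t under H1: effect size delta ~ Cauchy(0, r);
# t | delta ~ noncentral t with ncp = delta * sqrt(n).
jzs_bf10 <- function(t, n, prior_scale = 0.707) {
  nu <- n - 1
  h1 <- stats::integrate(function(delta) {
    suppressWarnings(stats::dt(t, df = nu, ncp = delta * sqrt(n))) *
      stats::dcauchy(delta, location = 0, scale = prior_scale)
  }, -Inf, Inf, rel.tol = 1e-9)$value
  h0 <- stats::dt(t, df = nu)
  h1 / h0
}

#' Paired t-test with a JZS Bayes factor
#'
#' Classical paired t-test plus the default Bayesian t-test: the Bayes
#' factor BF10 under a zero-centred Cauchy prior (scale 0.707 by default)
#' on the standardised effect size, computed by numerical integration of
#' the noncentral-t marginal likelihood.
#'
#' @param x,y equal-length paired samples.
#' @param prior_scale Cauchy prior scale.
#' @param compute_bf set FALSE to skip the Bayes-factor quadrature.
#' @return object of class `bf_result`: list with `t_statistic`, `df`,
#'   `p_value`, `mean_diff`, `bf10`, `bf01`, `prior_scale`.
#' @export
paired_t_bf <- function(x, y, prior_scale = 0.707, compute_bf = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  if (stats::sd(d) == 0) stop("undefined-t: zero-variance differences",
                              call. = FALSE)
  tt <- stats::t.test(x, y, paired = TRUE)
  bf10 <- if (compute_bf) jzs_bf10(unname(tt$statistic), length(x), prior_scale)
          else NA_real_
  structure(
    list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_diff = unname(tt$estimate),
         bf10 = bf10, bf01 = 1 / bf10, prior_scale = prior_scale),
    class = "bf_result"
  )
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g, BF10 = %.4g (Cauchy scale %.3f)\n",
              x$df, x$t_statistic, x$p_value, x$bf10, x$prior_scale))
  invisible(x)
}

#' Fixed-effect regression with z-scored predictors
#'
#' Fits a linear or logistic regression of `outcome` on the named
#' predictors, z-scoring each predictor and adding subject indicator
#' (fixed-effect) columns when a `subject` column is present. Returns the
#' coefficient table together with the log-likelihood and
#' BIC = k ln(n) - 2 logL, where k counts all estimated coefficients
#' (subject dummies included).
#'
#' @param data data.frame containing the outcome, predictors and
#'   (optionally) `subject`.
#' @param outcome name of the outcome column (binary for logistic).
#' @param predictors character vector of predictor column names (may be
#'   empty for a null model).
#' @param family "logistic" or "linear".
#' @param zscore z-score predictors before fitting.
#' @param subject_fe add subject fixed effects when a subject column exists.
#' @return object of class `regression_result`: list with `coefficients`
#'   (data.frame: term, beta, se, z/t, p), `loglik`, `bic`, `n`, `k`,
#'   `family`, `separation` flag, and the underlying `fit`.
#' @export
fixed_effect_regression <- function(data, outcome, predictors,
                                    family = c("logistic", "linear"),
                                    zscore = TRUE, subject_fe = TRUE) {
  family <- match.arg(family)
  stopifnot(outcome %in% names(data), all(predictors %in% names(data)))
  df <- data
  for (p in predictors) {
    v <- df[[p]]
    if (zscore) {
      s <- stats::sd(v)
      if (s == 0) stop(sprintf("rank-deficient: predictor `%s` is constant", p),
                       call. = FALSE)
      v <- (v - mean(v)) / s
    }
    df[[p]] <- v
  }
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  if (subject_fe && "subject" %in% names(df) &&
      length(unique(df$subject)) > 1L) {
    df$subject <- factor(df$subject)
    rhs <- paste(rhs, "+ subject")
  }
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  separation <- FALSE
  if (family == "logistic") {
    fit <- withCallingHandlers(
      stats::glm(fml, data = df, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
  } else {
    fit <- stats::lm(fml, data = df)
  }
  cf <- summary(fit)$coefficients
  if (qr(stats::model.matrix(fit))$rank < ncol(stats::model.matrix(fit))) {
    stop("rank-deficient design: collinear predictors", call. = FALSE)
  }
  n <- stats::nobs(fit)
  k <- length(stats::coef(fit))
  ll <- as.numeric(stats::logLik(fit))
  if (family == "linear") {
    # logLik counts sigma as well; BIC here counts regression coefficients
    # per the documented convention but uses the Gaussian ML log-likelihood.
    ll <- as.numeric(stats::logLik(fit))
  }
  coefs <- data.frame(term = rownames(cf), beta = cf[, 1L], se = cf[, 2L],
                      statistic = cf[, 3L], p = cf[, 4L],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(coefficients = coefs, loglik = ll, bic = k * log(n) - 2 * ll,
         n = n, k = k, family = family, separation = separation, fit = fit),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<%s regression: n=%d k=%d logL=%.2f BIC=%.2f%s>\n",
              x$family, x$n, x$k, x$loglik, x$bic,
              if (x$separation) " [separation]" else ""))
  nonfe <- x$coefficients[!grepl("^subject", x$coefficients$term), ]
  print(nonfe, digits = 3)
  invisible(x)
}

#' Sequentially orthogonalise design-matrix columns
#'
#' Each column is replaced by its residual against all earlier columns
#' (an intercept column is treated as first); earlier columns are left
#' unchanged, so the fitted values of the full model are preserved.
#'
#' @param X numeric matrix (columns in the desired order).
#' @param include_intercept residualise against an implicit leading
#'   intercept (i.e. de-mean) as well.
#' @return matrix of the same dimensions.
#' @export
orthogonalize <- function(X, include_intercept = TRUE) {
  X <- as.matrix(X)
  base <- if (include_intercept) matrix(1, nrow(X), 1L) else
    matrix(numeric(0), nrow(X), 0L)
  out <- X
  for (j in seq_len(ncol(X))) {
    Z <- cbind(base, out[, seq_len(j - 1L), drop = FALSE])
    if (ncol(Z)) {
      out[, j] <- stats::lsfit(Z, X[, j], intercept = FALSE)$residuals
    }
  }
  out
}

#' Split blocks by the size of a between-task difference
#'
#' Per subject x pairing, blocks are ranked by the absolute difference in
#' performance (or confidence) between the two tasks: the two smallest go
#' to "smaller", the two largest to "larger"; with the standard five
#' blocks the middle one appears only in the overall average. Ties are
#' broken by block presentation order. Fewer than five blocks triggers a
#' proportional split with a warning.
#'
#' @param blocks block-level data.frame (`subject`, `pairing`, `block`,
#'   and the task summary columns).
#' @param metric "performance_diff" or "confidence_diff".
#' @return the blocks with an added `split` column
#'   ("smaller"/"middle"/"larger").
#' @export
split_blocks <- function(blocks, metric = c("performance_diff",
                                            "confidence_diff")) {
  metric <- match.arg(metric)
  diff_col <- if (metric == "performance_diff") {
    blocks$a_acc - blocks$b_acc
  } else {
    blocks$a_conf - blocks$b_conf
  }
  blocks$split <- NA_character_
  for (key in unique(paste(blocks$subject, blocks$pairing))) {
    idx <- which(paste(blocks$subject, blocks$pairing) == key)
    m <- length(idx)
    if (m < 5L) {
      warning("fewer than 5 blocks in a subject x pairing cell: proportional split")
      n_lo <- floor(m * 2 / 5)
      n_hi <- floor(m * 2 / 5)
    } else {
      n_lo <- 2L
      n_hi <- 2L
    }
    ord <- idx[order(abs(diff_col[idx]), blocks$block[idx])]
    blocks$split[idx] <- "middle"
    if (n_lo > 0L) blocks$split[ord[seq_len(n_lo)]] <- "smaller"
    if (n_hi > 0L) blocks$split[rev(ord)[seq_len(n_hi)]] <- "larger"
  }
  blocks
}

#' Effect of learning duration on task choice
#'
#' One fixed-effect logistic regression per task pairing:
#' choice ~ duration (+ subject fixed effects).
#'
#' @param blocks block-level data.frame with `pairing`, `duration`,
#'   `task_choice`, `subject`.
#' @return data.frame with one row per pairing: beta (duration slope),
#'   se, p, separation flag.
#' @export
duration_effect <- function(blocks) {
  out <- lapply(sort(unique(blocks$pairing)), function(pg) {
    sub <- blocks[blocks$pairing == pg, , drop = FALSE]
    if (length(unique(sub$duration)) < 2L) {
      stop("duration effect undefined: single duration present", call. = FALSE)
    }
    if (stats::sd(sub$task_choice) == 0) {
      return(data.frame(pairing = pg, beta = NA_real_, se = NA_real_,
                        p = NA_real_, separation = TRUE))
    }
    fit <- fixed_effect_regression(sub, "task_choice", "duration", "logistic")
    row <- fit$coefficients[fit$coefficients$term == "duration", ]
    data.frame(pairing = pg, beta = row$beta, se = row$se, p = row$p,
               separation = fit$separation)
  })
  do.call(rbind, out)
}

#' Recency (quartile) regression of task choice on accuracy differences
#'
#' Splits each block's trial sequence into four chronological quartiles
#' (trial position p of n maps to quartile ceiling(4 p / n)), computes the
#' between-task accuracy difference (task A minus task B) within each
#' quartile, and fits a fixed-effect logistic regression of task choice on
#' the four quartile regressors X1-X4 with all pairings pooled. Blocks
#' with fewer than 4 trials per task are dropped with a warning.
#'
#' @param dataset an `spe_dataset`.
#' @return a `regression_result` (terms X1-X4), with attribute
#'   `n_blocks_dropped`.
#' @export
recency_regression <- function(dataset) {
  trials <- dataset$trials
  blocks <- dataset$blocks
  feats <- list()
  dropped <- 0L
  for (i in seq_len(nrow(blocks))) {
    bl <- blocks[i, ]
    tr <- trials[trials$subject == bl$subject & trials$block == bl$block, ,
                 drop = FALSE]
    if (bl$duration < 4L) {
      dropped <- dropped + 1L
      next
    }
    q <- ceiling(4 * seq_len(nrow(tr)) / nrow(tr))
    x <- vapply(1:4, function(k) {
      sub <- tr[q == k, , drop = FALSE]
      a <- sub$correct[sub$task_index == 1L]
      b <- sub$correct[sub$task_index == 2L]
      if (!length(a) || !length(b)) return(NA_real_)
      mean(a) - mean(b)
    }, 0)
    if (any(is.na(x))) {
      dropped <- dropped + 1L
      next
    }
    feats[[length(feats) + 1L]] <- data.frame(
      subject = bl$subject, X1 = x[1L], X2 = x[2L], X3 = x[3L], X4 = x[4L],
      task_choice = bl$task_choice, stringsAsFactors = FALSE)
  }
  if (dropped > 0L) warning(sprintf("%d block(s) dropped (too few trials per quartile)",
                                    dropped))
  df <- do.call(rbind, feats)
  out <- fixed_effect_regression(df, "task_choice", c("X1", "X2", "X3", "X4"),
                                 "logistic")
  attr(out, "n_blocks_dropped") <- dropped
  out
}

#' Consistency between task choices and ability ratings
#'
#' Computes (i) the fraction of blocks in which the chosen task was rated
#' strictly higher than the unchosen one, (ii) a paired t-test of
#' subject-mean chosen vs unchosen ratings, and (iii) a fixed-effect
#' logistic regression of task choice on the rating difference.
#'
#' @param blocks block-level data.frame with ratings (`a_rating`,
#'   `b_rating`) and `task_choice`.
#' @return list with `fraction_chosen_rated_higher`, `t_test`
#'   (a `bf_result`), `regression` (a `regression_result`).
#' @export
choice_rating_consistency <- function(blocks) {
  rated <- blocks[!is.na(blocks$a_rating) & !is.na(blocks$b_rating), ,
                  drop = FALSE]
  if (nrow(rated) == 0L) stop("no rated blocks", call. = FALSE)
  chosen <- ifelse(rated$task_choice == 1L, rated$a_rating, rated$b_rating)
  unchosen <- ifelse(rated$task_choice == 1L, rated$b_rating, rated$a_rating)
  frac <- mean(chosen > unchosen)
  by_subj <- stats::aggregate(cbind(chosen, unchosen),
                              by = list(subject = rated$subject), FUN = mean)
  tt <- tryCatch(paired_t_bf(by_subj$chosen, by_subj$unchosen),
                 error = function(e) NULL)  # all-tied ratings: no t-test
  rated$rating_diff <- rated$a_rating - rated$b_rating
  reg <- tryCatch(
    fixed_effect_regression(rated, "task_choice", "rating_diff",
                            "logistic", zscore = FALSE),
    error = function(e) NULL)  # constant rating differences: no fit
  list(fraction_chosen_rated_higher = frac, t_test = tt, regression = reg)
}

#' Parametric and non-parametric between-subject correlation
#'
#' @param x,y paired vectors, n >= 4.
#' @return list with `pearson_rho`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `n`.
#' @export
between_subject_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) stop("need at least 4 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(pearson_rho = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(x))
}
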