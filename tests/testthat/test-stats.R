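# Statistical pipeline: exclusions, trimming, ANOVA, Bayes factors,
# regressions, orthogonalisation, splits, correlations.

test_that("exclusion screen flags chance responders and constant raters", {
  co <- cached_cohort("exp1", n_subjects = 4, seed = 5)
  # inject a chance responder: correctness decoupled from the stimulus
  ds <- co
  s1 <- unique(ds$trials$subject)[1L]
  idx <- ds$trials$subject == s1
  ds$trials$correct[idx] <- rep(c(TRUE, FALSE), length.out = sum(idx))
  ds$trials$choice[idx] <- ifelse(ds$trials$correct[idx],
                                  ds$trials$target_side[idx],
                                  ifelse(ds$trials$target_side[idx] == "left",
                                         "right", "left"))
  # and a constant rater
  s2 <- unique(ds$trials$subject)[2L]
  ds$blocks$a_rating[ds$blocks$subject == s2] <- 75
  ds$blocks$b_rating[ds$blocks$subject == s2] <- 75
  scr <- exclude_subjects(ds)
  expect_setequal(scr$report$subject[scr$report$rule == "chance_responding"], s1)
  expect_setequal(scr$report$subject[scr$report$rule == "constant_rating"], s2)
  expect_false(any(scr$dataset$trials$subject %in% c(s1, s2)))
  # binomial operationalisation: 144/288 is not above chance
  expect_gt(binom.test(144, 288, alternative = "greater")$p.value, 0.05)

  # comprehension rule applies only when the table is supplied
  comp <- data.frame(subject = unique(co$trials$subject),
                     chance_rating = 50,
                     perfect_rating = c(55, rep(95, 3)))
  scr2 <- exclude_subjects(co, comprehension = comp)
  expect_true(unique(co$trials$subject)[1L] %in%
                scr2$report$subject[scr2$report$rule == "comprehension_failure"])
  expect_error(exclude_subjects(list(trials = data.frame())), "empty")
})

test_that("RT trimming removes exactly the >3sd trials, per subject", {
  tr <- data.frame(subject = "s1", rt_ms = c(rep(600, 20), 5000))
  out <- trim_rt_outliers(tr)
  expect_equal(nrow(out$trials), 20L)
  expect_equal(out$removed_fraction, 1 / 21)
  # all identical: sd = 0, nothing removed
  tr2 <- data.frame(subject = "s1", rt_ms = rep(700, 10))
  expect_equal(nrow(trim_rt_outliers(tr2)$trials), 10L)
  # nothing beyond 3 sd: no-op
  tr3 <- data.frame(subject = "s1", rt_ms = c(600, 650, 700, 750))
  expect_identical(trim_rt_outliers(tr3)$trials, tr3)
  # fewer than 3 trials: warning, untouched
  tr4 <- data.frame(subject = c("s1", "s1"), rt_ms = c(1, 1e6))
  expect_warning(out4 <- trim_rt_outliers(tr4), "fewer than 3")
  expect_equal(nrow(out4$trials), 2L)
})

test_that("repeated-measures ANOVA matches a manual sums-of-squares oracle", {
  # independent oracle: textbook two-way RM ANOVA from cell means
  rm_anova_oracle <- function(d) {
    y <- xtabs(value ~ subject + difficulty + feedback, d)
    n <- dim(y)[1L]
    gm <- mean(y)
    m_s <- apply(y, 1, mean); m_a <- apply(y, 2, mean); m_b <- apply(y, 3, mean)
    m_sa <- apply(y, c(1, 2), mean); m_sb <- apply(y, c(1, 3), mean)
    m_ab <- apply(y, c(2, 3), mean)
    ss_a <- 2 * n * sum((m_a - gm)^2)
    ss_b <- 2 * n * sum((m_b - gm)^2)
    ss_ab <- n * sum((m_ab - outer(m_a - gm, m_b - gm, "+") - gm)^2)
    ss_sa <- 2 * sum((m_sa - outer(m_s, m_a, "+") + gm)^2)
    ss_sb <- 2 * sum((m_sb - outer(m_s, m_b, "+") + gm)^2)
    ss_tot <- sum((y - gm)^2)
    ss_s <- 4 * sum((m_s - gm)^2)
    ss_sab <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_sa - ss_sb
    data.frame(
      effect = c("difficulty", "feedback", "difficulty:feedback"),
      F = c(ss_a / (ss_sa / (n - 1)), ss_b / (ss_sb / (n - 1)),
            ss_ab / (ss_sab / (n - 1))))
  }
  d <- with_seed(8, expand.grid(subject = sprintf("s%02d", 1:29),
                                difficulty = c("easy", "difficult"),
                                feedback = c("feedback", "absent"),
                                stringsAsFactors = FALSE))
  d$value <- with_seed(9, runif(nrow(d)))
  res <- anova_2x2_rm(d)
  ora <- rm_anova_oracle(d)
  expect_equal(res$F, ora$F[match(res$effect, ora$effect)], tolerance = 1e-6)
  expect_equal(res$df1, rep(1L, 3L), ignore_attr = TRUE)
  expect_equal(res$df2, rep(28L, 3L), ignore_attr = TRUE)

  # all cells identical: null effects
  d0 <- d; d0$value <- ave(d0$value, d0$subject)  # varies only by subject
  res0 <- anova_2x2_rm(d0)
  expect_true(all(res0$F < 1e-10))

  # transform endpoints
  expect_equal(asin(sqrt(0.5)), pi / 4)
  expect_equal(asin(sqrt(1)), pi / 2)
  dp <- d; dp$value <- pmin(pmax(d$value, 0), 1)
  expect_silent(anova_2x2_rm(dp, transform = "arcsine_sqrt"))
  expect_error(anova_2x2_rm(d[-1, ]), "unbalanced")
})

test_that("JZS Bayes factor agrees with the g-integral oracle", {
  # independent oracle: inverse-gamma mixture representation
  g_oracle <- function(t, n, r = 0.707) {
    nu <- n - 1
    num <- integrate(function(g) {
      (1 + n * g)^(-0.5) * (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
        r / sqrt(2 * pi) * g^(-1.5) * exp(-r^2 / (2 * g))
    }, 0, Inf, rel.tol = 1e-9)$value
    num / (1 + t^2 / nu)^(-(nu + 1) / 2)
  }
  # null-ish data: BF10 < 1, matching the oracle
  x <- with_seed(1, rnorm(30))
  y <- with_seed(2, rnorm(30))
  res <- paired_t_bf(x, y)
  expect_equal(res$bf10, g_oracle(res$t_statistic, 30), tolerance = 1e-6)
  expect_equal(res$bf10 * res$bf01, 1)
  # t exactly 0 at n = 30: evidence favours the null (oracle value 0.1944)
  expect_equal(metaspe:::jzs_bf10(0, 30), g_oracle(0, 30), tolerance = 1e-6)
  expect_equal(g_oracle(0, 30), 0.1944111, tolerance = 1e-5)
  # large effect: overwhelming evidence
  expect_gt(metaspe:::jzs_bf10(8, 29), 100)
  expect_error(paired_t_bf(1:5, 1:5 + 2), "zero-variance")
})

test_that("classical paired-t type-I error is calibrated at alpha = 0.05", {
  reps <- 10000
  n <- 12
  rejections <- with_seed(99, {
    vapply(seq_len(reps), function(i) {
      x <- rnorm(n); y <- rnorm(n)
      paired_t_bf(x, y, compute_bf = FALSE)$p_value < 0.05
    }, TRUE)
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.01)
})

test_that("fixed-effect regression reproduces closed-form null likelihoods", {
  # balanced binary outcome, intercept-only: logL = n log(1/2)
  d <- data.frame(y = rep(c(0, 1), 50))
  res <- fixed_effect_regression(d, "y", character(), "logistic",
                                 subject_fe = FALSE)
  expect_equal(res$loglik, 100 * log(0.5), tolerance = 1e-8)
  expect_equal(res$bic, log(100) + 138.6294, tolerance = 1e-3)
  expect_equal(res$k, 1L)
})

test_that("regression recovers generating coefficients and calibrates type I", {
  # beta_conf = 1, beta_acc = 0 on z-scored predictors
  n <- 2000
  d <- with_seed(5, data.frame(accDiff = rnorm(n), rtDiff = rnorm(n),
                               confDiff = rnorm(n)))
  eta <- 1 * scale(d$confDiff)[, 1L]
  d$choice <- with_seed(6, rbinom(n, 1, plogis(eta)))
  fit <- fixed_effect_regression(d, "choice", c("accDiff", "rtDiff", "confDiff"),
                                 "logistic", subject_fe = FALSE)
  cf <- fit$coefficients
  expect_equal(cf$beta[cf$term == "confDiff"], 1, tolerance = 0.2)
  expect_lt(abs(cf$beta[cf$term == "accDiff"]), 0.15)

  # type-I calibration: a null predictor is flagged in <= ~5% of replicates
  hits <- with_seed(31, vapply(1:200, function(i) {
    dd <- data.frame(x = rnorm(500), y = rbinom(500, 1, 0.5))
    f <- fixed_effect_regression(dd, "y", "x", "logistic", subject_fe = FALSE)
    f$coefficients$p[f$coefficients$term == "x"] < 0.05
  }, TRUE))
  expect_lt(mean(hits), 0.1)

  # collinear predictors are rejected
  d$dup <- d$confDiff
  expect_error(
    fixed_effect_regression(d, "choice", c("confDiff", "dup"), "logistic",
                            subject_fe = FALSE),
    "rank-deficient|collinear")
  # complete separation flagged
  ds <- data.frame(x = c(-(10:1), 1:10), y = rep(c(0, 1), each = 10))
  fs <- suppressWarnings(  # separated fits also emit a convergence warning
    fixed_effect_regression(ds, "y", "x", "logistic", subject_fe = FALSE))
  expect_true(fs$separation)
})

test_that("sequential orthogonalisation residualises in order", {
  # mutually orthogonal zero-mean columns are unchanged
  X <- cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1))
  expect_equal(orthogonalize(X), X)
  # a duplicated column becomes zero
  X2 <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  expect_equal(unname(orthogonalize(X2)[, 2L]), rep(0, 4), tolerance = 1e-12)
  # 5-row correlated case: second column equals the manual LS residual
  x1 <- c(1, 2, 3, 4, 5)
  x2 <- c(2, 1, 4, 3, 6)
  Z <- cbind(1, x1)
  manual <- x2 - Z %*% solve(crossprod(Z), crossprod(Z, x2))
  expect_equal(unname(orthogonalize(cbind(x1, x2))[, 2L]), manual[, 1L],
               tolerance = 1e-12)
  # same column space: fitted values unchanged
  y <- c(0, 1, 0, 1, 1)
  f1 <- lm.fit(cbind(1, x1, x2), y)$fitted.values
  O <- orthogonalize(cbind(x1, x2))
  f2 <- lm.fit(cbind(1, O), y)$fitted.values
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("block splits separate smaller and larger performance differences", {
  blocks <- data.frame(
    subject = "s1", pairing = 1L, block = 1:5,
    a_acc = 0.8 + c(0, 0.1, 0.2, 0.3, 0.4), b_acc = 0.8,
    a_conf = NA, b_conf = NA, task_choice = 1L, duration = 6L)
  out <- split_blocks(blocks, "performance_diff")
  expect_equal(out$split, c("smaller", "smaller", "middle", "larger", "larger"))
  # ties broken by block presentation order
  blocks$a_acc <- 0.8
  out2 <- expect_warning(split_blocks(blocks[1:4, ], "performance_diff"),
                         "proportional") # 4 blocks: proportional
  out3 <- split_blocks(blocks, "performance_diff")
  expect_equal(out3$split, c("smaller", "smaller", "middle", "larger", "larger"))
})

test_that("duration and recency regressions behave on constructed data", {
  # choice probability increasing in duration: positive significant slope
  dur <- with_seed(3, data.frame(
    subject = rep(sprintf("s%d", 1:20), each = 25),
    pairing = 1L,
    duration = rep(c(2, 4, 6, 8, 10), 100)))
  dur$task_choice <- with_seed(4, rbinom(nrow(dur), 1,
                                         plogis(-1 + 0.25 * dur$duration)))
  res <- duration_effect(dur)
  expect_gt(res$beta[1L], 0)
  expect_lt(res$p[1L], 0.05)
  # constant choice probability: slope near zero
  dur$task_choice <- with_seed(5, rbinom(nrow(dur), 1, 0.5))
  res0 <- duration_effect(dur)
  expect_gt(res0$p[1L], 0.01)
  # degenerate identical choices: separation flag
  dur$task_choice <- 1L
  expect_true(duration_effect(dur)$separation[1L])
  expect_error(duration_effect(dur[dur$duration == 2, ]), "single duration")

  # quartile partition of a 24-trial block: 6/6/6/6
  q <- ceiling(4 * seq_len(24) / 24)
  expect_equal(unname(table(q)), rep(6L, 4L), ignore_attr = TRUE)

  # constructed recency effect: only the last quartile drives choice
  co <- cached_cohort("exp1", n_subjects = 10, seed = 42)
  ds <- co
  feats_choice <- vapply(seq_len(nrow(ds$blocks)), function(i) {
    bl <- ds$blocks[i, ]
    tr <- ds$trials[ds$trials$subject == bl$subject &
                      ds$trials$block == bl$block, ]
    q <- ceiling(4 * seq_len(nrow(tr)) / nrow(tr))
    last <- tr[q == 4, ]
    x4 <- mean(last$correct[last$task_index == 1]) -
      mean(last$correct[last$task_index == 2])
    if (is.na(x4)) 0.5 else plogis(6 * x4)
  }, 0)
  ds$blocks$task_choice <- with_seed(11, rbinom(nrow(ds$blocks), 1,
                                                feats_choice))
  rec <- suppressWarnings(recency_regression(ds))
  cf <- rec$coefficients
  betas <- cf$beta[match(c("X1", "X2", "X3", "X4"), cf$term)]
  expect_equal(which.max(betas), 4L)
})

test_that("choice/rating consistency metrics follow their conventions", {
  blocks <- data.frame(
    subject = rep(c("s1", "s2"), each = 4),
    a_rating = c(80, 70, 90, 60, 85, 75, 65, 95),
    b_rating = c(60, 70, 70, 80, 65, 85, 65, 75),
    task_choice = c(1L, 1L, 1L, 0L, 1L, 0L, 1L, 1L))
  out <- choice_rating_consistency(blocks)
  # chosen rated strictly higher in 6 of 8 blocks (two exact ties rated 0)
  expect_equal(out$fraction_chosen_rated_higher, 6 / 8)
  # all ties: strict rule gives zero
  tie <- blocks; tie$b_rating <- tie$a_rating
  expect_equal(choice_rating_consistency(tie)$fraction_chosen_rated_higher, 0)
  expect_error(choice_rating_consistency(
    data.frame(a_rating = NA_real_, b_rating = NA_real_, task_choice = 1L)),
    "no rated blocks")
})

test_that("correlations match closed forms and the rank formula", {
  x <- c(1, 3, 2, 5, 4)
  res <- between_subject_correlation(x, x)
  expect_equal(res$pearson_rho, 1)
  expect_equal(res$spearman_rho, 1)
  res2 <- between_subject_correlation(x, -2 * x + 7)
  expect_equal(res2$pearson_rho, -1)
  expect_equal(res2$spearman_rho, -1)
  # hand case: one adjacent swap, rho = 1 - 6*sum(d^2)/(n(n^2-1))
  y <- c(1, 2, 3, 5, 4)
  res3 <- between_subject_correlation(1:5, y)
  expect_equal(res3$spearman_rho, 1 - 6 * 2 / (5 * 24))
  expect_error(between_subject_correlation(1:3, 1:3), "at least 4")
  expect_error(between_subject_correlation(rep(1, 5), 1:5), "zero variance")
})
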