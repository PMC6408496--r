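# Bayesian SPE learner: belief grid, feedback and soft-evidence updates,
# task choice and ratings.

test_that("belief initialisation matches Beta closed forms", {
  b <- init_belief(prior_a = 1, prior_b = 1)
  expect_equal(belief_mean(b), 0.5, tolerance = 1e-10)
  expect_equal(sum(b$weights), 1, tolerance = 1e-12)
  b21 <- init_belief(prior_a = 2, prior_b = 1)
  expect_equal(belief_mean(b21), 2 / 3, tolerance = 1e-3)
  expect_error(init_belief(prior_a = 0, prior_b = 1), "positive")
  # initialisation from subject parameters
  p <- subject_params(prior_a = 3, prior_b = 2)
  expect_equal(belief_mean(init_belief(p)), 0.6, tolerance = 1e-3)
})

test_that("updates preserve normalisation (property over random sequences)", {
  for (seed in 1:10) {
    b <- init_belief(prior_a = runif(1, 0.5, 3), prior_b = runif(1, 0.5, 3))
    ops <- with_seed(seed, sample(c("fb", "conf"), 30, replace = TRUE))
    cs <- with_seed(seed + 100, runif(30, 0.5, 1))
    os <- with_seed(seed + 200, runif(30) < 0.75)
    for (i in seq_len(30)) {
      b <- if (ops[i] == "fb") update_feedback(b, os[i]) else
        update_confidence(b, cs[i])
      expect_equal(sum(b$weights), 1, tolerance = 1e-12)
    }
  }
})

test_that("grid feedback updates agree with conjugate Beta to 1e-3", {
  for (seed in 1:8) {
    outcomes <- with_seed(seed, runif(20) < 0.8)
    b <- init_belief(prior_a = 1, prior_b = 1)
    for (o in outcomes) b <- update_feedback(b, o)
    a <- 1 + sum(outcomes)
    bb <- 1 + sum(!outcomes)
    expect_equal(belief_mean(b), beta_mean(a, bb), tolerance = 1e-3)
    expect_equal(belief_sd(b), beta_sd(a, bb), tolerance = 1e-3)
  }
  # single correct outcome on a flat prior: Beta(2, 1)
  b1 <- update_feedback(init_belief(prior_a = 1, prior_b = 1), TRUE)
  expect_equal(belief_mean(b1), 2 / 3, tolerance = 1e-3)
  # correct then error restores symmetry
  b2 <- update_feedback(b1, FALSE)
  expect_equal(belief_mean(b2), 0.5, tolerance = 1e-10)
})

test_that("confidence updates implement soft evidence", {
  b <- init_belief(prior_a = 1, prior_b = 1)
  # c = 0.5 is uninformative
  expect_equal(update_confidence(b, 0.5)$weights, b$weights,
               tolerance = 1e-14)
  # c = 1 is equivalent to correct feedback
  expect_equal(update_confidence(b, 1)$weights,
               update_feedback(b, TRUE)$weights, tolerance = 1e-14)
  # flat prior, c = 0.8: mean (0.8/3 + 0.2/6) / (1/2) = 0.6
  expect_equal(belief_mean(update_confidence(b, 0.8)), 0.6,
               tolerance = 1e-3)
  expect_error(update_confidence(b, 0.4), "\\[0.5, 1\\]")
  expect_error(update_confidence(b, 1.2), "\\[0.5, 1\\]")
})

test_that("point-mass beliefs keep their support; dead beliefs error", {
  b <- init_belief(prior_a = 1, prior_b = 1)
  b$weights <- as.numeric(abs(b$theta - 0.8) < 1e-9)
  b$weights <- b$weights / sum(b$weights)
  for (o in c(TRUE, FALSE)) {
    up <- update_feedback(b, o)
    expect_equal(which(up$weights > 0), which(b$weights > 0))
  }
  dead <- init_belief(prior_a = 1, prior_b = 1)
  dead$weights <- as.numeric(dead$theta == 0)
  expect_error(update_feedback(dead, TRUE), "all-zero mass")
})

test_that("task choice probability matches closed-form belief comparisons", {
  flat <- init_belief(prior_a = 1, prior_b = 1)
  res <- with_seed(1, choose_task(flat, flat))
  expect_equal(res$p_a_better, 0.5, tolerance = 1e-12)
  # Beta(2,1) vs flat: P(A > B) = 2/3
  res2 <- with_seed(1, choose_task(init_belief(prior_a = 2, prior_b = 1),
                                   flat))
  expect_equal(res2$p_a_better, 2 / 3, tolerance = 1e-3)
  # point beliefs: dominance
  pa <- flat; pa$weights <- as.numeric(abs(pa$theta - 0.9) < 1e-9)
  pb <- flat; pb$weights <- as.numeric(abs(pb$theta - 0.6) < 1e-9)
  res3 <- with_seed(1, choose_task(pa, pb))
  expect_equal(res3$p_a_better, 1)
  expect_equal(res3$choice, "A")
  # argmax policy at temperature 0
  res4 <- with_seed(1, choose_task(init_belief(prior_a = 2, prior_b = 1),
                                   flat, policy_temperature = 0))
  expect_equal(res4$p_choose_a, 1)
  # mismatched grids rejected
  other <- init_belief(prior_a = 1, prior_b = 1, n_points = 101)
  expect_error(choose_task(flat, other), "incompatible")
})

test_that("ratings map the posterior mean onto the 50-100 scale", {
  mk <- function(mean_target) {
    b <- init_belief(prior_a = 1, prior_b = 1)
    b$weights <- as.numeric(abs(b$theta - mean_target) < 1e-9)
    b$weights <- b$weights / sum(b$weights)
    b
  }
  expect_equal(rate_task(mk(0.5)), 50)
  expect_equal(rate_task(mk(0.85)), 85)
  expect_equal(rate_task(mk(0.3)), 50)  # clipped at the scale floor
  expect_equal(rate_task(mk(1.0)), 100)
})

test_that("run_block updates beliefs trial-by-trial and is deterministic", {
  p <- subject_params(seed = 7)
  d <- build_design("exp1", seed = 7)
  blk <- d$blocks[[1L]]
  bt <- d$trials[d$trials$block == blk$block, ]
  r1 <- with_seed(7, run_block(p, blk, bt, with_ratings = TRUE,
                               keep_trajectory = TRUE))
  r2 <- with_seed(7, run_block(p, blk, bt, with_ratings = TRUE,
                               keep_trajectory = TRUE))
  expect_identical(r1$record, r2$record)
  expect_identical(r1$trials, r2$trials)
  expect_equal(nrow(r1$trials), 24L)
  expect_true(all(r1$record[, c("a_rating", "b_rating")] >= 50))

  # all-correct feedback task: posterior mean strictly increasing
  blk_fb <- NULL
  for (b in d$blocks) {
    if (b$conditions[[1L]]$feedback_mode == "feedback") { blk_fb <- b; break }
  }
  bt_fb <- d$trials[d$trials$block == blk_fb$block, ]
  p_sharp <- subject_params(k_ch = 50)  # near-perfect accuracy
  r <- with_seed(1, run_block(p_sharp, blk_fb, bt_fb, keep_trajectory = TRUE))
  task1 <- r$trajectory[r$trajectory$task_index == 1L, ]
  if (all(r$trials$correct[r$trials$task_index == 1L]) &&
      blk_fb$conditions[[1L]]$feedback_mode == "feedback") {
    expect_true(all(diff(task1$post_mean) > 0))
  }
})

test_that("feedback sharpens the posterior at least as fast as confidence", {
  # matched outcome sequences: route the same trials through hard feedback
  # vs soft-confidence updating (confidence evaluated against the
  # observer's expected accuracy, as in the block simulator); the soft
  # posterior cannot be narrower
  ref <- pnorm(default_signals()[["easy"]])
  sds <- vapply(1:30, function(seed) {
    tr <- sim_trials(10, seed = 900 + seed, difficulty = "easy")
    b_fb <- b_cf <- init_belief(prior_a = 1, prior_b = 1)
    for (i in seq_len(10)) {
      b_fb <- update_feedback(b_fb, tr$correct[i])
      b_cf <- update_confidence(b_cf, tr$confidence[i], reference = ref)
    }
    c(fb = belief_sd(b_fb), cf = belief_sd(b_cf))
  }, c(fb = 0, cf = 0))
  # the ordering is distributional: a rare error trial carrying high
  # confidence can leave the soft posterior marginally narrower
  expect_gte(mean(sds["fb", ] <= sds["cf", ] + 1e-12), 29 / 30)
  expect_lt(mean(sds["fb", ]), mean(sds["cf", ]))
})

test_that("confidence updating underestimates relative to feedback early on", {
  # with a chance-level prior and above-chance true accuracy, soft updates
  # leave the posterior mean closer to the prior than hard feedback does
  ref <- pnorm(default_signals()[["easy"]])
  means <- vapply(1:20, function(seed) {
    tr <- sim_trials(12, seed = 1300 + seed, difficulty = "easy")
    b_fb <- b_cf <- init_belief(prior_a = 1, prior_b = 1)
    for (i in seq_len(12)) {
      b_fb <- update_feedback(b_fb, tr$correct[i])
      b_cf <- update_confidence(b_cf, tr$confidence[i], reference = ref)
    }
    c(fb = belief_mean(b_fb), cf = belief_mean(b_cf))
  }, c(fb = 0, cf = 0))
  expect_gt(mean(means["fb", ]), mean(means["cf", ]))
})
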