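# Shared fixtures: everything is generated in code at test time.

# Large seeded trial set from the perceptual module.
sim_trials <- function(n, k_ch = 1, k_conf = 1, signal = default_signals(),
                       seed = 1, difficulty = NULL) {
  p <- subject_params(k_ch = k_ch, k_conf = k_conf)
  with_seed(seed, {
    if (is.null(difficulty)) {
      difficulty <- sample(names(signal), n, replace = TRUE)
    } else {
      difficulty <- rep_len(difficulty, n)
    }
    simulate_trial(p, signal = unname(signal[difficulty]),
                   difficulty = difficulty,
                   target_side = sample(c("left", "right"), n, replace = TRUE))
  })
}

# Small cached cohorts so several tests can share one simulation.
cached_cohort <- local({
  cache <- list()
  function(experiment_id, n_subjects = 10, seed = 42) {
    key <- paste(experiment_id, n_subjects, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- simulate_cohort(
        cohort_spec(n_subjects, experiment_id, seed = seed))
    }
    cache[[key]]
  }
})

# Conjugate Beta moments, for grid-agreement oracles.
beta_mean <- function(a, b) a / (a + b)
beta_sd <- function(a, b) sqrt(a * b / ((a + b)^2 * (a + b + 1)))
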