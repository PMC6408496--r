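# metaspe

Modelling how people form **global self-performance estimates (SPEs)** —
beliefs about how good they are at a task — from external feedback and from
their own trial-by-trial decision confidence.

The paradigm: short learning blocks randomly interleave two colour-cued
"tasks", each a two-alternative dot-numerosity discrimination that is easy
or difficult and provides feedback or not (2 × 2 factorial, six possible
task pairings per block). At the end of each block the subject chooses the
task they think they performed better at, and in some designs rates their
ability on a 50–100% scale. The scientific question is how those
end-of-block judgments are built from what happened within the block when
external feedback is present versus absent.

## The model

`metaspe` implements a two-level generative model:

* **Perceptual module** (signal detection). On each trial an internal
  evidence sample x ~ N(±k_ch·s, 1) determines the choice (its sign), and
  confidence is the posterior probability that the choice was correct for
  an observer with (possibly different) sensitivity k_conf:
  c = 1 / (1 + exp(−2·k_conf·s·|x|)). Accuracy is Φ(k_ch·s) in closed
  form; default signal strengths are calibrated to 85% (easy) and 70%
  (difficult) correct at k_ch = 1. RTs are lognormal with difficulty-
  specific means (672/707 ms).

* **SPE learner** (Bayesian). Per task and per block, a discretised
  posterior over the task's accuracy θ is updated multiplicatively: by θ or
  (1−θ) on feedback trials, and on no-feedback trials by the soft-evidence
  likelihood (c/p)·θ + ((1−c)/(1−p))·(1−θ), confidence evaluated against a
  reference accuracy p (chance by default; the simulator uses the task's
  difficulty-based expectation). End-of-block choices are probability
  matching on P(θ_A > θ_B); ratings map the posterior mean onto the 50–100
  scale.

Around the model, the package provides the paradigm's full analysis
pipeline: maximum-likelihood **meta-d′** and metacognitive efficiency
(meta-d′/d′), AUROC2, subject exclusions, RT trimming, repeated-measures
ANOVA with arcsine transform, JZS Bayes-factor paired t-tests (Cauchy
scale 0.707), fixed-effect logistic regressions with natural-log BIC
comparison and sequential regressor orthogonalisation, block splits by
performance/confidence differences, recency (quartile) regression, and
between-subject correlations — plus a synthetic-cohort simulator and a
validated trial/block CSV schema.

## Worked example

```r
library(metaspe)

# a 30-block design: six pairings crossed with durations 2-10 trials/task
build_design("exp2", seed = 7)
#> <design exp2: 30 blocks, 360 trials, 6 pairings>

# simulate a cohort through the confidence-rating design and analyse it
cohort <- simulate_cohort(cohort_spec(n_subjects = 12, experiment_id = "exp3",
                                      seed = 11))
res <- analyze_dataset(cohort)

res$anova_accuracy
#>                effect           F df1 df2            p
#> 1          difficulty 201.7015350   1  11 2.023172e-08
#> 2            feedback   0.2534771   1  11 6.245666e-01
#> 3 difficulty:feedback   0.2294798   1  11 6.412911e-01

res$anova_choice
#>                effect           F df1 df2            p
#> 1          difficulty 22.88839309   1  11 0.0005675858
#> 2            feedback 15.93347627   1  11 0.0021161033
#> 3 difficulty:feedback  0.04899575   1  11 0.8288754058

res$bf_feedback_accuracy$easy
#> t(11) = 0.759, p = 0.4636, BF10 = 0.3674 (Cauchy scale 0.707)
```

Read: task difficulty strongly affects objective accuracy while feedback
availability does not (the Bayes factor favours the null), yet *both*
factors drive end-of-block task choices — the behavioural dissociation the
model exists to explain: without feedback, subjects' SPEs are built from
noisier internal confidence and stay closer to the chance-level prior, so
no-feedback tasks are chosen less often despite equal performance.

Per-subject metacognitive efficiency is also computed for confidence-rated
trials (`res$metacog_efficiency`; near 1 for calibrated simulated
observers), and the confidence-difference regression is compared against
the reduced accuracy+RT model by BIC (`res$bic_full`, `res$bic_reduced`).

A thin command-line front-end wraps the same functions:

```sh
Rscript inst/cli/metaspe.R design   --experiment exp2 --seed 7 --out design.csv
Rscript inst/cli/metaspe.R simulate --experiment exp3 --n 46 --seed 11 --out data/
Rscript inst/cli/metaspe.R analyze  --trials data/ --out results/
```

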