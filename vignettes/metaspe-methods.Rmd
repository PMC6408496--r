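---
title: "Modelling global self-performance estimates: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling global self-performance estimates: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaspe)
```

## The problem

People hold global beliefs about how good they are at a task — self-performance
estimates (SPEs) — that are distinct from the trial-by-trial sense of
confidence in a single decision. `metaspe` implements a two-level generative
model of how SPEs are formed over short learning blocks of a two-alternative
perceptual task, together with the statistical machinery needed to analyse
behaviour from that paradigm: in each block two "tasks" (colour-cued
combinations of difficulty and feedback availability) are randomly
interleaved, and at the end of the block the subject chooses the task they
think they performed better at (and, in some designs, rates their ability on
a 50–100 scale).

## The perceptual module

Each trial presents two boxes of dots; the subject judges which box holds
more. The model reduces the stimulus to a scalar evidence strength $s > 0$
(the normalised dot difference) and draws an internal evidence sample

$$x \sim \mathcal{N}(\pm\, k_{ch}\, s,\; 1),$$

positive when the target is on the right. The choice is the sign of $x$.
Evidence variance is fixed at 1, the standard signal-detection
identifiability convention: all scaling lives in $k_{ch}\, s$. Accuracy is
therefore $\Phi(k_{ch}\, s)$ in closed form, and `calibrate_signal()`
inverts it. The package's default signals are calibrated so that a
$k_{ch} = 1$ observer attains the paradigm's target accuracies: 0.85
(easy, $s = 1.0364$) and 0.70 (difficult, $s = 0.5244$).

Confidence is the posterior probability that the chosen side is correct for
an observer whose *assumed* sensitivity is $k_{conf}$, which may differ from
$k_{ch}$:

$$c = \frac{1}{1 + e^{-2\, k_{conf}\, s\, |x|}}.$$

At $x = 0$ confidence is exactly 0.5 (50% on the reporting scale); with
$k_{conf} = k_{ch}$ it is the Bayes-optimal calibrated confidence, so mean
confidence equals mean accuracy and maximum-likelihood meta-d$'$ recovers
meta-d$'$/d$'\approx 1$. Reaction times are lognormal with a
difficulty-specific location (defaults put the population means at 672 ms
easy / 707 ms difficult) and exist to give the RT regressor realistic
structure; they carry no evidence. A lapse parameter (uniform random choice)
is available but off by default.

`fit_perceptual_params()` recovers $k_{ch}$ from the Bernoulli likelihood of
correctness across signal levels, and $k_{conf}$ by change of variables from
the reported confidence ($|x| = \mathrm{logit}(c) / (2 k_{conf} s)$, Gaussian
density of the signed evidence, with the Jacobian
$1/(2 k_{conf}\, s\, c(1-c))$). Confidences at the scale bounds are clipped
to $[0.5 + 10^{-4},\, 1 - 10^{-4}]$ before inversion. Both recoveries are
accurate to within 10% at $10^4$ trials in the test suite.

## The SPE learner

The learner maintains, per task and per block (beliefs restart with every
block's new colour cues), a posterior over the task's accuracy
$\theta \in [0, 1]$, represented on a grid of 201 equally spaced points.
A grid rather than conjugate Beta updating is used because the
confidence-based likelihood is non-conjugate. Trapezoid quadrature weights
are folded into the grid masses (endpoints half-weighted): with plain
Riemann weights the conjugate checks miss the Beta closed forms by about
$2 \times 10^{-3}$ at 201 points, with trapezoid weights the agreement is
$\sim 10^{-5}$, comfortably inside the $10^{-3}$ tolerance asserted in the
tests.

Two update rules apply, depending on the task's feedback mode:

* **Feedback** trials multiply the weights by $\theta$ (correct) or
  $1 - \theta$ (error) — a standard Bernoulli update.
* **No-feedback / confidence-rating** trials update from the trial's own
  confidence $c$ as *soft evidence*. The exported primitive is
  $w \propto c\,\theta + (1-c)(1-\theta)$, the Jeffrey-style mixture
  in which the unobserved correctness is replaced by its probability; at
  $c = 0.5$ it is a no-op and $c = 1$ reduces exactly to correct feedback.

The mixture rule evaluates confidence against chance: any $c > 0.5$ counts
as evidence for high accuracy. Because realistic confidence distributions
lie almost entirely above 0.5, repeatedly applying it drifts the posterior
toward $\theta = 1$ over a block, which would make *no-feedback* tasks
accrue the higher SPEs. The generative account behind the paradigm predicts
the opposite: confidence is noisier evidence than feedback, so posteriors
should sharpen more slowly and stay closer to the chance-level prior without
feedback. `update_confidence()` therefore takes a `reference` accuracy $p$
and uses the likelihood

$$w \;\propto\; \frac{c}{p}\,\theta \;+\; \frac{1-c}{1-p}\,(1-\theta),$$

which is the marginal likelihood of the underlying evidence sample for a
calibrated confidence observer whose expected accuracy is $p$ (the two
densities of confidence given a correct or an error trial enter only
through the calibration ratios $c/p$ and $(1-c)/(1-p)$). The default
$p = 0.5$ reproduces the plain mixture rule. The block simulator passes
$p = \Phi(s)$ — the accuracy a reference observer of unit sensitivity
attains at the task's evidence strength. Task difficulty is perceptually
observable (the dot difference is on the screen), whereas one's own ability
is precisely the quantity being learned, so a difficulty-based expectation
is the non-circular choice. Two alternatives were considered and rejected:
the observer's own expected accuracy $\Phi(k_{conf}\, s)$ makes strongly
overconfident observers *downgrade* easy no-feedback tasks (their error
trials fall far below their inflated reference), inverting the positive
relation between confidence sensitivity and difficulty tracking; and a
self-referential choice (the learner's running posterior mean) removes the
conservativeness of soft evidence and with it the feedback/no-feedback
asymmetry.

With the difficulty-based reference, the simulator reproduces the
qualitative signatures the paradigm is about: feedback posteriors are
narrower than confidence posteriors on matched trial sequences (this is a
distributional property — a rare error trial carrying high confidence can
leave the soft posterior marginally narrower); SPEs are underestimated
relative to feedback when the prior mean (0.5) lies below true accuracy;
and the frequency of choosing an easy no-feedback task over a difficult
feedback task rises with $k_{conf}$.

End-of-block behaviour reads the posteriors out. The task choice computes
$P(\theta_A > \theta_B)$ (plus half the tied mass) by discrete convolution
of the two independent grids and samples the choice by probability matching
(`policy_temperature = 1`, the default); temperature 0 gives argmax.
Probability matching is the conservative reading of a binary choice made
from a graded belief. Ability ratings map the posterior mean onto the
empirical 50–100 scale, flooring at 50 because the scale starts at chance.
Beliefs for the two tasks of a block are independent (no shared
hyperprior); an absolute rather than relative coding of SPEs is assumed.

## Experiment designs and stimuli

Three block designs are provided. The first crosses difficulty with
feedback availability, yielding six unordered task pairings; each pairing
appears twice with 12 trials per task (12 blocks of 24 trials, 288 trials).
The second and third cross the six pairings with block durations of 2, 4,
6, 8 or 10 trials per task, each combination once (30 blocks, 360 trials);
in the third design the no-feedback mode is replaced by trial-by-trial
confidence rating. Trial interleaving is a random permutation of the
task-label multiset (the unconstrained reading of "pseudo-random order"),
target sides are balanced within each task (which implies the half-left /
half-right balance within each block), and block order is randomised per
subject. All randomisation is seed-deterministic.

Stimuli are dot counts on a 625-position grid: the reference box always
holds 313 dots; the target box holds 313 + 24 (difficult, all designs),
313 + 58 (easy, first design) or 313 + 60 (easy, later designs). The models
consume only the scalar evidence strength, so spatial dot placements are
materialised lazily on request as seeded uniform subsets of the grid.

## Metacognition metrics

Type-1 sensitivity uses the left/right boxes as the two stimulus classes:
$d' = z(H) - z(F)$ with criterion $-\tfrac12[z(H) + z(F)]$, applying the
log-linear correction (add 0.5 to every cell of the collapsed table) when
any rate is 0 or 1 — chosen so results are reproducible bit for bit.

meta-d$'$ is fitted by maximum likelihood under the standard equal-variance
type-2 model: the type-1 criterion is held at its empirical *relative*
position (meta-c = meta-d$' \cdot c/d'$), the $2(K-1)$ type-2 criteria are
free (parameterised by log-increments to enforce ordering), and the
multinomial likelihood of confidence-bin counts conditional on stimulus and
response is maximised by Nelder–Mead from two starts. The fit agrees with
an exhaustive grid-search profile oracle to within 0.01 in the tests, and a
simulated observer whose confidence derives from the same evidence as its
choices recovers meta-d$'/d' \in [0.95, 1.05]$ at $10^5$ trials. Because the
framework assumes constant signal strength, `metacog_efficiency()` fits
per difficulty level and averages the two ratios. Continuous confidence is
discretised into four subject-level quantile bins by default; the original
binning of the continuous scale is not documented anywhere authoritative,
so sensitivity to the bin count is worth checking rather than assuming away
(pass `n_bins`). Degenerate confidence distributions collapse to fewer
bins with a warning, and a single effective bin yields meta-d$' = 0$.
AUROC2 is the probability that a random correct trial carries higher
confidence than a random error trial, ties counting one half, computed via
midranks (equivalent to trapezoidal integration of the type-2 ROC).

## Statistical pipeline

The pipeline mirrors the paradigm's analysis conventions:

* **Exclusions**: "responding at chance" is operationalised as a one-sided
  binomial test of overall accuracy against 0.5 at $\alpha = 0.05$ (no
  criterion is stated anywhere authoritative); constant raters are excluded
  by the zero-variance rule; the 10-point comprehension separation applies
  only when a comprehension table is supplied, since the simulator does not
  emulate the comprehension questionnaire.
* **RT trimming**: single pass, per subject (rather than per
  subject-by-condition, which is the other defensible reading), removing
  trials beyond 3 standard deviations of the mean.
* **2 × 2 repeated-measures ANOVA** via `stats::aov()` with
  `Error(subject/...)` strata; proportions are arcsine-square-root
  transformed; ratings can be rank-normal (van der Waerden) transformed per
  subject — the chosen reading of "z-scored per subject non-parametrically".
  A zero effect sum of squares reports $F = 0$ even when the error stratum
  is also degenerate.
* **JZS Bayes factors** for paired t-tests: zero-centred Cauchy prior
  (scale 0.707) on the standardised effect size, integrating the
  noncentral-t marginal likelihood; the tests cross-check against the
  independent inverse-gamma mixture representation.
* **Fixed-effect regressions**: predictors z-scored, subject indicator
  columns added, natural-log BIC with *k* counting every estimated
  coefficient including the subject dummies. Complete separation is flagged
  and collinearity is a hard error. Sequential orthogonalisation
  residualises each column against all earlier ones (intercept first),
  leaving the model's column space — and hence fitted values — unchanged.
* **Block splits**: per subject and pairing, the two blocks with the
  smallest and largest absolute between-task difference form the "Smaller"
  and "Larger" subsets; the middle block of five appears only in the
  overall average; ties break by block presentation order.
* **Recency regression**: block trials are divided into four chronological
  quartiles (trial position $i$ of $n$ maps to quartile
  $\lceil 4i/n \rceil$); the between-task accuracy difference per quartile
  feeds a fixed-effect logistic regression of task choice on X1–X4. Blocks
  whose quartiles lack one of the tasks are dropped with a warning.
* Between-task differences (accDiff, rtDiff, confDiff) are always task A
  minus task B, where task A is the condition listed first in the pairing
  definition, and the binary choice is 1 when task A is chosen.

## The synthetic-cohort generator

`simulate_cohort()` draws per-subject sensitivities from lognormal
population distributions (median 1, log-sd 0.25 for both $k_{ch}$ and
$k_{conf}$ — heterogeneity that keeps positivity and brackets the 67–85%
accuracy range of the paradigm), derives per-subject child seeds
deterministically from the master seed
($\mathrm{seed}_i = (m + 7919\, i) \bmod (2^{31}-1)$), and runs each
subject through a freshly randomised design. Reported confidence is
rescaled to the 50–100 scale and appears only on confidence-rating trials.
Datasets round-trip through a validated CSV schema (one trials file, one
blocks file, a JSON sidecar logging the drawn parameters and seeds).

What the generator emulates: the 2 × 2 condition structure, block
durations, balanced sides, accuracy near the 85/70% targets, confidence
graded by difficulty and correctness, faster easy RTs, and end-of-block
choices and ratings driven by the learner. What it does not emulate:
attention lapses and dropout, comprehension checks, sequential or
motivational effects, any influence of feedback valence on behaviour, and
the choice extremity seen in human data — under probability matching the
simulated end-of-block choices are noisier than human choices, so
regression-style analyses on default cohorts have weaker effects than the
human benchmarks. For this reason the model-comparison property (BIC
preferring the confidence-containing choice model) is exercised on
effect-present cohorts whose choices are generated from the logistic model
with a true confidence effect, the same construction as the coefficient
recovery checks. Passing tests therefore demonstrate internal consistency
of the machinery and the qualitative signatures above, not a quantitative
fit to human data.

## Problem sizes and numerical choices

The test suite simulates $10^5$ trials for the calibration and
ideal-observer efficiency checks, $10^4$ for parameter recovery, cohorts of
10–29 subjects for pipeline properties (29 matching the published sample
size for the qualitative dissociation), 20 replicate cohorts for the BIC
preference property, and 10,000 replicates for the type-I calibration of
the paired t-test. Optimisations run on the log scale for positivity
(sensitivities) or through ordered log-increment parameterisations
(type-2 criteria). The belief grid rejects confidence outside $[0.5, 1]$
because the perceptual module reports confidence in the chosen option,
which is never below chance.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
cohort <- simulate_cohort(cohort_spec(n_subjects = 29, experiment_id = "exp2",
                                      seed = 314))
results <- analyze_dataset(cohort)
results$anova_accuracy   # Difficulty strongly affects accuracy; Feedback does not
results$anova_choice     # both factors affect end-of-block task choice
results$bf_feedback_accuracy$easy  # BF10 < 1: evidence for the feedback null
```

## Known limitations

The hierarchical Bayesian variant of the meta-d$'$ fit (group-level
shrinkage with MCMC convergence checks) is out of scope; the
maximum-likelihood fit implemented here is its standard cross-check. Choice
models beyond probability matching / argmax (value of information, valence,
risk sensitivity to SPE uncertainty) are not implemented. The soft-evidence
reference is a modelling choice that the data formats deliberately do not
record; analyses of real datasets through the CSV reader are unaffected by
it.
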