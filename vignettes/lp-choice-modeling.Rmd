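---
title: "Modeling learning-progress-driven activity choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling learning-progress-driven activity choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lpchoice` analyzes free-choice learning data: sessions in which a
participant repeatedly picks one of four activities — three learnable
categorization tasks of increasing difficulty (A1, A2, A3) and one
unlearnable task (A4, 50% random feedback) — after a forced
familiarization block of 15 trials per activity, and then 250 free-choice
trials. This vignette explains the model, the signal definitions and their
ambiguities, the synthetic-data generator, and the numerical decisions
baked into the implementation.

## The choice model and its assumptions

On every free-play trial the learner is assumed to score each activity by
two retrospective signals computed from the activity's most recent 15
outcomes (familiarization trials count):

* **PC**, the fraction correct in the window — current competence;
* **LP**, the absolute difference between the mean of an early and a late
  sub-window — a finite-difference surrogate for the derivative of
  competence. Taking the absolute value means deteriorating performance
  also attracts attention, so the model can re-engage activities that are
  being forgotten.

Utilities are linear, $U_{i,t} = w_{PC}\,PC_{i,t} + w_{LP}\,LP_{i,t}$, and
choice probabilities follow a softmax with gain $\tau \ge 0$:
$p_t(i) \propto e^{\tau U_{i,t}}$. $\tau = 0$ is exactly uniform choice.
The likelihood of a parameter triple is the product over free-play trials
of the probability assigned to the observed choice (categorical
likelihood); familiarization trials feed the signal windows but are forced,
so they carry no choice information and never enter the likelihood.

Assumptions worth keeping in mind: signals are window statistics (no decay
or Bayesian estimate of competence), utilities are linear and static per
participant (no learning of the policy itself), and trials are
conditionally independent given the signals. None of the model forms
describes *why* a weight is what it is — the fitted weights are a
description of revealed preferences.

### Identifiability

The parameterization has an exact one-dimensional degeneracy:
$(c\,w_{PC},\, c\,w_{LP},\, \tau/c)$ gives identical probabilities for any
$c > 0$. Only the *direction* of the weight vector and the product of
$\tau$ with its magnitude are identified. All reported comparisons
therefore use the unit-norm pair $(\hat w_{PC}, \hat w_{LP})$
(`normalize_weights()`); the effective gain is
$\tau\sqrt{w_{PC}^2 + w_{LP}^2}$. A fitted weight vector of exactly zero
cannot be normalized — the error message points at $\tau$, where the scale
has gone. Participants whose behavior is almost deterministic can be fit
to likelihood ≈ 1 by many parameter settings; their normalized direction
is then weakly constrained, which is visible as a wide restart spread
rather than hidden.

### Window definitions and the LP split

The PC window is "the most recent 15 outcomes, mean over 15". For LP, the
natural reading of "the first 10 and the last 9 of the same stretch of 15"
makes the sub-windows overlap by four positions (1–10 vs 7–15, divisors 10
and 9); that overlapping split is the package default (`lp_split =
"10v9"`). Because a reasonable implementer might instead want disjoint
halves, the split is configurable: `"10v5"` (1–10 vs 11–15) and `"8v7"`
(1–8 vs 9–15) are provided. All downstream results in the tests use the
default.

## Behavioral indices

* **Self-challenge (SC)**: per trial,
  $1 - (PC_{choice} - \min)/(\max - \min)$, where min and max run over all
  PC values experienced so far, on any activity, forced trials included.
  SC = 1 means choosing the currently-worst activity. When the running
  range is zero the trial is undefined and skipped (`NA`), not an error —
  this genuinely happens for the first trials of a perfectly uniform
  performer. A participant's SC index is the mean over defined free-play
  trials.
* **dwfPC**: final PC (last 15 outcomes) per learnable activity, averaged
  with rank weights 1/6, 1/3, 1/2. The weights sum to one, so a constant
  performer's dwfPC equals their PC.
* **Mastery / NAM**: an activity is mastered when *any* 15-consecutive-play
  window contains ≥ 13 correct (`mastery_scope = "any_window"`; a
  `"final_window"` variant is provided because "mastered" could defensibly
  be read as end-state competence). The 13/15 threshold is calibrated by
  its binomial tail probability under chance,
  $P(X \ge 13),\ X \sim \mathrm{Bin}(15, 0.5) = 0.0037$
  (`criterion_tail_probability()` lets you recalibrate alternatives).
* **Response-bias filter**: participants who repeat one response category
  within an activity at ≥ 95% frequency are flagged for exclusion. The
  threshold is configurable because the precise original rule is not
  specified beyond its intent; when no response column exists the filter
  warns and passes everyone.

Zero-mastery (NAM = 0) participants are excluded from model fitting by
default: their choice data are dominated by floor-level noise. Exclusions
are always itemized in the pipeline report.

## The synthetic-cohort generator

The generator exists so that every downstream stage — signals, likelihood,
fitting, comparison, simulation, regression — can be tested against known
ground truth. It emulates the experiment's structure, not its stimuli:

* **Performance model.** Success probability on an activity follows a
  saturating exponential in the number of prior plays,
  $p(n) = a - (a - b)e^{-n/r}$. This is the simplest monotone curve with a
  flat unlearnable special case ($a = b = 0.5$ for A4). Defaults
  (asymptotes 0.95/0.92/0.90, rates 8/25/60 plays for A1/A2/A3, all
  baselines 0.5) were chosen once so that familiarization accuracy is
  ordered A1 > A2 > A3 > A4 ≈ 0.5, matching the intended difficulty
  ordering of the task battery. The actual categorization stimuli
  (monsters, food preferences, rule complexity) are deliberately not
  simulated; Bernoulli curves suffice for everything the pipeline
  computes.
* **Choice model.** Simulated agents run the *same* PC/LP softmax policy
  the fitting stage assumes, sharing the window code path, so the
  generative model and the likelihood agree exactly — which is what makes
  parameter recovery a meaningful test.
* **Protocol.** Familiarization presents A1..A4 round-robin, 15 cycles
  (the original forced-trial ordering is not documented; round-robin is an
  assumption), then 250 free trials. Participant $i$ simulates under seed
  `master_seed + i`, so any individual is replayable in isolation and
  cohorts are byte-reproducible.
* **Generating weights.** By default each agent's $(w_{PC}, w_{LP})$
  direction is uniform on the unit circle with $\tau \sim U(20, 60)$ —
  gains in the range where behavior is strategy-driven but stochastic,
  spanning PC-driven, LP-driven, and mixed profiles in one cohort.

What passing tests on such cohorts do **not** show: real participants
surely carry dynamics the generator lacks (drifting strategies, choice
autocorrelation and familiarity effects, fatigue, forgetting). Recovery
results certify the estimator under the model's own assumptions, not the
model's truth for humans.

## Fitting protocol

Per participant and model form, the negative log-likelihood is minimized
with bounded L-BFGS-B. Initializations follow the protocol exactly:
weights $\sim U(-1, 1)$, $\tau \sim U(0, 100)$. The optimizer is restarted
until 50 restarts land within `tie_tol` (default $10^{-4}$ NLL) of the
incumbent best — the restart that establishes a new best counts as its
first tie — or `max_restarts` (2000) is exhausted, which is flagged, not
raised. Box bounds are $w \in [-10, 10]$, $\tau \in [0, 1000]$: thanks to
the scale degeneracy, wide bounds cost nothing and merely keep
$e^{\tau U}$ finite.

Numerical details: probabilities are computed as log-softmax with
max-subtraction, so large $\tau$ cannot underflow the likelihood;
gradients are finite-difference by default (`gradient = "analytic"`
supplies the closed form, which reaches the same optima and is tested to);
the `random` baseline is evaluated analytically as $T\ln 4$. Model
comparison breaks exact AIC ties toward fewer parameters. The three
fitted forms are nested (set $w_{LP} = 0$, $w_{PC} = 0$, or $\tau = 0$),
so per-participant NLLs must be ordered bivariate ≤ best univariate ≤
random up to `tie_tol` — the test suite asserts this ordering for every
fit.

## Drive classification

Normalized weights are binned per axis into [−1, −0.33), [−0.33, 0.33),
[0.33, 1]. PC-driven = strongly negative $\hat w_{PC}$ with near-zero
$\hat w_{LP}$; LP-driven = strongly positive $\hat w_{LP}$ with near-zero
$\hat w_{PC}$; everything else is "neither". The bin edges are half-open
exactly as printed, so $\hat w_{PC} = -0.33$ already counts as near-zero.

## Forward simulation and recovery

`simulate_allocation()` resamples coefficient triples from a fitted pool
(500 iterations by default), runs each as a full agent, and reports mean
time shares ± SE. The environment's success model is injected: synthetic
play-count-indexed curves by default, or flat empirical per-activity rates
via `empirical_activity_rates()` for real data — covering both defensible
readings of "using the observed success rates". `mastery_trajectories()`
tracks the cumulative A3-mastery fraction, the A4-minus-A3 preference
among not-yet-masters (undefined once nobody is left), and mean trial-wise
SC. `recovery_experiment()` wraps simulate-then-refit over a grid;
$\tau = 0$ cells are flagged unidentifiable rather than errored, since
uniform data carry no directional information.

One behavior of the model worth knowing: because A4's outcomes stay
Bernoulli(0.5), its LP *noise floor* is the highest of the four
activities, so even pure LP-seekers allocate substantial time to A4 —
just systematically less than PC-averse agents do, and with far higher
eventual A3 mastery. The directional contrasts, not the absolute shares,
are the stable signature.

For scoring direction recovery across a whole cohort we use the pairwise
(Fisher–Lee) circular correlation of generating vs recovered weight
angles. Mean-direction formulations of circular correlation are
ill-defined when angles cover the whole circle — precisely the recovery
setting — whereas the pairwise statistic is rotation-invariant and stable.

## The SC–performance regression

`sc_quadratic_fit()` regresses dwfPC on mean SC, SC², and control
covariates (mean familiarization accuracy as "initial performance"; the
group indicator when more than one group is present) by OLS, and compares
against the linear-only model by AIC. An inverted-U — best learning at
intermediate self-challenge — appears as a negative SC² coefficient with
an AIC advantage. "Initial performance" is operationalized as the mean
familiarization accuracy across activities; the original covariate is not
defined more precisely, and this is the simplest faithful reading.

## Problem sizes

The test suite and `scripts/acceptance.R` run everything at the sizes the
analysis is defined for — 250 free-play trials, 15-trial windows, the full
50-tie restart protocol, 500-iteration allocation simulations — with a
60-participant cohort for the recovery experiment and 120 synthetic
participants for the regression recovery; cohorts in quick unit tests are
smaller (4–60 participants) since they only exercise mechanics. A full
recovery-plus-simulation acceptance run completes in a few minutes on one
CPU.

## Known limitations

* The likelihood conditions on observed outcomes; it does not jointly
  model learning curves and choices.
* Per-participant fitting only — no hierarchical pooling, by design.
* The response-bias filter is a configurable stand-in for an exclusion
  rule whose exact original definition is unavailable.
* Deterministic participants (likelihood ≈ 1) leave the normalized weight
  direction weakly identified; downstream classification of such fits
  should be read with care.
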