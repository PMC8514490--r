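# lpchoice

Tools for asking *how people decide what to practice* when they are free to
move among several learning activities. In free-choice learning experiments,
participants sample repeatedly from a small set of activities (here four:
three learnable categorization tasks of increasing difficulty, A1–A3, and
one unlearnable task, A4, whose feedback is random at 50%), receive binary
correct/error feedback, and allocate their own study time. `lpchoice`
implements the full analysis pipeline for such data: dynamic competence and
learning-progress signals, softmax intrinsic-utility choice models fitted by
multi-start maximum likelihood, AIC model comparison, behavioral indices,
strategy classification, and forward simulation — plus a synthetic-cohort
generator so every stage can be exercised and validated without any
external data.

## The model

For each activity *i* at free-play trial *t*, two signals are computed from
the most recent 15 outcomes on that activity (familiarization included):

- **PC** (percent correct): the proportion of correct guesses in the
  window — a competence signal.
- **LP** (learning progress): |mean of the first 10 − mean of the last 9|
  of the same window — a cheap estimate of the temporal derivative of
  competence. The absolute value lets performance declines register as
  progress-to-recover.

Each activity's intrinsic utility is a linear combination

&nbsp;&nbsp;&nbsp;&nbsp;U<sub>i,t</sub> = w<sub>PC</sub> · PC<sub>i,t</sub> + w<sub>LP</sub> · LP<sub>i,t</sub>

and choices follow a softmax with gain (temperature) τ:

&nbsp;&nbsp;&nbsp;&nbsp;p<sub>t</sub>(i) = e<sup>τ·U<sub>i,t</sub></sup> / Σ<sub>k</sub> e<sup>τ·U<sub>k,t</sub></sup>

Per participant, the parameters (w<sub>PC</sub>, w<sub>LP</sub>, τ) are
estimated by minimizing the negative log-likelihood of the observed
free-play choices with L-BFGS-B, restarted from random initializations
(weights ~ U(−1, 1), τ ~ U(0, 100)) until 50 restarts tie the incumbent
best. The bivariate model is compared by AIC (2k − 2 ln L̂) against
PC-only and LP-only reductions and against the zero-parameter uniform
baseline, whose AIC for 250 trials over 4 activities is analytically
500·ln 4 = 693.147. Because (c·w<sub>PC</sub>, c·w<sub>LP</sub>, τ/c)
yields identical probabilities, fitted weights are reported normalized to
unit Euclidean norm; binning the normalized pair at ±0.33 yields
**PC-driven** (ŵ<sub>PC</sub> ≈ −1, ŵ<sub>LP</sub> ≈ 0) and **LP-driven**
(ŵ<sub>LP</sub> ≈ 1, ŵ<sub>PC</sub> ≈ 0) strategy classes.

Derived behavioral indices:

- **SC** (self-challenge): per trial, 1 minus the chosen activity's PC
  rescaled by the running min–max range of all PCs experienced so far;
  1 = always picking the currently-hardest activity.
- **dwfPC**: difficulty-weighted final performance,
  fPC<sub>A1</sub>/6 + fPC<sub>A2</sub>/3 + fPC<sub>A3</sub>/2, where fPC
  is the mean of the last 15 outcomes on the activity.
- **NAM**: number of activities mastered, where mastery is ≥ 13 correct in
  any 15-outcome stretch of one activity (binomial chance probability
  0.0037).

## Worked example

```r
library(lpchoice)

cfg    <- cohort_config(n_per_group = 5L, master_seed = 42L)
cohort <- generate_cohort(cfg)           # 10 participants, 60 + 250 trials each
summ   <- participant_summaries(cohort$trials)
fits   <- fit_cohort(cohort$trials, seed = 1L)
compare_models(fits$fits)
```

```
   participant_id best_form best_aic delta_aic decisive bivariate_best
 1 p001           pc_only        4       2     TRUE     FALSE
 2 p002           pc_only        4       2     TRUE     FALSE
 3 p003           bivariate    200.     95.2   TRUE     TRUE
 4 p004           bivariate     25.4    15.2   TRUE     TRUE
 5 p005           bivariate     67.8   184.    TRUE     TRUE
 ...
```

`best_form` is the AIC argmin across the four model forms, `delta_aic` its
margin over the next-best form, and `decisive` flags margins of at least 2
AIC points. Participants fitted at `best_aic = 4` behaved deterministically
enough that the 2-parameter PC-only model already reaches likelihood 1.

Recovery of a known strategy — participant `p009` was generated as an
almost pure LP-seeker (normalized direction (−0.034, 0.999), τ = 39):

```r
b  <- subset(fits$fits, participant_id == "p009" & form == "bivariate")
nw <- normalize_weights(b$w_pc, b$w_lp)
nw
#> <normalized_weights (-0.0460, 0.9989)>
classify_drive(nw)
#> [1] "lp_driven"
```

The per-participant summary table carries the behavioral indices
(`dwfpc`, `nam`, `mean_sc`, exclusion flags), e.g. `p009` mastered all 3
learnable activities (`nam = 3`, `dwfpc = 0.90`, `mean_sc = 0.55`).

One call runs everything (simulate or read data, summaries, fits,
comparison, classification, allocation simulation, SC regression) and
writes a verifiable CSV bundle:

```r
res <- run_pipeline(run_config(out_dir = "demo_run"))
verify_bundle("demo_run")
```

A thin shell wrapper lives at `inst/scripts/run_pipeline.R`.

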