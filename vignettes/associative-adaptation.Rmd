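---
title: "Conditioning models of clamped-feedback reaching: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditioning models of clamped-feedback reaching: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptcond)
```

## The scientific setting

In a visuomotor adaptation task with *clamped* feedback, the cursor's angle
relative to the target is fixed on every trial — 15° away from the target (an
error signal) or 0° (no error) — while its radial position tracks the hand.
Participants are told to ignore the cursor and reach straight; their heading
angle nevertheless drifts away from the clamp, the signature of implicit
adaptation. `adaptcond` treats this task as a classical-conditioning
experiment: arbitrary tone and light cues that trigger the movement act as
conditioned stimuli (CSs), the clamped feedback is the unconditioned stimulus
(US), and the feedforward change in heading angle is the conditioned
response. The movement plan itself is modeled as an additional,
highly salient CS that is present on every trial.

Two trial-level models are implemented.

**Rescorla-Wagner (RW).** Each CS `i` carries an associative strength `V_i`
(degrees). On trial `n` the predicted heading is the summed strength of the
CSs present (plan + cue(s)). After the trial every present CS is updated by
the shared prediction error,

    V_i[n+1] = V_i[n] + alpha_i * beta * (lambda * US[n] - V_total[n])

with `US = 1` on 15°-clamp trials and `0` on 0°-clamp and no-feedback trials.
`lambda` (degrees) is the conditioning ceiling, `beta` the US learning rate,
`alpha_i` the salience of CS `i`. Absent CSs carry their strengths forward.
Because the update error is shared, simultaneously presented CSs compete for
a fixed associative capacity: the compound's strength is exactly the sum of
its elements' (additivity), and, for a fixed `alpha_tone + alpha_light`,
strength gained by one element is lost by the other (overshadowing).

**State-space (SS).** A single motor state with retention `A` and learning
rate `B`, driven by the previous trial's clamp error:
`x[n] = A*x[n-1] + B*e[n-1]`, `e = +15` on error-clamp trials and `0`
otherwise. The state does not depend on the current trial's cue, so the
model predicts adaptation effects but no cue-specific (Pavlovian) response.

All simulation uses adaptive-positive coordinates (positive heading = away
from the clamp), so the SS driving error is `+15`; this is the same model as
one driven by `-15` with the sign flipped afterwards.

### Default parameters

| parameter | default | units | why |
|---|---|---|---|
| `lambda` | 15 | deg | matches typical implicit-adaptation asymptotes |
| `beta` | 0.12 (differential) / 0.02 (compound) | — | standard simulation values for the two designs |
| `alpha_plan` | 0.99 | — | the movement plan absorbs nearly all salience |
| `alpha_tone`, `alpha_light` | 0.002 (differential) / 0.1 (compound) | — | arbitrary cues carry little salience |
| `A`, `B` | 0.9, 0.12 | — | conventional retention/learning values for reaching |
| fitting bounds | rates in (0, 1); `lambda` in (−30, 60) | | keeps fits in the interpretable regime |

## Trial schedules

Differential designs interleave CS+ (15° clamp) and CS− (0° clamp) trials
50/50 across 600 acquisition trials, then 200 no-feedback probe trials
(100 per CS). Orders are drawn by shuffling a balanced multiset — which
guarantees the exact counts — and rejection-sampled until the acquisition CS
sequence shows no significant lag-1 autocorrelation (two-sided p > 0.05 from
`cor.test` on the sequence against its one-trial lag), so participants (or
simulated learners) cannot predict the next cue from the current one. The
compound design pairs tone+light with the 15° clamp on all 600 acquisition
trials and probes compound, tone-alone and light-alone 100 times each.

Two numerical notes. First, the balanced-without-replacement construction
leaves a small negative long-range dependence in the sequence (if many CS+
occur early, CS− must dominate later); this shows up as a tiny positive bias
(~0.015°) in the current-CS regression weight of state-space simulations and
is far below every effect of interest. Second, the lag-1 screen virtually
always passes within a few shuffles; the attempt budget exists only to
surface genuinely over-constrained designs.

## Two notions of the "Pavlovian effect" for model trajectories

For data (and simulated data), the Pavlovian effect is empirical: the
trial-to-trial heading change `delta[n] = theta[n] - theta[n-1]` is averaged
in the 2×2 cells defined by the previous and current trial's CS type, and
the effect is the current-CS column contrast with previous-CS levels weighted
equally (`trajectory_effects()`, `cell_stats()`).

For noiseless model trajectories on a *single realized schedule*, that
empirical contrast is contaminated by finite-schedule sampling: the
state-space state `x[n-1]` depends on the whole CS history, and its sample
covariance with the current CS is not exactly zero even for sequences that
pass the lag-1 screen (it is zero only in expectation). A hand example makes
this concrete: on the 9-trial schedule `+,-,+,-,+,+,-,-,+` with `A = 0.5`,
`B = 0.1`, the empirical cell contrast of the state-space trajectory is
0.23° even though the model has no cue-specific response at all.

The parameter sweeps (`sweep_pavlovian()`) therefore default to the
*predictive* contrast (`predicted_cs_contrast()`): on each trial, the
difference between the heading the model would produce under the CS+ cue and
under the CS− cue given the same learning state — `V_tone - V_light` for RW,
identically 0 for SS. This is the structural quantity the heatmaps are
about: it is exactly zero for every (A, B) of the state-space model and
strictly positive for RW whenever `alpha_cs`, `beta` and `lambda` are
positive. The empirical contrast remains available via
`contrast = "empirical"`, and is always what the data-analysis pipeline
uses. Sweeps average over 8 seeded schedules to smooth residual schedule
idiosyncrasies.

## Synthetic participants

`generate_participant()` layers, on top of a model trajectory:

* iid Gaussian motor noise on heading, default `sigma_m = 3.5°` — the
  minimal execution-noise assumption consistent with the analyses;
* platform-dependent outliers (default rate 0.001 lab / 0.0135 web, matching
  reported exclusion rates), replacing the heading with a draw outside the
  platform's screening bounds;
* reaction and movement times from truncated Gaussians (293 ± 49 ms within
  [100, 400]; 103 ± 31.2 ms within [30, 300]) with a configurable
  slow-trial probability (default 0.07) that pushes RT above 400 ms or MT
  above 300 ms — the trials the delta analyses exclude;
* a feedback-correction discrepancy between the target-radius and 50-ms
  headings, Gaussian with mean −0.32° and SD 2.92°;
* counterbalanced clamp direction (cw/ccw; raw headings are stored
  unoriented) and CS+ cue assignment, with a schedule unique to each
  participant.

What this generator deliberately does **not** emulate: slow motor drift
(autocorrelated noise), participant-specific baseline reach biases, explicit
strategy use, online feedback corrections within a movement, or awareness
effects. Passing tests on synthetic cohorts therefore validate the
*pipeline* — that each stage computes what it claims on data with the
assumed structure — not the empirical claims about human behavior.

## Preprocessing rules

Orientation (sign-flip for ccw participants), baseline subtraction of the
first acquisition trial, outlier screening (lab: |heading| > 100° or
trial-to-trial change > 25°; web: heading outside (−50°, 70°) or change >
20°), and slow-trial flags (RT > 400 ms and/or MT > 300 ms, strict). Design
choices where the rules are silent: the change-based outlier rule flags the
*later* trial of the pair (preserving the already-accepted earlier
observation); screening runs on oriented angles (material only for the web
platform's asymmetric bounds); the delta spanning the acquisition/probe
boundary is never valid, since the phases are analyzed separately; slow
trials are excluded from delta analyses only, while model fitting masks only
outliers (the participant's learning system experienced slow trials too, and
their headings are real observations).

## Statistics

The 2×2 within-subject ANOVA is computed by `stats::aov` with an
`Error(id/(prev*cur))` stratification; partial eta-squared is
`SS_effect / (SS_effect + SS_error)` per stratum, and each effect's group
contrast gets a paired-t 95% CI (for a two-level within factor, F = t²
exactly — one of the identities the test suite checks against a longhand
sums-of-squares oracle). The compound probe uses `stats::friedman.test` over
per-participant medians (medians because the condition distributions are
skewed for small probe counts), Kendall's W = chi-squared / (N(k−1)), and
Bonferroni-corrected signed-rank pairwise tests. Dynamics: per 50-trial bin,
OLS of valid deltas on centered ±1 codes of previous CS, current CS and
their product (so main-effect weights are half-differences); per-participant
slopes of each weight series over bins are tested with one-sample and
paired t tests — a deliberate simplification of a mixed-model type × bin
interaction, chosen because per-participant bins are balanced by
construction here; it is reported as such.

## Fitting

Multi-start bounded least squares: 200 uniform draws within bounds, each
polished by L-BFGS-B (`pgtol 1e-10`, finite-difference step `1e-7`; the
coarse default step visibly limits achievable precision, so it is not used).
The RW family counts k = 5 parameters as written and the SS family k = 2,
with `AIC = n log(SSR/n) + 2k` on the valid-trial residuals. Only the
products `alpha_i * beta` (and their interplay with `lambda`) are
identifiable from one time course; every RW fit should be read through that
caveat. Model state propagates through masked trials; masked residuals are
dropped.

Recovery properties under the default noise (`sigma_m = 3.5°`, 16
participants, full 800-trial sessions): the cohort-median recovered products
`alpha_plan*beta` and `alpha_cs*beta` land within roughly 5–15% of the
generating values across cohort seeds, while the median per-participant
|relative error| is larger, roughly 25–35%. Two reasons: the single-trial
baseline subtraction injects a constant series offset of SD `sigma_m` that
the model class cannot absorb (the plan-rate error roughly triples relative
to fitting unbaselined series), and the cue salience contributes only
~0.0036°/trial against 3.5° noise. Estimation error grows monotonically
with `sigma_m` (checked over 1°, 3.5°, 6°).

## Problem sizes used by the test suite

Simulation checks run on full 600 + 200 trial sessions. Cohort-level checks
use 16 participants (the differential design's sample size); the
model-selection replication uses 20 cohorts of 4 participants at 20 restarts
per fit, which preserves the AIC ordering while keeping the suite quick; the
recovery check uses the full 200 restarts.

## Known limitations

* The conditioning models have no time axis within a trial: CS-US interval
  effects are represented only as design labels, not mechanistically.
* No Bayes factors, no mixed-effects slope model, no bootstrap CIs on fitted
  parameters.
* The generator's noise model is iid; structured residuals in parameter
  recovery would indicate the missing drift component.
* `aic()` refuses perfect fits (SSR = 0): compare SSR directly in that
  degenerate case.
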