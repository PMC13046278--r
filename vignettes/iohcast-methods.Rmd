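---
title: "Forecasting intraoperative hypotension: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting intraoperative hypotension: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
forecasting problem, the models and their assumptions, what the synthetic
data generator does and does not emulate, and the numerical and design
choices made where the problem left the design genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The forecasting problem

Intraoperative hypotension (IOH) is defined throughout as mean arterial
pressure (MAP) strictly below a threshold — 65 mmHg by default, 60 and 55 as
sensitivity settings — sustained for at least `min_duration` minutes
(default 1). Time is case-relative, 0-based, in integer minutes; a "1-minute
epoch" is the half-open interval [t, t+1). The classification unit is the
epoch ending at minute *t*, described by a 15-timepoint window of 17 dynamic
features plus age and sex, and labeled positive for horizon *h* ∈ {5, 10,
15} iff an IOH event **starts** within (*t*, *t+h*].

Three labeling decisions deserve emphasis:

- Epochs whose current minute is already below threshold are excluded by
  default (`exclude_in_event_epochs`): alerting on an event already underway
  is clinically vacuous. The behavior is configurable.
- Epochs whose future window touches sub-threshold minutes without a *new*
  event start are ambiguous (typically the tail of an ongoing event); they
  are excluded and counted rather than forced into either class.
- Epochs whose history or future window would extend past the case
  boundaries are dropped, so a case of duration *D* contributes at most
  *D − seq_len − h + 1* epochs.

One related property is subtler than it looks: lowering the threshold
65 → 60 → 55 monotonically shrinks the *set of sub-threshold minutes*, and
every 60-event nests inside a 65-event, but the event *count* is not
monotone — a single 65-run whose interior crosses 60 twice splits into two
60-runs. The tests assert the monotone formulations (minute coverage and
nesting).

## Cleaning pipeline

The order is fixed: plausibility filtering → percentile truncation →
missingness measurement → MAP formula imputation → forward fill → case
exclusion → (separately) z-score normalization. Bounds are strict — "MAP
below 30 or above 200 mmHg" removes 29.9 but keeps 30.0. Truncation limits
(type-7 percentiles at 0.1 and 99.9) and normalization statistics are
estimated on the training cohort only and frozen for reuse on validation or
external data; clinical cleaning pipelines rarely state their leakage
control for these statistics, and freezing is the defensible choice. A case is excluded
iff its missing-cell fraction over all channels × minutes — measured after
plausibility filtering and before imputation — strictly exceeds 10 %.

Two details are deliberate:

- **Which channels does grid-alignment fill?** `resample_to_grid()` applies
  its fill method (forward fill by default, linear interpolation as the
  sensitivity alternative) only to protocol-sparse channels, by default the
  non-invasive cuff pressures that are measured every few minutes by design.
  If resampling forward-filled *every* channel, monitor dropout could never
  be measured and the >10 % exclusion rule would be vacuous. `fill_channels
  = "all"` restores the blanket behavior.
- **The MAP imputation formula.** The conventional approximation is
  MAP = DBP + (SBP − DBP)/3. The source pipeline prints the inverted
  weighting MAP = ⅓·DBP + ⅔·SBP. Both are implemented
  (`cleaning_config(map_formula = )`); the default is the physiologically
  standard form, and the printed variant is retained verbatim rather than
  silently corrected, since its intent is unknowable.

## Feature construction

The 17 dynamic features are the 11 monitored channels (HR, pulse, SBP, DBP,
MAP, non-invasive SBP/DBP, respiratory rate, SpO₂, ETCO₂, temperature) plus
6 MAP-derived trend channels: 1- and 5-minute differences, trailing
5-minute rolling mean, SD and minimum, and minutes below 70 mmHg in the
trailing 5 minutes (70 mmHg sits above the 65 mmHg event threshold, so this
channel activates before an event does). The exact feature set of the
original model is not recoverable from its description, so the
`feature_spec()` is explicit, serialized with every model, and
user-replaceable. The 2 static covariates are age and sex, encoded by the
fixed affine maps (age − 50)/15 and sex − 0.5 — constants, hence
leakage-free.

The boosted benchmark flattens each window into 7 summary statistics per
channel — mean, SD, min, max, last value, least-squares slope, and minutes
below a channel-specific clinical reference (70 mmHg for MAP, 90 % for
SpO₂, ...) — plus the statics. Windows are stored normalized; the recipes
de-normalize with the dataset's frozen statistics so thresholds keep their
physical meaning.

## The Transformer and its training

Architecture (printed defaults): Conv1D over time (kernel 3, same padding)
lifting 17 channels to d_model = 64, additive sinusoidal positional
encoding, 8 pre-norm encoder layers (8 heads, feed-forward width 256, ReLU,
dropout 0.1 on both residual branches), a final layer norm, global average
pooling over the 15 timepoints, concatenation of the 2 statics, and a
linear head whose sigmoid gives the IOH probability. Choices the
description leaves open — kernel width 3, sinusoidal encoding, pre-norm
blocks, ReLU — are standard defaults and recorded in `model_config()`.

Training minimizes focal loss (α = 0.6, γ = 2; probabilities clamped to
[10⁻⁷, 1−10⁻⁷]) plus λ = 0.5 times a pairwise ranking surrogate of 1 − AUC:
the mean of softplus(s₋ − s₊) over positive–negative logit pairs, with at
most 10⁴ pairs subsampled per batch and the loss and gradient sharing one
subsample. The functional form of the "AUC-ranking term" is not pinned down
by its source; the RankNet-style softplus surrogate is the most common
differentiable choice. Note that this surrogate weights pairwise margins,
so its ordering across models agrees with 1 − AUC only statistically
(Spearman ρ ≈ 0.95 on random score sets), not identically.

The optimizer is AdamW (learning rate 2 × 10⁻⁴, decoupled weight decay
0.01, batch size 512 within the printed 400–1000 range). Validation loss is
monitored every `eval_every` epochs and training stops after `patience`
consecutive evaluations without improvement, returning the
best-validation checkpoint. The phrase "three consecutive epochs without
improvement" alongside "validation loss every 10 epochs" admits two
readings; both are implemented (`patience_unit = "evaluations"` — the
default — evaluates every 10 epochs, `"epochs"` evaluates every epoch).
The learnability checks in the test suite and the acceptance script use the
per-epoch reading with `max_epochs = 40`: on the strongly planted synthetic
signal the model converges within roughly ten epochs, and the per-epoch
rule lets early stopping act at convergence instead of only at 10-epoch
boundaries. The assertion itself (validation AUC ≥ 0.85) is unchanged.

The forward/backward pass is hand-written single-precision RcppArmadillo.
Its correctness is established two ways in the test suite: the forward pass
matches an independent pure-R double-precision implementation to ~10⁻⁷, and
the analytic parameter gradient matches central finite differences of that
reference to ~10⁻⁵ relative error. One analytic fact falls out of the
check: the gradient of the key-projection bias is exactly zero, because
adding a constant to every key shifts each attention row uniformly and
softmax is shift-invariant.

Dropout masks come from a dedicated xorshift generator seeded per training
step, so runs are bit-reproducible given one integer seed, independent of
R's RNG state.

## The boosted benchmark

`train_boosted()` fits XGBoost (single-thread, seeded) on the derived
features. Hyperparameter candidates are scored by grouped 5-fold
cross-validation — folds are patient-disjoint, the same leakage control as
the train/validation split — and the best row is refit on all training
data. The default grid is a single conventional configuration (eta 0.1,
depth 6, subsample 0.8), so no search runs unless requested; a one-row grid
skips cross-validation entirely and equals a direct fit.

## Evaluation and calibration

AUC uses the Mann–Whitney identity with tied pairs counted ½ (equivalent to
trapezoidal ROC integration); its 95 % CI is a seeded stratified bootstrap
(positives and negatives resampled separately, percentile interval, 1000
replicates by default), with DeLong's interval available through pROC for
cross-checking. Average precision is the step-wise PR integral with tied
scores collapsed to one operating point, so a constant predictor scores the
prevalence. The expected calibration error uses 10 equal-width bins on
[0, 1] (p = 1 falls in the last bin) with a percentile-bootstrap CI; the
binning and CI method are unstated in the source and follow common
practice, both configurable. Decision thresholds at operating points are
selected on the internal validation set (Youden's J with the gap-midpoint
convention, a recall floor, or a fixed probability) and every report
records its threshold provenance. Ties at the threshold count as positive
predictions.

## Alert simulation

`rolling_predict()` applies a trained model at every minute with a full
15-minute history, exactly reproducing batch predictions on identically
constructed epochs (asserted), and `simulate_alerts()` fires whenever the
probability reaches the decision threshold (≥ by default, matching the
operating-point convention; strict > and an optional refractory period are
configurable but off). The per-event lead time — minutes from the first
qualifying alert in the preceding horizon window to the event start — is a
package addition for synthetic validation; the original alert simulation
was qualitative and defines no such statistic.

## Hypotension burden and renal outcomes

Burden is the depth-weighted area under threshold,
Σₜ max(0, threshold − MAPₜ) × 1 min over minutes with MAP ≤ threshold
(mmHg·min); a duration-only mode (minutes below) is also reported because
the phrase "cumulative exposure ... in mmHg·minutes" admits both readings.
Exposure comparison is ≤ while event detection is strict < — the two
operators intentionally differ, as printed in their definitions. Missing
minutes contribute zero and are counted.

AKI staging (days 0–7) uses the KDIGO creatinine rules: stage ≥ 1 on a
≥ 0.3 mg/dL rise within any 48-h window (the preoperative baseline counts
as a day-0 value) or ≥ 1.5× baseline; stage 2 at ≥ 2.0×; stage 3 at ≥ 3.0×
or ≥ 4.0 mg/dL with a qualifying rise. Urine-output criteria are out of
scope (the cohort is defined by creatinine availability). AKD staging
(days 8–90) applies the ratio bands alone, stage 0 when no qualifying value
exists. Patients without a postoperative value inside 7 days are
indeterminate and excluded from the AKI model. One monotonicity subtlety:
raising only an *early* creatinine value can erase a 48-h rise without
reaching 1.5×, so "higher timeline ⇒ higher stage" holds in the directed
sense of increments non-decreasing in time (a worsening course), and that
is what the property test asserts.

The exposure–outcome model is a maximum-likelihood logistic regression of
the staged outcome on burden/60 (so the odds ratio is per 60 mmHg·min)
adjusted for a configurable covariate list (age, sex, diabetes, surgery
duration by default), with Wald 95 % CIs. Doubling the scaling constant
doubles the log-odds per increment exactly — a reparameterization identity
the tests check. Zero events, all-zero exposure, and suspected separation
(|coefficient| or SE > 15) are errors with diagnostics.

## The synthetic generator

`generate_case()` builds MAP as a per-case baseline (Normal(85, 8) mmHg,
truncated to [75, 110]) plus a discrete-time mean-reverting
(Ornstein–Uhlenbeck) noise process (reversion 0.15/min, innovation SD
0.8 mmHg) — the simplest process with realistic minute-scale
autocorrelation — and a deterministic episode profile: hypotensive episodes
are scheduled as a Poisson process (2.5/h), each preceded by a linear
descent starting 20 minutes before onset (longer than the longest forecast
horizon, so the planted signal is learnable at every horizon), holding a
nadir near 57 mmHg for a few minutes, then recovering. Overlapping episodes
merge via the pointwise minimum, so the logged schedule count stays exactly
Poisson. SBP/DBP are generated so the standard MAP formula holds exactly
(hence SBP ≥ MAP ≥ DBP everywhere); heart rate is negatively coupled to MAP
deviations; the remaining channels are stationary noise in physiological
ranges. Cuff pressures are observed every 5 minutes; monitor dropout (2 %
of cells; 15 % for a 5 % subset of cases, which the cleaning pipeline must
exclude) and implausible spikes (0.1 % of cells, values chosen outside the
plausibility bounds) are injected with their positions logged, so cleaning
tests are exact accounting identities, not statistical checks. Case
duration is Normal(120, 40) minutes floored at 45, age 54 ± 16 years, 49 %
male, and ~5 % of patients return for a second surgery so patient-level
splitting is exercised.

What the generator does **not** emulate: drug dosing and fluid events,
surgical stimulus, waveform morphology, measurement-device artifacts beyond
point spikes, circadian or case-phase nonstationarity, and any correlation
between hypotension risk and the static covariates. Consequently, passing
learnability tests show that the pipeline can extract a planted
pre-hypotensive drift under realistic noise, missingness and imbalance —
they say nothing about discrimination on real patients, where the
achievable AUC is set by physiology, not by construction.

`generate_renal_cohort()` draws burden from a zero-inflated gamma (40 %
zeros; gamma shape 1.2, scale 60 mmHg·min), covariates, and AKI/AKD
outcomes from logistic models whose exposure coefficient is log(OR) per
60 mmHg·min — the known truth that parameter-recovery tests target, with
defaults 1.10 (AKI) and 1.26 (AKD) and intercepts giving roughly 15 % and
5 % prevalence. Creatinine timelines are then *constructed* to encode the
drawn stage: negatives stay within [baseline − 0.05, baseline + 0.2] mg/dL
(which can neither reach 1.5× a baseline ≥ 0.5 nor rise 0.3 mg/dL within
48 h), positives peak in stage-specific ratio bands with safety margins
([1.55, 1.95], [2.05, 2.90], [3.10, 3.80]) chosen so rounding and noise
cannot cross a KDIGO boundary, and baselines are clamped to [0.5, 1.3]
mg/dL so the absolute ≥ 4.0 mg/dL rule cannot collide with a stage-2 band.
Staging the constructed timelines therefore recovers the drawn stages
exactly, which the tests assert. AKD severity leans on AKI severity when
both occur, giving the transition table its clinical gradient; the two
outcomes are otherwise drawn independently given burden and covariates.

## Problem sizes and numerical choices

The test suite and acceptance script run on one CPU. Sizes were chosen once
to make every statistical check informative at interactive timescales: the
learnability study uses a 300-case cohort (~23,000 labeled epochs,
~19,000 training) with the per-epoch early-stopping reading described
above; permuted-label null controls permute labels in both folds — the
exact null, AUC = 0.5 ± sampling noise, which also detects any leakage
through the pipeline — and train briefly, since the null does not depend on
training length; odds-ratio recovery runs 100 replicates per true OR at
n = 20,000 and pools 300 CIs (a scratch replication put Wald coverage near
its nominal 95 %, so short replicate runs are dominated by Monte Carlo
error in the coverage estimate itself); the calibration property uses 10⁵
draws. Determinism is asserted byte-for-byte on the pipeline's JSON
artifacts across two runs under one seed.

Other numerical conventions: type-7 percentiles everywhere; layer-norm
epsilon 10⁻⁵; probability clamp 10⁻⁷; Youden ties resolved toward the
lowest maximizing cutoff with the gap-midpoint convention; z-scored
channels with zero variance map to 0 with a warning; cells still missing
after imputation (leading gaps) enter the model at the channel mean (0 on
the z-scale).

## Known limitations

- The Transformer runs in float32 on CPU; training at the original study's
  scale (hundreds of thousands of cases) is out of scope, and no claim is
  made about reproducing discrimination or calibration values reported on
  institutional data.
- KDIGO/ADQI staging uses creatinine only; urine output and dialysis
  criteria are not implemented.
- The burden model is a single-exposure logistic regression; time-varying
  exposure, competing risks and causal adjustment beyond a covariate list
  are out of scope.
- The ranking term's pair subsample makes the training loss stochastic
  within a batch; with the per-step seeding this is reproducible but means
  λ > 0 runs are not invariant to the subsample cap.
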