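---
title: "Models and methods behind lineens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lineens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineens)
```

`lineens` implements an individual-differences pipeline for ensemble
perception with line stimuli: constrained stimulus generation, a generative
observer model, participant screening, reliability estimation, and Bayesian
correlation inference. This vignette explains each model, the numerical
choices, and what the simulation-based tests do and do not establish.

## Stimulus construction

Line features live on discrete grids: 19 lengths (44–116 px, step 4) and 19
orientations (4.5°–85.5° clockwise from vertical, step 4.5°). Each task's
120 trials fully cross 5 task-relevant means × 2 relevant SDs × 3
irrelevant means × 2 irrelevant SDs × 2 repetitions. The five relevant
means coincide with the five response probes, which is what makes "correct"
well defined as zero error in the 5-AFC format.

**Exact means on a discrete grid.** `sample_feature_values()` works in
integer grid-step units. The target mean fixes the required sum of the 12
step indices, and every search move transfers one step from one line to
another, so the sample mean is preserved *bit-exactly* throughout; only the
spread is searched. A greedy descent picks, at each iteration, the transfer
bringing the sum of squared deviations closest to the target
`(n−1)·sd²`, with random restarts to escape bound-constrained local optima.

**SD convention and tolerance.** We target the sample SD (n−1 denominator)
and accept solutions within ±0.5 px / ±0.5° (configurable). Exact SDs are
often unattainable: a parity argument shows the sum of squared step
deviations is fixed modulo 2, so, e.g., a 12-line ensemble with step-4
lengths and target SD 12 px can only reach SD 11.94 or 12.06. Means,
by contrast, are always hit exactly for every design cell (all targets are
representable; the tests verify this for all 8 + 6 design means). Practice
trials use the same machinery at SD 4 px / 4.5°.

**Pairing and layouts.** Lengths and orientations are shuffled
independently before being paired with layout cells, keeping the two
features uncorrelated across lines within an ensemble. Spatial layouts are
drawn per experiment version under the structural constraint (12 of 20
cells on a 5-column × 4-row grid, exactly 3 per row) and then held fixed
across every trial of a task, making location fully predictable. The
specific configurations used in the original data collection are not
recoverable, so the package samples constraint-satisfying layouts from a
seed; what matters to the analysis is the constraint and the fixedness, not
the particular cells. Trial order is a single seeded shuffle recorded in
the design output.

## The observer model

The paper-level analysis needs per-participant error scores with a
controllable shared-ability structure; the generative model is deliberately
minimal:

* Observer *i* has internal noise SDs `(σ_len, σ_ori)`, with
  `(log σ_len, log σ_ori)` bivariate normal: locations `μ_len, μ_ori`,
  spreads `τ_len, τ_ori`, correlation `ρ_ability`. The log-normal keeps
  noise positive and makes one correlation parameter the single source of
  shared ability.
* On each trial the internal estimate is `true mean + N(0, σ_task)`; the
  response is the nearest of the 5 probes. Midpoint ties go to the lower
  probe — a measure-zero event under continuous noise, fixed only for
  determinism.
* With probability `lapse_rate` (always, for an inattentive observer) the
  response is instead uniform over the probes.

Because the probes are 12 px / 13.5° apart, a middle-probe trial is correct
iff the estimate falls within ±6 px (±6.75°) of the truth, giving the
closed-form accuracy `acc(σ) = (8Φ(6/σ) − 3)/5` over the balanced design
(the two extreme probes have one-sided decision boundaries). This closed
form is both a unit-test oracle and the calibration tool.

### Calibration of the default preset

The default `cohort_params()` represents the *included* cohort of a study
of this design: n = 77 attentive observers, no inattentive fraction, 2%
lapses. Its values were set analytically and confirmed by simulation:

* `μ`: inverting `acc(σ)` at the target marginal accuracies (0.43 for
  length, 0.50 for orientation) gives σ ≈ 15.8 px and 13.4°.
* `τ`: the delta method on `acc(σ)` maps the target accuracy SDs (0.11,
  0.16) to spreads of 0.45 and 0.5 on the log-noise scale.
* `ρ_ability = 0.71`: the across-task correlation of *observed* mean
  absolute errors is the latent correlation attenuated by trial-level
  measurement noise (reliability ≈ 0.92–0.94 with 120 trials), so a latent
  0.71 yields an observed correlation centred on 0.65 — the calibration
  target. Across 200 simulated cohorts the median observed r is ≈ 0.66
  with a 95% cohort-to-cohort band of roughly (0.52, 0.78).

The generator emulates the first two moments of the error measures, their
reliability, and the correlation structure. It does **not** emulate
sequential/learning effects, reaction times, eccentricity weighting,
response biases (e.g. salience-driven overweighting of long lines), or
non-Gaussian noise; passing recovery tests therefore show that the
*pipeline* is sound under the stated generative assumptions, not that real
data obey them.

## Scoring

Error is the absolute distance between the chosen probe and the true mean,
in feature units; the per-participant measures are accuracy, mean absolute
error, and the SD of errors. For the SD-of-errors measure we use *signed*
errors (chosen − true): its role is robustness against bias confounds,
which only signed errors can expose; the SD of absolute errors is emitted
as a secondary column. Orientation is treated linearly — the stimulus range
spans less than 90°, so circular wrap-around never binds.

## Screening

Trial difficulty is the proportion correct on each trial among participants
above chance (> 1/5) on that whole task, computed in a single pass (not
iterated). Person fit is the Pearson correlation between a participant's
0/1 correctness vector and the task's difficulty vector, computed per task
because the difficulty vectors are task-specific; a participant at or below
chance on some task is rescued only if their fit is ≥ 0.15 on *every* such
task. An undefined fit (constant correctness) fails the criterion: an
all-incorrect vector carries no evidence of effort. Exclusions with no
algorithmic definition (technical failure, misread instructions) enter as
an explicit manual-exclusion ID list.

One structural fact worth knowing: a fully random 5-AFC responder clears
the strict `> 1/5` chance criterion on one 120-trial task with probability
`P(Bin(120, 0.2) > 24) ≈ 0.446`, hence on both tasks with probability
≈ 0.20. The inclusion rule is therefore intrinsically porous to uniform
responders — no implementation of it can exclude more than ≈ 78% of them
(the person-fit rescue adds ≈ 2.5 points of inclusions). The screening
tests assert rates consistent with this cap.

## Reliability and disattenuation

Cronbach's α treats the 120 per-trial absolute errors as items:
`α = k/(k−1) · (1 − Σ item variances / variance of participant totals)`.
Items are the absolute errors (not correctness) because α must bound the
correlation of the mean-absolute-error scores that enter the analysis. The
attenuation correction divides the observed correlation by `√(α₁·α₂)`;
values above 1 are flagged, never clamped. The shared-variance percentage
squares the disattenuated r *after* rounding it to the 2-decimal reporting
precision, so the printed percentage is exactly consistent with the printed
correlation (0.69² = 47.6%); the unrounded square is also returned.

## Bayesian correlation inference

**Likelihood.** We use the exact sampling density of the Pearson
correlation given ρ and n, in Hotelling's rapidly converging form with the
Gauss hypergeometric factor `₂F₁(1/2, 1/2; n−1/2; (1+ρr)/2)`. The Bayes
factors of interest are astronomically large (10⁸ and beyond), where the
Fisher-z approximation drifts by an order of magnitude in the tails; the
z approximation is retained behind `method = "fisher-z"` as a cross-check.
The ₂F₁ series is summed directly (termwise ratio < x < 1, with the large
third parameter accelerating convergence) to a 10⁻¹⁴ relative tail bound.

**Prior.** A stretched beta on (−1, 1) with width κ: `(1+ρ)/2 ~
Beta(1/κ, 1/κ)`. The default κ = 1 is the uniform prior, the common
analysis-software default; κ is exposed as a parameter. The one-sided
`BF₊₀` truncates the prior to (0, 1).

**Numerics.** The likelihood ratio is evaluated in log space; its maximum
over a 401-point grid is factored out before adaptive quadrature
(`stats::integrate`, relative tolerance 10⁻⁸), so a BF of 10¹¹ loses no
precision. At r = 0 the one-sided and two-sided Bayes factors coincide by
symmetry — a structural identity the tests check. The credible interval is
*central* and computed under the two-sided prior (the convention matching
how such intervals are reported alongside BF₊₀), via trapezoid
normalization of the log posterior on an 8192-point grid and interpolated
CDF inversion; the grid resolves quantiles well beyond the 10⁻⁴ level.
Degenerate inputs — |r| = 1, n < 4, zero-variance score vectors — are
rejected or flagged (`correlate_tasks()` returns a flagged degenerate
result rather than an error, since a zero-noise cohort is a legitimate
boundary case of the simulator).

**Jeffreys labels.** Evidence bands are half-open on the left — (1, 3] very
weak, (3, 10] substantial, (10, 30] strong, (30, 100] very strong, > 100
decisive — so a boundary value takes the weaker label; BF ≤ 1 is labelled
as favouring the null.

**Sequential design.** `sequential_bf()` evaluates BF₊₀ first at
`n_start = 75` pairs and then after each additional pair (batch size
configurable), stopping at the first crossing of 3 or 1/3. Under the
calibrated preset the first look virtually always lands far beyond the
upper boundary, so the design stops at 75 with positive support.

## Problem sizes in tests and the acceptance script

Monte-Carlo checks use sizes chosen to put the Monte-Carlo error well below
the asserted tolerances: 10⁶ prior draws per grid point for the Bayes
factor oracle (relative error ≲ 0.4% against a 1% tolerance), 10⁶ response
draws for the Gaussian-CDF accuracy oracle (binomial SE ≈ 0.0005 against a
0.002 tolerance), 200 cohorts of 77 observers for parameter recovery, and
100 cohorts for screening recovery. The acceptance script re-derives every
reported quantity from these same computations under a caller-supplied
seed.

## Known limitations

* The observer model is a stand-in: real participants' error distributions
  are constrained here only through their first two moments and the 5-AFC
  error support.
* The attained ensemble SDs are grid-limited (±0.5 tolerance); analyses
  that depend on exact stimulus variance should use the realized values
  recorded in the design output, not the nominal targets.
* The screening rule cannot exclude more than ≈ 78% of uniform-random
  responders (binomial porosity of the chance criterion above); studies
  needing stronger protection must add criteria beyond this rule.
* The disattenuated correlation is a ratio estimator without an
  uncertainty interval here; it is reported as a point value, flagged when
  it exceeds 1.
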