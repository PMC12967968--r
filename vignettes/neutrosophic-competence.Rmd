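---
title: "Neutrosophic scoring of stereotactic surgical performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutrosophic scoring of stereotactic surgical performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutroscore)
library(dplyr)
```

## The problem

Conventional assessment of stereotactic targeting skill — deep brain
stimulation electrode placement being the canonical example — reduces a
trajectory to one number, the final Euclidean deviation `d` from the
target, and applies a fixed cutoff such as *pass if d ≤ 2 mm*. That rule
is blind to *how* the position was reached: a trainee with a tremulous,
drifting instrument can land inside tolerance and be certified alongside
a genuinely steady expert. `neutroscore` implements a scoring model that
treats competence, ambiguity and error as three separate quantities so
that exactly those cases become visible.

## The model

Each attempt is summarised by the behavioural vector `(d, s)`:

* `d` — Euclidean distance (mm) between the instrument tip and the
  target, computed from 3-D coordinates by `target_deviation()`;
* `s` — motor instability, the total variance (trace of the positional
  covariance) of the tracked tip trajectory over an observation window,
  computed by `trajectory_instability()`. It is a scalar surrogate for
  tremor and micromovement.

The attempt is mapped to a single-valued neutrosophic triple, three
*independent* memberships in [0, 1]:

* **Truth** (competent): `T = max(0, 1 − d/d_max) · max(0, 1 − s/s_max)`
  — high only when both deviation and instability are low;
* **Indeterminacy** (borderline): `I = max(0, 1 − |d − d_mid|/d_range) ·
  min(1, s/s_max)` — a triangular kernel centred on the mid-risk
  deviation, switched on by instability. It captures the attempt that is
  "near tolerance but shaky";
* **Falsity** (unsafe): `F = max(min(1, d/d_crit), min(1, s/s_max))` — a
  worst-case criterion: either excessive deviation or excessive
  instability alone is enough to call the attempt unsafe.

Unlike a probability distribution the triple is not constrained to sum
to one (`0 ≤ T + I + F ≤ 3`); hesitation and error can coexist. The
composite competence score collapses it order-preservingly:

$$S = \frac{2 + T - I - F}{3} \in [0, 1],$$

increasing in Truth, decreasing in both Indeterminacy and Falsity —
unresolved ambiguity is penalised exactly like active error. The fully
saturated error state (T = 0, I = 0, F = 1) pins the score at the floor
`S = 1/3`; with default parameters every attempt with `d ≥ 4` mm sits
there no matter how steady the hand (`nx_evaluate()` and the tests
verify this identity exactly).

## Parameters, units, defaults

All five constants live in `nx_params()` and are injected into every
computation; nothing is hard-coded at call sites.

| parameter | default | unit | role |
|---|---|---|---|
| `d_max` | 3.0 | mm | Truth distance normaliser — upper bound of generally accepted targeting error |
| `s_max` | 0.30 | model units | instability normaliser, a conservative ceiling above physiological tremor amplitude |
| `d_crit` | 4.0 | mm | deviation at which Falsity saturates — clearly unsafe placement |
| `d_mid` | 1.5 | mm | centre of the ambiguous zone: the transition from high precision to elevated risk |
| `d_range` | 1.5 | mm | half-width of that zone; Indeterminacy vanishes outside `d_mid ± d_range` |

Two deliberate conventions:

* **Distinct normalisers.** The Truth function's distance normaliser
  (3 mm) and the instability normaliser (0.30) are distinct, independently
  configurable constants, here named `d_max` and `s_max`.
* **Units of `s`.** Instability is formally a variance, but every
  formula uses only the ratio `s/s_max`, so `s` is treated as a
  dimensionless model unit; only consistency between `s` and `s_max`
  matters. If your trajectories are recorded in mm, pass the variance
  from `trajectory_instability()` and set `s_max` on the same scale.

Band cut points on S default to 0.3, 0.5 and 0.7 (`nx_bands()`),
delimiting the *unsafe*, *at-risk*, *indeterminate* and *expert* regions
of the landscape. Scores exactly on a cut are assigned upward
(left-closed intervals) — a deterministic tie-break we fixed since crisp
regions versus purely visual contours is a presentation choice; the cut
points and labels are fully configurable.

## The synthetic cohort

`simulate_cohort()` generates the three-class validation cohort:
independent Gaussian draws per class, 20 attempts each by default,

| class | d prior | s prior |
|---|---|---|
| expert | N(0.5, 0.20) | N(0.05, 0.01) |
| indeterminate | N(2.0, 0.30) | N(0.15, 0.05) |
| novice | N(4.0, 0.50) | N(0.25, 0.07) |

rectified to the non-negative domain. Truncation `max(0, x)` is the
default; reflection `|x|` is available as `rectify_mode = "absolute"`
since both conventions are defensible and, at these priors, nearly
indistinguishable (negative draws are rare). `d` and `s` are drawn
independently within each class — an explicit modelling assumption, not
a claim about real kinematics.

What the generator emulates is *inter-subject* variability of the two
summary variables. It does not simulate trajectories over time,
correlated deviation–instability behaviour, heavy-tailed tremor, or
learning effects; passing tests on this cohort demonstrates the internal
consistency and discriminative geometry of the score, not clinical
validity on real recordings.

```{r cohort}
cohort <- simulate_cohort(seed = 1)
describe_groups(cohort)
```

## Validation pipeline

`validate_cohort()` reproduces the standard assessment chain on any
scored cohort: per-group descriptives of S; Shapiro–Wilk normality per
group (delegated to `stats::shapiro.test()` — assessment plumbing, not
the contribution); a Kruskal–Wallis omnibus test; Dunn's post-hoc
pairwise z tests with Bonferroni adjustment (`min(1, m·p)` over
`m = k(k−1)/2` pairs). The nonparametric branch always runs and both the
normality gate outcome and the rank tests are reported.

The rank statistics are implemented in the package (no Dunn
implementation ships with the installed stack) in their tie-corrected
forms: mid-ranks for ties, the `1 − Σ(t³−t)/(N³−N)` divisor in H, and
the `Σ(t³−t)/(12(N−1))` term in the Dunn variance. Tie correction is
material here, not cosmetic: novice scores tie *exactly* at the 1/3
floor by construction. Tests verify both statistics against a
brute-force sort-and-average rank oracle on random tied instances and
against `stats::kruskal.test()`. Two-sided p-values throughout; with all
pooled values identical, H is defined as 0 and the Dunn z as 0.

Typical behaviour across replicate cohorts at these defaults: the
omnibus test and the expert-vs-novice and expert-vs-indeterminate
contrasts reject essentially always, the novice group fails normality in
most runs (its distribution is a truncated spike at 1/3), and the
indeterminate-vs-novice contrast hovers around the significance
boundary — its Bonferroni-adjusted p falls on either side of 0.05 in
roughly half of the seeds, which is itself an informative feature of the
overlap between borderline and unsafe performers.

```{r validate}
report <- validate_cohort(cohort)
glance(report)
tidy(report)
```

## Landscape and discordance

`competence_surface()` evaluates the full bundle on a regular grid
(default d ∈ [0, 5] mm in 0.02 mm steps, s ∈ [0, 0.35] in 0.005 steps —
251 × 71 nodes, covering all class priors ±4σ plus the saturation
region; a finer grid changes nothing but file size, since the surface is
piecewise linear between the model's breakpoints). Grid evaluation is
required by tests to agree with scalar evaluation node for node.
`decision_regions()` applies the band classifier cellwise,
`contour_masks()` extracts the super-level sets at the cuts (nested by
construction), and `autoplot()`/`plot_decision_regions()` render them.

`discordance_table()` performs the audit the model exists for: it flags
attempts that pass the classical rule (`d ≤ 2` mm,
`classical_pass()`) while the neutrosophic band sits below *expert*.
The canonical example: `d = 1.9`, `s = 0.29` passes classically, yet
T ≈ 0.012, I ≈ 0.709, F ≈ 0.967 give S ≈ 0.11 — deep in the unsafe band.
In simulated cohorts several indeterminate-class attempts per run are
such false positives.

```{r discordance}
discordance_table(cohort) |>
  filter(discordant) |>
  count(group)
```

## Numerical choices and edge cases

* Pure closed-form arithmetic throughout — no iterative numerics; test
  tolerances are 1e-9 or tighter (1e-12 for exact identities).
* Negative or non-finite `(d, s)` inputs are rejected with row numbers;
  rectification of negatives must be requested explicitly
  (`rectify = "truncate"`/`"absolute"`).
* Trajectory variance uses population normalisation (1/n) by default,
  with the sample convention (1/(n−1)) switchable; the choice is
  immaterial to the model (only `s/s_max` enters) but documented for
  reproducibility.
* Cohort CSVs are written with `%.17g` precision so write-then-read
  round-trips doubles exactly; human-readable statistical tables are
  rounded to 4 decimals separately.
* Every stochastic entry point takes an explicit seed and restores the
  caller's RNG state; identical configurations reproduce output files
  byte for byte.

## Problem sizes used in the test suite

Replicate-based checks use 100 cohorts of 60 attempts (the study-scale
configuration), property sweeps use 10⁵ random `(d, s)` points, and the
rank-statistic oracle runs 200 random tied instances of ≤ 20 values —
sizes at which every distributional claim checked is already stable.

## Known limitations

* The triangular/rectified-linear kernels are fixed; no trapezoidal or
  Gaussian alternatives, no interval-valued extensions, and no fitting
  of parameters to data.
* The instability surrogate discards all spectral/temporal structure of
  tremor; windowing of trajectories is the caller's responsibility.
* The simulator's Gaussian, independence and rectification assumptions
  are idealisations; conclusions about real surgical performance require
  real kinematics, for which the parameter set should be recalibrated
  (`nx_params()` exists precisely so that this is a configuration
  change, not a code change).
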