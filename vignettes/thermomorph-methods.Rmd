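---
title: "Models and methods behind thermomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermomorph)
```

`thermomorph` analyses three measurement streams from colour-polymorphic
grasshoppers — radiant heat-up traces, thermal-gradient occupancy tracks and
reflectance spectra — and tests morph, brightness, mass and sex effects with
a design-respecting bootstrap and a classical test-selection tree. This
vignette records the models, the tunable parameters and their defaults, the
numerical conventions, and the design choices made where the design was
genuinely open. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## The measurement design being modelled

Each individual (species ∈ {*ungarica*, *sibiricus*, *parallelus*}, sex,
colour morph, body mass) contributes:

* an **internal** temperature trace (thoracic thermocouple, one sample per
  5 s) and an **external** trace (thermal camera, per 20 s), for ~13.2 min
  (792 s) under an infrared lamp after chilling to 5.8 ± 3.0 °C;
* a **gradient track**: six runway positions at 10-min intervals on an
  80 cm thermal gradient (≈10 °C cold end to ≈51 °C hot end, release at
  40 cm), each sighting missing with small probability (1.6%) when the
  animal perched on walls or lid;
* ten **reflectance spectra** (five dorsal pronotum, five lateral lobe) on
  a 1 nm grid over 300–1000 nm, each carrying a narrow spurious instrument
  peak between 654 and 659 nm.

*ungarica* and *sibiricus* are dimorphic (green/brown; pied browns pooled
with plain brown); *parallelus* adds dorsal-green and lateral-green
intermediates. Analyses subset by species × sex (six subsets).

## Summary statistics

* **Heat-up speed** — traces are truncated at 20 s because internal
  readings can still *fall* during the first seconds (haemolymph mixing,
  seen in ~24% of animals); the speed is the endpoint rate
  (T(240) − T(20)) / 220 s, reported in °C/min. An OLS-slope variant over
  the same window is available (`method = "ols"`) as a sensitivity check;
  the endpoint form is the default because it is the minimal reading of a
  "rate of change between two time points". Both window ends are
  inclusive, and both sampling grids (5 s, 20 s) hit 20 and 240 exactly.
* **Equilibrium temperature** — mean over 660–760 s inclusive (21 internal
  samples, 6 external). Groups that never plateau are flagged per
  species × sex in configuration (`equilibrium_not_reached`, default
  `"ungarica.F"`), not auto-detected: the original judgement was made by
  inspection, and an automated plateau detector would silently change which
  animals enter which analysis.
* **Preferred temperature** — substrate temperatures come from a
  least-squares cubic fitted to the five calibration points per runway
  (exactly recovering any polynomial of degree ≤ 3; no extrapolation
  outside 0–80 cm). The preference is the mean over sightings at minutes
  30–60 *inclusive* (4 of 6 sightings). Inclusivity at 30 min was an open
  reading of "between the 30th and 60th minutes"; we include both ends to
  maximise data use. Missing sightings drop out; the result is missing only
  if all four window sightings are.

## Spectra processing

Raw spectra are resampled (linear interpolation) onto the fixed 1 nm grid
if needed, then artefact-corrected: samples at 655–658 nm are replaced by
the scalar mean of the flanks at 650–654 and 659–664 nm. The published
window bounds overlap at the nanometre level ("654 and 659" as artefact
bounds, flanks "650–654" and "659–664"); we resolve the overlap by treating
654 and 659 as *flank* (trusted) samples. The correction is idempotent and
touches nothing else. The ten corrected replicates are averaged pointwise
(body parts implicitly weighted 5 + 5), and **mean brightness** is the
arithmetic mean over all 701 grid points. Brightness is linear under
aggregation — the mean-spectrum brightness equals the mean of replicate
brightnesses exactly — so correcting before or after averaging is
equivalent; we correct raw spectra first. No visual-system weighting is
applied: this is physical, not perceived, brightness.

## The morph-constrained bootstrap

The exchangeable unit is the individual: a resample draws whole records
(summaries plus complete time series) with replacement *within each morph
stratum*, keeping every stratum at its original size. This preserves the
design's morph balance and keeps difference-of-means statistics comparable
across replicates. With B = 1000 replicates, the 95% CI is read off the
replicate distribution by the percentile method; we use quantile type 7
(linear interpolation of order statistics, R's default), configurable,
since "percentile method" does not pin down a convention. An effect is
declared when the CI excludes zero. The point estimate is always computed
on the original subset and never altered by resampling.

For time-resolved curves (green-minus-brown mean difference, or Spearman
correlation of brightness/mass with temperature, per time point), **one**
set of resamples is drawn and evaluated at every time point, giving
coherent bands rather than independent pointwise resamples. Internal and
external channels keep their own grids; nothing is interpolated across
channels. Covariate (brightness/mass) bootstraps also preserve morph
strata; whether the original analysis did is not recoverable from the
text, and we chose uniformity — this is an interpretation, flagged here.
Replicates on which a statistic is undefined (e.g. zero rank variance) are
recorded as missing; a result with more than half missing is flagged
invalid.

No multiple-testing correction is applied across time points or subsets
(none was applied in the original analyses), and intervals are plain
percentile, not BCa or studentized.

## The classical decision tree

Two groups: Student *t* when normality and homoscedasticity hold, Welch
when only normality holds, Mann–Whitney otherwise. More than two groups
(the four *parallelus* morphs): one-way equal-variance ANOVA when
assumptions hold, else Kruskal–Wallis, with all pairwise Mann–Whitney
comparisons attached when KW gives p ≤ 0.05. Covariates: Pearson under
bivariate normality, else Spearman. All tests are two-sided.

Normality was originally judged from QQ plots; an automated default must
stand in for that judgement, and we use per-group Shapiro–Wilk at α = 0.05,
overridable by explicit flags so a user can reproduce any manual call.
Homoscedasticity uses the F test (2 groups) or Bartlett (> 2); when it
fails and all values are positive, the checks are repeated on log-scale and
`transform = "log"` is reported when that rescues homoscedasticity (the
log-transform branch applies to parametric tests only; rank tests are
transformation-invariant). Note a structural consequence of the automated
default: with three independent α = 0.05 checks, perfectly well-specified
data pass all of them with probability ≈ 0.95³ ≈ 0.857, not 0.95 — the
package's tests assert exactly that rate.

The Mann–Whitney U is computed from mid-ranks (ties get half-weight); the
p-value uses the exact null distribution when there are no ties and both
n ≤ 20, and otherwise a normal approximation with tie-corrected variance
and continuity correction.

## The synthetic generator: what it emulates

The generator's defaults *are* the study's stated conditions: sample sizes
(60/68, 38/26, 120/120 females/males; morph strata 30/34, 19/13, 30/30 per
sex), group mass and brightness means/SDs as printed, chill start
5.8 ± 3.0 °C, dip incidence 0.24, runway endpoints 10.0/51.0 °C with the
printed endpoint SDs and a 27.1 °C release temperature at 40 cm, missing
sightings at 0.016, six sightings at 10-min intervals, and the 654–659 nm
spike.

Where the study states no value, one realistic choice was made and frozen:

* **Heat-up model.** No functional form is published; we use
  lumped-capacitance Newton heating, T(t) = T_eq − (T_eq − T0)·e^(−kt),
  with k = k0·(m/m_ref)^β, β = −1/3 (surface-to-volume scaling). This is
  the simplest model producing all three observed phenomena: heavier
  animals heat more slowly, traces plateau, and sex differences ride on
  mass. k0 = 0.006 s⁻¹ at m_ref = 0.2 g: the endpoint heat-up speed
  f(k) ∝ e^(−20k) − e^(−240k) is increasing in k only below
  k ≈ 0.0113 s⁻¹, and k0 = 0.006 keeps every realistic mass on that rising
  flank so that speed is strictly decreasing in mass — at larger k0 the
  summary statistic would be insensitive to mass, contradicting the
  phenomenology being emulated.
* **Equilibrium asymptote** T_eq = 40 °C for all groups (the study reports
  no per-group asymptotes). Sex differences in *measured* equilibrium then
  emerge mechanically: heavier individuals are further from the asymptote
  during 660–760 s. *ungarica* females get k_scale = 0.15 so they do not
  plateau within 13.2 min, as observed; this is a config default, not
  hard-coded.
* **Initial dip**: with probability 0.24 the first 20 s are replaced by a
  linear segment from T0 + 1.5 °C down to the backbone value at 20 s. Only
  its existence and cause are documented; a linear decline is the least
  structured emulation. For fast heaters the segment can be non-monotone
  (the backbone rises quickly); it always lies above the backbone start
  and is removed by truncation before any analysis.
* **Observation noise** 0.3 °C (internal) and 0.8 °C (external — the
  camera is spec'd at ±2 °C); **preferred temperatures** N(32, 3) °C
  within the species' known 22–41 °C preference range, with *ungarica*
  males at 33.3 and females at 30.5 (the study reports a ≈2.8 °C sex gap
  in that species); **track relaxation** toward the preferred position
  with a 3-min time constant (converged well before the first sighting)
  plus 2 cm positional noise, clamped to the runway; **spectral shapes** —
  a 550 nm reflectance peak plus near-infrared rise for green, a gently
  rising featureless curve for brown, intermediates green on one body part
  only — scaled so the expected processed brightness equals the group
  target, with mean-one lognormal replicate jitter (σ = 0.05) and a
  +15% spike at 654–659 nm.
* **Randomness** is one cohort stream split hierarchically by individual
  id (FNV-style string hash), so enlarging a cohort never perturbs
  already-generated individuals.

Morph effects on thermal parameters default to **zero** — the generated
world is the study's null. Setting `morph_effect_teq`, `morph_effect_k` or
`morph_effect_pref` nonzero gives green (and, at half weight, the
intermediate morphs) an offset for power studies.

### What a green test does and does not establish

The generator reproduces the design's sampling structure and the marginal
group distributions, not real cuticles or real behaviour: spectra are
smooth two-shape mixtures (no individual spectral texture), movement is
relaxation-to-preference (no exploration, no wall-perching dynamics beyond
missingness), traces are exactly Newtonian plus white noise (no lamp
drift, no autocorrelated sensor error), and masses/brightnesses are
Gaussian within groups. Green tests therefore establish that the *pipeline
code* is correct and calibrated under the stated design — e.g. that the
constrained bootstrap's null rejection rate is near nominal — not that the
biological conclusions would replicate on new animals.

### Known numerical and statistical caveats

* The spike contaminates the two flank samples at 654 and 659 nm, so
  artefact correction leaves a bias of ≈ +0.06% reflectance in mean
  brightness at spike +15 — an order of magnitude below group SDs and
  inside the Monte-Carlo tolerance of the brightness tests; accepted
  rather than making generator and corrector artificially consistent.
* Percentile intervals for a difference of means over-reject slightly at
  small strata (≈7% at 15 + 15 under this generator); at the study's
  30-per-morph strata the rate is within 5% ± 2 pp. This is a property of
  the percentile method, not of the implementation.
* The trace grid is `seq(0, by = dt, length.out = floor(duration/dt) + 1)`
  (792 s duration → samples to 790 s internally, 780 s externally);
  divisibility of duration by the sampling interval is deliberately not
  required.
* Calibration inversion (position for a target temperature) is a 0.01 cm
  grid search over the calibrated span — robust to mild non-monotonicity
  of the fitted cubic; out-of-range preferences clamp to the nearest end
  and are flagged.
* `fit_newton_k()` (a test utility, not a pipeline stage) uses `nls` with
  `scaleOffset = 1` so the relative-offset criterion also converges on
  noiseless traces; it recovers generator rate constants to < 1e-6
  relative error.

## Reproducibility

Every stochastic entry point takes a seed; pipeline reruns with the same
config and seed produce byte-identical CSVs. The run manifest records the
config hash, seeds, B, CI level, subset sizes and the observed
missing-sighting rate. `scripts/acceptance.R --seed <s> --out <path>`
recomputes the externally checkable quantities (mass ratios from the
published group means; 432 individuals and 432 averaged spectra at the
study's sample sizes; the null rejection rate over 500 simulated subsets)
from scratch against the installed package.
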