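# thermomorph

Analysis pipeline for thermal physiology and thermal preferences in
green–brown colour-polymorphic grasshoppers.

Many acridid grasshoppers occur in discrete green and brown morphs. Field
surveys find brown individuals running warmer than green conspecifics, which
could reflect morph-specific thermal physiology (the thermal melanism
hypothesis: darker, less reflective animals heat faster and plateau hotter)
or morph-specific thermal preferences. Testing either requires processing
three awkward kinds of raw data — radiant heat-up traces, thermal-gradient
occupancy tracks, and reflectance spectra — and an inference scheme that
respects the design: individuals, not observations, are the exchangeable
unit, and colour-morph strata must keep their sample sizes.

`thermomorph` implements that workflow end to end:

- **Spectra** (300–1000 nm, 10 replicates/individual): instrument-artefact
  correction at 654–659 nm (replaced by the mean of the 650–654 and
  659–664 nm flanks), replicate averaging, and *mean brightness* (mean %
  reflectance over the full range).
- **Gradient assay**: per-runway degree-3 polynomial calibration of
  position → temperature from five measured points (0–80 cm), substrate
  temperatures at the six 10-min sightings, and *preferred temperature*
  (mean over minutes 30–60, missing sightings dropped).
- **Physiology**: traces truncated at 20 s (initial haemolymph-mixing dip),
  *heat-up speed* = (T(240 s) − T(20 s))/220 s in °C/min, and *equilibrium
  temperature* = mean over 660–760 s, for internal (5 s) and external
  (20 s) channels through one code path.
- **Inference**: morph-constrained nonparametric bootstrap — whole
  individuals resampled with replacement, each morph stratum kept at its
  original size; B = 1000; 95% percentile CIs; an effect is called when the
  CI excludes zero. Works for summary statistics, time-resolved
  mean-difference curves (T_green − T_brown per time point, one resample
  set shared across the grid), and Spearman correlation curves for
  brightness and mass.
- **Classical tests**: the field's decision tree — Student *t* (normal +
  homoscedastic), Welch (normal only), Mann–Whitney (otherwise); one-way
  ANOVA vs Kruskal–Wallis with pairwise Mann–Whitney follow-up for the
  four-morph species; F/Bartlett variance checks with a log-transform
  rescue; Pearson vs Spearman for covariates.
- **Synthetic data**: a generator emulating the measurement design
  (lumped-capacitance Newton heating T(t) = T_eq − (T_eq − T0)e^(−kt) with
  k = k0·(m/m_ref)^(−1/3), chill start 5.8 ± 3.0 °C, 24% initial-dip
  incidence, 10–51 °C runways, 1.6% missing sightings, spectrometer spike)
  so the whole pipeline is testable without the original data.

## Worked example

```r
library(thermomorph)

res <- run_pipeline(sim_config(seed = 1), B = 1000, seed = 2)
r   <- res$results
r[r$kind == "contrast" & r$contrast == "green-brown" &
    r$response == "heatup_internal", ]
```

With the default (null-morph-effect) generator at the study's sample sizes
(432 individuals: 60/68 + 38/26 + 120/120 F/M per species), this prints:

```
       subset estimate  ci_low ci_high excludes_zero
   ungarica.F   0.0495 -0.0326   0.134         FALSE
   ungarica.M  -0.0332 -0.3014   0.273         FALSE
  sibiricus.F   0.3712  0.0338   0.694          TRUE
  sibiricus.M  -0.1872 -0.6285   0.257         FALSE
 parallelus.F   0.0843 -0.2275   0.416         FALSE
 parallelus.M  -0.1860 -0.4737   0.102         FALSE
```

Each row is the green-minus-brown difference in internal heat-up speed
(°C/min) for one species × sex subset with its 95% percentile-bootstrap CI.
Under the generator's null, morphs are exchangeable, so flags are false
positives at ≈ the nominal 5% rate (one of six here). Sex contrasts, by
comparison, are real in the generated world — females are heavier, heat
more slowly (e.g. *sibiricus* `t = -4.40, p = 4.3e-05`), and *ungarica*
females never plateau within the 13.2-min trial, so their equilibrium
analyses are skipped, as in the study design.

## Command line

```sh
Rscript inst/cli/thermomorph.R simulate --out data/ --seed 4
Rscript inst/cli/thermomorph.R validate --in data/
Rscript inst/cli/thermomorph.R run-all --in data/ --out results/ --B 1000
```

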