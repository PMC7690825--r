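---
title: "Methods: energy partition of growing pigs from respiration-chamber data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energy partition of growing pigs from respiration-chamber data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermopartition)
```

## The measurement problem

A growing pig in an open-circuit respiration chamber exchanges O~2~, CO~2~
and CH~4~ with a metered air stream. From the concentration differential
between inlet and outlet air and the airflow, daily gas volumes are
integrated; combined with the nitrogen and energy contents of feed, feces
and urine they yield the animal's complete energy ledger:

* heat production by the Brouwer equation,
  `HP (kJ) = 16.18 O2 (L) + 5.02 CO2 (L) − 2.17 CH4 (L) − 5.99 urinary N (g)`;
* the energy cascade GE → DE → ME → NE, where DE subtracts fecal energy,
  ME additionally subtracts urinary energy and methane energy
  (39.4 kJ per L CH~4~), and NE is retained energy plus maintenance;
* retained energy `RE = ME − THP`, partitioned into protein
  (`RE_P = N retention × 6.25 × 23.86 kJ/g`, per kg BW^0.6^) and lipid
  (`RE_L = RE − RE_P`, which may legitimately be negative);
* maintenance estimated by fasting heat production (FHP), measured in the
  22:00–06:00 window of a fasting night and extrapolated to 24 h;
* all rates normalised per kg metabolic bodyweight, BW^0.6^.

The package implements this pipeline end to end for trials in which
temperature treatments are assigned to chambers: a synthetic trial
generator with known ground truth, the gas-exchange integration, the
ledger, bodyweight-by-temperature response surfaces fitted by Gauss–Newton
least squares, the treatment statistics customary in this literature, and a
plasma-metabolite screening rule.

## Gas-exchange integration: choices that matter

**Collection windows.** Feces/urine collection (08:00–08:30 and
15:00–15:30) opens the chamber; those samples do not reflect the animal.
`compute_gas_volumes()` drops them and rescales the retained integral by
`1440/(1440 − minutes excluded)` to a 24-h equivalent. For a signal that is
constant within the day this is exact; the alternative of simply summing
the remaining 23 h would bias volumes low by ~4%. The windows are an
argument, so the no-rescaling variant is a one-line change
(`exclusion_windows(character(0))`).

**Days.** Days are clock days (00:00–24:00, chamber-local). Fed-state
values are the means of the balance days; the fasting day follows them.

**FHP extrapolation.** The 8-h fasting-night volumes are multiplied by 3.
Fasting metabolism drifts slowly and no within-night trend model is
warranted by 96 five-minute samples, so the linear factor is used; it is
reported in the return value rather than hard-coded downstream.

**Negative volumes.** Analyzer noise around a zero differential (mainly
CH~4~) can integrate to slightly negative daily volumes. Values within
0.5% of the daily mean magnitude are clipped to zero with a warning;
anything larger is a QC error, as is a day missing more than 5% of its
samples.

**Not modelled.** No inlet/outlet lag alignment, no analyzer drift
correction, no water-vapour (STPD) corrections: volumes are generated and
integrated on a common ideal basis, so these corrections would cancel in
every round-trip check while complicating the contract.

## The synthetic trial generator

No public per-animal data exist for trials of this design, so the
generator is the test bed. It emulates two growth stages: six temperatures
(18, 21, 23, 27, 29, 32 °C) × six replicates entering at 26.4 ± 1.9 kg,
and four temperatures (18, 23, 27, 32 °C) × six replicates at 64.2 ± 3.1 kg
(`trial_design_25kg()`, `trial_design_65kg()`; the first trial's chambers
were nominally set to 30 °C at the fifth level but the realised treatment
reported throughout is 29 °C, which is what the generator uses). Each
animal gets five fed balance days plus a fasting day, 5-min gas sampling,
and twice-daily collection windows.

Ground truth is drawn first, observations second:

* intake follows the published quadratic BW^0.6^ × temperature surface
  (`pig_surface_coefficients()$vfi`) with mean-one log-normal noise;
* digestibility (DE/GE ≈ 0.855), urinary energy (≈1.1% of DE), methane
  energy (≈0.4% of DE) and the fecal/urinary nitrogen fractions are drawn
  per animal around typical grower-pig values read off the energy-balance
  literature for this breed and weight range;
* fed THP per kg BW^0.6^ rises linearly with ME intake
  (`THP ≈ 290 + 0.31 ME_i`, the line through the treatment means of the
  25-kg stage), FHP centres on 700 kJ/kg BW^0.6^/d, and RQ is ≈1.07 fed /
  0.80 fasted;
* gas volumes are then *derived* from THP, RQ and urinary N by inverting
  the Brouwer equation (`O2 = (THP + 5.99 N + 2.17 CH4)/(16.18 + 5.02 RQ)`,
  `CO2 = RQ·O2`), so the closure identity holds exactly by construction and
  any downstream discrepancy is attributable to the analysis code;
* the chamber log spreads each day's volumes uniformly over its minutes,
  damps the differential while the doors are open, and adds Gaussian
  analyzer noise (defaults of 0.003/0.002/0.0002 percentage points,
  of the order of the analyzers' stated 1%-of-range sensitivity).

Within-treatment variance components are not reported in this literature,
so every noise SD is a free parameter with a documented default, and
`trial_truth_params(noise_scale = 0)` gives the noise-free trial on which
the pipeline must reproduce ground truth to numerical precision — the
package's strongest internal check. What the generator does **not**
emulate: thermoregulatory physiology (heat-dissipation physics, panting,
activity), diurnal metabolic rhythms, analyzer drift, or carry-over between
successive replicates in a chamber. Tests passing on synthetic data
therefore validate the bookkeeping and estimators, not the biology.

Bodyweight grows linearly at a configured average daily gain; only the
period-average bodyweight (mean of entry and exit weights) enters the
analysis, so within-period curvature is immaterial.

## Response surfaces

The four responses (voluntary feed intake; ME intake; protein and lipid
retention, the latter two with ME intake as an extra covariate) share the
form

```
y = a + b·m + c·m² + d·T + e·T² + f·m·T (+ g·ME_i),   m = BW^0.6.
```

`fit_response_surface()` estimates the coefficients by Gauss–Newton
least squares (`gauss_newton()`), pooling both stages, with reported
RMSE = √(RSS/(n−p)), R², and an overall F test. The surface is linear in
its parameters, so Gauss–Newton lands on the normal-equation solution in
one step from the zero start; the iterative form is kept so the same code
extends to genuinely nonlinear response laws. Convergence is declared on
the relative step size (default 10⁻¹⁰) rather than the raw gradient norm:
the responses differ by four orders of magnitude in scale and an absolute
gradient criterion would be meaningless across them. Rank deficiency stops
the fit with the offending term named rather than silently dropping it.

Voluntary feed intake is modelled as-fed (kg/d); with dry-matter fractions
near 0.9 the distinction is a near-constant rescaling, and the choice is
confined to the diet specification.

**Identifiability of the `g` term.** In a noise-free simulation where
ME intake is itself an exact function of bodyweight and temperature, the
`g` column is exactly collinear with the rest of the design and the fit
refuses it. Real ME intake always carries animal-level variation, so the
noiseless identification checks keep the covariate's residual SD while
zeroing the response noise.

**A design limitation worth stating plainly.** With 60 animals in two
tight bodyweight clusters, `m` and `m²` are nearly collinear, and at noise
levels giving R² ≈ 0.85 the sampling SD of individual coefficients ranges
from ~15% to many hundreds of percent of their values (worst for the small
`b`, `c` terms of the lipid surface). Coefficient-wise recovery to a few
percent is therefore impossible *at this design* for any unbiased
estimator — a property of the experiment, not of the fitting code, which
recovers all coefficients to 10⁻⁸ at zero noise. Predictions of the fitted
surface are far better determined than its individual coefficients, and
cross-study comparisons should be made on predictions, not coefficients.

## Treatment statistics

One-way ANOVA with temperature as the only fixed effect; SEM is the pooled
√(MSE/n). The chamber random effect sometimes written into such models is
omitted deliberately: each chamber runs one fixed temperature, so chamber
is completely confounded with treatment and its variance component is
inestimable from these designs.

Tukey HSD p-values come from the studentized-range distribution; the
compact letter display assigns letters as the maximal cliques of the
"not separated at α" graph, ordered from the highest mean, so that two
levels share a letter **iff** their Tukey p ≥ α — the greedy
insert-and-absorb shortcut can violate that contract and is not used.

Polynomial contrasts are built on the *actual* unequally spaced
temperatures: `stats::contr.poly(k, scores = levels)` for balanced data
(for 18–32 °C the linear vector is proportional to the centred levels
−7, −4, −2, 2, 4, 7), and a weighted Gram–Schmidt construction
(`poly_contrast_vectors()`) when group sizes differ. Contrast t-tests use
the ANOVA residual mean square.

The cross-treatment CV (`cv_across_treatments()`) is 100·SD/mean of the
*treatment means* — the definition that can be computed from published
tables. CVs computed from per-animal records will differ somewhat;
published values of that kind are not reproducible from treatment means
and are not targets of this package. Outlier handling, where wanted, is
studentized-residual screening at |r| > 3 applied by the user before the
ANOVA; no rule is run by default because none is standard.

## Metabolite screening

Feature tables (samples × features, three temperature groups low/neutral/
high) are Pareto-scaled (`(x − mean)/√SD`) before testing; fold changes and
CVs are computed on raw intensities, so selection is invariant to global
rescaling of the matrix. The selection rule is the conjunction

* some pairwise fold change > 1.5 **or** < 1/1.5 (two-sided, because both
  up- and down-regulated metabolites are of interest),
* maximum within-group CV < 20% (the CV basis is not standardised across
  labs; within-group is the choice here and is an argument),
* one-way ANOVA p < 0.05 on the scaled intensities, uncorrected for
  multiplicity (the convention of this screening literature; the
  conjunction with the fold-change and CV gates is what controls the
  false-positive load in practice).

Compound identification against spectral libraries and pathway topology
scoring require instrument data and external services and are out of
scope; `screen_pca()` provides the explained-variance QC summary only.

## Problem sizes and numerical tolerances used in the checks

The test suite simulates small trials (2–4 replicates, 2–3 balance days)
for speed and the full 36 + 24-animal two-stage design where the design
itself matters: 200 replicate fits for the coefficient-recovery study,
2000 null replicates for the contrast-uniformity KS test (α = 0.01), and a
200-feature table with 13 planted effects for the screening check. Ledger
closure is asserted to 10⁻⁹ relative; zero-noise pipeline identity to
10⁻⁹; the gas round trip to 0.1%; noiseless coefficient recovery to 10⁻⁸.
Heat-production adjustment to the common ME intake of 2.4 MJ/kg BW^0.6^/d
uses the pooled within-trial regression slope of THP on ME intake; other
adjustment conventions exist, and published adjusted values cannot be
reproduced without per-animal data, so the method is documented rather
than benchmarked.
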