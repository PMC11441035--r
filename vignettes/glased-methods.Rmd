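---
title: "Methods: LV marker panel, synthetic cohorts and survival engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LV marker panel, synthetic cohorts and survival engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(glased)
```

This vignette is the package's own account of its science: the marker
model and its assumptions, the synthetic-cohort generator and what it does
and does not emulate, the survival engine's numerical choices, and the
design decisions that were genuinely open.

## 1. The marker model

All markers derive from seven base measurements per subject — end-diastolic
and end-systolic volume (mL), LV muscle volume (mL), mean end-diastolic
endocardial diameter (mm), mean end-diastolic wall thickness (mm), peak
global longitudinal strain (%, negative for shortening), and brachial
systolic pressure (mmHg) — plus height and weight.

The longitudinal wall stress uses the thick-walled-cylinder (Lamé)
solution evaluated on the *pre-deformed* end-diastolic geometry:
`sigma_l = P_i r_i^2 / (r_o^2 - r_i^2)`, with the cuff systolic pressure
standing in for the peak inner pressure. Assumptions worth stating:

* the ventricle is treated as a thick cylinder with a single mean inner
  radius and a single mean wall thickness from basal-to-mid short-axis
  slices; `r_o = r_i + mean wall thickness`;
* brachial cuff pressure approximates peak LV systolic pressure (no
  outflow obstruction);
* nominal (end-diastolic) rather than instantaneous geometry is used,
  which tracks finite-element estimates of the stress–strain-loop area
  well while staying computable from four inputs.

GLASED is the product form `1/2 |sigma_l| |eps_l|` of the strain-energy
density: stress (kPa) times dimensionless strain gives kJ/m^3, taken with
magnitudes so the quantity is positive. GLASE multiplies by the muscle
volume (kJ/m^3 x mL = mJ, reported in J). Both measure contractile *work*:
GLASED per unit myocardium (tissue health), GLASE for the whole ventricle
(whether there is enough myocardium).

Unit conventions are fixed once: 1 mmHg = 133.322 Pa exactly, so stroke
work is SV x SBP x 1.33322e-4 J; stress in kPa; energies in J. These are
dimensionally forced rather than tunable.

Body surface area defaults to Du Bois
(`0.007184 w^0.425 h_cm^0.725`), the conventional choice in CMR reference
ranges; Mosteller is available via `bsa_formula = "mosteller"`. Height
indexing uses height^2.7 in metres. LV mass is 1.05 g/mL x LVMV.

`compute_panel()` emits exactly 23 markers in a fixed canonical order.
Missing base fields propagate `NA` to exactly the markers that need them
(with a `complete` flag); physiologically impossible non-missing values
(ESV >= EDV, non-positive volumes or pressures) are rejected with the
offending field named, because silent clamping would bias downstream
per-SD standardization.

## 2. The synthetic cohort: a stated world

The generator's defaults *are* the conditions the package is calibrated
to; they are not free dials.

* n = 44,957; male fraction 21,631/44,957 = 0.481; age ~ Normal(64, 8)
  truncated to [45, 82].
* Measurements are sex-stratified Gaussians on transformed scales (log
  for the three volumes) with one shared 7x7 correlation matrix
  (`default_generator_config()$meas_cor`), chosen so that the derived
  panel reproduces the qualitative structure reported for community
  cohorts: females have higher LVEF, |GLS| and GLASED despite smaller
  volumes; LVEF and LVGFI correlate strongly (r ~ 0.85 here); GLASED
  correlates moderately with |GLS| (~0.6) and weakly with LVEF; stress
  and strain are nearly uncorrelated.
* Age trends (per decade: volumes -4/-5% on the log scale, diameter
  -0.8 mm, wall +0.15 mm, GLS +0.3 points, SBP +4 mmHg) and risk-factor
  shifts (hypertension raises SBP, wall thickness and worsens GLS;
  diabetes, dyslipidaemia and smoking worsen GLS; activity and BMI act in
  opposite directions) act additively on the measurement *means*. Risk
  factors therefore influence outcomes only through measurements, which
  is what makes fully adjusted (Model 2) effects attenuate
  mechanistically rather than by construction.
* Follow-up: censoring times are drawn from a piecewise-linear quantile
  function anchored at (0, 0.5 y), (0.25, 1.9), (0.5, 2.7), (0.75, 4.1),
  (1, 6.8) — staggered entry with administrative close-out, matching the
  target median/IQR/maximum by construction. No dropout process.
* Endpoints are exponential cause-specific hazards
  `h0 exp(beta_m z_m + beta_age z_age + beta_sex male)` with `z`
  within-cohort standardized and adverse-direction oriented. `h0` is
  root-found (`calibrate_baseline_hazard()`, relative tolerance 1e-3)
  so the expected event fraction under the realized censoring times
  equals the target: 0.9% mortality, 1.8% MACE, 0.5% HF. Endpoints are
  simulated independently — death does not censor MACE/HF — which is a
  deliberate simplification; each endpoint is analysed separately, and a
  competing-risk structure would add realism the analyses never use.
* Default plantings (`planted_hr_table()`): mortality GLASED 1.38 and
  GLS 1.09; MACE 1.39 / 1.12; HF: diameter/height^2.7 1.45, GLASED 1.41,
  GLS 1.30; age HR ~2 per SD and male ~1.6-1.8 per endpoint. Only these
  distinctly-reported effects enter the hazard directly; every other
  marker associates through correlation. We implemented and rejected two
  alternatives: (a) planting the full 23-vector as *conditional*
  coefficients double-counts shared variance (the implied marginal for
  LVGFI/LVCF then nearly ties GLASED); (b) solving for conditional
  coefficients that reproduce a full 23-vector of marginals is
  ill-conditioned (the panel correlation matrix has eigenvalues down to
  5e-4 because several markers are functions of one another) and ridge
  or truncated solves produce oscillating or flattened effect patterns.

What a green test does and does not establish: the generator reproduces
moments, correlations qualitatively, incidences, censoring quantiles and
planted effects; it does not reproduce real measurement error, ICD-coded
endpoint misclassification, competing risks, non-proportional hazards, or
any supplementary distribution table cell-for-cell. Recovery of a planted
hazard ratio validates the *pipeline*, not the biology.

## 3. The survival engine

Written from scratch (the `survival` package appears only as an
independent oracle in the test suite).

* **Cox fits**: Newton–Raphson on the Efron tie-corrected log partial
  likelihood (Breslow by flag), convergence at gradient sup-norm < 1e-8
  or 50 iterations, step-halving on likelihood decrease. Covariates are
  centred internally (coefficient-invariant, stabilizes `exp`);
  covariance is the inverse observed information. Zero-variance
  covariates are rejected; |beta| > 15 is flagged as probable monotone
  likelihood. Risk-set sums use reverse cumulative sums so a 45,000-row
  fit is a few vectorized passes per iteration.
* **Per-SD orientation**: each marker carries a declared adverse
  direction (`marker_orientation()`, data not code): low is adverse for
  the energy/strain/stress/stroke-work/function markers, high for
  mass/volume/diameter. Hazard ratios are reported for one SD in the
  adverse direction, so HR >= 1 throughout.
* **Wald intervals** `exp(b +- 1.96 se)`; the interval method is a
  convention choice, profile likelihood would also have been defensible.
* **AIC** = 2k - 2 logPL; within one ranking table every model has the
  same k, so ranking is by partial likelihood alone; ties break by
  canonical marker order.
* **Kaplan–Meier** product-limit curves; cumulative hazard defaults to
  -log(S) with Nelson–Aalen by flag. Tertiles cut at the empirical 1/3
  and 2/3 quantiles, ties assigned to the lower tertile
  deterministically.
* **Log-rank**: observed-minus-expected with the full hypergeometric
  variance matrix (df = groups - 1), pairwise tests reported raw with
  Holm-adjusted columns available — whether pairwise curve comparisons
  should be multiplicity-corrected is genuinely open, so both are
  exposed.
* **Harrell's C**: event-anchored usable pairs; pairs tied on time are
  excluded, score ties count 1/2; no truncation time is applied (an open
  choice documented rather than hidden).
* **Schoenfeld diagnostic**: scaled residuals `s V^-1` correlated against
  the rank of event time, 1-df chi-square per covariate with the average
  per-event covariance; calibrated under proportional hazards by
  simulation in the test suite. This is a screening diagnostic, not a
  substitute for model inspection.
* **Holm–Bonferroni** step-down with monotone adjusted p-values.

## 4. Reproducibility

Every stochastic stage consumes a sub-seed derived deterministically from
one master seed; identical configuration gives byte-identical cohorts,
outcomes and report bundles (hash-checked in `run_pipeline()`'s
manifest). Pipeline configs are JSON.

## 5. Known limitations and honest-red analyses

* At the HF event count (0.5% of 44,957 = ~225 events) the sampling SD of
  a fitted per-SD log-HR is ~0.09-0.10, i.e. ~0.13-0.15 on the HR scale.
  A single-replicate recovery band of +-0.10 around HR 1.41-1.45 is then
  a ~1-SE criterion with only ~60-70% pass probability per seed. The
  recovery is verified *unbiased* (mean over 20+ replicates within 2
  MC-SE of the planting); individual HF replicates can and do fall
  outside +-0.10. Mortality (413 events) and MACE (831) recover tightly.
* In the fully adjusted mortality AIC ranking, GLASED's margin over its
  closest competitors (the GLASE family) is a few AIC units — the same
  order as the margin observed in large community data. A margin of that
  size is not statistically resolvable to near-certain rank-1 stability
  across replicates; GLASED ranks first in roughly 9 of 10 replicates
  under the default plantings, occasionally yielding to GLASE or LVGFI.
* The Lamé stress model inherits propagation error from wall thickness
  and diameter; the generator does not model measurement error, so
  real-data attenuation from noisy geometry is not represented.
* Harrell's C at registry scale is computed over ~events x n pairs;
  at 45,000 subjects this is the slowest diagnostic and is off by
  default in ranking paths (`diagnostics = FALSE`).
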