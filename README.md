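# glased

Comparative prognostic modelling of left-ventricular (LV) imaging markers,
centred on the **global longitudinal active strain energy density
(GLASED)** — the mechanical work performed per unit volume of myocardium in
the long axis — together with a synthetic survival-cohort generator and a
from-scratch survival-statistics engine.

## Who this is for

Researchers in cardiovascular imaging epidemiology who want to

* compute a standard 23-marker panel of LV structure and contractile
  function from CMR-derived measurements (volumes, myocardial volume,
  end-diastolic diameter and wall thickness, peak global longitudinal
  strain, brachial systolic pressure);
* compare the markers' prognostic value for all-cause mortality, major
  adverse cardiovascular events (MACE) and heart-failure (HF)
  hospitalization with per-SD Cox hazard ratios, AIC model rankings,
  Kaplan–Meier tertile analyses, concordance statistics and
  Holm–Bonferroni multiplicity control;
* exercise and validate that entire pipeline on seeded synthetic cohorts
  with *planted* (known-truth) effect sizes, because large community
  imaging cohorts are access-restricted.

## The model

The marker at the core is derived from thick-walled-cylinder mechanics.
With brachial systolic pressure `P_i` (converted at 1 mmHg = 133.322 Pa),
mean end-diastolic endocardial radius `r_i` and outer radius
`r_o = r_i + wall thickness`, the peak nominal Lamé longitudinal stress is

    sigma_l = P_i * r_i^2 / (r_o^2 - r_i^2)        [kPa]

and, with peak global longitudinal strain `eps_l` (negative for
shortening),

    GLASED = 1/2 * |sigma_l| * |eps_l|             [kJ/m^3]
    GLASE  = GLASED * LV muscle volume             [J]

The panel further contains the pressure–strain product, |GLS|, stroke work
(SV × SBP, in J) and its indexed forms, LV global function index
`SV / (LVMV + (EDV+ESV)/2)`, ejection fraction, contraction fraction
`SV / LVMV`, LV mass (1.05 g/mL × LVMV), end-diastolic volume and
diameter, each also indexed to body surface area (Du Bois) and
height^2.7 — 23 markers in all.

Survival analysis is per-SD: each marker is standardized to unit cohort SD
and sign-oriented to its declared adverse direction (low contractile
function / high mass or size), so a hazard ratio above 1 always means
"more adverse". Cox models maximize the Efron tie-corrected partial
likelihood by Newton–Raphson (adjustments: Model 1 = age + sex, Model 2 =
age + sex + BMI, hypertension, diabetes, dyslipidaemia, smoking, alcohol,
physical activity), and marker models are ranked by AIC.

The synthetic generator emulates a community imaging cohort of 44,957
subjects (48.1% male, age 64 ± 8), correlated sex-stratified CMR
measurements, staggered administrative censoring (median 2.7 years, IQR
1.9–4.1, maximum 6.8) and exponential cause-specific hazards calibrated to
event proportions of 0.9% (death), 1.8% (MACE) and 0.5% (HF), with per-SD
log-hazard effects planted on named markers.

## Worked example

```r
library(glased)

rec <- data.frame(edv = 135, esv = 60, lvmv = 100, inner_diameter_ed = 50,
                  wall_thickness_ed = 10, gls_percent = -18, sbp_mmhg = 120,
                  height_m = 1.75, weight_kg = 80)
round(unlist(compute_panel(rec)[1, c("glased", "glase", "lame_stress",
      "stroke_work", "lvef", "lvgfi", "lvcf", "lv_mass")]), 3)
#>      glased       glase lame_stress stroke_work        lvef       lvgfi
#>       1.500       0.150      16.665       1.200      55.556      37.975
#>        lvcf     lv_mass
#>       0.750     105.000
```

A stress of 16.665 kPa with 18% shortening stores 1.5 kJ of contractile
work per m³ of myocardium; over a 100 mL muscle volume that is 0.15 J per
beat, about an eighth of the 1.2 J of lumen-side stroke work.

```r
co <- generate_cohort(default_generator_config(8000), seed = 42)
co
#> synthetic LV cohort: 8000 subjects (47.9% male), seed 42
#> endpoints simulated: mortality, mace, hf

fit_cox(survival_data(co, "mortality"), "glased", adjustment = "model1")
#> Cox per-SD fit: glased (model1), n=8000, events=68
#>   HR 1.350 (95% CI 1.017-1.793), p=0.038, AIC=1127.38
#>   C=0.718, Schoenfeld p=0.0656
```

The generator plants a per-SD hazard ratio of 1.38 on GLASED for
mortality; at 8000 subjects (68 events) the fit recovers 1.35 with a wide
interval — at the registry scale of 44,957 the recovery is tight (see the
acceptance suite).

## Command line

```sh
inst/cli/glased generate --n 10000 --seed 1 --out-prefix cohort
inst/cli/glased markers  --in cohort_subjects.csv --out panel.csv
inst/cli/glased analyze  --markers cohort_markers.csv --outcomes cohort_outcomes.csv \
                         --subjects cohort_subjects.csv --endpoint mortality --model 1 --out hr.csv
inst/cli/glased scenario --id t1 --seed 1
```

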