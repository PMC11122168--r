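# metsdx

Screening accuracy of anthropometric and lipid indexes for metabolic
syndrome (MetS) in adults with severe obesity.

Clinicians need fast, cheap screens that flag which severely obese
patients are likely to carry MetS before full laboratory work-up.
`metsdx` implements and evaluates three candidate screening indexes:

- **BAI** (body adiposity index): `HC / height_m^1.5 − 18`, anthropometry
  only (hip circumference HC in cm, height in m);
- **LAP** (lipid accumulation product): `(WC − 65) × TG` for males,
  `(WC − 58) × TG` for females, with waist circumference WC in cm and
  fasting triglycerides TG in mmol/L;
- **CMI** (cardiometabolic index): `(TG / HDL) / (WC / HC)`, lipids in
  mmol/L.

MetS is called from the International Diabetes Federation component
thresholds — abdominal obesity (WC ≥ 102 cm male / ≥ 88 cm female),
TG ≥ 150 mg/dL, HDL < 40/50 mg/dL (male/female), BP ≥ 130/85 mmHg,
fasting glucose ≥ 100 mg/dL, each overridable by a treatment flag — with
MetS+ defined as ≥ 3 of the 5 components (a mandatory-waist variant is
available via `idf_strict = TRUE`).

Each index is evaluated as a screening test by ROC analysis: AUC with
DeLong 95% confidence intervals, Youden-optimal cutoff
(J = sensitivity + specificity − 1, ties broken toward specificity),
and positive/negative likelihood ratios, on the whole cohort and
stratified by sex and by age (≤ 50 vs > 50 years).

Because patient-level data for the motivating cohort are not deposited,
the package ships a Gaussian-copula synthetic cohort generator whose
per-sex marginal means/SDs reproduce the published summary statistics of
a severely obese adult population (n = 1912, 11.6 % male, BMI > 35
kg/m²), with right-skewed (lognormal) triglycerides and glucose and a
configurable latent correlation structure that can be calibrated to a
target MetS prevalence.

## Worked example

```r
library(metsdx)

cfg    <- calibrate_prevalence(default_config(seed = 20240511), 0.623)
cohort <- simulate_cohort(cfg)
report <- run_full_analysis(cohort, seed = cfg$seed)
print(report)
```

```
<analysis_report> n = 1912, overall MetS prevalence 61.7%
  BAI: AUC 0.500 (0.473-0.526), cutoff 43.82, sens 70.8%, spec 31.1%, LR+ 1.03
  LAP: AUC 0.708 (0.685-0.731), cutoff 93.7, sens 57.4%, spec 77.0%, LR+ 2.50
  CMI: AUC 0.790 (0.770-0.811), cutoff 1.197, sens 69.7%, spec 76.2%, LR+ 2.93
```

Read: on a synthetic cohort calibrated to ~62 % MetS prevalence, the
anthropometry-only BAI carries no discriminating information (AUC ≈ 0.5),
while the lipid-bearing LAP and CMI separate MetS+ from MetS− clearly
(AUC 0.71 and 0.79) — the qualitative ordering reported for the real
cohort (0.82/0.82 vs 0.50).  A subject above the LAP cutoff is about 2.5
times more likely to be MetS+ than one above the cutoff without MetS
(LR+).  `render_report(report, "csv_bundle", "out/")` writes the table
analogues; `"json"` and `"text"` give machine- and human-readable forms.

The numbered drivers under `analysis/` run the same workflow as a
pipeline (`01_simulate.R` → `02_analyze.R` → `03_reference_checks.R`),
writing cohort, config, reports and identity checks under `results/`.

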