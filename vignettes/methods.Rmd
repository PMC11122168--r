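---
title: "Methods: index computation, MetS classification, ROC evaluation, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: index computation, MetS classification, ROC evaluation, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsdx)
```

## The problem

Metabolic syndrome (MetS) — the co-occurrence of central obesity,
dyslipidemia, raised blood pressure and hyperglycemia — is common in
severe obesity and multiplies cardiovascular risk.  Screening indexes
built from tape-measure anthropometry and routine lipids promise a
cheap first-pass triage.  This package computes three such indexes,
classifies MetS from its component criteria, and quantifies each
index's discriminating ability, with a synthetic cohort standing in for
patient-level data that are not publicly deposited.

## Indexes

For one subject with waist circumference WC (cm), hip circumference HC
(cm), height (m), fasting triglycerides TG and HDL cholesterol HDL
(both mmol/L):

* BMI = weight / height², kg/m²;
* BAI = HC / height^1.5 − 18 (sex-invariant, anthropometry only);
* LAP = (WC − 65) × TG for males, (WC − 58) × TG for females;
* CMI = (TG / HDL) / (WC / HC).

Two formula choices deserve note.  First, LAP is implemented with the
anchor subtracted *before* the product.  The unparenthesized reading
`WC − 65 × TG` occasionally seen in print gives ≈ 21 at the cohort means
of our reference population, an order of magnitude away from that
population's published mean LAP of 97.6, whereas the anchored-difference
form gives ≈ 98; only the latter is offered.  Second, CMI divides the
lipid ratio by waist-to-*hip* (so hip appears in the denominator of the
denominator), and the lipid ratio is taken in mmol/L; mg/dL ratios
differ by a constant factor of 88.57/38.67 ≈ 2.29 and are inconsistent
with the published CMI means (≈ 1.4).  The data model carries lipids in
mg/dL (the units of routine laboratory reports) and converts internally
with the molar-mass factors 88.57 (TG), 38.67 (cholesterol), 18.016
(glucose) mg/dL per mmol/L.

Subjects with WC at or below the LAP anchor get a non-positive LAP and a
degeneracy flag rather than an error: they cannot occur under a
BMI > 35 kg/m² inclusion rule but must not crash general use.

## MetS classification

The five components, with sex-specific thresholds and treatment
overrides, are: WC ≥ 102/88 cm (M/F); TG ≥ 150 mg/dL or lipid
treatment; HDL < 40/50 mg/dL (M/F) or lipid treatment; SBP ≥ 130 or
DBP ≥ 85 mmHg or treated hypertension; fasting glucose ≥ 100 mg/dL or
diagnosed type 2 diabetes.  All ≥ thresholds are inclusive; the HDL
threshold is strict.  The single lipid-treatment flag satisfies both
lipid components, since specific treatment attaches to each.

The default call is MetS+ iff ≥ 3 of 5 components — the rule used in
the motivating analysis, where every subject was centrally obese and
the canonical IDF rule (mandatory central obesity plus ≥ 2 of the rest)
coincides with it.  `idf_strict = TRUE` switches to the canonical rule
for general cohorts.

## ROC evaluation

Higher index ⇒ predicted MetS+, with no automatic direction flipping
(the published cutoffs are lower bounds).  Candidate thresholds are the
distinct observed scores plus ±∞ sentinels; a subject is test-positive
when score ≥ threshold.  The AUC is computed as the Mann–Whitney pair
probability from midranks, which equals the trapezoidal area under the
empirical curve exactly; both routes are computed and property-tested
against each other at 1e-12.

The 95% CI uses DeLong's nonparametric placement variance
(deterministic); a seeded stratified percentile bootstrap (2000
resamples) is available as a cross-check.  When a class has fewer than
two members the interval is undefined and reported as NA.

The operating point maximizes Youden's J = sensitivity + specificity − 1
by exhaustive search over candidate thresholds.  Ties in J (compared at
1e-12, so floating-point noise cannot reorder exact ties) are broken
toward the higher specificity — in a screening context false positives
carry the follow-up cost — then the higher threshold.  The reported
cutoff is the observed score itself, not an inter-point midpoint,
matching how the reference cutoffs align with plausible observed
values.  Likelihood ratios are LR+ = sens/(100 − spec) and
LR− = (100 − sens)/spec, with undefined denominators reported as
infinite.

Group comparisons use the pooled-variance Student t (Welch optional),
Fisher's exact test (two-sided, by summation of hypergeometric
probabilities not exceeding the observed table's), and Pearson
correlation with the conventional strength bands on |r| — the published
band edges leave gaps (e.g. 0.10–0.11), closed here as half-open
intervals [0.10, 0.40), [0.40, 0.70), [0.70, 0.90), [0.90, 1].
P-values are kept at full precision and also binned
(ns, <0.05, <0.01, <0.001, <0.0001) for table display.

## The synthetic cohort

The generator emulates the reference population: n = 1912, male
fraction 0.116, per-sex marginal means/SDs set verbatim from its
published sex-stratified summary table (male height 172.0 ± 7.9 cm,
female WC 120.1 ± 12.4 cm, male TG 164.7 ± 87.0 mg/dL, ...).  A
Gaussian copula imposes a shared latent correlation matrix; each latent
coordinate is pushed through its marginal:

* triglycerides and glucose: lognormal, parameterized to hit the target
  mean/SD exactly — these laboratory variables are right-skewed in real
  cohorts, and the published SD/mean ratios (≈ 0.5 for TG) are
  incompatible with a normal truncated to positive support;
* all other variables: truncated normal via the inverse CDF, with
  truncation encoding inclusion criteria (BMI > 35 kg/m², age ≥ 18) and
  physiologic plausibility (height 100–230 cm, circumference 40–250 cm,
  pressure bounds).

Truncation is applied by quantile transform rather than resampling, and
the pre-truncation (μ, σ) are solved numerically so the *truncated*
marginal matches the configured mean/SD.  Naive truncation would
shift moments — the BMI bound alone moves the mean by ≈ +1.25 kg/m² —
and resampling whole latent vectors would distort the copula; the
quantile transform preserves both the marginal targets and the latent
rank structure.  Body weight is derived as BMI × height², so the
published near-equality of BMI across sexes and the sex gap in body
weight both emerge correctly; blood pressures are rounded to the
nearest 5 mmHg, mirroring aneroid sphygmomanometer reading practice.

No covariance structure is published for the reference population, so
the default latent correlations are declared assumptions, not
estimates: moderate positives among adiposity measures (WC–HC 0.6,
WC–BMI 0.7, HC–BMI 0.65), weak metabolic couplings (TG–glucose 0.2,
TG–HDL −0.3), SBP–DBP 0.6, and weak age–SBP/age–glucose couplings (0.2)
so the observed age gradient in MetS prevalence (51 % in ≤ 50 s vs 71 %
in > 50 s) is qualitatively representable; all other entries are zero
and every entry ships in the user-editable YAML config.  Treatment-flag
probabilities default to 0 because no comorbidity prevalences are
published; the flags exist so the classifier's override logic is
testable.

`calibrate_prevalence()` scales the latent correlations among the
criterion-driving variables (WC, SBP, DBP, glucose, HDL, TG) by a
single multiplier in [0, 1], bisecting (≤ 30 iterations, common random
numbers, n = 20,000 per evaluation) until realized MetS prevalence is
within ±2 percentage points of the target.  With the default marginals
the attainable range is ≈ 58–64 %, comfortably containing the 62.3 %
target; an unattainable target raises an explicit error rather than
returning the nearest endpoint.

### What the generator does and does not show

The generator matches marginal means/SDs, positive lipid/glucose skew,
inclusion bounds and an overall prevalence target.  It does *not* know
the real joint distribution: published index–variable r² values are
emergent, not fitted, and the real cohort's exact AUCs (0.82/0.82/0.50)
and cutoffs (91.05/1.22/43.55) are not reproducible from summary
statistics alone.  Passing tests therefore demonstrate correctness of
the pipeline and the *qualitative* contrast — lipid-bearing indexes
dominate the anthropometry-only BAI by ≥ 0.15 AUC, BAI ≈ 0.5 — not
quantitative agreement with the original data.  On default calibrated
cohorts the realized AUCs are ≈ 0.70 (LAP), ≈ 0.79 (CMI), ≈ 0.50 (BAI).

## Numerical and design choices

* Problem sizes: marginal-recovery checks run at n = 20,000 (3-SE mean
  band, 5 % SD band); skewness checks at n ≥ 5,000; oracle
  equivalence sweeps use 1,000 random instances of n ≤ 30; the DeLong
  coverage simulation uses 1,000 replicates of n = 100.
* The truncated-normal moment solver is Nelder–Mead on (μ, log σ) with
  a 1e-10 residual guard; bounds further than 6 SD from the target are
  treated as non-binding.
* Reference operating points carry an `lr_consistent` flag: rows of the
  published table whose printed LR disagrees with its own
  sensitivity/specificity (typographical artefacts) are excluded from
  identity checks.  Where the running text and the table disagree
  (older-CMI specificity 88.04 vs 88.00), the internally consistent
  variant is carried.
* Known limitations: no ATP-III/harmonized MetS variants; no AUC
  comparison test between correlated curves; no ROC smoothing; single
  shared correlation matrix across sexes; treatment flags are
  independent Bernoulli draws, not comorbidity-linked.
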