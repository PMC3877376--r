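---
title: "Methods: polygenic risk modelling, pooling and reclassification in melprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic risk modelling, pooling and reclassification in melprs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melprs)
```

`melprs` implements a complete case-control analysis of a weighted
polygenic risk score (PRS) for melanoma: score construction, logistic
association, random-effects meta-analysis, AUC-based model comparison,
and risk reclassification, together with a synthetic-cohort generator
that reproduces the statistical structure the analysis assumes. This
vignette documents the models, the tunable parameters, the numerical
conventions, and the design choices that were genuinely open.

## The score

For a panel of biallelic SNPs, each individual's score is the weighted
sum of risk-allele dosages, `PRS_i = sum_j w_j g_ij`, with `g_ij` in
{0, 1, 2} and weights `w_j` in log-odds units. The bundled
`default_panel()` holds 11 melanoma susceptibility SNPs, one per gene
region so that linkage disequilibrium between panel members can be
neglected. Two caveats are deliberate and documented rather than hidden:

- **Frequencies.** The published panel table reports minor-allele
  frequencies without stating, per SNP, whether the risk allele is the
  minor allele. The default panel takes the minor-allele frequency as
  the risk-allele frequency — a single self-consistent convention.
  For SNPs whose risk allele is in truth the major allele this
  understates the population mean allele count (the simulated total
  count distribution is centred near 6–7 of a possible 22, whereas a
  panel with several major risk alleles would centre higher). Users
  with better information can override `risk_allele_freq` per SNP.
- **Weights.** The original analysis weighted alleles by effect sizes
  from prior studies; those coefficients were not printed. The default
  weights are the natural logs of the three-study pooled odds ratios —
  a stand-in of the same order of magnitude, again overridable.

Missing dosages are handled by `missing_policy`: `"mean"` (default)
imputes the HWE mean dosage `2f_j`, keeping every individual in the
analysis so per-model Ns vary only with covariate availability;
`"drop"` flags the individual's score as missing so model fits exclude
them. An all-missing individual is always flagged, never scored zero.

Groupings reproduce the published contrasts: tertiles (cutpoints at the
1/3 and 2/3 quantiles of the analysis sample, cases plus controls —
the published phrasing "participants in the highest tertile" motivates
using the full sample rather than controls only, and a `reference_scores`
argument switches this), allele-count bands (≤6, 7–14, ≥15), and a
top-5% split (strictly above the 95th percentile). All quantiles use
type 7 (linear interpolation between order statistics) so that results
are reproducible bit for bit; tertile occupancy on tie-free data is
balanced to within one individual. Whether the original tertiles were
study-specific or pooled across studies is not stated; study-specific
is the default here, since each cohort is analysed separately before
pooling.

## Association models

All effects are maximum-likelihood logistic fits via `stats::glm`, with
Wald standard errors from the observed information and 95% CIs
`exp(beta ± 1.959964 · se)` — the Wald convention matches the
`OR (95% CI)` presentation that the meta-analysis layer inverts, which
is why profile-likelihood intervals are not used. Per-SNP models are
additive in dosage and unadjusted. PRS models come in four forms
(continuous, tertile-3-vs-1 with the middle tertile retained through
indicator coding, allele band ≥15 vs ≤6, top-5%) and adjust for the
study scheme's covariates exactly: sex, age, skin, eye and hair colour
and tanning ability in the discovery scheme; age, hair, tanning and
family history in the all-female cohort; age, hair, eye and family
history in the all-male cohort. Categorical covariates enter as
indicator sets (the source tables list them as categories); age is
linear in years.

Diagnostics are explicit: non-convergence is always an error; runaway
coefficients (|beta| > 10 on the log-odds scale, the signature of
separation or an empty cell) abort a direct `fit_logistic()` call, while
in the adjusted PRS models they are tolerated for nuisance covariates
(a sparse hair-colour cell in a small cohort should not abort the fit)
but the PRS coefficient itself is still guarded — an unstable estimate
of interest is an error, never a silent result.

`variance_explained()` quantifies how much pigmentation phenotype the
score carries, as the squared Pearson correlation between the score and
the trait's ordinal coding. This is the simplest convention consistent
with a reported 1–3.6% range; the exact per-trait values in the source
were in supplementary material that is not public, so only that range
constrains the simulator's calibration.

## Meta-analysis

Pooling is DerSimonian–Laird throughout: fixed-effect weights
`w = 1/se²`, Cochran `Q = Σ w (θ − θ_FE)²`,
`τ² = max(0, (Q − df)/(Σw − Σw²/Σw))`, random-effects weights
`1/(se² + τ²)`, and `I² = 100 · max(0, (Q − df)/Q)`. The classic DL
moment estimator was chosen because the source describes exactly the
"random effects model with inverse variance weight" recipe, and because
the heterogeneity footnotes it prints are reproduced by DL recomputation
from the rounded per-study rows (within ±0.3 of a percentage point on
I²; the tests encode a ±1.5-point band to absorb the input rounding).
With τ² = 0 the pool reduces exactly to the fixed-effect
precision-weighted mean; a single study passes through unchanged with
Q = 0. REML or Paule–Mandel estimators are intentionally out of scope.
The implementation is cross-checked against `metafor::rma(method =
"DL")` in the test suite to 10 decimal places.

Printed `OR (low–high)` rows are inverted by `or_ci_to_effect()`:
`log_or = ln(OR)`, `se = (ln(hi) − ln(lo)) / (2 · 1.959964)`. Pooling
from rounded printed estimates rather than full-precision per-study
fits drifts by ≤ 0.01–0.02 on the OR scale; both entry points (printed
rows via `pool_or_rows()`, raw estimates via `meta_from_estimates()`)
are supported, with full precision preferred when available.

## Discrimination

AUCs use the Mann–Whitney estimator with ties half-credited, computed
from midranks — algebraically identical to exhaustive pairwise
comparison, which the tests verify directly at n ≤ 200. Paired
contrasts use the DeLong structural-component covariance, matching the
default of the SAS ROC-contrast procedure used in the source analysis,
and are cross-checked against `pROC::roc.test` and a 10,000-resample
stratified bootstrap. The five-model suite (index SNP; PRS; sex + age;
sex + age + pigmentation; the latter plus PRS) is fit on the identical
complete-case subset of the richest model so every contrast is paired.
AUCs are in-sample (apparent), matching the source procedure; no
cross-validation is applied.

## Reclassification

Predicted risks are cut at 20% and 50% (the 0.50 boundary assigned
upward, consistent with a "≥ 50%" top category). The categorical NRI
keeps the non-event quantity in the published orientation,
`(up − down)/n_nonevents`, with the subtraction applied in the total:
`NRI = (up_e − down_e)/n_e − (up_ne − down_ne)/n_ne`. This is the only
reading under which the three published values (0.1220, 0.1111, 0.0109)
are mutually consistent; a conventionally signed non-event accessor is
also returned. The z-test follows Pencina's count-based form, and the
IDI is the difference in mean predicted-probability gain between events
and non-events with a paired-difference z-test. Feeding the published
3×3 count tables (`published_reclassification_counts()`) through
`categorical_nri()` reproduces the printed block to four decimals and
its p-value 0.6076.

## The synthetic-cohort generator

The generator exists so every downstream stage is testable without the
original individual-level data; its defaults are the study conditions,
not tuning knobs.

- **Genotypes**: independent HWE draws (two Bernoulli trials per SNP at
  the risk-allele frequency). No LD, no imputation uncertainty —
  dosages are exact integers.
- **Disease**: `P(case) = logistic(b0 + Σ beta_j g_j)`, with `beta_j`
  defaulting to the panel weights and baseline `b0 = −1.2`, chosen once
  as a realistic population log-odds that makes rejection sampling
  efficient at all three cohort sizes. Cases and controls are accrued
  by rejection from the population model until the exact target counts
  are reached; odds ratios are invariant to such outcome-dependent
  sampling, which is why the simpler prospective scheme was preferred
  over a retrospective one. An unattainable quota fails explicitly
  after a bounded number of sampling blocks.
- **Cohort sizes and schemes**: 1,804/1,025 (discovery, both sexes,
  full pigmentation), 317/3,376 (all female), 177/2,251 (all male),
  with the covariate-availability mask of each study; covariates absent
  under a scheme are `NA` and are never fabricated downstream.
- **Pigmentation**: each trait derives from a latent Gaussian
  `sqrt(r²)·z_PRS + sqrt(1−r²)·ε`, so the squared correlation with the
  standardized PRS equals `pigmentation_r2` (default 0.03, the middle
  of the reported 1–3.6% range), then is cut at fixed normal quantiles
  matched to the published control marginals (e.g. skin
  light/medium/dark ≈ 44.5/47.8/7.7%). Categorization attenuates the
  realized squared correlation somewhat below the latent target; tests
  bound it in (0.01, 0.05) at the default.
- **Family history** is generated with the published case/control rates
  where the scheme collects it; ages are normal with the published
  means and spreads; the sex ratio matches each study.
- **Determinism**: one master seed derives per-study seeds, and the
  same seed yields a bit-identical cohort; the full pipeline writes
  byte-identical summary files across runs with the same seed.

What passing tests on these cohorts do **not** show: robustness to LD
between panel SNPs, to genotyping or imputation error, to population
stratification, or to covariate missingness patterns more complex than
scheme-level availability. The generator emulates the first moments and
dependence structure the analysis assumes — nothing more.

## Problem sizes used in the tests

The test suite favours many small, seeded simulations over few large
ones: parameter recovery uses 100 replicates of 2,000/2,000 single-SNP
cohorts (CI coverage of the simulation truth ≥ 90%); type-I calibration
uses 300 replicates at 120/120; AUC monotonicity of the model suite
uses 8 replicates at the full discovery size (1,804/1,025); the
end-to-end determinism check runs the complete pipeline twice at the
published sizes. These sizes give Monte-Carlo error comfortably inside
the asserted bounds while keeping the whole suite fast.

## Known limitations

- The default panel's frequencies and weights are stand-ins (see above);
  analyses of real data should supply measured risk-allele frequencies
  and externally estimated weights.
- Continuous per-unit PRS effects depend on the score's scale; with the
  default weights one PRS unit is one log-odds unit of simulated risk,
  which is larger than a typical per-allele unit, so per-unit ORs are
  not directly comparable across differently scaled weight sets.
- No conditional-logistic, survival or matched designs; no gene–gene or
  gene–environment interactions; no continuous (category-free) NRI.
- VCF support covers biallelic SNP records with GT fields; positions in
  emitted VCFs are synthetic placeholders since the analysis is
  position-agnostic.
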