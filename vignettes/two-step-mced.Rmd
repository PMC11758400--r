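---
title: "Two-step MCED screening: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step MCED screening: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcedsim)
```

## The screening problem

Population-wide cancer screening is judged on three axes: cancers found,
false alarms raised, and money spent. A multi-cancer early detection (MCED)
blood test covers many tumour types in one draw, but the best-performing
tests are sequencing-based and expensive. The two-step idea mirrors
established practice in prostate (PSA then MRI) and colorectal (FIT then
colonoscopy) screening: a cheap first-line test screens everyone, and the
expensive confirmatory test is reserved for first-line positives. This
package implements the full quantitative machinery for studying that
cascade: the two test models, the cascade itself, case-control performance
metrics, and the projection of an operating point onto a screening
population with cost accounting.

## Step 1: the probability-of-cancer index

The first-line test quantifies seven circulating protein tumor markers
(AFP, CA125, CA15-3, CA19-9, CA72-4, CEA, CYFRA 21-1) on routine clinical
immunoassay analyzers. `fit_poc()` fits a binomial generalized linear model
with logit link on the log10 concentrations and returns a probability of
cancer (POC) in [0, 1]; `classify_poc()` calls POC ≥ 0.5 screen-positive,
with the boundary itself positive.

Numerical choices:

* **log10 transform.** Marker concentrations are log-normal-ish and span
  orders of magnitude; the decades scale is the one clinicians read.
* **Winsorization at the pooled 99.9th percentile.** Immunoassay analyzers
  saturate; capping keeps a handful of extreme concentrations from
  dominating the likelihood. The caps are stored in the model so scoring
  applies the identical transform.
* **Separation fallback.** If the two groups are linearly separable the ML
  estimate diverges; the fit is then repeated with a small ridge penalty
  (`glmnet`, lambda = 0.01) and flagged `separable = TRUE` rather than
  returning infinite coefficients.
* **No demographic terms.** Age and sex are simulated for cohort realism
  but deliberately excluded from the model: the marker panel alone should
  carry the discrimination, and the published index is defined on the
  panel.

## Step 2: the cancer risk score

The confirmatory test profiles cell-free DNA with shallow whole-genome
sequencing (~3x) and summarizes it as four per-sample scores — copy-number
aberration (CNA), fragment size (FS), end motif, and oncogenic virus — to
which the marker panel's POC is added as a fifth (PTM) feature. Deriving
those genomic scores from reads is out of scope here; they enter as
numbers. The integrated cancer risk score is linear:

CRS = a·CNA + b·FS + c·EndMotif + d·Virus + e·PTM

`grid_search_weights()` chooses (a, …, e) by exhaustive enumeration,
maximizing the empirical (Mann-Whitney) AUC. Design choices where the
procedure is genuinely underdetermined:

* **Simplex constraint, step 0.05.** AUC is invariant to positive scaling
  of the weight vector, so only its direction is identifiable; restricting
  to nonnegative weights summing to 1 makes the search finite (10,626
  tuples) without excluding any direction a risk score would plausibly use.
* **Noncancer z-scoring.** Each feature is standardized against the
  noncancer training mean and SD before weighting, so a simplex weight
  means the same thing on every channel.
* **Deterministic tie-break.** Among AUC-tied tuples the lexicographically
  smallest in (a, b, c, d, e) order wins, so refits are bit-identical.
* **Calibration.** The reported scale fixes one point: the cutoff that
  achieves 98% specificity in noncancer training subjects equals 2.0. One
  anchor does not determine an affine map, so a second is imposed for
  identifiability: the noncancer median maps to 0. Percentiles are type-7
  (linearly interpolated order statistics, R's default) throughout, and the
  same convention is used by `threshold_at_specificity()`, so the two
  modules can never disagree by an interpolation rule.
* **Training population.** The CRS is trained and calibrated on the full
  cohort, not only on step-1 positives, matching how the standalone test is
  evaluated before being slotted into the cascade. Whether a deployed
  product would recalibrate on the step-1-positive subpopulation is an open
  operational question; the package keeps the two stages independently
  calibrated.

`run_cascade()` then composes the two decisions: POC < 0.5 ends at step 1
(no CRS is ever computed for those subjects); otherwise CRS ≥ 2.0 predicts
cancer. Both boundaries are inclusive. Structural consequences — cascade
positives are a subset of step-1 positives, cascade specificity can only
rise and sensitivity only fall relative to step 1 — are asserted as
property tests.

## Performance metrics

`empirical_auc()` is the all-pairs Mann-Whitney statistic with half-credit
for ties; `delong_test()` compares two correlated AUCs on the same subjects
via placement values, with a two-sided normal p-value (the published
comparisons report two-sided significance); `sens_spec_at()` uses the
"≥ cutoff is positive" convention shared by both classifiers and exact
Clopper-Pearson intervals, the default of the epidemiology packages this
mirrors. Degenerate inputs (constant scores) are flagged rather than
yielding a fabricated p-value.

## The synthetic cohort generator

The real cohort (617 cancer, 580 noncancer; stage mix I 26.3%, II 18.6%,
III 21.4%, IV 22.2%, plus 5.3% not stageable and 6.2% missing) is under
controlled access, so every downstream stage is exercised on synthetic
cohorts whose *summary behaviour* matches the published one. The generator
emulates:

* **Genomic features** as unit-variance Gaussians: mean 0 in controls,
  mean `binormal_shift(target)` = √2·Φ⁻¹(AUC) in cases, so each feature's
  theoretical AUC equals its published value (CNA 0.797, FS 0.865, end
  motif 0.877, virus 0.654).
* **Marker concentrations** as log-normals around healthy-adult medians of
  the clinical assays, with three cancer effects: (i) a Bernoulli
  *elevation* per marker whose probability rises with stage (0.17 at stage
  I to 0.40 at stage IV per marker), multiplying the concentration by
  10^1.5–10^2.1; (ii) marker *co-elevation* within a patient through a
  latent tumour severity (probit correlation 0.90) — tumours that shed one
  marker tend to shed several; (iii) a mild continuous stage-graded *drift*
  (0.18–0.46 marker-SD) on all markers, because marker levels track tumour
  burden even below frank positivity. Controls carry benign elevations at
  4.5% per marker: cholestasis, endometriosis and smoking raise these
  markers without cancer, and this is what keeps the marker panel's
  false-positive rate realistic.
* **Cross-channel structure.** The latent severity driving marker
  elevation and the one driving genomic features are correlated at 0.6,
  and the genomic features share their latent at equicorrelation 0.94.
  These two parameters matter: with independent features, four channels
  with the published marginal AUCs would integrate to an AUC near 0.97,
  far above the published 0.899 — the real channels are evidently highly
  redundant, all being functions of tumour burden and shedding. The
  defaults were calibrated once, by simulation, so that the *fitted* models
  land on the published summaries (marker-panel AUC ≈ 0.79, integrated
  AUC ≈ 0.90, ≈ 50% sensitivity at the 91%-specificity marker threshold,
  cascade ≈ 40%/99%); they are study conditions, not tuning knobs.
* **Demographics** (age means/SDs and sex split per group) match the
  published table but feed no model.

What the generator does **not** emulate: per-cancer-type marker signatures
(27 tumour types collapse into one generic cancer process with stage
effects), raw sequencing observables (fragment-length distributions,
end-motif frequencies, viral read counts), inter-marker correlation
structure beyond the single latent, and real assay floor/ceiling effects.
Passing tests therefore demonstrate that the *pipeline* recovers the
published operating characteristics under a faithful statistical emulation
— not that it would do so on the original patients.

Everything is seeded: `generate_cohort(spec, seed)` is bit-reproducible and
restores the caller's RNG stream.

## Screening projection and costs

`project()` maps an operating point onto a screening population in closed
form. The default scenario set matches the published five-million-person
simulation: incidence 1.9%, case-control sensitivities 49.9% (marker
panel), 60.0% (sequencing test), 39.9% (cascade), 51.5% (comparator), and
specificities 91.0/98.3/99.3/99.1%.

The rounding pipeline is part of the contract, reverse-engineered so every
printed cell reproduces exactly: the proportional real-world adjustment
(multiply by the comparator's prospective/retrospective sensitivity ratio
28.9/51.5) is rounded to one decimal *in percent* before any count is
formed (95,000 × 0.224 = 21,280; the unrounded product would give 21,271);
counts round half-up to whole people; rates and likelihood ratios are
displayed to one decimal; per-case and per-person costs round to whole
dollars only at display time. The cancer count `population × incidence` is
treated as exact. The two-step budget charges the first-line price for
everyone plus the follow-up price (which omits the already-measured marker
panel) for the *projected* step-1 positives (TP + FP of the first-line
scenario): 5M × $80 + 468,050 × $670 = $713,593,500. Per-case cost divides
by true positives only — a screen's yield is confirmed cancers.

## Problem sizes and determinism

The test suite and the acceptance script work at the published case-control
size (n = 1,197) with three seeds for calibration checks — large enough
that binormal sampling error (SE(AUC) ≈ 0.012 per seed) sits well inside
the ±0.035 acceptance bands — and at reduced sizes (a few hundred subjects,
coarser grid steps) for structural and property tests. The full pipeline,
including the 10,626-tuple grid search, runs in a few seconds;
`run_pipeline()` output is byte-for-byte reproducible for a fixed config
and seed.

## Known limitations

* The published weight values a–e were never disclosed; only the selection
  *procedure* is reproducible, and the synthetic-cohort weights need not
  match the originals.
* The proportional sensitivity adjustment is a strong assumption imported
  from the comparator test's retrospective-to-prospective gap; nothing in
  the package validates it.
* Costs are static per-test prices: no downstream diagnostic-workup costs,
  no discounting, no quality-adjusted life-year modelling.
* The cascade's specificity gain assumes the two tests' errors are only
  partially correlated; the generator's cross-channel correlation is a
  modelling choice, and real-world error correlation could differ.
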