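---
title: "Validating fertility indices for IVF outcome prediction with efindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating fertility indices for IVF outcome prediction with efindex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efindex)
```

## Scope and model

`efindex` implements the full analysis pipeline of a paired
diagnostic-accuracy study in reproductive medicine: two prognostic
indices — the r-AFS endometriosis stage and the Endometriosis Fertility
Index (EFI) — are computed for every patient from structured surgical
and clinical records and compared, on the same cohort, in their ability
to predict a binary IVF outcome (clinical pregnancy after a fresh
embryo transfer). This vignette records the methodological choices: the
scoring conventions, the statistical machinery and its tolerances, what
the synthetic-cohort generator does and does not emulate, and where the
design was genuinely open.

## r-AFS scoring

The 1985 revised-AFS form is implemented as literal lookup tables
(`afs_implant_points()`, `afs_adhesion_points()`,
`afs_culdesac_points()`), not as arithmetic shortcuts, so the point
values are directly reviewable. Conventions worth making explicit:

* **Size and enclosure band edges.** A 1 cm or 3 cm implant falls in
  the middle band ("1–3 cm"); bands are closed on the right.
* **Worst-per-category scoring.** Multiple implants in the same
  site-by-depth category score only the largest: the form scores the
  extent of disease per category, not per lesion. Tested explicitly.
* **Fimbria override.** Any tubal adhesion whose fimbriated end is
  completely enclosed is re-assigned 16 points regardless of its
  enclosure band.
* **Canonicalization.** At most one adhesion per (organ, side, type)
  survives input validation; duplicates collapse to the worst.
* **Absent ovary.** A lesion or adhesion recorded on a surgically
  absent ovary is a *validation error*, never a silent zero — in a
  cohort like this one it signals an inconsistent record.
* **Total 0.** A record scoring 0 has no stage; the package warns
  ("no endometriosis scored") and returns `NA`, since every patient in
  the intended cohort has histologically confirmed disease.

**Open question resolved: the "lesion score" fed to the EFI.** The EFI
rubric bands an "AFS lesion score" at 16 and the AFS total at 71, but
whether cul-de-sac obliteration points belong to the lesion score is
not stated in the source material. The package defaults to *including*
them (`lesion_score_includes_culdesac = TRUE`) — on the original form
the cul-de-sac is scored among the implants, not among the adhesions —
and exposes the switch so either convention is reproducible. The total
score always includes all three components.

## EFI

The EFI adds historical points (age ≤ 35 → 2, 36–39 → 1, ≥ 40 → 0;
infertility ≤ 3 y → 2, else 0; any prior pregnancy → 1) to surgical
points (LF 7–8 → 3, 4–6 → 2, 0–3 → 0; AFS lesion score < 16 → 1; AFS
total < 71 → 1). Choices:

* **Edge inclusivity.** Values exactly on a band edge (age 35.0,
  duration 3.0 y) take the *higher-scoring* band, matching the form's
  "≤ 35" / "≤ 3" wording. Tested on both sides of each edge.
* **LF = 0.** The printed LF bands start at 1; an LF of 0 (both sides
  nonfunctional) scores 0 surgical LF points, the only consistent
  extension.
* **Doubling rule.** With one ovary absent the LF total is twice the
  contralateral side's score; with both absent the LF (and the EFI) is
  undefined and the package errors rather than guessing.
* **Ratings are inputs.** Organ function (0–4 per tube, fimbria,
  ovary, per side) is surgeon-assigned at laparoscopy. The package
  never infers ratings from lesion/adhesion records;
  `suggest_function_ratings()` exists as an explicitly opt-in drafting
  aid and is never called implicitly.
* **Prior pregnancy** means any gravidity — ectopic pregnancies,
  miscarriages and abortions count.

## Diagnostic accuracy

The ROC machinery follows the classical nonparametric toolkit:

* The empirical curve has one operating point per distinct observed
  index value ("positive if index ≥ t", direction-adjustable) plus the
  trivial endpoints.
* The AUC is the Mann–Whitney two-sample statistic (concordant pairs
  plus half ties over all pairs), identical to the trapezoidal area of
  the empirical curve — an equality the test suite asserts on a
  thousand random instances rather than assuming.
* **SE method.** The source analysis was run in SPSS, which does not
  name its SE; the package's primary method is Hanley–McNeil
  (`Q1 = A/(2−A)`, `Q2 = 2A²/(1+A)`), with a stratified bootstrap as an
  alternative. On the published cohort (AUC 0.641, 85/114) the
  Hanley–McNeil SE is 0.0400 against a printed 0.039 — agreement within
  the ±0.002 the analysis plan allows. Under the null with equal group
  sizes the formula collapses to `SE² = (2n+1)/(12n²)`, the exact
  tie-free Mann–Whitney null variance, which is why the null-coverage
  calibration below works.
* **CI and test.** Wald on the probability scale, clipped to [0, 1]:
  `AUC ± 1.96·SE`, with a two-sided normal test of AUC = 0.5. This
  reproduces the published 0.564–0.717 from (0.641, 0.039) and
  p ≈ 0.18 from (0.445, 0.041).
* **Direction convention.** Both indices are analysed with the same
  "higher index ⇒ predict pregnancy" orientation, *including* r-AFS.
  That is deliberate: an r-AFS AUC below 0.5 (worse stage, slightly
  better IVF prognosis in the advanced-disease tail) is a finding, not
  an orientation bug, and flipping the direction would hide it.
* **Cut-off semantics.** "Cut-off = 6" means positive iff index ≥ 6.
  The Youden optimum maximizes `J = sens + spec − 1`; ties are broken
  toward higher sensitivity, then toward the lower cut-off, making the
  selection deterministic.

## Two-group comparison battery

* **χ² without continuity correction.** The five published 2×2
  statistics (11.881, 4.153, 12.266, 10.862, 5.698) are reproduced to
  three decimals by the uncorrected Pearson formula and by nothing
  else; Yates correction is therefore not offered in the report path.
* **Student's pooled t** is the default (the SPSS-reported row), Welch
  by flag. Summary-statistic t (`t_from_summary()`) lets a reader check
  printed "mean ± SD" rows.
* **Mann–Whitney z** uses the normal approximation with tie
  correction, no continuity correction, and an exact small-sample path.
  Sign convention: z < 0 when the first-listed group is stochastically
  smaller. The published tables print all-negative z regardless of
  direction, a convention SPSS does not document; ours is fixed,
  documented, and verified antisymmetric under group exchange.
* **Routing is declared, not inferred.** Which variables are compared
  by t vs Mann–Whitney mirrors the published tables' normality
  superscripts; the package does not run automatic normality tests.
* **Rates are recomputed.** Every rate row carries its numerator and
  denominator; percentages are derived outputs, never inputs.
  Per-embryo rows (implantation rate) use embryos, not patients, as
  denominator.

## Paired sample size

The pilot design compares two classifications of the *same* patients
against a gold standard, so the driving quantity is the discordant mass
`ψ = p₁ + p₂ − 2p`. The implemented closed form is the standard
McNemar-type one (see README). On the pilot table (44, 47, 23, 47) it
yields **n = 202**. The published computation reports 196 from a
formula whose typesetting is corrupted; 196 is not reproducible from
the printed counts by the standard formula under any of its common
variants, so the package documents the discrepancy and asserts only its
own closed form. z-quantiles are used at full double precision and the
result is rounded up — both choices stated because the original
arithmetic is not reproducible digit-for-digit.

## The synthetic world

`generate_cohort()` emulates the cohort structure the analysis assumes,
so that every pipeline stage is exercisable without patient data. The
defaults *are* the stated world, chosen once and frozen:

* age ~ Normal(32.0, 4.2) years; infertility duration log-normal with
  median 5.0 y (the IQR ratio 7/3 sets the log-SD ≈ 0.63, so the
  quartiles are ≈ 3.3–7.6 — the family is a modelling choice, the
  median is matched exactly); prior pregnancy 32%.
* lesion/adhesion occurrence probabilities set so that, at n = 20,000,
  the marginal structure matches the intended cohort: ~71% stage
  III–IV (target 69%), ~60% EFI ≥ 6 (target 58%), overall fresh-cycle
  pregnancy ~44% (target 43%). Every patient has at least one implant
  (histological diagnosis implies one), so stage is always defined.
* function ratings are degraded from 4 with severity coupled to the
  patient's adhesions (coupling is a config switch, default on), which
  is what makes EFI and r-AFS realistically correlated — and what
  produces the r-AFS AUC slightly *below* 0.5 on simulated cohorts,
  the same qualitative signature as the published analysis.
* pregnancy follows `logit P = β₀ + β₁·EFI`, with
  `calibrate_outcome_model()` solving deterministically (damped Newton,
  analytic Jacobian, tolerance 10⁻¹⁰) for the coefficients that give
  the stated group rates 28.6% (EFI ≤ 5) and 53.0% (EFI ≥ 6) over the
  realized EFI distribution.
* cycle counts (AFC, oocytes, 2PN, cleavage, availability) are
  statistical stand-ins: negative-binomial/binomial cascades with rates
  near the published marginal rates, linked to ovarian function. They
  are *not* a mechanistic embryology model. Couplings the source
  doesn't constrain are deliberately left null rather than guessed.
* one master seed drives an independent substream per table, so adding
  a column to one table never perturbs the draws of another.

**What a green test does and does not establish.** The simulation
reproduces marginal structure and the EFI–pregnancy link; it does not
reproduce inter-variable correlations the source never quantified
(e.g. between hormone levels and stage), surgeon rating variability, or
center effects. Calibration tests on this world (rate recovery within
±1% at n = 50,000; logistic refit within 3 SE; null AUC CI coverage
95% ± 3% over 1,000 replicates) validate the package's machinery, not
the biology.

## Numerical and degenerate-input policy

* Validation failures raise a dedicated condition class
  (`efindex_validation_error`), which the CLI maps to exit code 1
  (runtime errors map to 2).
* Degenerate ROC inputs: an all-one-class outcome is an error; a
  constant index yields AUC 0.5 with J = 0; an AUC of exactly 0 or 1 is
  nudged half a pair inward before the Hanley–McNeil SE (which is
  undefined at the boundary).
* 2×2 machinery requires positive margins; sample-size requires
  `p₁ ≠ p₂` and `ψ > d²`.
* All randomness is seed-controlled; bootstrap and generator restore
  the caller's RNG state.

## Known limitations

* The EFI ignores uterine factors (fibroids, adenomyosis); records
  here are assumed pre-screened, as in the source cohort.
* Single-rater function ratings are assumed; no inter-rater model.
* No DeLong paired AUC-difference test: the source comparison is
  descriptive, and so is ours. No partial AUC, no multiple-testing
  adjustment (none was applied in the source battery).
* The published AUC values themselves (0.641 / 0.445) depend on
  per-patient data that were never released; the package reproduces
  everything computable from printed counts exactly, and covers the
  rest with property-based and calibration tests on the synthetic
  world.
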