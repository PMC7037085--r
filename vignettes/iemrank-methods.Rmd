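---
title: "Ranking inborn errors of metabolism from untargeted metabolomics: methods and design"
author: "iemrank authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking inborn errors of metabolism from untargeted metabolomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iemrank)
```

## The diagnostic problem

Untargeted direct-infusion high-resolution mass spectrometry (DI-HRMS)
of a single plasma or dried-blood-spot sample yields thousands of m/z
features. For a metabolic diagnostic laboratory, the question is not
"which features changed" but "which inborn error of metabolism (IEM)
could explain this profile". iemrank implements a knowledge-based
scoring algorithm that converts a sample's feature-level Z-scores into
a ranked differential diagnosis (DD) over a curated panel of diseases,
so that a laboratory specialist reviews a short preselected list
instead of the raw matrix.

The algorithm needs two inputs: an **expected library** — one row per
(disease, metabolite, fluid) stating the expected alteration and its
diagnostic value — and the **observed** per-sample Z-scores of
annotated m/z features relative to control samples of the same batch.

## The scoring model

### Entry weights

Each library entry receives a signed weight, the product of four
factors:

| factor | levels (default value) |
|---|---|
| direction | increase (1), decrease (−1.5) |
| specificity | only known biomarker (5), substrate/product of the affected enzyme (3), other (1) |
| fluid | plasma / DBS / CSF (2), urine (1) |
| importance | critical (5), important (3), supportive (1) |

Decreases carry a negative factor of larger magnitude because
metabolite decreases are usually subtler than accumulations and would
otherwise be under-valued. The maximum positive weight is
1 × 5 × 2 × 5 = 50 and the maximum magnitude is 75 (a critical
only-biomarker decrease in blood). Two design points are worth making
explicit because the factor table alone does not determine them:

* **Specificity precedence.** Only-biomarker (5) and substrate/product
  (3) are alternatives within one category. An entry flagged as both
  uses 5, never 15.
* **Neutral specificity.** Entries that are neither get factor 1, the
  multiplicative identity.

All ten factors live in a `WeightConfig` object (YAML-overridable), so
retuning the library weighting is a configuration change, not a code
change.

### Metabolite scores and signed ranks

Per sample, every retained feature gets
`Z = (x − mean(controls)) / sd(controls)` and a rank within its sign
class: positive Z-scores ranked 1, 2, … from the maximum down, negative
Z-scores ranked from the minimum up. The metabolite score of a feature
is

```
metabolite score = Z / (rank × 0.9)
```

The rank attenuates unremarkable alterations — a Z of 3 that is only
the 30th largest in its sample says less than the same Z at rank 2 —
and the constant 0.9 weights the rank slightly below the Z-score
itself.

### Disease probability score, gating, classification

For disease *d* with library entries *E(d)*, deduplicated to unique
observed m/z features:

```
score(d) = Σ weight(e) × Z(e) / (rank(e) × 0.9)
```

Entries whose metabolite resolves to no annotated feature contribute
0. After summation, **critical gating** applies: a critical entry
expected increased that is not observed increased (Z < 1.6), or
expected decreased and not observed decreased (Z > −1.2), zeroes the
disease's score. Scores then map to likelihood classes — very likely
(> 50), likely (> 10), possible (> 1), unlikely (> 0), very unlikely
(≤ 0) — and the DD is the score > 1 subset, sorted by descending score.

Note the sign logic: an expected decrease has negative weight, and an
observed decrease has negative Z, so a confirmed decrease contributes
*positively*. A paradoxical increase of an expected-decreased
metabolite subtracts from the disease's score.

## Decisions where the model was genuinely open

These choices are not implied by the factor table or the formulas and
are documented here as the package's own design:

* **Adducts.** Observed m/z are matched as [M+H]⁺ in positive and
  [M−H]⁻ in negative mode (proton mass 1.007276 Da), the minimal
  physically coherent reading of DI-HRMS annotation; the adduct
  specification is a `buildMassIndex()` argument.
* **ppm window.** The 2 ppm tolerance is inclusive (≤) with the
  theoretical m/z in the denominator. At 2 ppm the choice of
  denominator is itself far below 2 ppm.
* **SD convention.** Sample standard deviation (n − 1), the standard
  choice for small control cohorts.
* **Replicates.** Technical triplicates are averaged (arithmetic mean;
  median available) before Z-scoring.
* **Tie-breaks.** Ranking ties break by ascending m/z, then positive
  mode before negative; DD ties break alphabetically by disease name.
  Both exist only to make output deterministic.
* **Zero Z-scores** carry no rank and contribute 0 wherever they
  appear; their metabolite score would be 0 at any rank.
* **Mode resolution.** A metabolite observed in both ionization modes
  uses the feature with the larger |Z| — one observation per
  metabolite, preferring the stronger signal.
* **"Unique m/z" deduplication.** When isomers collapse several
  entries of one disease onto one observed feature, that feature is
  counted once, through the entry with the largest |weight|; anything
  else would double-count a single measurement.
* **Missing critical metabolite.** A critical entry with no observable
  feature fails its gate. An indispensable marker that cannot be
  measured cannot support inclusion; `validateLibrary()` surfaces such
  library/mass-table mismatches before any sample is scored.
* **Boundaries.** Likelihood bins are lower-exclusive/upper-inclusive
  so every score maps to one class; a score of exactly 1 is excluded
  from the DD (membership requires > 1); Z exactly 1.6 passes the
  increase gate and Z exactly −1.2 passes the decrease gate.
* **Urine entries** still contribute (with fluid factor 1) when blood
  samples are scored; the fluid factor weights rather than excludes.
* **Batch scoping.** Z-scores and ranks are computed within one batch
  against that batch's controls; no cross-batch normalization is
  attempted.

Extension points deliberately *not* implemented: metabolite-specific
Z cut-offs and phenotype-informed prioritization. Both would slot into
`GateThresholds` / the scoring call without structural change.

## The synthetic-data generator

Real expected libraries encode curated clinical knowledge and cannot
be shipped here; the generator builds self-consistent stand-ins with
known ground truth so that every pipeline stage is testable offline.

`simulateReference()` draws metabolite masses from a 10-ppm-spaced log
grid over 71–599 Da with sub-ppm jitter: all pairwise gaps exceed
3 ppm, safely outside the 2 ppm annotation window, except for a
configurable fraction of deliberate isomer pairs sharing a mass
exactly (the galactose/glucose failure mode). Each synthetic disease
gets 2–5 signature metabolites, disjoint across diseases, with
direction, fluid, role and importance drawn per configuration
(defaults: 80% increases; 25% critical).

`simulateCohort()` draws control intensities per feature from a
log-normal with feature-specific mean (log-uniform over 10⁴–10⁶
arbitrary units) and coefficient of variation 0.2, emulating the
positivity and right skew of MS intensities. Every metabolite yields
one feature per ionization mode. Patient samples multiply each
signature metabolite's intensity by

```
k = 1 + z_target × cv_total        (increase)
k = max(1 − z_target × cv_total, 0.02)   (decrease)
```

where `cv_total` is the coefficient of variation of a
replicate-averaged control intensity (biological/analytical spread
plus technical noise at CV 0.1 over 3 replicates), so the expected
observed Z of a spiked feature equals the target. Decrease targets
beyond what a positive intensity can express (|Z| > 1/cv) clamp near
zero intensity, i.e. at the attainable extreme. A zero effect size
gives k = 1: patients are then generatively identical to controls,
which is exactly the null condition the evaluation tests use.

The generator does **not** emulate ionization suppression, adduct
diversity, instrument drift, batch effects, missingness, or the
asymmetric abundance of isomer partners. Passing recovery tests on
synthetic cohorts therefore demonstrates the correctness of the
scoring machinery under its own assumptions, not the clinical accuracy
of any particular library on real spectra.

## Numerical and evaluation choices

* DD-length intervals use nearest-rank 5th/95th percentiles,
  reproducible on small n; medians are standard.
* Percentages are displayed rounded to whole percent; JSON output
  keeps full precision.
* End-to-end runs are deterministic given a seed; scores reproduce
  across platforms to well below 1e-9.
* Features with zero control spread are excluded from their batch
  with a warning and recorded in the result's metadata rather than
  silently producing infinite Z-scores.

## Problem sizes used in the shipped checks

The test suite validates the scoring engine against naive
reference implementations (all-pairs annotation scan, sort-based
ranking, double-loop score accumulation) on ~1000 randomized
library/profile instances of up to 100 entries, and runs spike-in
recovery studies of 200 patients and 30 controls over 12 diseases and
60 metabolites at target |Z| = 8 (recovery ≥ 95% in DD expected) and
|Z| = 0 (patient and control DD lengths compared by rank-sum test).
These sizes were chosen as the smallest cohorts at which the recovery
and null properties are statistically stable.

## Known limitations

* The algorithm ranks only diseases present in the library; it cannot
  flag "no library disease fits".
* Isomer masking is faithfully represented but not resolved: a
  low-abundance metabolite sharing an m/z with an abundant isomer
  inherits the isomer's Z-score.
* Critical gating is binary; a marker at Z = 1.59 zeroes a disease
  that a marker at Z = 1.60 would leave ranked first. The
  `GateThresholds` object makes the cliff explicit and tunable.
* Weights encode curation quality; the shipped toy library is a
  structural illustration, not clinical knowledge.

## Session info

```{r}
sessionInfo()
```
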