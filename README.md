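# iemrank

Ranked differential diagnosis of inborn errors of metabolism (IEM)
from untargeted metabolomics of a single blood sample.

## What problem this solves

Untargeted direct-infusion high-resolution mass spectrometry (DI-HRMS)
measures thousands of m/z features per sample, but turning that matrix
into a diagnostic hypothesis is labor-intensive. iemrank automates the
preselection step for metabolic diagnostic laboratories: given a
curated **expected library** of metabolite alterations per disease and
a sample's feature **Z-scores** against control samples, it scores
every disease in the panel and returns a short, ranked differential
diagnosis (DD) for a specialist to review.

## The algorithm

Each library entry (disease × metabolite × fluid) carries a signed
weight, the product of four factors: direction (increase 1 /
decrease −1.5), specificity (only biomarker 5 / substrate or product
of the affected enzyme 3 / other 1), fluid (plasma, DBS, CSF 2 /
urine 1) and importance (critical 5 / important 3 / supportive 1).

Per sample, each m/z feature gets a Z-score against the batch controls
and a rank within its sign class (largest positive Z ranks 1; most
negative Z ranks 1). The disease probability score sums over the
disease's entries, deduplicated to unique observed m/z:

    score(d) = Σ  weight(e) × Z(e) / (rank(e) × 0.9)

A disease whose *critical* entry is not observed as expected
(Z < 1.6 for expected increases, Z > −1.2 for expected decreases) is
gated to score 0. Scores classify as very likely (> 50), likely
(> 10), possible (> 1), unlikely (> 0), very unlikely (≤ 0); the DD is
the score > 1 subset, sorted descending.

Peak annotation matches observed m/z to monoisotopic metabolite masses
([M+H]⁺ / [M−H]⁻) within an inclusive 2 ppm window over the 70–600 m/z
scan range, keeping isomer ambiguity: isomers share one feature and
one Z-score.

See `vignettes/iemrank-methods.Rmd` for the full model, the design
decisions and the synthetic-data generator.

## Worked example

A patient profile with strongly increased phenylalanine (Z = 9) and
normal downstream neurotransmitter metabolites, scored against the
packaged toy library (a structural illustration, not clinical
knowledge):

```r
library(iemrank)
lib <- readExpectedLibrary(system.file("extdata", "toy_library.tsv", package = "iemrank"))
mt  <- readMassTable(system.file("extdata", "toy_mass_table.tsv", package = "iemrank"))
idx <- buildMassIndex(mt)   # [M+H]+ / [M-H]-, 2 ppm

peaks <- data.frame(
  mode = "positive",
  mz = mt$monoisotopic_mass[match(
    c("HMDB0000159", "HMDB0000158", "HMDB0000118", "HMDB0000763",
      "HMDB0000187", "HMDB0000161", "HMDB0000641"), mt$hmdb_id)] + 1.007276)
annot <- annotationTable(annotatePeaks(peaks, idx))
profile <- rankZScores(z = c(9.0, -0.5, 0.2, 0.1, 0.4, 0.3, 0.6),
                       mode = peaks$mode, mz = peaks$mz,
                       sampleId = "patient_01")
dd <- buildDD(lib, profile, annot)
ddTable(dd)
#>   dd_rank  iem_id                                  name     score classification
#> 1       1     PKU                       Phenylketonuria 301.66667    very_likely
#> 2       2 DNAJC12                    DNAJC12 deficiency  59.70000    very_likely
#> 3       3    DHPR Dihydropteridine reductase deficiency  59.54444    very_likely
```

All three phenylalanine-increase diseases enter the DD —
phenylalanine alone cannot separate them — but phenylketonuria ranks
first because its phenylalanine entry carries the highest weight
(critical substrate, weight 30 vs 6). The decomposition shows exactly
where the score comes from:

```r
ddResults(dd)$PKU@contributions[, c("hmdb_id", "weight", "z", "rank",
                                    "metabolite_score", "product")]
#>       hmdb_id weight    z rank metabolite_score    product
#> 1 HMDB0000159     30  9.0    1       10.0000000 300.000000
#> 2 HMDB0000158     -3 -0.5    1       -0.5555556   1.666667
```

Phenylalanine contributes 30 × 9.0/(1 × 0.9) = 300; the mildly
decreased tyrosine (an expected decrease, so negative weight × negative
metabolite score) adds another 1.67. The serine-deficiency and
galactosaemia entries of the toy library are gated out: their critical
markers are not altered in this profile.

Cohort-level workflow (synthetic data, CLI form):

```sh
Rscript inst/exec/iemrank simulate --out-dir run --seed 11
Rscript inst/exec/iemrank score --mass-table run/mass_table.tsv \
    --library run/library.tsv --intensities run/intensities.tsv \
    --truth run/truth.tsv --out-dir run
Rscript inst/exec/iemrank evaluate --dd run/dd.tsv --truth run/truth.tsv --out-dir run
```

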