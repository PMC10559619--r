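# momic

Multi-omic integration and cross-species subtype classification for
mouse mammary tumor models.

Mouse models of breast cancer are only useful insofar as their tumors
resemble human disease. Assessing that takes several omics layers at
once: which somatic variants are real (two callers rarely agree), which
copy-number events actually drive expression, which pathways separate
histological subtypes, which mutational processes shaped each genome,
and — after removing platform batch effects — which human intrinsic
subtype each mouse tumor most resembles. momic packages that entire
analysis as composable, tested R functions plus numbered driver scripts,
for computational biologists working with heterogeneous tumor cohorts
(mouse or otherwise) who need the integration machinery without any
external download: a synthetic-data module generates every input shape
the pipeline consumes, with ground truth attached.

## What is implemented

| Stage | Core method |
|---|---|
| Variant consensus | two-caller SNV intersection on (chrom, pos, ref, alt) + germline subtraction; SV consensus with per-breakpoint 100 bp margin, length > 10 kb, MAPQ ≥ 60, wildtype subtraction; translocations at 1 kb / MAPQ ≥ 50 gated by gene-break intersection |
| CN–expression | Kendall τ-b = (C − D)/√((n₀−n₁)(n₀−n₂)) and Pearson r per gene with discrete CN change; inclusive flags τ ≥ 0.3, r ≥ 0.7 |
| Differential expression | pooled-variance two-sided Student's t per gene; integrative gene set = DE ∩ conserved CN event (same-sign Δ, ≥ 66% of a group), homolog-mapped |
| Pathway scoring | ssGSEA: integrated running-sum statistic with rank weights \|x\|^α, α = 0.75; volcano rule \|Δ\| ≥ 0.4 and p ≤ 0.05 |
| Signatures | 96-channel catalogs; exposure refit by forward selection with sum-≤1 nonnegative least squares, cutoff 0.06, tol 1e-3 |
| Batch adjustment | parametric empirical-Bayes location-scale model (normal prior on γ, inverse-gamma on δ², method-of-moments hyperparameters, fixed point to 1e-4) |
| Subtype classifier | RFECV (RBF-SVM, permutation importance, stratified 10-fold) → soft-voting ensemble of 5 learners over 15 stratified 70/30 instantiations; accuracy, weighted F1, multiclass MCC |
| Survival | Kaplan–Meier product-limit, Greenwood variance, log-log CIs, Brookmeyer–Crowley median CI, log-rank test |

## Worked example

The numbered scripts under `analysis/` run the whole pipeline on
simulated cohorts (seed 42; override with `MOMIC_SEED`):

```sh
Rscript analysis/01_simulate.R    # writes results/synth/*
Rscript analysis/02_variants.R
Rscript analysis/03_integration.R
Rscript analysis/06_subtype.R
Rscript analysis/07_survival.R
```

Selected output and what it means:

```
SNV consensus: kept 240 of 420 / 380 calls after germline subtraction (expected 240 )
SV consensus: 48 merged calls; recall 1, precision 1
```

Of 420 and 380 single-caller SNV calls, exactly the 240 planted
caller-shared, non-germline calls survive; the 48 merged structural
variants are exactly the truth events that pass the length/MAPQ/wildtype
filters.

```
correlation: 100 genes with discrete CN change; 100% at r >= 0.7, 100% at tau >= 0.3
integrative gene set: 60 homolog-mapped genes both DE and in a conserved CN event
```

With expression coupled to copy number at 2 units per copy, every
CN-varying gene is flagged, and the integrative set recovers exactly the
60 genes planted in conserved per-class CN blocks.

```
RFECV selected 19 of 45 genes (best CV accuracy 1 )
ensemble: accuracy 0.997, weighted F1 0.997, MCC 0.996 (mean over 15 instantiations)
mouse assignment: 100.0% of samples recover their generating class
```

After joint batch adjustment of the human-like and mouse-like cohorts,
feature elimination narrows the panel, the five-learner soft-voting
ensemble separates the six intrinsic subtypes, and every mouse-like
sample is assigned the subtype whose distribution generated it.

```
altered    median 65.7 months (95% CI 59.0-77.8), 316 events / 500
unaltered  median 177.6 months (95% CI 154.6-204.4), 324 events / 500
log-rank chi-square 99.9, p = 1.64e-23
```

Kaplan–Meier medians estimated from the simulated altered/unaltered
cohort (generating medians 77.7 and 164.3 months, 35% censoring), with
the log-rank comparison.

## Repository layout

```
R/                  package implementation (all computation lives here)
analysis/           numbered narrative drivers over the package
scripts/acceptance.R  end-to-end quantitative summary
tests/testthat/     unit, property and end-to-end acceptance tests
vignettes/          methods vignette (models, assumptions, parameters)
```
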