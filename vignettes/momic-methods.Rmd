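---
title: "Methods: multi-omic integration and cross-species subtyping with momic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic integration and cross-species subtyping with momic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

momic re-implements, as a tested pipeline, the analysis arc used to
characterize genomically heterogeneous mouse mammary tumor cohorts and
relate them to human breast cancer: consensus somatic variant merging,
copy-number-to-expression correlation, single-sample pathway scoring,
mutational-signature refitting, empirical-Bayes batch adjustment, and a
soft-voting intrinsic-subtype classifier, plus Kaplan-Meier survival
machinery. Every stage is exercised end to end on synthetic cohorts
generated by the package itself (`analysis/01_simulate.R` through
`analysis/07_survival.R` in the source repository), so the full analysis
reproduces offline from a single seed.

This vignette documents the models, their assumptions, the tunable
parameters, and the design decisions taken where the procedure was
genuinely open.

## Consensus somatic variants

**SNVs.** Two callers' call sets for the same tumor are intersected on
exact (chromosome, position, reference base, variant base) identity;
annotation (predicted impact, gene) is carried from the first caller.
Strain-background (germline) variants are then subtracted by the same
four-field identity. Subtraction is idempotent and order-preserving.

**CNVs and inversions.** A call from caller A matches a call from
caller B when the type and chromosome agree and *both* breakpoints lie
within 100 bp. The margin is applied per breakpoint — the stricter and
symmetric reading of a positional tolerance on two-breakpoint events —
and matching is one-to-one: candidate pairs are resolved greedily by
smallest combined breakpoint distance, ties broken by the leftmost
caller-A call. Merged calls carry caller-A coordinates and the pair's
minimum MAPQ, a deliberately conservative quality summary. Three filters
follow, in any order (they commute): length strictly above 10,000 bp,
MAPQ at least 60, and no same-type wildtype call matching under the same
positional rule. On call sets whose events are well separated relative
to the margin — the regime real breakpoint jitter produces — the greedy
matcher provably coincides with exhaustive minimum-distance matching,
and the test suite checks this against an exhaustive oracle on hundreds
of random instances.

**Translocations.** The same consensus machinery with a 1,000 bp margin,
no length minimum, and MAPQ at least 50. Instead of wildtype
subtraction, a merged translocation is retained only when one of its
annotated genes appears in an independent gene-break table for the same
sample — gene-level corroboration as the false-positive control.

**Integer copy number.** Segment log2 ratios map to integers as
`round(ploidy * 2^log2)`, half-up, floored at zero, with baseline ploidy
2 everywhere (sex chromosomes are treated as autosomes unless the
baseline is overridden; whole-chromosome gains of one and two copies
appear as ratios of log2(3/2) and 1).

**Conserved mutations.** A gene counts as conserved in a histology group
when at least 66% of the group's tumors carry a MODERATE or HIGH impact
call in it; LOW and MODIFIER annotations never contribute. The 66%
threshold and the impact restriction are exposed as arguments.

## Copy number and expression

Correlation between integer copy number and expression is computed per
gene across the samples shared by both assays, as Kendall's tau-b (with
full tie corrections, the form appropriate for a discrete variable) and
Pearson's r. Correlations are only defined for genes with a discrete
copy-number change — copy number varying across samples and reaching at
least one copy away from diploid; constant-CN genes emit undefined
records. Significance flags are inclusive: tau >= 0.3 and r >= 0.7.

Differential expression between groups uses a pooled-variance two-sided
Student's t-test per gene on (assumed log-scale) expression, with
`log_fc` the plain mean difference. Degenerate genes (zero pooled
variance) get p = 1 when the means agree and p = 0 otherwise. No
multiple-testing correction is applied by default because the
integrative gene set downstream consumes an uncorrected p < 0.05 rule;
the cutoff is an argument.

The **integrative gene set** is the intersection of two evidence
streams: genes differentially expressed (p below the cutoff in at least
one pairwise group contrast) that also sit in a conserved copy-number
event — same-sign delta of at least one copy in at least 66% of some
group's samples. The surviving genes are mapped through a homolog table
(e.g. mouse to human symbols) and unmapped genes are dropped. Both
knobs (p cutoff, conservation fraction) are arguments: the precise
recipe behind such integrative sets is rarely fully specified, so the
implementation exposes the choices rather than hard-wiring one.

Stratification summaries use Ward-linkage hierarchical clustering
(`hclust`, "ward.D2", Euclidean distance) and two-component PCA on
standardized features; zero-variance features are dropped with a
warning.

## Single-sample GSEA

For one sample, genes are ranked by descending expression, ties broken
by gene symbol so scores are deterministic. Walking the ranked list, an
in-set cumulative distribution advances by `|x|^alpha` (normalized over
in-set genes; the rank statistic is the expression value itself) and an
out-of-set distribution advances by `1/(N - m)`. The score is the
*integrated* enrichment statistic — the sum of the running difference
over all positions — rather than its extremum, which is what makes the
statistic sensitive to coordinate shifts of the whole set. `alpha`
defaults to 0.75, the canonical single-sample weighting; at `alpha = 0`
the score depends on expression only through ranks, and the tests assert
that invariance. When a set spans the whole universe the out-of-set step
is undefined and the closed-form in-set maximum is returned.

Matrix-level scoring optionally normalizes by the global (max - min)
score range, the convention applied before clustering enrichment
profiles. Differential pathway tables flag a set as significant when
|mean difference| >= 0.4 *and* p <= 0.05 (pooled t), both inclusive; a
set can therefore have a vanishing p-value and still not be flagged if
its effect is below the fold-change threshold.

## Mutational signatures

Catalogs are 96-channel counts: six pyrimidine-reference substitution
classes by sixteen flanking contexts, channels in lexicographic order
(`A[C>A]A` … `T[T>G]T`); purine-reference calls are reverse-complemented
during collapse.

Exposure refitting mirrors the forward-selection refit used by the
established R tooling: the catalog is normalized to frequencies; at each
step the signature whose inclusion most reduces the residual sum of
squares is added, with weights refit by nonnegative least squares
constrained to sum at most 1 (projected-gradient iterations with an
exact simplex projection — any solver reaching the same SSE is
conforming); selection stops when the best improvement falls below
`tol = 1e-3`; weights below `cutoff = 0.06` are discarded, survivors are
refit once, and retained weights are renormalized to sum 1. Both
constants are the cited tooling's documented defaults and are exposed as
arguments. The SSE path is returned and is non-increasing by
construction.

Two numerical consequences are worth knowing. First, the `tol` stopping
rule acts on SSE of *frequency* vectors, so mixture components
contributing less than roughly `sqrt(tol)` of catalog mass — or larger
components whose profiles are well approximated by combinations of
already-selected ones — can be absorbed rather than reported: with the
default synthetic mixture (0.60 / 0.25 / 0.15 over correlated sparse
profiles) the 0.15 component is typically folded into the other two,
while 0.7 / 0.3 mixtures are recovered within ±0.05 at 10,000
mutations. Second, exposures of pure-signature catalogs converge to 1 as
the catalog grows; the tests check the mean error decreases over
10^2, 10^3, 10^4 mutations. No trinucleotide-abundance (exome/genome)
renormalization is applied by default.

## Batch adjustment

`eb_batch_adjust` implements the parametric empirical-Bayes
location-scale adjustment: per-gene standardization by the
batch-size-weighted grand mean and pooled variance; per-batch, per-gene
additive (gamma) and multiplicative (delta^2) effects estimated on the
standardized data; gamma shrunk under a normal prior and delta^2 under
an inverse-gamma prior, hyperparameters by method of moments, with the
joint shrinkage fixed point iterated to a relative change below 1e-4;
adjusted data `(Z - gamma*)/delta*` restored to the original scale. The
implementation follows the reference empirical-Bayes tooling exactly —
including its convergence bookkeeping — and the test suite asserts
bit-level agreement with it on two-batch synthetic data.

Assumptions and limits: no covariate model is used, so biological groups
should be balanced across batches or the biology itself will be partly
absorbed into the batch terms; a single batch returns the input
unchanged with a warning; genes with zero pooled variance are dropped.
Because gamma estimates are *shrunk*, per-gene batch means are not
removed exactly — the residual scales like half the batch-mean sampling
error — and the per-gene grand mean is preserved only approximately
(exactly, in the no-shrinkage limit). With ~240 samples per batch the
mean absolute residual batch difference falls below 0.1 on unit-variance
data.

## Cross-species subtype classification

The classifier operates on the canonical intrinsic-subtype order BASAL,
CLAUDIN_LOW, HER2, LUMA, LUMB, NORMAL, which is the single tie-break
authority everywhere (argmax ties resolve to the earlier class).

**Feature selection.** Recursive feature elimination with stratified
10-fold cross-validation, using an RBF-kernel SVM. Kernel SVMs expose no
coefficients, so per-feature importance is *permutation importance*:
the drop in held-out accuracy when the feature's column is permuted in
the validation fold, averaged over folds. At each feature count the mean
CV accuracy is recorded; the subset maximizing it (ties toward fewer
features) is returned with the whole curve. Note one inherent property
of this procedure (shared with the standard implementations): the same
folds drive both elimination and scoring, so curve points for small,
adaptively chosen subsets are optimistically biased — on pure-noise
features the curve maximum sits above chance even though the
full-feature point is unbiased. The tests assert chance level at the
full-feature point and planted-gene recovery (at least 7 of 8
class-defining genes in at least 80% of seeds) for the selection itself.

**Ensemble.** Five base learners — ridge-regularized multinomial
logistic regression (lambda = 1/n), RBF-kernel SVM with probability
outputs, a 100-tree random forest, 100 rounds of gradient-boosted trees,
and a single-hidden-layer perceptron (8 units, weight decay 1e-3) — are
fit on a stratified 70/30 shuffle split and their class-probability
outputs averaged with equal weight (soft voting). This is repeated for
15 independent instantiations; accuracy, support-weighted F1 and the
generalized multiclass Matthews correlation coefficient are computed per
instantiation and averaged, and the confusion matrix is summed across
instantiations with pooled-confusion metrics reported alongside (the
averaged and pooled readings answer slightly different questions, so
both are kept). Hyperparameters are deliberately the widely used
defaults and live in one place (`fit_base_learners`). A fixed root seed
makes splits, fits, metrics and downstream assignments bit-identical
across runs.

The description of the split procedure in the source methods mixes
k-fold language with a 70/30 split; the operational reading — 15
independent stratified 70/30 shuffle splits with probabilities averaged
over instantiations — is implemented.

**Assignment.** New (e.g. mouse) samples, batch-adjusted jointly with
the training cohort and restricted to the model's features, receive the
average probability over all 5 x 15 fitted learners; the argmax is the
assigned subtype, and per-cohort proportion tables summarize model-level
tendencies.

## Survival

The Kaplan-Meier product-limit estimator processes events before
censorings at tied times; Greenwood's formula supplies the pointwise
variance (defined as 0 wherever S is 0 or 1), and 95% intervals use the
complementary log-log transform. The median is the first *event* time
with S <= 0.5 — the step-function convention, not interpolated — and its
interval inverts the pointwise bands (first times the lower / upper
confidence curves reach 0.5). Two-group comparison is the standard
log-rank chi-square with one degree of freedom. All of these are checked
against the standard survival tooling to within numerical precision, and
on exponential synthetic data the median estimate converges to
`log(2)/rate` with sample size.

## The synthetic cohorts

The generators produce every input shape the pipeline consumes, with the
statistical structure the analysis assumes, and each returns a
ground-truth sidecar for recovery tests. Defaults describe the study
conditions the pipeline targets:

* **Expression**: 3 histology classes (microacinar, squamous, EMT) x 14
  samples — a 42-sample cohort — over 500 genes, with 60 informative
  genes in class-specific blocks (effect size 2, noise sd 1, log-like
  scale). Batches act as location-scale distortions
  (`offset + scale * (signal + noise)`), the model the EB adjustment
  assumes, with samples assigned round-robin within class so classes
  stay balanced across batches.
* **Copy number + expression**: a matched 9-sample (3 per class) cohort;
  each class carries one conserved 20-gene block (deltas +2, -1, +1 —
  whole-chromosome-like gains and losses conserved within a class), 40
  genes vary in exactly one sample per class (sample-private events that
  can never reach a 2/3 conservation threshold), the rest are diploid.
  Expression is `cn_beta * (CN - 2) + noise`.
* **SV call sets**: one truth set (default 60 events across DEL, DUP,
  INV, TRA; lengths 20 kb–1 Mb, MAPQ 60) emitted into two caller call
  sets with independent Gaussian breakpoint jitter (default sd 20 bp,
  rounded, clamped to >= 1); caller-private false positives at a
  configurable rate, placed at least 10 kb from every truth breakpoint
  so oracle tests are exact; a leading fraction (default 25%) of truth
  duplicated into the wildtype set as germline contamination.
* **Mutation catalogs**: multinomial draws (default 10,000 mutations)
  from a mixture of synthetic sparse signature profiles (Dirichlet-like,
  concentration 0.3); the default mixture 0.60 / 0.25 / 0.15 emulates a
  dominant-process tumor.
* **Survival**: exponential event times with per-group medians 77.7 and
  164.3 months — the printed altered-vs-unaltered contrast the survival
  stage targets — with independent exponential censoring tuned to a 35%
  censored fraction, a typical overall-survival cohort.

What the generators deliberately do *not* emulate: probe-level
microarray artifacts, read-level noise, subclonal copy number, signature
profiles with flat (non-sparse) shapes, or non-proportional hazards.
Passing tests on these cohorts therefore demonstrate correctness of the
algorithms under their stated assumptions, not robustness to every
failure mode of real data.

## Problem sizes used by the test suite

The suite runs in a few minutes on one CPU: consensus-matching oracles
on 50 random instances of 40 events; 1,000 short-vector tau-b
comparisons; signature recovery over 20 seeds at 10,000 mutations;
batch adjustment on 3 x 160 samples x 250 genes (sized so the shrinkage
residual, ~0.5 sd/sqrt(n), clears the 0.1 band); the ensemble on 600
samples x 32 genes over 15 instantiations; RFECV recovery over 10 seeds
of an 80-sample, 32-gene design; and survival power over 20 seeds at 500
per arm. These sizes are the package's own choices for tight yet
informative statistical bands.
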