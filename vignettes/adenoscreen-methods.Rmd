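---
title: "Models and methods behind adenoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind adenoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(adenoscreen)
```

This vignette is the package's own account of its statistical machinery:
the model behind each assay, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices that a reader re-deriving the results
would need to know.

## The detection problem

Advanced adenomas shed little DNA into plasma, so any single blood-based
marker has modest sensitivity. The framework therefore combines four
orthogonal signals — cfDNA fragmentation patterns, chromosome-arm
aneuploidy, circulating protein levels, and tissue-informed mutation
detection — each calibrated on its own training population to a 99.5%
specificity threshold, and declares a sample positive when any assay is
positive. The high per-assay specificity is what makes the OR-combination
tolerable: each added assay buys sensitivity at a bounded specificity
price.

## Fragmentation score

**Input.** An integer matrix of read counts, samples × amplicons, over a
genome-wide panel of repeated-element amplicons, with per-amplicon
expected insert length and chromosome arm.

**Stage 1 — batch filtering** (`filter_amplicons`). Counts are divided by
the sample total and each amplicon is tested across sequencing batches
with a Kruskal–Wallis test; Benjamini–Hochberg q < 0.05 drops the
amplicon, as does a median normalized count below 10% of the panel median
(which also removes all-zero amplicons). The published description of this
stage is a figure without formulae, so the Kruskal–Wallis/floor rule is
this package's own operationalization and is documented as such. Run it on
training controls only, so batch structure is not confounded with disease.

**Stage 2 — per-arm normalization and signatures**
(`normalize_by_arm`, `extract_signatures`). Within each arm, a sample's
counts are divided by the sample's arm total, giving compositions that are
invariant to sequencing depth; each arm's amplicons × samples matrix is
factorized as V ≈ WH with W, H ≥ 0 under Frobenius loss. Columns of W are
rescaled to sum to one, so each signature is a distribution over the arm's
amplicons. Numerical choices: multiplicative updates, at most 500
iterations, relative convergence tolerance 1e-6 checked every 10
iterations, and a deterministic SVD-based initialization (positive parts
of the leading factor pairs) with a small seeded uniform jitter on zeros —
so the factorization is reproducible bit-for-bit given the seed. The same
number of signatures k is used on every arm, because the cross-validated
dimension choice treats k as a single model-complexity knob.

**Stage 3 — fragmentation-consistent selection**
(`select_fragmentation_features`). Each signature's length centroid is its
signature-mass-weighted mean insert length. Disease plasma is more
fragmented, so informative signatures should pair a short centroid
(below the panel median insert length) with higher exposure in cases, or a
long centroid with lower exposure. Each signature is tested with a
one-sided Wilcoxon rank-sum test in the direction its centroid implies;
Benjamini–Hochberg q < 0.1 with the correct effect direction selects it.
The selection may be empty; the pipeline then warns and falls back to all
signatures rather than failing.

**Stage 4 — SVM scoring** (`train_signal`, `signal_fit`, `score_signal`).
Exposures are non-negative least-squares projections of a sample's per-arm
composition onto the arm's signatures (the same projection at train and
score time, rather than re-using the factorization's H, so new samples are
handled identically to training samples). Selected exposures are
standardized with training statistics and classified by a radial-kernel
SVM with Platt sigmoid probability calibration, giving a score in [0, 1].
The kernel bandwidth default is γ = 1/d² for d features. The common 1/d
heuristic was rejected deliberately: with these low-dimensional, strongly
separable exposures it saturates the calibrated probabilities and makes
the decision surface non-monotone beyond the training cloud, which
destroys the score's ability to rank samples by tumor burden; 1/d² gives
the same operating characteristics with a monotone, better-ranked score.

**Dimension choice** (`choose_dimension`). For each candidate k the whole
pipeline is refit on stratified training folds; out-of-fold scores are
pooled, the threshold is read at the target specificity on pooled control
scores, and sensitivity at that threshold is recorded. The chosen k is the
smallest whose sensitivity is within ε = 0.01 of the grid maximum — a
plateau rule that prefers parsimony over chasing noise in the CV estimate.

## Global aneuploidy score

Features are per-arm fractions of total reads, z-scored against the
training controls' means and SDs — depth-invariant by construction. The
positive training class mixes real cancers with in-silico aneuploid
samples built from controls: counts on altered arms are multiplied by
1 + t/2 for a single-copy gain (or 1 − t/2 for a loss) at tumor fraction
t, then the whole vector is multinomially re-sampled to the original
depth so the synthetic sample has realistic integer counts at unchanged
coverage. The in-silico grid spans tumor fractions
{0.01, 0.02, 0.05, 0.1, 0.2} and 1–5 altered arms with random gain/loss
states. Sex chromosomes are excluded from the synthetic panel design to
avoid sex confounding. The SVM and threshold calibration are shared with
the fragmentation score.

## Protein-17 score

Concentrations of the 17 plasma analytes are transformed log10(x + 1),
standardized per analyte with training statistics, and scored by the same
calibrated SVM machinery. Analytes are matched by name against a canonical
order, so column order never changes a score; missing values are filled
with the column median. The original model family is unpublished, so
SVM-with-Platt on log-standardized levels is this package's declared
stand-in.

## Multi-well mutation statistic

Each target mutation (identified in the patient's adenoma tissue) is
sequenced in up to 95 wells of ≤300 genome equivalents. Wells below 100
total reads are excluded. The background-noise pool collects well-level
MAFs from two sources: non-target variants in the patient's own amplicons
and all variants in a matched no-cancer control run; at least 50 pooled
values are required. A mutation's score is the sum over its qualifying
wells of −log of the add-one empirical tail probability of that well's MAF
under the pool; the per-sample aggregate is the sum over mutations. The
per-well sum, rather than a tail probability of the depth-pooled MAF, is
used because background MAFs are heavily zero-inflated: the pooled
statistic takes so few distinct values that its null p-values degenerate,
while the per-well sum is nearly continuous and is exactly the quantity
the partitioning assay was designed to amplify. (The pooled-MAF tail score
remains available as `score_mutation` for per-mutation summaries.)

The null distribution is Monte-Carlo: every qualifying well redraws its
mutant reads binomially at the pool's aggregate background rate and its
own observed depth, and is scored through the same empirical tail map.
The p-value uses the add-one rule (1 + #null ≥ observed)/(n_null + 1), so
it is never zero; positivity is p < 0.01. An empirical-pool resampling
null was evaluated and rejected: under heavy ties the add-one tail map
treats resampled pool members and fresh MAFs asymmetrically, inflating
the type-I error by half again its nominal value, whereas the binomial
null is exchangeable with observed wells when all MAFs are noise. A
method-of-moments beta fit (after a pseudo-count of half a read at the
mean depth) is stored alongside the empirical pool as a smooth summary.

## Evaluation layer

Thresholds are calibrated as the smallest control score t whose exceedance
count is within ceiling(n·(1 − specificity)) — at specificity 1 this is
the control maximum. Positivity uses strict ">" on raw scores; the
`printed_rounded` mode instead compares two-decimal scores with "≥", which
is the rule needed to reproduce counts from a score table published at
two decimals, where rounded ties must count as positive. Percentages are
rounded half away from zero to one decimal. Wilson score intervals use
z = 1.959964 without continuity correction. Severity subgroups are
assigned with priority high-grade dysplasia → ≥2 cm → 1–<2 cm, which makes
them disjoint and exhaustive; comparator expectations multiply published
per-subgroup sensitivities by subgroup sizes and round half away from
zero. Mutation calls are excluded from assay combinations: tissue-informed
mutation testing has no screening analogue, so combining it would flatter
the panel.

## Synthetic-data generator

`gen_cohort` draws a panel (8 arms × 240 amplicons by default, insert
lengths uniform on 80–160 bp), per-amplicon baseline propensities
(log-normal), per-batch multipliers (log-normal, SD 0.05), and per-subject
biological jitter (log-normal, SD 0.25) that is renormalized within arms —
locus-level amplifiability varies between people, but a euploid subject's
arm dosage is fixed by karyotype, so the jitter must not leak into arm
fractions. Counts are negative-binomial with dispersion 0.1 (amplicon
assays are over-dispersed; Poisson would flatter every downstream test).
In a cancer sample with tumor fraction t ~ U(0.02, 0.25), propensities
acquire a log-linear fragmentation tilt exp(−β·t·(len − min len)) with
β = 0.06 per bp, and 1–3 random arms are multiplied by 1 ± t/2. The
defaults were fixed once, against two stated design conditions: cancers at
t = 0.05 are detectable but not trivially separable, and the panel is the
smallest at which both the factorization can recover the tilt direction
and arm-level z-scores resolve a t = 0.1 single-arm gain (the real assay
has ~9,000 loci per arm; desk scale trades that density for runtime).
Training cohorts default to 327 controls and 379 cancers, the size of the
fragmentation score's published training population.

Duplicate-aliquot mode (`replicate_seed`) redraws counts from the same
latent propensities — two aliquots share the subject's biology, batch and
tumor burden, and differ only in counting noise. Replicate experiments in
the tests use adenoma-like burdens (t ~ U(0.01, 0.1)) because the
published reproducibility analysis re-assayed adenoma cases, whose scores
spread across the whole unit interval rather than saturating.

`gen_proteins` draws log-normal analyte baselines (a fixed "assay world"
reusable across cohorts) and elevates 6 of 17 analytes in cases by e^1.
`gen_wells` partitions mutant templates binomially across wells at the
true MAF, adds per-read sequencing error at rate 1e-4, and generates 60
non-target noise variants plus a matched control run — the count reflects
that the real assay harvests background MAFs from every base pair of each
amplicon, and the mutation statistic's type-I calibration genuinely
depends on a background pool of that size.

**What the generator does not emulate:** GC and sequence-composition
bias, library-preparation chemistry, sub-arm copy-number structure,
correlated amplicon dropout, assay-platform differences between protein
panels, and population structure in protein baselines. Tests passing on
these synthetics show the algorithms recover the structure they assume;
they do not certify performance on real plasma.

## Problem sizes and runtime

The test suite trains the fragmentation score on the default 706-sample
cohort over the 1,920-amplicon panel (seconds to a few tens of seconds),
calibrates thresholds on 2,000 synthetic controls and evaluates held-out
false-positive rates on 2,000 more, runs 2,000 null multi-well assays
(n_null = 1,500 each) for type-I calibration, and 100 power replicates.
Cross-validated dimension choice in tests uses reduced panels (4 arms ×
80 amplicons) because it refits the factorization folds × grid times.

## Known limitations

* The published versions of the batch filter, feature selection, GAS
  feature set, protein model and exact mutation score live in unpublished
  supplementary material; the rules here are faithful to their described
  contracts but are this package's own concrete choices, and are labelled
  as such throughout.
* The original 0.78/0.71/0.96 thresholds cannot be re-derived (the
  training cohorts' raw data are unpublished); they are treated as fixed
  constants of the published study, while `calibrate_threshold` shows the
  mechanism on synthetic populations.
* Thresholds calibrated on n controls have estimation noise of order
  1/n; the held-out false-positive tolerance therefore uses the
  two-sample binomial variance (calibration plus held-out), not the
  one-sample form.
* The per-control scores of the published study are unpublished; the
  packaged control table is synthetic and only constrained to reproduce
  the published control positivity counts, so control-side analyses
  beyond those counts are illustrative.
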