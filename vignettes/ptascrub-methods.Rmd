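---
title: "Filtering PTA amplification artifacts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering PTA amplification artifacts: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptascrub)
```

Single-cell whole-genome sequencing with primary template-directed
amplification (PTA) produces far fewer artifacts than older amplification
chemistries, but still enough that naive variant calling overestimates
somatic mutation burdens severalfold. ptascrub separates true somatic
variants from amplification artifacts using signals that distinguish a
mutation present in the cell's genome from one created in the reaction tube:
a true variant sits on one parental haplotype and therefore tracks the local
B-allele behaviour of the surrounding phased germline heterozygous sites,
phases consistently with them on individual sequencing fragments, and has
the allele fraction of a heterozygous site; an artifact appears on a random
subset of amplicons, phases inconsistently, drifts to low allele fractions,
and carries the mutational spectrum of the amplification chemistry.

This vignette records the models, the tunable parameters, and the design
decisions taken where the procedure left genuine freedom. Everything stated
here is computed by the package's tests or its acceptance script; no claims
about real sequencing data are made.

## Pipeline overview

For base substitutions: quality pre-filters define the candidate somatic
set; an allelic-imbalance test and a read-backed phasing score are computed
per candidate; a random forest over 26 genomic features assigns each
candidate an artifact probability; two per-sample calibration procedures
convert probabilities into a PASS/FAIL cutoff. Indels are filtered by
cross-individual recurrence and homopolymer context instead of a classifier.
Copy-number variants, copy-neutral loss of heterozygosity (cnLOH) and
breakend-supported structural variants are called from panel-of-normals
(PON) normalized read depth, the deviation-of-allele-frequency (DAF) profile
of germline hets, and breakend records.

## Pre-filters

A candidate is somatic only if its flag set is empty after
`apply_prefilters()`. Thresholds (defaults in `ptascrub_config()`):
site quality QUAL ≥ 100 (inclusive); base coverage ≥ 10 at ~30x or ≥ 5 at
~15x, in the test sample and every control, computed as the AD sum with a DP
fallback; mapping quality strictly > 55; genotype quality ≥ 99 for
heterozygous and ≥ 10 for homozygous base substitutions; VAF ≥ 0.3 (30x) or
≥ 0.2 (15x) for substitutions and ≥ 0.25 for indels; no evidence in any
paired control (zero alternate reads *and* a homozygous-reference genotype —
the strictest reading, since "evidence" is not quantified in the method);
absence from the panel of unmatched normals, matched exactly on
chromosome + position + ref + alt. Upstream hard-filter verdicts already in
the `FILTER` column are honoured rather than recomputed, because they depend
on raw caller annotations this package does not re-derive. In the
no-dedicated-control mode, a variant shared by two or more samples of the
individual is flagged instead. Missing values fail their check rather than
passing silently, with one exception: MQ is skipped when the input has no MQ
annotation at all.

## Allelic imbalance

Phased germline hets are filtered to sites heterozygous in the bulk control
with a dbSNP-style identifier; the allele depths of sites whose alternate
allele is phased to the second haplotype are swapped, giving a
haplotype-oriented BAF series. For a candidate, all oriented hets within
200 kb are fitted by a locally weighted least-squares regression of degree 2
weighted by total allele depth, and the fit is evaluated at the candidate
position. The kernel and span are not pinned down by the procedure's
published description, so the package uses the classical tricube kernel with
a span covering all in-window points (`stats::loess`, `span = 1`,
`surface = "direct"`); with at least `ai_min_hets = 10` informative sites the
fit is defined, otherwise the classifier falls back to the model without the
allelic-imbalance feature (on simulated data this affects a few percent of
candidates, matching the small undefined fraction expected in practice).
The prediction is clamped to [0.001, 0.999] — 1/1000 is far below the
resolution of any realistic depth — so the subsequent test is always
defined. The test itself is a two-sided exact binomial test of the observed
alternate count against the predicted BAF, using the standard
point-probability summation convention (the choice of sidedness is ours; the
natural log of the p-value is the classifier feature).

## Read-backed phasing

For each candidate, every read spanning both the candidate and a nearby
germline het is classified *cis* (both alternate or both reference alleles)
or *trans* (anything else). Three hypotheses — cis, trans, mixed — with
expected cis-read fractions `1 − ε`, `ε`, `0.5` receive binomial likelihoods
multiplied across germline sites under uniform priors, and the score is
`−10·log10(1 − max(P(cis), P(trans)))`, capped at 3000. The allele-observation
error `ε = 0.005` is configurable. Scores below 100 mark likely false
positives, above 1000 likely true variants, between them uncertainty.

A structural property of this posterior is worth stating plainly: a fully
concordant read multiplies the odds against the mixed hypothesis by only
`2(1 − ε)`, about 3 Phred per read, so reaching the 1000-score band requires
hundreds of concordant spanning reads. At desk-scale simulated coverage the
confidently-true category is therefore empty, the precision–recall cutoff
below is absent, and the merge rule takes its cosine-only branch — exactly
the fallback the calibration defines for samples with too few confidently
phased variants. The mixed hypothesis is what makes chimeric artifacts score
near zero, so it is kept despite this ceiling.

## The 26 classifier features

The feature families are: the allelic-imbalance log p-value; the mutation
type on the pyrimidine strand (6 classes; purine-reference variants are
reverse-complemented, which also flips the context); twenty positional
context bases, one per position −10…−1 and +1…+10; distance to the nearest
gene; distance to the nearest simple repeat; transcriptional strand
(untranscribed/plus/minus/both, the distinct union over overlapping genes);
and replication timing (median over overlapping intervals, undefined when
none). This is the only decomposition of those families totalling 26.
Categorical features are encoded natively as factors, not one-hot, so the
count stays 26. Distances follow the bedtools-closest convention (adjacent
= 1, 0 inside a feature), are capped at 10 Mb and log10-transformed for
split stability. Context windows off a chromosome end pad with an `N`
category.

## Random forest and fallbacks

Rows with an undefined allelic-imbalance value or replication timing are
excluded from training; the majority class is then subsampled to a 1:1
balance. The forest uses 500 trees and 4 variables per split (the cited
implementation's defaults; only the variables-per-split value is prescribed).
Two fallback models — without the AI feature, and without AI and replication
timing — are trained on the identical rows so that candidates with undefined
features can still be scored; their probabilities are strongly
rank-correlated with the main model's on simulated data. The artifact
probability is the fraction of trees voting artifact. When the cutoff is
calibrated on the very rows the forest was trained on (the self-test
situation of simulations), `oob_probability()` substitutes out-of-bag votes
for resubstitution predictions, which would otherwise be biased towards 0
and 1. Feature importance is the mean Gini impurity decrease, and
`importance_and_ablation()` retrains while discarding the least important
feature at each step, tracking out-of-bag balanced accuracy
(`(TPR + TNR)/2`).

## Per-sample cutoff calibration

Two procedures, then a merge:

1. **Precision–recall**: only candidates labelled confidently by phasing
   (score ≥ 1000 or < 1) are used. Over cutoffs 0…1 in steps of 0.01 a
   candidate with probability below the cutoff is predicted true; the cutoff
   where the precision and recall curves intersect is chosen — implemented
   as the grid argmin of |precision − recall| with ties resolved toward the
   lower cutoff, since the curves are monotone in opposite directions.
   Grid points where precision is undefined (no positive predictions) are
   skipped.
2. **Cosine similarity**: for cutoffs 0.1…0.8 in steps of 0.025 (29 nested
   groups) the 96-channel spectrum of sub-cutoff substitutions is computed,
   requiring at least 30 substitutions below the lowest cutoff; the 29×29
   cosine matrix is clustered (complete linkage on the Euclidean distances
   between similarity rows — the embedding is our choice, recorded here and
   configurable) into two clusters, and the highest cutoff in the cluster
   containing the 0.1 group is returned.

The final cutoff is the mean of the two when the best precision–recall value
is at least 0.7 and both exist, otherwise the cosine cutoff alone; variants
with probabilities above it are flagged `FAIL_RF`.

Two limitations of the cosine procedure emerged from simulation and are
inherent to its construction. First, when artifact probabilities rise
gradually above the true-variant mass, the contaminated spectrum groups form
a smooth chain starting arbitrarily close to the pure groups, so the
two-cluster cut lands *inside* the artifact probability mass rather than at
its onset — the returned cutoff is permissive by roughly the width of the
transition. Second, when the classifier is strong and classes are balanced,
the artifacts that leak below any cutoff are precisely those whose features
— including their trinucleotide context — resemble true variants, leaving
the 29 spectra nearly identical; the clustering then keys on small-sample
noise in the lowest groups and can return an overly strict cutoff. Both
behaviours are exercised by the test suite; the command-line interface
accepts a manual cutoff for samples where calibration is degenerate.

## Indel filtering

No classifier is used for indels; recurrence filtering is the published
finding. An exclusion list is built from per-individual call sets: calls
with VAF > 0.15 are collected, left-aligned against the reference (the
match key is representation-dependent otherwise; the canonical
truncate-then-extend-left normalization is used), and keys observed in at
least two distinct individuals are kept with sample/individual counts and
frequencies. Candidate indels matching an exclusion key are flagged, as are
insertions of one or two copies of a single base that extend a reference
homopolymer run of five or more of that base adjacent to the insertion
point. The run is counted on the reference only, on either side of the
insertion point; multi-base insertions are exempt, and deletions are never
flagged by the homopolymer rule.

## Coverage, DAF and structural variants

**Normalization.** Per-1-kb read counts of the test sample are scaled to the
panel's total and divided by the per-bin panel mean, removing shared
amplification waves. The bottom and top 1% of panel bins and bins within
1 Mb of centromeres/telomeres are excluded with a recorded reason.

**Segmentation.** Segments minimize the within-segment sum of squares plus a
penalty per breakpoint, solved exactly by dynamic programming with
PELT-style pruning (the pruning is lossless for this cost, which the test
suite verifies against exhaustive search). The published `gamma = 100`
applies to an implementation that internally standardizes its input, so the
penalty here is `gamma * sigma²` with `sigma²` a difference-based robust
noise variance floored at 1e-12; the floor makes the minimal-breakpoint
optimum unique on noiseless data. 100-kb segment boundaries are fine-mapped
to the boundaries of overlapping 1-kb segments.

**Coverage evidence.** Each segment's 1-kb ratios are compared with the
pooled ratios of the top 25% of segments whose mean is closest to the
diploid level: a Z score and a one-sided normal p-value in the direction of
the deviation give the sample p-value; the same construction against the
panel's per-bin expectation gives the PON p-value. Candidates require
sample p < 0.05 and PON p < 0.2.

**Allele-frequency evidence.** The DAF of a germline het is |VAF − 0.5|.
Mean DAFs in 100-kb bins are segmented twice: on all hets (losses, cnLOH)
and after excluding hets with DAF > 0.45 (gains, which dropout-induced LOH
would otherwise mask). Crude boundaries snap to the nearest het within
200 kb whose DAF is within 0.1 of the segment mean (the similarity tolerance
is ours). VAF modes per segment come from a Gaussian KDE with Silverman
bandwidth, suppressing modes below 10% of the peak density.

**State calls.** Loss = coverage-loss candidate overlapping a DAF segment
above 0.45; gain = coverage-gain candidate overlapping a
gain-segmentation segment with mean DAF above the sample average and a
multimodal VAF distribution with modes within ±0.12 of 1/3 and 2/3;
cnLOH = DAF segment above 0.45 with no overlapping coverage candidate.
Calls are made on interval intersections. The 0.45 threshold is the stated
one, although |0.1 − 0.5| = 0.4 — the procedure's own equivalence between
DAF 0.45 and VAF 0.1/0.9 is arithmetically loose, and the stated number
wins.

**Breakends.** Junctions are paired via mate identifiers and classified by
orientation (+/− deletion-type, −/+ duplication-type, equal-sign inversion,
cross-chromosome CTX). Filters: panel proximity within 2 kb of positions
clustered across ≥ 2 individuals; duplications need local DAF ≥ 0.18 and
copy number ≥ 2.5; deletions need DAF ≥ 0.4 and copy number ≤ 1.5 — these
thresholds only make sense on the copy-number scale, so the local statistic
is 2 × the mean normalized ratio between the breakpoints; at the 15x
coverage class, breakends in 1-kb bins with more than 100 reads are dropped;
inversions need both reciprocal junctions and ≥ 1 kb span; single-junction
inter-chromosomal events are dropped unless within 100 kb of a called CNV
(rescuing unbalanced translocations). Integration emits CNVs on
coverage+DAF support regardless of breakends, emits surviving
breakend-only (balanced) events, and merges a junction into a matching CNV
call with both evidence tags.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with the
statistical structure the method assumes and a truth table that never leaks
into the observables except through the declared distributions.

* Phased hets: Poisson-spaced sites, random haplotype labels, Poisson depth
  (default mean 30, a standard single-sample WGS depth), binomial allele
  depths following a positionally smooth imbalance profile (constant 0.5 in
  balanced regions).
* Candidates: true somatics draw VAF from Binomial(depth, 0.5)/depth,
  trinucleotide context from a clock-like spectrum (CpG-context C>T
  enriched over a flat background), earlier replication timing and smaller
  gene distances; artifacts draw VAF success probabilities from
  Uniform(0.1, 0.4) — the sub-clonal appearance of amplification errors,
  a modelling stand-in since no explicit artifact VAF law is published —
  and context from a fixed T>C- and C>T-enriched spectrum standing in for
  the universal PTA artifact signature. A single separation parameter in
  [0, 1] scales every class difference; at 0 the classes are one
  distribution and any classifier's expected balanced accuracy is 0.5.
  Three percent of rows get undefined AI or replication-timing values to
  exercise the fallback models.
* Read evidence: a few informative germline sites per candidate with ~10
  spanning reads each; true somatics phase consistently, artifacts place the
  somatic allele on a random haplotype per read.
* Coverage/DAF: per-1-kb counts around a shared sinusoidal "wave" baseline
  scaled by local copy number, so panel division removes the waves; het VAFs
  binomial at 0.5 (diploid), 1/3 or 2/3 (trisomic), 0.02/0.98 (loss and
  cnLOH). Defaults: 100 reads per kb, five panel samples, het density
  1/1500 bp.

The generator does **not** emulate mapping errors, GC-dependent coverage
beyond smooth waves, read-level base errors, index hopping, or the joint
selection effects of real variant callers. Passing tests therefore
demonstrate correctness of the algorithms under the stated statistical
model, not performance on real sequencing data — the published headline
numbers (out-of-bag accuracy near 0.74 on real training data, ~87–90%
sensitivity) depend on protected patient data and are plausibility context
only.

## Numerical choices and degenerate inputs

Exact binomial p-values sum point probabilities with the conventional
`1 + 1e-7` tie tolerance; predicted BAFs are clamped to [0.001, 0.999];
the segmentation penalty floor (1e-12) makes noiseless data segment with
the minimum number of breakpoints; zero-variance reference sets leave a
segment `undetermined` rather than producing p-values; empty spectra refuse
cosine similarity; a candidate with no spanning reads is `uninformative`
rather than scored; multi-allelic VCF rows are split and filtered per
allele; chromosome names are matched with the `chr` prefix stripped and
preserved on output. Internally all intervals are 0-based half-open with
conversion only at the VCF boundary.

## Problem sizes

The test suite runs at desk scale by design: classifier checks use 150–400
candidates per class with 60–500 trees; segmentation oracles enumerate all
breakpoint placements up to 12 bins (plus 20-bin spot checks); CNV recovery
uses a 20-Mb chromosome with 1-kb bins, five panel samples and five seeds;
the end-to-end run uses a 10-Mb genome. These sizes keep the full suite
around two minutes while exercising every code path; nothing in the
algorithms is specific to these sizes.
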