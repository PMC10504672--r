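# ptascrub

Filtering whole-genome-amplification artifacts from PTA-based single-cell
sequencing data.

Primary template-directed amplification (PTA) makes single-cell whole-genome
sequencing practical, but the amplification reaction still creates false
variant calls — chimeric molecules and polymerase errors that look like
somatic mutations. ptascrub is for researchers measuring somatic mutation
burdens, spectra and structural variation in single cells: it separates true
somatic variants from artifacts without needing a matched clone.

The signals it uses, and the models behind them:

* **Allelic imbalance** — a true heterozygous variant tracks the local
  B-allele behaviour of the surrounding phased germline hets. Oriented BAFs
  of hets within 200 kb are fitted with a degree-2 locally weighted
  regression (weights = allele depth); a two-sided exact binomial test of
  the candidate's alternate count against the predicted BAF gives `log p`,
  a classifier feature.
* **Read-backed phasing** — reads spanning a candidate and a germline het
  are counted as *cis* (both alternate or both reference alleles) or
  *trans*; hypotheses {cis, trans, mixed} with cis-read fractions
  {1−ε, ε, ½} are compared by a Bayesian posterior, Phred-scaled as
  `−10·log10(1 − max(P(cis), P(trans)))`. Chimeric artifacts phase "mixed"
  and score near zero.
* **A random forest over 26 genomic features** (allelic imbalance, mutation
  type, 10-bp context per side, gene and simple-repeat distances,
  transcriptional strand, replication timing; 500 trees, 4 variables per
  split, classes balanced 1:1, two fallback models for undefined features)
  assigns each candidate an artifact probability.
* **Per-sample cutoff calibration** — a precision–recall intersection over
  phasing-labelled candidates and a cosine-similarity clustering of the
  96-channel spectra of 29 nested probability groups, merged by the
  published rule (mean, or cosine-only when the PR evidence is weak).
* **Indels** — recurrence across ≥ 2 individuals (left-aligned exact keys,
  VAF > 0.15) plus removal of 1-bp insertions extending ≥ 5-bp reference
  homopolymers.
* **CNVs / cnLOH / SVs** — panel-of-normals normalized 1-kb read depth,
  exact penalized least-squares segmentation, one-sided segment tests
  (sample p < 0.05, PON p < 0.2), deviation-of-allele-frequency profiles
  (DAF = |VAF − ½|, LOH above 0.45), VAF mode finding (modes near 1/3 and
  2/3 mark trisomy), and breakend filtering with the published DAF /
  copy-number / junction-count rules.

A synthetic-data module (`simulate_phased_hets()`, `simulate_candidates()`,
`simulate_read_evidence()`, `simulate_coverage_daf()`, `simulate_genome()`)
generates all of these inputs with the statistical structure the method
assumes, so the whole pipeline is testable without sequencing data.

## Worked example

```r
library(ptascrub)

# simulate a labeled candidate set and train the classifier
sim <- simulate_candidates(n_true = 400, n_artifact = 400,
                           feature_separation = 1, seed = 7)
bundle <- train_rf(sim$features, sim$truth$label, seed = 7)
glance(bundle)
#>   n_train n_true n_artifact ntree  mtry oob_balanced_accuracy
#> 1     752    376        376   500     4                 0.936

head(tidy(bundle), 5)
#>   term               mean_decrease_gini
#> 1 gene_distance                   100.0
#> 2 ai_log_p                         74.1
#> 3 mutation_type                    43.1
#> 4 repeat_distance                  35.3
#> 5 replication_timing               33.7
```

752 of the 800 simulated candidates had defined allelic-imbalance and
replication-timing values and enter training (376 per class after 1:1
balancing); the forest separates the classes with out-of-bag balanced
accuracy 0.936, leaning most on gene distance and the allelic-imbalance
p-value.

```r
# score the candidates (out-of-bag, since these are the training rows)
# and calibrate the per-sample cutoff
ev <- simulate_read_evidence(sim$variants, sim$truth$label, seed = 7)
v <- linkage_analysis(sim$variants, ev)
res <- classify_candidates(v, sim$features, bundle, oob = TRUE)
res$cutoff
#> <cutoff_result> final cutoff 0.175 ( cosine_only )
#>   PR cutoff: NA best PR value: 0
#>   cosine cutoff: 0.175

table(pass = is_pass(res$variants), truth = sim$truth$label)
#>        truth
#> pass    artifact true_somatic
#>   FALSE      398          172
#>   TRUE         2          228
```

At desk-scale read counts no candidate reaches the ≥ 1000 phasing score that
defines the confidently-true group, so the PR cutoff is absent and the merge
rule takes its cosine-only branch. Here the spectral clustering picks a
strict cutoff (0.175): the PASS set is nearly artifact-free (2/230) at the
cost of recall — see the methods vignette for why this regime is hard for
the cosine procedure and when to prefer a manual cutoff.

```r
# extrapolate a mutation burden over the callable fraction
callable <- tibble::tibble(chrom = "1", start = 0, end = 8e7)
extrapolate_burden(res$variants, callable, c("1" = 1e8))
#> burden: 228 PASS in callable / fraction 0.80 = 285.0
```

For CNV/SV calling see `simulate_coverage_daf()`, `normalize_coverage()`,
`segment_values()`, `daf_profile()`, `call_cn_segments()`,
`filter_breakends()` and `integrate_svs()`; `vignettes/ptascrub-methods.Rmd`
walks through every model. A thin command-line front end lives at
`inst/cli/ptascrub.R` (`simulate`, `snv`, `indel`, `sv` subcommands).

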