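# amlsubtypes

Multi-cohort expression subtype discovery and drug prioritization for
NPM1-mutated acute myeloid leukemia.

NPM1-mutated AML is a single diagnostic entity with very heterogeneous
biology and outcome. This package stratifies it from bulk RNA-seq into two
expression subtypes — **primitive** (stem-like) and **committed**
(myelomonocytically differentiated) — discovered *independently in each
cohort* and matched *across cohorts without batch correction*, then carries
the subtype onto a cell-line panel to rank drugs by subtype-selective
sensitivity. It is written for computational hematology groups who have
several incompatible expression cohorts and a drug screen, and for anyone
who wants a tested reference implementation of this analysis pattern.

## What it computes

- **Per-cohort consensus clustering.** Resampled K-medoids (100 repetitions
  on 80% of samples and 80% of features, k = 2..8) on the correlation
  distance; a consensus matrix C with `C_ij` = co-clustering frequency;
  final labels from K-medoids on `1 − C`; k chosen by mean silhouette width
  `s(i) = (b−a) / max(a,b)` on the consensus distance.
- **Meta-clustering.** Cluster centroids on the shared gene universe,
  a network with cross-cohort edges weighted by Pearson r (threshold or
  permutation gate), label-propagation communities made deterministic by
  seeded restarts with majority vote, and primitive/committed annotation by
  a stemness-signature score.
- **DE meta-analysis.** Per-cohort Welch effects on the log scale combined
  by fixed-effect inverse variance: `est = Σ w·lfc / Σ w`,
  `se = (Σ w)^{−1/2}`, `w = 1/se_i²`, with BH q-values.
- **Drug prioritization.** Hill dose–response fits
  `y = 1 / (1 + (x/EC50)^H)`, normalized AUC over the tested log10 range
  (`auc_d`, lower = more sensitive), an elastic-net subtype classifier
  (alpha and lambda tuned by stratified 10-fold CV), and per-drug
  concordance index between predicted primitive probability and `auc_d`
  with a permutation p and BH q.
- **Characterization statistics.** Kaplan–Meier curves, log-rank test,
  exact/approximate Wilcoxon rank-sum, Matthews correlation and stepwise
  AUPRC for mutation–subtype association.
- **A simulator with planted truth** (`sim_config()`, `simulate_cohorts()`,
  `simulate_cellline_panel()`, `simulate_survival()`) emulating exactly the
  structure above, so the whole pipeline is testable without
  access-controlled patient data.

## Worked example

```r
library(amlsubtypes)

cfg <- sim_config(n_cohorts = 3, samples_per_cohort = c(50, 60), n_genes = 1000)
sim <- simulate_cohorts(cfg, seed = 7)

res <- discover_subtypes(sim$cohorts, signature = sim$truth$stem_up,
                         pre_cfg = preprocess_config(n_variable_genes = 1000),
                         n_reps = 50, seed = 7)
res$per_cohort[[1]]
#> <ConsensusResult> cohort 'cohort1': chosen k = 2 (silhouette 0.860), 52 samples
table(res$subtypes)
#> committed primitive
#>        82        84

de <- run_de_meta(res$log_matrices, res$subtypes)
head(de[order(de$q), c("gene_id", "meta_estimate", "meta_se", "z", "q")], 3)
#>     gene_id meta_estimate    meta_se         z            q
#> 903   g0903      1.239334 0.09938249  12.47035 1.083521e-32
#> 213   g0213      1.063675 0.08776382  12.11975 4.150746e-31
#> 641   g0641     -1.120610 0.09437971 -11.87342 5.422700e-30

surv <- simulate_survival(sim$truth$subtype, cfg, seed = 7)
logrank_test(surv$time, surv$event, surv$group)
#> log-rank chisq = 21.90, p = 2.87e-06

mutation_subtype_association(sim$metadata, res$assignments)
#>   mutation   n      mcc     auprc
#> 1 FLT3_ITD 166 0.388299 0.6472044
```

Each cohort independently selects k = 2; the meta-clustering matches the
clusters across cohorts into a primitive and a committed group; the top DE
meta-estimates are the planted signature genes at roughly their planted
±1 log2 effect; primitive samples show clearly worse simulated survival;
and the FLT3-ITD-like flag is only weakly associated with the subtype
(MCC ≈ 0.39 here) — mutations do not define these subtypes.

For the transfer arm, see `prioritize_drugs()`: it trains on one cohort,
predicts primitive probabilities for a cell-line panel, fits all Hill
curves, and returns a ranked drug table in which planted subtype-selective
drugs surface at the top with `ci < 0.5` (`sensitive_in_primitive`).

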