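---
title: "Methods: multi-cohort subtype discovery and drug prioritization"
author: "amlsubtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort subtype discovery and drug prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amlsubtypes)
```

## The problem

NPM1-mutated acute myeloid leukemia is formally one WHO entity, but patients
within it differ widely in co-mutations, differentiation state, and outcome.
`amlsubtypes` implements a transcriptome-driven stratification of this group
into a *primitive* (stem-like) and a *committed* (myelomonocytic) expression
subtype, discovered independently in several cohorts and matched across them
without any cross-cohort batch correction, and then carries the subtype onto a
cell-line panel to rank drugs by subtype-selective sensitivity. Because the
patient-level datasets this kind of analysis runs on are access-controlled,
the package ships a fully parameterized simulator with planted ground truth;
every claim the test suite makes is made about that simulator.

## Preprocessing

Counts are filtered per cohort: a gene is removed when its zero-count
fraction is *strictly greater* than 10% of samples (`max_zero_fraction`,
default 0.10). Filtering is per cohort rather than on the cohort union, so a
gene may survive in one cohort and not another; the meta-analysis layer
handles genes present in only a subset of cohorts.

Normalization uses median-of-ratios size factors (per-sample median of
count over gene-wise geometric mean, computed on genes with no zero count),
falling back to library-size factors when fewer than 50 such reference genes
exist, followed by `log2(count / sf + 1)`. This mirrors the count model a
negative-binomial DE engine assumes while keeping the package dependency-free
at this step.

The clustering feature space is not dictated by the upstream analysis
convention, so it is a package decision: the top `n_variable_genes`
(default 5000) by log-scale variance, z-scored per gene within each cohort.
Z-scoring per cohort removes additive per-(cohort, gene) batch shifts
exactly, which is the property the downstream meta-clustering relies on.

## Per-cohort consensus clustering

Each cohort is clustered with resampled K-medoids: 100 repetitions, each on
80% of samples and 80% of features drawn without replacement, at every k
from 2 to 8. The sample-sample distance is 1 minus the Pearson correlation
over the z-scored features — scale-free and standard for expression
subtyping. The K-medoids kernel is the classical alternation (random
medoids, nearest-medoid assignment, medoid recomputation, repeat to
stability), best of 10 seeded restarts; when `choose(n, k) <= 256` every
medoid subset is used as a start instead, which provably returns the exact
optimum and is what makes the small-instance oracle tests sharp.

The consensus matrix entry for a sample pair is the fraction of repetitions
in which the pair co-clustered among those where both were drawn. At the
default settings a pair is co-drawn in about 64% of repetitions, so a
never-co-drawn pair is essentially impossible (p ~ 0.36^100); if it happens
the entry is set to the neutral 0.5 with a warning rather than fabricating
certainty either way.

Final labels at each k come from K-medoids on the consensus distance
`1 - consensus`, and k is chosen by the mean silhouette width *on that same
consensus distance* — model selection scores the consensus structure that
produced the labels, not the raw distance. Exact silhouette ties resolve to
the smallest k, favoring the more parsimonious model.

## Meta-clustering across cohorts

Cluster centroids (mean z-scored profile of members, restricted to the gene
universe shared by all cohorts) are compared across cohorts by Pearson
correlation. Pairs from different cohorts with r at or above
`min_edge_corr` (default 0.5) become weighted edges; same-cohort pairs are
never connected. Communities in this network are found by asynchronous
weighted label propagation. Plain label propagation is visit-order
dependent, so the implementation runs 101 seeded restarts and keeps the most
frequent canonical partition (ties broken lexicographically), making the
result reproducible for a given seed. An optional permutation gate
(shuffling gene labels to get an empirical null for each edge) is available
through the network threshold configuration rather than re-deriving the
original framework's edge-significance machinery, whose details are not part
of this package's contract.

Meta-clusters are annotated by a stemness signature score: the mean over
member centroids of the mean z-score of a user-supplied signature gene set
(the simulator plants one; on real data any leukemia-stem-cell gene list
serves). The higher-scoring of two meta-clusters is `primitive`, the lower
`committed`. This replaces reference-profile cellular deconvolution, which
needs an external sorted-population expression atlas that the package
deliberately does not depend on. With more than two communities, only the
extreme-score pair is labeled and the rest stay `unlabeled` with a warning;
an exact score tie is an error asking for a larger signature.

## Differential expression and meta-analysis

Per cohort, the subtype effect per gene is the difference of group means on
the log-normalized scale with a Welch standard error (zero-variance genes
floored at se = 1e-8 and flagged). This is an explicit substitution for a
negative-binomial GLM engine: the cross-cohort *combination* is the step
this package owns, and it is exact — fixed-effect inverse-variance weights
`w = 1/se^2`, pooled estimate `sum(w * lfc) / sum(w)`, pooled standard error
`sqrt(1 / sum(w))`, two-sided normal p, Benjamini-Hochberg q. Genes missing
from some cohorts are combined over the cohorts that have them, with the
count carried in the output.

## Dose-response and drug ranking

Viability follows the Hill form `y = 1 / (1 + (x / EC50)^H)`; in
log10-concentration space this is a logistic with midpoint `log10(EC50)`.
Replicates are averaged per concentration, viabilities above 1.2 are clipped
with a warning, and the least-squares fit runs over bounded parameters
(`log10(EC50)` within the tested range widened by two decades on each side,
`H` in `[0.1, 10]`), started from a 20 x 20 grid whose best cells are
refined by bounded local optimization — the grid start is what defuses the
Hill fit's well-known multi-modality. Fits explaining less than 5% of the
variance relative to a flat line are flagged `degenerate_flat` with EC50
reported at the boundary on the side the mean viability indicates.

The drug response summary `auc_d` is the area under the *fitted* viability
curve over the tested log10-concentration range, normalized to `[0, 1]`
(closed form of the logistic integral; a trapezoid-on-raw-points mode is
available). Lower `auc_d` means more killing, i.e. more sensitive; this sign
convention is fixed package-wide.

Subtype transfer trains an elastic-net logistic model on one patient cohort
(features z-scored per dataset on the gene intersection with the panel;
constants dropped). Both alpha (0.1 to 1.0 by 0.1) and lambda (a 50-value
path per alpha) are tuned by seeded, class-balanced 10-fold CV on binomial
deviance. Cell lines get a continuous primitive probability, and each drug
is scored by the concordance index between probability and `auc_d` —
`ci < 0.5` means primitive-like lines are more sensitive. Significance is a
two-sided permutation p (1000 seeded shuffles of the probability vector,
with the add-one correction, so p is never below 1/1001), BH-adjusted
across drugs; ranking is by ascending q, then descending `|ci - 0.5|`, then
drug id, so ranks are unique and deterministic.

## Survival and association statistics

Overall survival between subtypes uses the Kaplan-Meier product-limit
estimator and the standard log-rank test (via the survival package). The
Wilcoxon rank-sum test switches from exact enumeration to the
tie-and-continuity-corrected normal approximation at a combined sample size
of 12 or with ties present; the switch point is configurable. Mutation flags
are compared to the subtype per flag with the Matthews correlation
coefficient and with AUPRC treating the flag as a predictor of the primitive
class; AUPRC uses the step-wise (rectangular) rule because published values
differ between interpolation variants, and unassayed samples (blank cells,
never 0) are dropped per flag. A multivariable Cox model is intentionally
out of scope: it is an off-the-shelf fit on the subtype table this package
already emits.

## What the simulator emulates — and what it does not

`sim_config()` defaults are the package's study conditions: 5 cohorts of
60-100 samples, 2000 genes with baseline log2 means Uniform(3, 10), 10%
subtype-informative genes at 1 log2 unit (half up in primitive — the
planted stem signature), negative-binomial counts at dispersion 0.2,
additive per-(cohort, gene) batch shifts of sd 0.3 log2 units, primitive
prevalence 0.45, a FLT3-ITD-like flag hitting an expected MCC of 0.32 with
the subtype at 35% overall frequency, a 60-line panel with 20 drugs of
which 3 shift `auc_d` by -0.25 in primitive-like lines (EC50 moved so the
closed-form AUC drops by exactly that much, active-drug baselines drawn
from the top EC50 decade so the shift never clips), viability noise sd
0.05, survival hazard ratio 2.2 over an exponential baseline with median
730 days, and Uniform censoring calibrated to 20%.

Batch shifts are additive per (cohort, gene) precisely so that naive
pooling of cohorts would be confounded — the condition meta-clustering
exists to handle. The simulator does *not* emulate gene-gene correlation
structure, library-size gradients within a cohort, subtype-mixture
continua, assay plate effects, or partially overlapping gene panels, so
passing recovery tests demonstrate correctness of the machinery under the
stated generative model, not clinical performance on real cohorts.

## Numerical choices and problem sizes

All randomness flows from one user seed through deterministic substreams
(an integer hash per component), so cohort simulation, resampling,
restarts, folds, and permutations are independently reproducible. The
K-medoids kernel carries its own xorshift RNG to be platform-stable. The
test suite exercises the full default scenario over 20 seeds for subtype
recovery and drug ranking, 20 + 10 seeds for meta-analysis calibration and
power (1000 genes), and 20 + 40 seeds for survival power and size
(n = 150); unit tests use smaller fixtures with exact hand-computed or
enumerated oracles.

## Known limitations

Welch-on-log effects are less efficient than a dispersion-shrinking count
model at very small n (the package requires at least 3 samples per subtype
per cohort and is designed for tens). Label propagation on very sparse
networks can fragment; isolated centroids become singleton communities with
a warning rather than being force-merged. The elastic-net transfer assumes
the panel shares enough non-constant genes with the training cohort (at
least 50). The Hill model is the two-parameter unit-interval form; screens
with partial maximal effect need the four-parameter variant this package
deliberately omits.
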