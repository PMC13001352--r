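---
title: "acuteomix: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{acuteomix: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`acuteomix` implements the analysis path of an acute-exercise multi-omics
study in human skeletal muscle: participants randomized to non-exercise
control (CON), endurance (EE) or resistance (RE) exercise in a 3:8:8 ratio,
biopsied before exercise and at 15 minutes, 3.5 hours and/or 24 hours
afterwards according to a randomized timepoint arm (Early / Middle / Late /
All). Five omes are handled — RNA-seq counts, ATAC-seq peak counts, protein
and phosphosite log-ratios, metabolite abundances — through preprocessing,
difference-in-changes mixed models, enrichment statistics, cross-omic
latent variables, phospho-TF regulatory network inference, nearest-neighbor
phosphosite analysis and CpG region merging. Everything upstream of a
feature-by-sample matrix (alignment, peak calling, MS searching, drift
correction) is out of scope, as is differential methylation model fitting,
which real pipelines delegate to an external tool.

# The difference-in-changes model

Each feature is fit with a cell-means linear mixed model: one fixed mean
per group-by-timepoint cell, covariates (sex, age, batch by default;
configurable because the original covariate selection lives outside this
package's sources), and a participant random intercept. The inferential
quantity is the difference in changes,

$$\hat\delta = (\mu_{g,t} - \mu_{g,\text{pre}}) -
               (\mu_{\text{CON},t} - \mu_{\text{CON},\text{pre}}),$$

for exercise group $g$ at post timepoint $t$, which removes time-of-day,
fasting and biopsy effects captured by the control arm.

Implementation choices worth knowing:

* **REML engine.** The variance ratio $\lambda = \sigma^2_a/\sigma^2_e$ is
  profiled by one-dimensional optimization; per-participant blocks give a
  Sherman–Morrison closed form for $V^{-1}$, so 2,000-feature runs take
  seconds. At the $\lambda = 0$ boundary the fit collapses to (weighted)
  least squares. The reference analysis delegates to an external mixed-model
  package whose internals are not restated anywhere we could consult, so
  this engine is validated against a dense-matrix profiled-likelihood grid
  search in the tests rather than against that package.
* **Degrees of freedom.** Contrast t statistics use the fixed-effect
  residual df ($n - p$), a deliberately conservative choice; matching an
  external package's Satterthwaite-style df is not attempted.
* **Count omes.** RNA and ATAC counts get TMM scaling factors (30% M-trim,
  5% A-trim, precision-weighted, geometric-mean centered), log2-CPM with a
  0.5 offset (the standard voom convention; the offset is not stated in the
  sources and 0.5 is the field default), and precision weights from a
  lowess smooth of $\sqrt{\text{residual SD}}$ against mean log count.
* **Moderation.** Residual variances are shrunk toward a scaled
  inverse-$\chi^2$ prior fitted by moment matching of log variances
  (digamma/trigamma equations). When the observed spread of log variances
  does not exceed chi-square sampling noise the prior df is infinite and the
  common variance is estimated by the mean, so constant inputs pass through
  unchanged. BH runs separately within each (ome, contrast) stratum;
  significance is adjusted p < 0.05.
* **Eligibility.** A feature enters the analysis only if at least 3
  participants have paired pre/post observations in every group at every
  post timepoint present in the design; failures anywhere exclude the
  feature entirely.

# Preprocessing rules

Filters are applied literally as stated for each ome: RNA genes are removed
when they have 0.5 or fewer CPM in at least 10% of samples; ATAC peaks are
kept with at least 10 reads in at least 6 samples; proteomics features
(including phosphosites) are removed below 30% quantification; metabolites
are removed above 20% missingness.

The RNA sentence as printed is, we believe, ambiguous: read literally it
removes a gene as soon as 10% of samples are weakly expressed, which on
sparse data removes almost everything. Both readings ship
(`filter_rule("rna", reading = "literal")` is the default;
`"keep_expressed"` keeps genes with CPM > 0.5 in more than 10% of samples),
and the rule parameters are configurable.

Metabolite imputation is KNN over features when more than 12 features are
present, otherwise half-minimum. Metabolite normalization is log2(x+1) —
the +1 keeps values in (0,1) positive — followed by median-MAD scaling only
when neither sample medians nor upper quartiles associate with sex or group
(Kruskal–Wallis p < 0.01); the MAD constant 1.4826 (normal consistency) is
used because no constant is stated. PCA outlier flagging extends boxplot
whiskers to 5 interquartile ranges on the retained components; the number
of components examined ("top components") is unstated, so we default to
those explaining 95% of variance, capped at 10. Batch residualization fits
each feature on the column-bound protected design (group-by-timepoint cell
means, sex, age) and technical covariates, and subtracts only the technical
component.

# Enrichment statistics

Moderated t statistics become z-scores through a sign-preserving normal
quantile transform of the t CDF (computed on the log scale in the tails);
multiple features per gene collapse to the entry of maximum absolute value,
with ties broken toward the first feature in sorted id order so the matrix
is reproducible. Multi-site phosphosite ids (`protein_S1;S2`) split into
single sites carrying identical statistics, deduplicated by maximum
absolute value.

* **CAMERA-PR** uses the standardized set-mean difference with variance
  inflation $1 + (m-1)\rho$; $\rho = 0.01$ is the conventional preranked
  default (the sources state none). At $\rho = 0$ the statistic reduces
  exactly to a two-sample equal-variance t-test, which is the oracle used
  in the tests. Kinase collections are flagged at adjusted p < 0.10, all
  others at < 0.05.
* **ORA** is the one-sided hypergeometric tail.
* **PTM-SEA** ranks sites by signed statistic with members of "down"
  signatures sign-flipped first, accumulates an unweighted running sum
  (+1/m at members, −1/(G−m) elsewhere), and scores the mean of the running
  statistic over all positions (the area statistic). NES divides by the
  mean |ES| of same-sign permutation scores; p is the smoothed same-sign
  tail over 1,000 feature-label permutations; signatures with fewer than 5
  matched sites are skipped. The external implementation's exact NES
  normalization and directional-set handling are not restated in our
  sources; the directional sign-flip here is an explicit approximation,
  and parity with that implementation is not claimed. Only sites with
  localization confidence above 17 enter the analysis.
* Collection filtering: sets need at least 5 surviving members after
  intersection with the universe, and gene sets (only) must retain at
  least 70% of their original members.

# Cross-omic latent variables

For the ATAC–RNA–protein decomposition, rows are proteins present in all
three omes whose gene has at least one annotated promoter peak
("Promoter (<=1kb)"); the ATAC row is the **cumulative** (summed) promoter
accessibility, read literally from "cumulative"; a mean is available via
`cumulative = "mean"`. Promoter scores use log-CPM values (counts vs
quantile-normalized values being unstated, log-CPM is the package's
choice). The RNA–phospho variant sums site-level values per protein over
all sites passing the localization filter. Each ome block is row z-scored
and the blocks concatenated column-wise.

The decomposition minimizes
$\|Y - ZB\|^2 + \lambda_1\|Z - CU\|^2 + \lambda_2\|B\|^2 + \lambda_3|U|_1$
with $U \ge 0$, by exact ridge updates for $Z$ and $B$ and nonnegative
lasso coordinate descent for $U$; every outer iteration is a block-exact
minimization, so the objective is non-increasing by construction and the
tests assert it. Penalties default to $0.1 \times$ the mean singular value
of $Y$ (none are stated). The LV count is twice the number of significant
principal components, counted by parallel analysis (20 seeded column
permutations, 95th percentile) because the external heuristic is not
restated; infeasible estimation falls back to 100 LVs. After convergence,
loadings are normalized to unit columns with compensating scaling of the
scores — pure identifiability cosmetics applied once, outside the monotone
loop. LV significance compares within-subject post-minus-pre score deltas
between each exercise group and CON by Welch's t-test (the sources name
only a generic comparison function), with BH across the full grid.

# Regulatory networks

Regulators are phosphosites on transcription factors with at most 40%
missingness, completed by a compact chained-equations imputation (each
incomplete site regressed on its most correlated sites, with Gaussian
residual draws) run 15 times with seeds 1..15 and averaged. Features are
clustered by fuzzy c-means after scaling rows by standard deviations
computed with two appended zero columns (the implicit pre-exercise
baseline); the fuzzifier comes from the closed-form estimator
$m = 1 + (1418/N + 22.05)D^{-2} + (12.33/N + 0.243)
D^{-0.0406\ln N - 0.1134}$, and the cluster count is chosen by the minimum
centroid distance validity index.

Edge inference regresses each differentially abundant transcript on its
co-clustered regulator sites (falling back to all regulators when none
co-cluster — the restriction rule is this package's reading of "clustering
prior to inferring the network", and the fallback prevents orphan targets)
with extremely randomized regression trees; the edge weight is the
normalized impurity importance (fraction of target variance attributed to
the regulator), with sites on the target's own gene excluded. Permutation
trimming shuffles the regulator sample columns relative to the targets —
preserving within-matrix structure, which the sources' phrasing leaves
open — re-runs inference 100 times, pools the null weights, and keeps
edges with BH-adjusted permutation p < 0.05 **and** weight > 0.1.

Circuit linking is declared a simplified stand-in for a Bayesian
cis-regulatory sampler: candidates are (TF, peak, gene) triplets with a
differential peak (raw p < 0.005), differential gene (adjusted p < 0.05),
peak center within ±100 kb of the TSS and the TF motif in the peak; the
statistic is the product of peak–gene and TF-activity–peak correlations
with a 1,000-fold sample-permutation null. The TF activity proxy is the TF
transcript by default (phosphosite mean optional). Networks integrate as a
multiset union — an edge found by both routes appears twice, with
provenance labels preserved.

The Network Motif Score sums, over feed-forward loop, diamond and 3-chain
motifs, each node's min-max-normalized instance count; a motif type with
constant counts contributes zero. The original score's formula is
attributed to prior work and not restated in our sources, so this
definition is the package's own; raw counts are always exported so other
weightings can be applied. Counting uses adjacency-matrix algebra and is
verified against exhaustive enumeration on all test graphs.

# Nearest-neighbor phosphosites

A site's profile is its six delta-delta estimates in the fixed order
EE-15min, EE-3.5h, EE-24h, RE-15min, RE-3.5h, RE-24h (both modalities
concatenated; per-modality correlation is available but the concatenated
form is the default reading of "across the time points for EE and RE").
Neighbors of an anchor satisfy pairwise-complete Pearson r ≥ 0.8 over at
least 3 shared cells (missing-cell handling is unstated; 3 is the minimum
that leaves a df) and are differentially abundant at one or more cells.
Protein-level ORA reports sets with at least 5 contributing proteins at
adjusted p < 0.05.

# CpG region merging

Sites need 5x coverage in at least half the samples (a site at exactly 50%
is kept). Merging follows the four-step algorithm: per-sample nCpG10;
samples below the 20th percentile excluded from clustering; MCL on the
graph of sites with 10x coverage in all remaining samples, edges within
the merge window weighted by the Pearson correlation of methylation
fractions (fractions, not coverages — correlating coverage would capture
depth, not co-methylation; negative correlations are zeroed because
merging captures co-methylation, not anti-methylation); assignments then
applied to all samples. The proximity window is never defined in our
sources; the package defaults to 1,000 bp and logs it in the output. MCL
uses inflation 2, expansion 2, pruning 1e-5 (standard defaults, none
stated); self-loops are set to each node's maximum incident weight so the
clustering is invariant to uniform rescaling of the weights. Clusters are
split into runs of consecutive sites so every region is contiguous in the
site ordering, and every site lands in exactly one region.

# The synthetic cohort

The generator states the world the pipeline assumes rather than emulating
any particular dataset: 174 participants by default, allocated 3:8:8 by
largest-remainder rounding (realized counts can be supplied directly);
timepoint arms equiprobable because the original arm allocation is not
published; sex 72% female, age ~N(41, 15) truncated to 18–70, randomized
processing batches of 20 (randomized so batch never aliases group — an
ordered assignment would make the cell-means model singular). Counts are
negative binomial (dispersion 0.1) with a per-feature participant random
intercept of SD 0.3 log2 units; continuous omes are Gaussian on the log2
scale with per-feature SDs drawn log-normal (median 0.5); these generative
values are free choices — no generative model is published — picked so
that variance moderation and precision weights have something real to do.
Injected effects are pure group-by-timepoint shifts, so CON's expected
change from pre is exactly zero and the delta-delta estimand equals the
injected value. Planted regulatory edges couple target transcripts to
standardized regulator phosphosite values (coefficient 0.8); planted
circuits couple peaks to the TF site the same way. Missingness is MCAR by
default with an optional left-censored mode for intensity-dependent
dropout.

What a green test does and does not establish: the generator has no
library-size gradients, GC or length biases, batch-by-feature
interactions, correlated missingness across omes, or realistic pathway
overlap structure, so passing recovery tests certifies the statistical
machinery under its own assumptions — not performance on real data.
Feature counts in tests are hundreds to a few thousand (not 20,000); the
acceptance suite says so where it scales a stated replicate count down.

# Numerical notes

Seeds: every stochastic routine takes a seed and derives sub-stream seeds
below $2^{31}$; identical (config, seed) pairs give bit-identical bundles.
The REML search runs over $\log\lambda \in [\log 10^{-6}, \log 10^{3}]$
with an explicit boundary check at 0. The z transform uses log-scale tail
probabilities to stay finite at |t| ≈ 50. FCM distances are floored at
1e-12; MCL prunes below 1e-5 and declares convergence below 1e-6 with a
best-iterate warning at 200 iterations. Ties in the z-matrix collapse and
in largest-remainder rounding are broken by sorted order, never at random.
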