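---
title: "Methods: association networks and differential connectivity for serum metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association networks and differential connectivity for serum metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabnet)
```

## Scope and model

metabnet analyses targeted serum metabolomics cohorts in which samples fall
into a small number of clinical groups (the shipped defaults use CRC —
colorectal cancer, PP — polyposis, and CTR — healthy controls). The input is
a samples × metabolites matrix of non-negative MS peak intensities with
per-sample group labels. The pipeline has two complementary arms:

* an **abundance arm** — per-metabolite two-group Student's t-tests with
  Benjamini–Hochberg (BH) control, and resampled random-forest
  classification — asking *which metabolites change in level* and *how well
  the profiles separate the groups*; and
* a **network arm** — PCLRC association-network inference per group,
  permutation-based differential connectivity, topology comparison, and
  pathway over-representation — asking *how the correlation structure among
  metabolites is rewired* between groups, which can change even when no
  single metabolite shifts in mean.

## Preprocessing

**Outlier screening.** Samples are projected on the first two principal
components of the unit-variance-scaled, pooled-group matrix, and a sample is
removed when its Mahalanobis distance from the score centroid exceeds the
Hotelling cutoff `2(n−1)/(n−2) · F₀.₉₅(2, n−2)` — the standard 95%
confidence ellipse for two estimated components. Screening runs once; it is
not re-fit after removal, so a masked second-tier outlier is deliberately
retained rather than chased iteratively. At `confidence = 1` the cutoff is
infinite and nothing is flagged.

**Normalisation.** Each metabolite is mapped through the rank-based inverse
normal (Blom) transform `qnorm((rank − k)/(n − 2k + 1))` with offset
`k = 3/8` and average ranks for ties. Because the transform is monotone in
ranks, every Spearman correlation — and hence the whole network arm — is
invariant under it; its role is to tame the heavy right tails for PCA and
classification. The t-tests instead use square-root-transformed raw
intensities (the usual variance stabiliser for count-like MS intensities).
Whether univariate testing should run on square-root, inverse-normal, or
square-root-then-inverse-normal data is genuinely ambiguous in practice; the
package defaults to `sqrt_raw` and exposes `univariate_input` in
`pipeline_config()` (note that `sqrt_int` is identical to `int` up to the
rank invariance of the transform).

**Missing values** are kept as explicit `NA` on input and imputed as half
the minimum positive value of the metabolite (the common
limit-of-detection convention); a metabolite missing in more than 20% of any
group is rejected because imputation would dominate that group.

## PCLRC network inference

For one group with `n` samples, `pclrc_infer()` repeats `n_iterations`
times (default 1000):

1. draw `⌊0.75 n⌋` samples without replacement;
2. compute the Spearman correlation matrix of the subsample and square it
   (so strong negative associations count as strong associations; the sign
   is restored from the full-data correlation when reporting);
3. apply the CLR (context likelihood of relatedness) background filter:
   `z_{i|j} = (M_ij − mean(M_i·))/sd(M_i·)` over row `i` excluding the
   diagonal, combined as `sqrt(max(0,z_{i|j})² + max(0,z_{j|i})²)` — an edge
   scores high only when it stands out from the typical association level
   of *both* endpoints;
4. mark the top 30% (`retention_quantile`) of the strictly positive CLR
   scores as kept.

The edge probability `p_ij` is the fraction of rounds in which edge
`(i, j)` was kept. Defaults (1000 iterations, 0.75 fraction, 0.30 retention,
`p ≥ 0.95`) follow the reference implementation of the method. Figure-style
networks additionally require `|r_ij| ≥ 0.6` on the full-data Spearman
correlation; connectivity statistics (below) deliberately do **not** apply
these thresholds — the displayed network answers "which individual
associations are strong and reliable", the connectivity profile answers
"how strongly is this metabolite embedded overall", and thresholding the
latter would create cliff artifacts.

The Monte-Carlo error of `p_ij` shrinks as `1/sqrt(n_iterations)`;
with `subsample_fraction = 1` the procedure degenerates to a deterministic
binary mask (the top quantile of the full-data CLR scores), which the tests
pin against an independent pure-R implementation.

## Differential connectivity

The connectivity of metabolite `i` in one group is the probability-weighted
absolute strength `C_i = Σ_j p_ij |r_ij|`; it reduces to a weighted degree
when `P` is binary. `differential_connectivity()` compares
`Δ_i = C_i(a) − C_i(b)` against a permutation null: group labels are
shuffled among the pooled samples (preserving group sizes) and both
connectivity profiles are recomputed per permutation with PCLRC at a
reduced iteration count (default 100 — the tractability knob; each
permutation refits two networks). p-values are two-sided and BH-adjusted;
`q ≤ 0.05` flags a metabolite.

Two nulls are provided. The default `"pooled"` null compares `|Δ_i|` with
the permuted `|Δ|` values of *all* metabolites jointly. The per-metabolite
alternative uses only metabolite `i`'s own permuted values; it makes no
exchangeability assumption, but its p-values cannot fall below
`1/(n_perm + 1)`, and with a small number of truly rewired metabolites
among ~100, BH then needs p-values far below that floor unless thousands of
permutations are run. Pooling — as in classic permutation-based omics
procedures — restores resolution at 100 permutations while remaining valid
when the null connectivity deltas are exchangeable across metabolites,
which holds by construction for the synthetic cohorts and approximately for
rank-based connectivity on real data. Per-permutation seeds are derived
deterministically from the master seed, so swapping the two groups exactly
negates every `Δ_i` and leaves every p-value unchanged.

## Classification

Pairwise random forests are fitted on `k = 100` stratified resamplings
retaining 85% of each group for training, with standard forest defaults
(500 trees, `mtry = ⌊sqrt(p)⌋`). Evaluation uses the held-out 15%
(`eval = "holdout"`); out-of-bag scoring is available. Accuracy,
sensitivity and specificity use the first group of the pair as the positive
class; AUROC is the rank (Mann–Whitney) statistic on case-class
probabilities. Summaries are arithmetic means with 2.5/97.5-percentile
intervals over the `k` resamplings. Model significance is a label
permutation test with 1000 permutations at the paper scale; the observed
statistic is recomputed at the same (possibly reduced) `k` as the permuted
ones so that both are exchangeable, and one p-value per metric is reported,
`p = (1 + #{perm ≥ obs})/(1 + n_perm)`. Per-metabolite importance p-values
come from the same permuted fits with BH adjustment.

## Topology metrics

`node_topology()` computes the ten standard per-node measures of the
unweighted thresholded graph (degree, average shortest path length,
betweenness, closeness, clustering coefficient, eccentricity, neighborhood
connectivity, radiality, stress, topological coefficient). Conventions are
pinned in the tests so cross-implementation drift is caught: betweenness is
normalised by `(n_c−1)(n_c−2)/2` within each connected component; closeness
is the reciprocal mean distance to reachable nodes; isolated nodes get 0
for closeness, eccentricity, clustering, average path length and radiality
(the latter two are not defined for singleton components; 0 keeps the
metric table fully numeric for downstream PCA); nodes with fewer than two
neighbours get topological coefficient 0. Edge weights influence network
construction only, never path lengths.

`topology_pca()` compares networks by stacking the (network, node) rows of
several metric tables, unit-variance scaling the columns, and projecting on
two principal components; the distance between network centroids summarises
separation. Treating dots as (network, node) observations is an
interpretation choice — three networks alone cannot support a
ten-loading PCA — and per-network mean aggregation is available via
`aggregate = "network"`.

## Pathway over-representation

For a query of differentially connected metabolites, each pathway with `K`
members in a universe of `N` library compounds is scored with the
hypergeometric upper tail `P(X ≥ k)` for `k` matched members of `n`
universe-matched query compounds, BH-adjusted across pathways. The impact
score is the matched fraction of the pathway's compound-importance mass
(`Σ importance(matched) / Σ importance(all)`); pathways with impact ≤ 0.01
are dropped. When the library carries no importance column every compound
weighs 1 and impact reduces to `k/K`. Name matching is exact after
canonicalization (lowercase, punctuation stripped) plus an optional
synonyms table — deliberately no fuzzy matching. The shipped library
(`inst/extdata/synthetic_pathways.tsv`) is synthetic, built over the
simulated metabolite namespace so that the full pipeline can run
end-to-end; real analyses should supply a curated (e.g. KEGG-derived)
library, whose content is versioned and licensed and therefore not bundled.

## The synthetic cohort generator

`simulate_abundance()` draws, per group, a latent Gaussian matrix with
block-structured correlation — within a block every metabolite is
`sqrt(ρ)·factor + sqrt(1−ρ)·noise`, giving exact pairwise latent
correlation ρ — adds mean shifts `δ` (in latent SD units) for selected
metabolites, adds a per-metabolite baseline log-abundance shared across
groups, and exponentiates. The latent-Gaussian-copula-with-`exp` choice is
deliberate: all association estimation downstream is Spearman, which is
invariant under the monotone marginal transform, so a planted latent ρ
corresponds to a population Spearman of `(6/π)·asin(ρ/2)` (≈ 0.786 for
ρ = 0.8) regardless of the marginal skew. Differential connectivity is
planted by block *rewiring*, and mean effects by `δ` shifts, so network
and univariate signals can be switched on independently — mirroring
cohorts in which two groups differ in correlation structure but not in
any single metabolite's level.

The shipped `serum_cohort_design()` fixes the study conditions: 100
metabolites; post-QC group sizes 65 (CRC), 74 (PP), 87 (CTR); two
correlation blocks common to all groups (ρ = 0.7 and 0.6); an 8-metabolite
ρ = 0.8 block present only in CRC; a 6-metabolite ρ = 0.65 block present
only in PP; and a 1-SD latent mean shift on 10 metabolites in CRC.
`differential_nodes()` reads the ground truth straight off the design.

What the generator does **not** emulate: detector saturation, batch and
run-order effects, heteroscedastic measurement noise, missing-not-at-random
censoring at the detection limit, and metabolite-identity-specific
behaviour. Passing tests therefore demonstrate statistical correctness and
calibration of the machinery under a clean copula model, not robustness to
every artifact of real LC-MS/MS data.

## Numerical choices and problem sizes

* Spearman matrices use average ranks; constant columns correlate 0 with a
  warning rather than `NA`.
* CLR rows with zero standard deviation contribute 0; retained edges per
  PCLRC round are the top `⌈0.30 · #positive⌉` CLR scores, ties at the
  cutoff all kept.
* Zero pooled variance in a t-test yields `p = 1` with a warning, never
  `NaN`.
* All randomness flows from explicit integer seeds; child seeds for
  resampling rounds and permutations are derived deterministically from the
  master seed, so every result object and pipeline run is bit-reproducible.
* The test suite and the acceptance script run the stochastic stages at
  reduced sizes chosen once as realistic desk-scale settings: PCLRC
  calibration at 100 iterations on 80-sample groups; differential
  connectivity recovery on 65 + 87 samples × 100 metabolites with 100
  iterations and 100 permutations over 10 seeds; null calibration on
  60 + 60 × 60 over 20 trials; random-forest checks at k = 20 resamplings
  (k = 2 within the 1000-fold permutation test). Paper-scale settings
  (1000 iterations, 1000 permutations, k = 100) remain the package
  defaults.

## Known limitations

* The pooled permutation null assumes exchangeability of connectivity
  deltas across metabolites under the null; strongly heterogeneous
  per-metabolite null variances would make it conservative for stable
  metabolites and liberal for volatile ones — the per-metabolite null is
  the safe (but permutation-hungry) alternative.
* Permutation PCLRC runs at reduced iteration counts by default; the
  resulting extra Monte-Carlo noise inflates the null slightly and makes
  the test mildly conservative.
* The mwTab reader targets the flat `MS_METABOLITE_DATA` export layout
  only; it is not a general mwTab parser.
* Hypergeometric enrichment inherits every limitation of the supplied
  library: universe definition, compound naming, and importance weights
  dominate the results, so impact scores are comparable only within one
  library version.
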