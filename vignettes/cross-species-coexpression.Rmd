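---
title: "Cross-species weighted co-expression analysis with xwgcna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species weighted co-expression analysis with xwgcna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xwgcna)
```

## The analysis

`xwgcna` implements a cross-species weighted gene co-expression workflow:
two species' expression meta-sets are harmonized onto a shared ortholog
index, a weighted co-expression network is built for each species and for
their consensus, modules are detected and summarized by eigengenes, and two
complementary questions are asked of the pair of networks:

1. **Module preservation** — is a module found in the reference species
   still a densely interconnected unit in the other species?  Answered by
   permutation Z statistics combined as
   `Z_summary = (Z_density + Z_connectivity) / 2`, with `Z_summary > 10`
   read as high preservation, `5 < Z_summary < 10` as moderate, and a
   random "gold" sham module as the negative control.
2. **Eigengene-network preservation** — is the *correlation structure
   between modules* conserved?  Answered by the pairwise preservation
   adjacency `Preserv_IJ = 1 - |cor_A(E_I, E_J) - cor_B(E_I, E_J)| / 2`,
   its per-module scaled connectivity `C_I`, and the overall density `D`
   (the mean of `C_I`; 1 = perfect conservation), plus meta-modules
   (clusters of positively correlated eigengenes).

Finally, module gene sets are handed to a nearest-shrunken-centroid
classifier to extract a minimal signature separating two sample classes,
with 10-fold cross-validated shrinkage selection and AUROC evaluation over
repeated randomized train/test splits.

## Preprocessing model

Meta-sets are assembled in a fixed order: probe rows are collapsed to one
row per gene by the maximum-mean rule (ties broken by the
lexicographically smallest probe identifier, for determinism); each study
is standardized gene-wise to mean 0, sd 1 (denominator n − 1) and studies
are then column-concatenated; gene universes are intersected; the second
species is relabeled with its one-to-one orthologs (ambiguous mappings are
dropped — no confidence-based resolution is attempted); genes with global
variance below 0.3 are removed last.  Standardizing *within* each study is
what removes additive per-study batch offsets; standardizing the
concatenated meta-set instead would leave them in place, and a regression
test asserts this ordering.

## Network model and its parameters

* **Adjacency** `a_ij = |cor(x_i, x_j)|^β` (unsigned, the default; a
  signed variant `((1 + cor)/2)^β` is available via `signed = TRUE`), with
  β = 7 as the default soft threshold.  Unsigned correlation is used
  because it is the historical default of the framework this package
  follows; the choice is exposed, not hard-coded.
* **Topological overlap** `ω_ij = (ℓ_ij + a_ij)/(min(k_i, k_j) + 1 −
  a_ij)`; `1 − ω` is the clustering dissimilarity.
* **Consensus**: the weighted average (default 0.5/0.5) of the two
  species' correlation matrices, then the same adjacency/TOM/clustering
  machinery with the same parameters as single-species networks.  The
  averaging weights are exposed because no principled default beyond
  equality exists.

### Module detection

Modules are branches of the average-linkage dendrogram of `1 − TOM`,
selected by an adaptive pruning rule designed for this package: a branch
is accepted as a module when the ratio of its mean internal dissimilarity
to its mean dissimilarity to everything else is at most
`0.85 + 0.02 · deepSplit` (deepSplit 0–4, default 1), unless its two
children are themselves mutually distinct by the same ratio, in which case
the search descends.  Accepted branches are trimmed gene-wise: a member
whose mean within-branch dissimilarity exceeds 0.95 of its dissimilarity
to the branch's complement is released to `"unassigned"`.  Branches that
never qualify fragment until they drop below the minimum module size
(default 30) and are labeled `"unassigned"`.  The ratio criterion is
scale-free in the dissimilarity, so it behaves consistently across β and
correlation strengths; the trim ratio 0.95 only has to separate members
(ratio well below 1) from stragglers (ratio ≈ 1) and is deliberately
lenient.  The procedure is deterministic.

Modules whose eigengenes are closer than `cutHeight = 0.25` (on `1 −
cor`) are merged iteratively, recomputing eigengenes after each pass; in
consensus mode the merge distance is the weighted average of the two
species' eigengene correlations, consistent with the consensus
correlation.

### Eigengenes

A module eigengene is the first right-singular vector of the module's
row-standardized genes × samples block, oriented so that it correlates
nonnegatively with the module's mean standardized profile (the sign of a
singular vector is arbitrary; fixing it makes runs comparable).  Module
membership (kME) is the Pearson correlation of a gene with an eigengene.
Module–trait association uses Pearson correlation against binary
membership codes with asymptotic t p-values (n − 2 df); group differences
in eigengene expression use the tie-corrected Kruskal–Wallis test; sample
regrouping uses classical MDS on Euclidean distances with k-means (fixed
seed, 25 restarts) on the first two coordinates.  Euclidean distance was
chosen for the MDS step (a correlation distance is equally defensible;
the choice is config-level, not baked into other stages).

## Preservation statistics

For each reference module the package computes, in the test data: two
density statistics (mean within-module correlation, mean within-module
adjacency) and two connectivity statistics (the cross-set correlations of
intramodular connectivity kIM, and of module membership kME, over the
module's genes).  The null distribution permutes module labels across
genes in the test network — i.e. re-draws gene sets of the same size —
and each observed statistic becomes `Z = (obs − mean_perm)/sd_perm`.
`Z_density` and `Z_connectivity` are the medians within each family,
`Z_summary` their mean, and the summary p-value is the median of the
log10 empirical upper-tail p-values (`+1` smoothing in numerator and
denominator avoids log 0).  The default of 200 permutations keeps the
Monte-Carlo error on `Z` below about 5% of its value.

This is a deliberately minimal roster — two density and two connectivity
statistics — rather than the full published collection of preservation
measures; the composite only requires a median within each family.  One
empirical caveat worth knowing: with strong globally-shared structure,
permuted gene sets mix genes from several preserved modules and inherit
part of their cross-species connectivity agreement, so `Z_connectivity`
is conservative (it can sit near or below zero even for well-preserved
modules) and `Z_summary` is carried mostly by density on such data.  The
gold module — a uniform random gene set, default 100 genes — sits at
`Z_summary ≈ 0` by construction and anchors the scale.

## The synthetic generator

The generator emulates the structure of a merged two-species microarray
compendium: per species, a genes × samples matrix split into studies with
additive per-study, per-gene batch offsets (sd `batch_shift_sd`); a
one-to-one ortholog subset shared between species; planted modules from a
single-factor model; binary traits tied to module activity; and a
two-class (healthy/disease) labeled cohort.

Gene g of module m is `x_g = r_g f_m + noise_sd · sqrt(1 − r_g²) · ε`, so
at `noise_sd = 1` the population correlation of two member genes is
exactly `r_g r_h`.  The factor correlations `r_g = sqrt(ρ) v_g` use
mean-one multipliers `v_g` spread over the widest interval compatible
with the mean pairwise correlation equalling the design's
`within_module_correlation` ρ — this plants a *hub gradient* (kIM and kME
vary systematically across member genes), which real modules always have
and which the preservation connectivity statistics require to be
meaningful.  Shared modules reuse the same loadings on ortholog-matched
genes in both species; the factor *realizations* are drawn per species
because the two species have disjoint samples — preservation statistics
depend only on within-species correlation structure, which this
preserves.  Species-specific modules are planted outside the ortholog
subset, so the consensus network has clean negatives.

Each trait link flags a random half of the samples and shifts the linked
module's factor by `effect` for them; one designated marker gene of the
module additionally receives the same shift directly, creating an
unambiguous strongest classifier gene (recorded in `truth$markers`).  The
default design — 700 genes per species, 400 orthologs, two shared and one
species-specific module of 80 genes at ρ = 0.8, two studies of 30 samples
per species, batch sd 0.5, one disease trait with effect 1.5 — is sized
so that a full run takes seconds while every downstream stage operates in
its intended regime.  Trait effects default to 1.5 sd; no claim is made
that this matches any particular study, and it is config-exposed.

What the generator does *not* emulate: probe-level intensity
distributions, array spatial artifacts, heavy-tailed or heteroskedastic
noise, overlapping modules, and correlated background genes.  Passing
tests therefore demonstrate correctness of the machinery under a clean
factor model, not performance on any real compendium.

## Classification

The nearest-shrunken-centroid model follows the canonical formulation:
standardized centroid differences `d_ik = (x̄_ik − x̄_i)/(m_k(s_i + s_0))`
with `m_k = sqrt(1/n_k − 1/n)` and `s_0 = median(s_i)`, soft-thresholded
by Δ; the heterogeneity penalty of some variants is omitted.  Δ is chosen
by stratified 10-fold cross-validation as the *largest* Δ achieving the
minimal CV error (the most parsimonious signature; ties must be broken
somehow and parsimony is the sensible direction).  Evaluation repeats a
stratified 75/25 train/test split (fraction config-exposed) ten times;
each split reports the test AUROC and the gene ranking by largest
absolute shrunken difference.  ROC curves sweep score thresholds with
tied scores stepping diagonally, so the trapezoidal AUROC equals the
Mann–Whitney U statistic divided by `n₁n₀` exactly.  The discriminant
score is oriented so that a lower discriminant for the positive class
(the second factor level) yields a higher score.

## Numerical and degenerate-input choices

* Variances and standard deviations use denominator n − 1 throughout.
* A gene constant within a study is zeroed there (with a warning) rather
  than propagating NaN; constant genes are rejected at network build time
  with the offending gene named.
* Modules with fewer than 3 genes are skipped by preservation (a
  correlation of two connectivity values is meaningless); a permutation
  sd of 0 yields `NA` rather than an infinite Z.
* Single-gene modules get their standardized gene as eigengene, with a
  warning.
* The printed preservation band inequality is read as `5 < Z < 10` for
  moderate preservation, consistent with `Z > 10` meaning high.
* Ten-fold CV requires every class to have at least `k` samples so each
  fold contains both classes; `k = n` is treated as leave-one-out, where
  stratification is impossible by definition.
* All stochastic steps (generator, permutations, fold and split
  assignment, k-means restarts, gold sampling) are driven by explicit
  seeds; `run_pipeline()` fans a single global seed out to fixed
  per-stage seeds.

## Problem sizes used in validation

The bundled tests and the acceptance script run the default design (700
genes, 60 samples per species) for recovery, preservation (200
permutations; 20 replicate seeds for the gold-module calibration) and
classification, and scaled-down designs (200–400 genes, 40 samples) for
unit-level checks.  These sizes were chosen as the smallest at which each
stage operates away from its detection threshold; the machinery itself
has no special-casing by size and has been exercised up to a few thousand
genes, matching the intended desk scale of roughly ≤ 6000 genes.

## Known limitations

* The branch-pruning module detector is this package's own algorithm; it
  shares the spirit of dynamic dendrogram cutting but not its exact
  output, and deepSplit values are not numerically comparable to other
  implementations.
* Consensus TOM is computed from the consensus *correlation* matrix;
  consensus-of-TOMs is a defensible alternative reading and is not
  implemented.
* `Z_connectivity` is conservative under strong shared global structure
  (see above).
* No block-wise approximation is provided for very large gene sets.
* Real-data concerns — probe QC, platform effects beyond additive
  offsets, ortholog confidence weighting — are out of scope.
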