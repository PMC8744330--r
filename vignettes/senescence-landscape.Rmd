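---
title: "Mapping senescence-gene co-expression landscapes across tissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping senescence-gene co-expression landscapes across tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the model

Cellular senescence leaves transcriptional fingerprints in healthy tissues,
but senescence genes (SnGs) — genes whose manipulation induces or inhibits
senescence — were mostly characterized in vitro. `senescape` implements a
network-biology pipeline for asking where, and with which partners, SnGs are
co-expressed in vivo: tissue-specific co-expression networks, SnG-enriched
modules, a cross-tissue consensus of those modules, and single-cell/spatial
statistics that test whether the consensus genes really co-occur with
senescence markers in individual cells and tissue regions.

The pipeline is a chain of well-defined statistical steps:

1. **Bulk preprocessing.** Per tissue, genes are kept when their
   log2(CPM) exceeds 1 in strictly more than 25% of samples; counts are
   TMM-normalized, log2-transformed (`log2(CPM_TMM + 1)`), and residualized
   by per-gene OLS against collection site, RIN, ischemic time, exonic/rRNA/
   intergenic rates and sex (optionally also age, giving the age-adjusted
   network set). Residuals are exactly orthogonal to the design, so network
   edges cannot be driven by those covariates. Donor age enters as
   decade-bin midpoints (25, 35, ..., 75), mirroring cohorts that release
   age only as ten-year ranges.
2. **Planar filtered networks.** All pairwise Pearson correlations get
   two-sided p-values from the t transform with `m - 2` df; pairs passing a
   BH FDR of 0.05 are ranked by `|r|` (the network is unsigned) and grown
   into a planar maximally filtered graph: each edge is kept iff the graph
   stays planar, up to the planar bound `3|V| - 6`. Planarity is decided by
   an exact Demoucron–Malgrange–Pertuiset edge-embedding test per
   biconnected component (implemented in C++), not a heuristic.
3. **Multiscale modules and hubs.** The hierarchy comes from recursive
   Louvain splitting with a degree-preserving rewire null: a split is
   accepted only when its modularity exceeds the mean + 2 SD of 100 rewired
   replicates of the same subgraph. A resolution ladder (0.1, 0.5, 1, 2 by
   depth) makes the top level coarse and deeper levels finer — the
   "scales of compactness" of the hierarchy. Hubs are genes whose
   within-module degree exceeds the module's mean + 2 SD.
4. **Module statistics.** One-tailed hypergeometric (Fisher) enrichment
   against gene sets with BH correction (per tissue by default), module
   eigengenes (first PC of the z-scored module submatrix, oriented along
   mean module expression) and Spearman age correlations with midrank ties.
5. **Landscape clustering and aggregation.** SnG x flagged-module binary
   presence matrices are clustered by consensus k-means (k = 4, 100 runs,
   k-means++ seeding; co-assignment fractions cut by average-linkage
   clustering); row clusters found in more than half the surveyed tissues
   contribute their genes to the conserved SnG list. Tissue subnetworks of
   flagged-module genes are merged with integer conservation weights (number
   of supporting tissues/networks); nodes with weight < 5 are filtered.
   Three-layer neighborhoods around seed genes aggregate the same way, with
   the seed retained unconditionally.
6. **Single-cell and spatial validation.** LogNormalize (scale 10,000,
   natural log), variable-gene PCA, KNN-graph Louvain clustering
   (resolution 0.05), one-vs-rest Wilcoxon markers (FDR < 0.05, ln-scale
   LFC >= 0.25, expressing fraction >= 0.25), per-cell and per-voxel
   weighted-KS GSEA with gene-label permutation p-values (enriched at
   p < 0.01), coexistence-proportion Wilcoxon tests against 1,000 random
   background genes, and ligand-receptor communication permutation tests
   (10,000 permutations) between cell-type marker sets.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `log2cpm_threshold`, `sample_fraction` | 1, 0.25 | expression filter; "more than 25%" is a strict inequality |
| `pseudocount` | 1 CPM | added before log2; keeps zeros finite |
| `edge_fdr` | 0.05 | BH cutoff on correlation p-values |
| `min_module_size`, `max_depth` | 10, 4 | hierarchy granularity bounds |
| `resolution_ladder` | 0.1, 0.5, 1, 2 | Louvain resolution per depth |
| `alpha_q` (module flagging) | 0.05 | BH-adjusted enrichment threshold, non-strict (`q <= alpha`) so the `alpha = 1` limit returns every overlapping module |
| `k`, `runs` | 4, 100 | consensus k-means |
| `min_node_weight` | 5 | conservation filter ("weights < 5" removed) |
| `layers` | 3 | neighborhood radius in edges |
| `scale` | 10,000 | LogNormalize scale factor |
| `lfc_min`, `min_frac`, `q_max` | 0.25, 0.25, 0.05 | marker thresholds (natural-log LFC) |
| `n_perm` | 1,000 (GSEA), 10,000 (LR) | permutation counts |
| `p_enriched` | 0.01 | per-cell / per-voxel enrichment call |

## What the synthetic data emulate — and what they do not

The generators produce every input with planted, recoverable truth:

* **Bulk cohorts** are lognormal-Poisson counts. Within a module, latent
  log-expression follows a one-factor model whose pairwise correlation is
  exactly the requested `within_correlation`; loading signs are random, so a
  module is library-size neutral (the network is unsigned, so sign-balanced
  modules are statistically equivalent — and a sign-imbalanced block would
  otherwise leak into every other gene through CPM normalization, a real
  compositional artifact worth knowing about). Covariates act as a shared
  sample-level shift; age trends run through the module factor so the module
  eigengene carries the age signal.
* **Single-cell cohorts** plant disjoint marker blocks per cell type
  (Poisson counts, natural-log fold changes) with independent Bernoulli
  dropout. Dropout independent of expression level is a simplification;
  real dropout is abundance-dependent.
* **Ligand-receptor tables** mix planted marker-to-marker pairs with decoys
  from non-marker genes.
* **Spatial slides** mix cell-type mean profiles by per-voxel simplex
  weights on a grid, with a corner region both skewed toward one type and
  elevated in a designated module's genes.

What passing tests show is that the statistics recover planted structure of
the kind each method assumes. What they do not show: robustness to batch
effects, abundance-dependent dropout, ambient RNA, segmentation errors,
realistic covariate distributions, or the annotation noise of real SnG
catalogues. Scale is also deliberately desk-sized (hundreds of genes, three
tissues); the headline counts of a full-scale atlas are not reproducible
from synthetic cohorts, which is why the acceptance machinery checks
properties and oracles, not literature values.

## Numerical choices

* **Pseudocount**: +1 on the CPM scale before log2. Configurable; recorded
  with the output.
* **TMM**: trim 30% on M, 5% on A, precision-weighted mean, factors
  normalized to log-mean 0; the reference is the sample whose upper-quartile
  fraction is closest to the mean (computed by edgeR; the test suite checks
  it against an independently coded trim-and-weight oracle to 1e-10).
* **Correlation p-values**: t transform with `m - 2` df; no df correction
  for the covariates already removed.
* **Tie-breaks**: everywhere lexicographic on gene symbols (edge ranking,
  GSEA rankings), making every ordering deterministic.
* **Enrichment universe**: the tissue's post-filter network genes, not the
  genome; configurable, and all five counts are reported so any fold
  enrichment can be recomputed externally.
* **Eigengene**: per-gene z-score before the SVD; sign anchored to the mean
  standardized module profile.
* **Consensus clustering**: the combining rule (co-assignment matrix +
  average-linkage cut) is a standard consensus construction; k-means++
  seeding is hand-coded, with a 1e-9 jitter on centers to avoid degenerate
  duplicate centers on binary data.
* **GSEA**: weighting exponent 1; hit weights normalized to sum 1; the
  enrichment score is the signed maximum deviation of the running sum; the
  null redraws the gene labels of the set per permutation, and
  `p = (1 + #{ES_perm >= ES_obs}) / (1 + n_perm)` so p-values never reach 0.
  Per-cell and per-voxel scoring share one C++ core.
* **Permutation units**: the per-cell/per-voxel permutation scheme is
  gene-label permutation (a per-cell ranking has no sample phenotype to
  permute); this is recorded in the method tags.
* **Degenerate inputs**: zero-variance genes are excluded from correlations
  (with a count) and dropped from eigengenes (with a warning); all-zero
  samples/cells are hard errors naming the offender; empty gene sets give
  p = 1 with NA fold enrichment; a seed gene absent from a network yields an
  empty neighborhood with a warning.
* **Seeds**: one master seed derives per-stage seeds as
  `(seed mod 1e6) * 1000 + stage`, all below 2^31, so each stage is
  independently reproducible and two runs with one config are byte-identical.

## Design decisions in the open

* **Multiscale clustering stand-in.** The compactness statistics of the
  original multiscale embedded network analysis are not public in citable
  form; the hierarchy here is recursive Louvain with a rewire null, which
  produces the same artifact shape (nested modules + hubs) and is testable
  against planted truth. Results carry the method tag
  `recursive-louvain-rewire-null` so they are never mistaken for the
  original algorithm's output.
* **BH scope** for module flagging is per tissue per gene-set family by
  default (configurable to global); recorded in the output metadata.
* **"Surveyed tissues"** for conserved-SnG selection defaults to the
  tissues contributing at least one flagged module.
* **Edge filtering in aggregation**: nodes are filtered by conservation
  weight; edges are kept whenever both endpoints survive (an optional
  `min_edge_weight` exists, default 1), since the method statement filters
  nodes only.
* **LR null-calibration design.** A permutation p-value built on a small
  count statistic is valid but very discrete; testing its uniformity with a
  continuous-null KS test only makes sense when the count has wide support.
  The calibration studies therefore use dense marker sets and a large
  ligand-receptor table; sparse settings are exercised separately for
  correctness, not uniformity.

## Problem sizes used by the bundled studies

The default pipeline cohort is 3 tissues x 300 genes x 40 samples, 800
cells, 400 voxels, 60 SnGs with 30 planted per tissue — sizes chosen so the
planted structure is comfortably recoverable by the method's own thresholds
while a full run stays in the minutes range on one CPU. The calibration
studies use 200–2,000 replicates as noted in each test.

## Known limitations

* PMFG construction re-tests planarity from scratch per candidate edge
  (O(VE) per test); fine at desk scale, but a full-genome network would
  want an incremental embedding.
* Louvain below the resolution ladder's coarsest level can still split
  internally homogeneous planar modules; the rewire null guards the split
  decision, not the partition's interpretability.
* Library-size normalization induces compositional coupling: strong planted
  signal in one cell type deflates that type's other genes after
  normalization, which can surface as weak "markers" of the remaining
  types. This is a property of global-scaling normalization itself and is
  visible in the marker false-discovery numbers of the synthetic studies.
* The Wilcoxon tests use the normal approximation with tie correction;
  exact small-sample p-values are not attempted.
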