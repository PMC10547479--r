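---
title: "Identifying a matrisome-associated macrophage polarisation state: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying a matrisome-associated macrophage polarisation state: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mamscope)
```

## The scientific problem

Fibrotic diseases of the liver, lung, heart, skin, endometrium and kidney
share an expansion of SPP1+ (osteopontin-expressing) macrophages.  Within
that compartment a further polarisation state — the matrisome-associated
macrophage, MAM — can be resolved: SPP1+MAM+ cells express an
extracellular-matrix-remodelling and metabolic gene programme, sit at the
end of a monocyte-to-macrophage differentiation trajectory, and expand with
disease, while SPP1+MAM− cells occupy the preceding stretch of the same
trajectory.  mamscope implements the complete quantitative machinery needed
to identify and characterise such a state from multi-tissue single-cell
RNA-seq counts, together with a ground-truth synthetic data generator so
that every stage is testable without access to the original cohorts.

Throughout the package expression matrices are cells × genes.  Batch
integration (Harmony / CCA / SCTransform and their kin) is deliberately out
of scope: every function that consumes a reduced representation accepts an
externally supplied embedding verbatim, so integrated reductions can be
plugged in where a user has them.

## Quality control and normalisation

`apply_qc()` retains cells detecting between 300 and 5000 genes
(inclusive), with a mitochondrial read fraction strictly below 20 % (genes
matching `^MT-`) and a haemoglobin fraction (HBA, HBB) strictly below
0.1 %.  Tissues with constitutively high mitochondrial content can use the
lenient 40 % cutoff (`lenient = TRUE`).  Genes detected in no remaining
cell are dropped, and `filter_shared_genes()` restricts pooled per-tissue
datasets to genes expressed in at least two of them.  `log_normalize()` is
the standard library-size transform
`ln(1 + 10^4 · count / cell total)`.

## Clustering with silhouette-guided resolution selection

`embed_cells()` selects 2000 highly variable genes by standardized
dispersion (variance/mean of the exponentiated normalized values, z-scored
within 20 equal-frequency mean-expression bins — the paper-cited toolchain
names a function, not a criterion, so the criterion is documented here),
z-scales them with clipping at ±10, and takes the top 30 principal
components.  `cluster_cells()` builds a shared-nearest-neighbour graph
(k = 20, Jaccard weights, pruned below 1/15) and partitions it by Leiden
modularity optimisation at a given resolution; any modularity method at
matched resolution is an acceptable implementation of this contract, and
the seed makes it deterministic.

`select_resolution()` scans resolutions 0.20–1.00 in steps of 0.05,
computes the mean silhouette width of every labelling (Euclidean distances
on the same embedding used for clustering — with integration out of scope
the embedding *is* the metric space), and returns the maximiser among
resolutions ≥ 0.30; lower resolutions are treated as under-clustering and
cannot win, a single-cluster labelling has undefined silhouette (−∞), and
ties break toward the lowest resolution.

`merge_clusters()` computes each cluster's pseudo-bulk profile as the
per-component mean of its cells' top-30-PC coordinates and merges every
cluster pair with Pearson r strictly above 0.6.  Merging is a single-pass
transitive closure over all pairs (union–find, no recomputation between
merges): this makes the result deterministic and independent of merge
order, which an iterated recompute-and-merge scheme would not be.

`myeloid_filter()` operationalises "PTPRC+ CD68+ clusters" as: every keep
marker detected in ≥ 25 % of the cluster's cells (the threshold is
configurable since the source analysis leaves it unstated).  Kept cells are
re-clustered and clusters in which any removal panel (NK: GZMB/GNLY/CCR7;
dendritic: CD1C/FCER1A; proliferation: STMN1/TUBB; mesenchymal: DCN/LUM)
has at least half its markers at ≥ 25 % detection are removed.

`rank_markers()` reimplements cluster-vs-rest marker testing: log2 fold
change on exponentiated normalized means with pseudocount 1e-9 (the source
is silent on the pseudocount), detection fractions, a tie-corrected
Wilcoxon rank-sum test and Benjamini–Hochberg FDR within cluster.

## Cross-tissue signature derivation

`differential_stats()` computes, per tissue, the MAM+ vs MAM− log2 fold
change and the difference in detection fractions (diff.pct), then averages
both across tissues unweighted.  The averaged diff.pct is z-scaled across
genes, and a one-tailed upper z-test p-value with BH FDR is attached.
`derive_cross_tissue_signature()` keeps genes with mean log2FC > 0.5 and
z > 1.96 (up), or both reversed (down); the homeostatic-signature variant
additionally requires FDR < 0.05.  One documented wrinkle: 1.96 is the
*two*-sided 5 % critical value, yet the test is described as one-tailed.
The literal numeric threshold 1.96 is applied on z and the one-tailed p is
reported alongside, so users can filter on either.

`module_score()` is an expression-matched score: genes are binned into 24
equal-frequency bins by dataset-wide mean normalized expression; each set
gene draws 100 seeded control genes from its bin (topping up from adjacent
bins when a bin is too small), and the score is the mean over set genes
minus the mean over pooled controls.  Set genes are excluded from every
control pool — otherwise a genuinely shifted gene set partially subtracts
its own signal through controls that happen to be fellow set members, which
biases planted effects downward by exactly the contamination fraction.

`elbow_select_markers()` post-processes marker-panel predictions (the
panel search itself, a combinatorial XL-mHG scan, is an input): genes are
ranked by occurrence count across panels, a line is drawn from the first to
the last (rank, count) point, and the cut falls at the gene with maximal
perpendicular distance to that line (ties toward the smaller rank), after
which the kept genes are intersected with the signature.
`hypergeometric_enrichment()` is the upper-tail overlap test, and
`derive_pathway_subsignature()` applies the NES > 1.6 / adjusted-p < 0.05
filter to an externally computed enrichment table and intersects the
passing leading edges with the signature.

## Differentiation propensity

`transition_matrix()` builds a locally-scaled Gaussian diffusion kernel on
the first 50 embedding components: k = max(2, ⌈0.10 · n⌉) nearest
neighbours (capped at n − 1), per-cell bandwidth σ_i = distance to the
⌈k/2⌉-th neighbour (floored at machine-epsilon scale for duplicate
points), weights exp(−d²/(σ_i σ_j)) on the symmetrised kNN graph,
density normalisation by the row-sum products, and row normalisation to a
stochastic matrix P with zero diagonal.  The cited diffusion-map software
does not restate its kernel; this one is specified completely so results
are reproducible from the documentation alone.  Self-transitions are
excluded because the score below only concerns transitions *between*
states.

For each MAM− cell, `propensity_scores()` computes a = Σ P[i, j] over
MAM+ cells and b = Σ P[i, j] over transitional cells and reports
a/(a+b) — the per-cell reading of the propensity quotient (scores are
displayed per cell and binned into four equal-width bins; a cohort-level
pooled ratio is the alternative reading, noted but not implemented).
Cells with a + b = 0 are flagged undefined and excluded from comparisons
rather than imputed, and the count is reported.
`compare_conditions()` applies the two-sided Wilcoxon rank-sum test (exact
when both groups have ≤ 20 tie-free observations, tie-corrected normal
approximation otherwise).  `downsample_cells()` performs the seeded uniform
25,000-cell downsampling used for very large tissues.

## Regulon prioritisation

Regulon inference (GRN + motif pruning) is an input: regulons arrive as
GMT entries with a `TF:<symbol>` description.  `aucell_score()` computes
the rank-recovery AUC: per cell, genes are ranked by expression with ties
broken by one seeded permutation shared across cells; with cutoff
m = ⌈top_fraction · G⌉ the recovery curve counts regulon genes among the
top r ranks (r = 1..m) and the AUC is its area divided by the maximal
area.  The default top_fraction of 0.05 matches the convention for
transcriptome-scale gene universes; on the synthetic namespaces of a few
thousand genes, where cells detect over half of all genes, the pipeline
and acceptance runs use 0.30 so that the cutoff covers the same
"well-expressed" band of the ranking it covers in real data.

`binarize_activity()` fits a seeded two-component Gaussian mixture
(deterministic EM with quantile initialisation) and thresholds at the
equal-responsibility crossing between the component means; if the means
differ by less than 0.05 the distribution is declared unimodal and all
cells inactive.  The mixture-based rule is itself a design decision (the
cited tool's binarisation is package-internal); mclust serves as an
independent cross-check in the test suite, not as the implementation.

`retention_filter()` keeps regulons active in ≥ 10 % of cells in ≥ 4
tissues (boundaries inclusive; with fewer tissues the requirement adapts).
`compute_dor()` evaluates the diagnostic odds ratio
(TP + 0.05)(TN + 0.05) / ((FP + 0.05)(FN + 0.05)) per tissue — activation
in MAM+ cells as "cases" — and takes the median across tissues.
`regulon_specificity()` combines hypergeometric overlap significance with
summed fold changes:
((−ln p_up) − (−ln p_dn)) · (S_up − S_dn) / |regulon|.  The log base is
unstated in the source; natural log is used and documented.  The
hypergeometric universe is the set of genes entering the differential
analysis.  Note that both factors flip sign when the up/down signatures are
swapped, so the score is swap-invariant, and mirror-symmetric overlaps give
exactly zero.  `trajectory_slopes()` fits the two segment regressions (AUC
on signature score over transitional ∪ MAM−, then MAM− ∪ MAM+): a regulon
driving the MAM+ transition shows a steeper second slope.

## Ageing association

`pseudobulk_scores()` takes per-subject medians of per-cell module scores,
excludes donors with fewer than 10 cells, and z-scales across retained
subjects.  Both raw medians (`score_*`) and z-scaled columns (`z_*`) are
kept: z-scaling standardises cross-signature display, but a regression
meant to estimate a slope on the module-score scale must use the raw
columns — rescaling the response would silently rescale the estimate —
so `covariate_regression()` (OLS on age, sex and smoking, one-hot encoding
dropping one level, constant covariates dropped with a warning) defaults
to them.  Smoking is modelled as a covariate; stratified re-runs are a
row-filter away rather than a separate code path.  `map_orthologs()`
transfers signatures across species by table lookup (each source gene
expands to all its targets; unmapped genes are dropped and counted), and
`group_compare()` performs the young (1–3 months) versus aged (21–30
months) Wilcoxon comparison.

## What the synthetic generators emulate — and what they do not

`simulate_multitissue()` draws negative-binomial counts
(variance μ + φμ², φ = 0.3 by default) with log-normal library sizes and
per-subject, per-gene log-normal random effects, over a gene namespace
shared across tissues.  Five populations are planted: FCN1+ monocytes,
transitional macrophages, homeostatic macrophages, and SPP1+MAM−/MAM+
macrophages, with condition-dependent composition (disease carries larger
MAM fractions).  Design choices worth restating:

* **Broad state programmes.** Each of the three non-MAM populations
  carries its own broad expression programme (sd 0.4 log2 over the
  housekeeping pool); MAM− and MAM+ share a single SPP1-macrophage
  programme.  Real cell types differ across much of the transcriptome,
  while polarisation states of one cell type differ focally — and this
  also guarantees the planted signature is the *only* systematic MAM+/MAM−
  difference, so recovery can be scored exactly.
* **A differentiation continuum.** The monocyte→transitional→MAM−→MAM+
  axis carries trapezoid programme activations in a latent pseudotime,
  cross-fading at segment boundaries, plus linear trajectory genes, so
  expression varies continuously along the axis; per-segment pseudotime
  densities peak at segment centres, keeping boundaries low-density and
  clusterable.  Disease MAM− cells sit closer to the MAM+ end.
* **Detection-sensitive baselines.** Signature genes are planted at
  baselines around 0.7 expected counts, where a 2-fold shift moves the
  detection fraction appreciably: the derivation rule filters on
  z-scaled diff.pct, which no expression shift can satisfy for genes whose
  detection is saturated.  The default namespace (2000 genes, of which
  ~6 % carry planted structure) keeps the z-scale realistic; much smaller
  namespaces concentrate the planted structure, inflate the z-scale and
  make the fixed 1.96 cutoff unattainable at the planted log2FC of 1.0.
* **Regulons.** The driver regulon targets the leading signature genes
  (as a MAM+ driver TF would) with activity ramping along the MAM branch;
  decoys are bimodal (40 % activation) with low-baseline target pools so
  activation moves targets into the top ranks; one rare decoy (5 %)
  exercises the retention filter.
* **QC violations.** 5 % of cells are planted as violations: half
  high-mitochondrial (~30 % fraction — removed at the default cutoff but
  retained under the lenient one), a quarter low-depth, a quarter
  haemoglobin-contaminated.

`simulate_aging_cohort()` plants a linear age effect directly on the
natural-log scale of the MAM− signature genes (high baselines ≈ 40 counts,
dispersion 0.05, spread over several expression bins), so that the
module-score slope equals the nominal `age_slope`; subject identity adds a
random intercept (sd 0.2 on the score scale), which is the dominant noise
source and makes the regression's confidence intervals honestly sized.
Mouse mode renames the namespace, emits the ortholog table, and splits
subjects into young/aged groups.

`simulate_branching_embedding()` generates the geometry the diffusion
analysis consumes: cells along a smooth curve in 50-dimensional embedding
space with isotropic noise and *overlapping* class-conditional pseudotime
distributions.  This is deliberately a separate generator: after
integration, neighbouring polarisation states form one continuous manifold
in which most MAM− cells have both MAM+ and transitional neighbours —
exactly what a per-cell transition-mass ratio needs — whereas the
expression generator produces cluster-resolved populations, as the
clustering stages require.  One geometry cannot make per-cell
neighbourhoods heavily mixed and keep cluster recovery near-perfect at the
same time; since the propensity module takes an embedding as its input by
contract, its behavioural guarantees are tested on the branching
generator.

Neither generator simulates doublets, ambient RNA, or batch effects
(integration being out of scope).  Passing tests therefore demonstrate the
correctness and calibration of the *methods* under the stated generative
model, not robustness to artefacts the model omits.

## Numerical choices and degenerate inputs

* Wilcoxon tests: exact null distribution when both groups have ≤ 20
  tie-free observations, tie-corrected normal approximation otherwise;
  zero rank variance gives p = 1.
* z-scaling with zero spread defines all z as 0 (nothing passes).
* All strict/inclusive boundaries follow the stated rules: signature
  cutoffs and the merge threshold are strict; QC gene bounds and the
  retention boundaries are inclusive.
* Cells with zero counts fail normalisation by name; empty datasets pass
  QC unchanged; a resolution yielding one cluster cannot win selection.
* Seeds: every stochastic step takes an explicit seed; the pipeline fans a
  single global seed into fixed per-stage substreams (multiplicative
  congruential mixing, always below 2³¹), so stages can be rerun in
  isolation and a rerun is bit-identical.

## Problem sizes

The default synthetic study conditions are six tissues × 2000 cells ×
2000 genes with a planted 100-gene MAM+ programme at log2FC 1.0; the
ageing cohort uses 85 subjects (60 cells each) with a planted slope of
0.02 per year over ages 25–75; propensity checks use 500 cells per class
on the branching manifold.  The test suite runs recovery over 10 seeds,
coverage over 100 seeds and the null rejection rate over 600 replicates at
reduced per-replicate sizes (50 subjects × 15 cells, 360-gene namespace);
the bundled pipeline demonstration uses 2 tissues × 220 cells so a full
run with manifest takes seconds.

## Known limitations

* Mean silhouette is computed from a full distance matrix: fine up to a
  few thousand cells per tissue, quadratic beyond.
* The merge step correlates 30-component pseudo-bulk profiles; with very
  few informative components the Pearson correlation of short profile
  vectors is noisy.
* The elbow cut is only defined up to its documented tie-breaks when
  occurrence counts are nearly flat.
* The mixture binarisation assumes at most two activity modes; regulons
  with more complex activity landscapes are thresholded at the dominant
  crossing.
* The ageing regression is ordinary least squares per signature; no
  mixed-effects modelling across tissues is attempted.
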