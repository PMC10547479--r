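# mamscope

Cross-tissue identification of a matrisome-associated macrophage (MAM)
polarisation state from single-cell RNA-seq counts.

In fibrotic disease of many organs, SPP1+ (osteopontin-expressing)
macrophages expand, and within them a further polarisation state — the
SPP1+MAM+ macrophage — expresses an extracellular-matrix-remodelling and
metabolic programme and sits at the end of a monocyte-to-macrophage
differentiation trajectory.  mamscope packages the full quantitative
machinery needed to find and characterise such a state, for computational
biologists working with multi-tissue single-cell cohorts:

* **QC and normalisation** — `apply_qc()` (300–5000 detected genes, <20 %
  mitochondrial with a 40 % lenient option, <0.1 % haemoglobin),
  `log_normalize()`, `filter_shared_genes()`.
* **Clustering** — PCA on highly variable genes (`embed_cells()`, or any
  externally integrated embedding), Leiden clustering on a
  shared-nearest-neighbour graph (`cluster_cells()`), silhouette-guided
  resolution selection over 0.20–1.00 with a 0.30 under-clustering floor
  (`select_resolution()`), pseudo-bulk cluster merging at Pearson r > 0.6
  (`merge_clusters()`), the two-step myeloid filter (`myeloid_filter()`),
  and Wilcoxon marker ranking (`rank_markers()`).
* **Cross-tissue signatures** — per-tissue log2FC and detection-fraction
  differences averaged across tissues, with the z-scaled diff.pct rule
  `mean log2FC > 0.5 & z > 1.96` (`differential_stats()`,
  `derive_cross_tissue_signature()`), expression-matched module scores
  (`module_score()`), elbow-based marker selection from panel predictions
  (`elbow_select_markers()`), hypergeometric enrichment and pathway
  sub-signatures from NES > 1.6 / p.adjust < 0.05 leading edges.
* **Differentiation propensity** — a locally-scaled Gaussian diffusion
  kernel (top 50 PCs, k = 10 % of cells) row-normalised to a transition
  matrix (`transition_matrix()`), and for each SPP1+MAM− cell the score

  `P(MAM+ | MAM−) / (P(MAM+ | MAM−) + P(transitional | MAM−))`

  (`propensity_scores()`), with two-sided Wilcoxon condition comparisons
  and seeded 25,000-cell downsampling.
* **Regulon prioritisation** — rank-recovery AUC activity scoring
  (`aucell_score()`), Gaussian-mixture binarisation, the ≥10 %-cells-in-≥4
  tissues retention filter, the diagnostic odds ratio

  `DOR = (TP + 0.05)(TN + 0.05) / ((FP + 0.05)(FN + 0.05))`

  with its cross-tissue median (`compute_dor()`), the signature
  specificity score `((−ln p_up) − (−ln p_dn)) · (S_up − S_dn) / |regulon|`
  (`regulon_specificity()`), and two-segment trajectory regressions.
* **Ageing association** — per-donor median pseudo-bulk module scores
  (≥10-cell donors), OLS on age/sex/smoking (`pseudobulk_scores()`,
  `covariate_regression()`), ortholog transfer (`map_orthologs()`) and
  young-vs-aged comparisons (`group_compare()`).
* **Synthetic data with ground truth** — `simulate_multitissue()` (five
  monocyte/macrophage populations with a latent differentiation axis,
  planted signatures, regulon programmes, QC violations, subject effects),
  `simulate_aging_cohort()` (planted score-vs-age slope, mouse mode with
  ortholog table), and `simulate_branching_embedding()` (the continuous
  manifold geometry used by the propensity analysis).

Batch integration and UMAP are out of scope by design; every stage that
needs a reduced space accepts an external embedding.

## A worked example

```r
library(mamscope)

# a synthetic six-tissue cohort with known ground truth
sims    <- simulate_multitissue(sim_config(seed = 1))
tissues <- lapply(sims, function(s) log_normalize(apply_qc(s$dataset)))

# cluster one tissue with silhouette-guided resolution selection
emb <- embed_cells(tissues[[1]])
sel <- select_resolution(emb, seed = 1)
mg  <- merge_clusters(emb, sel$labels)
adjusted_rand_index(mg$labels, tissues[[1]]$cell_meta$population_label)
#> [1] 0.9945735

# derive the cross-tissue MAM+ signature and compare with the planted truth
pops <- lapply(tissues, function(d) d$cell_meta$population_label)
st <- differential_stats(tissues,
                         lapply(pops, function(p) p == "MAM_pos"),
                         lapply(pops, function(p) p == "MAM_neg"))
sig <- derive_cross_tissue_signature(st, direction = "up")
truth <- sims[[1]]$truth$signature$genes
c(recall = length(intersect(sig$genes, truth)) / length(truth),
  false_positives = length(setdiff(sig$genes, truth)))
#>          recall false_positives
#>            0.94            0.00
```

The chosen resolution is the silhouette maximiser at or above 0.30; the
adjusted Rand index of ~1 says the QC → embed → cluster → merge chain
recovered the five planted populations almost perfectly; the derived
signature recovered 94 of the 100 planted genes with no false positives at
the published cutoffs (log2FC > 0.5, z(diff.pct) > 1.96).

Full pipeline runs write every stage output plus a hash manifest:

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "run1"))
res$summary$cluster_ari        # population recovery
res$summary$top_regulon        # highest median-DOR regulon
```

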