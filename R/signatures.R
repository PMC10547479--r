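#' Cross-tissue differential statistics between two cell groups
#'
#' For each tissue computes, per gene, the log2 fold change between groups A
#' and B (on exponentiated normalized means, pseudocount 1e-9) and the
#' difference in detection fractions (`diff_pct = pct_A - pct_B`).  The
#' per-tissue values are then averaged (unweighted) across tissues; the mean
#' diff.pct is z-scaled across genes and a one-tailed z-test p-value (upper
#' tail of the standard normal) is attached, with a Benjamini-Hochberg FDR.
#'
#' @param datasets list of per-tissue [ged()]s, each with a normalized
#'   layer.
#' @param group_A,group_B lists of logical masks (one per tissue, aligned to
#'   the dataset's cells) selecting the two groups.  A tissue lacking cells
#'   in either group is skipped with a warning.
#' @return list of class `diff_stats` with `per_tissue` (long data.frame:
#'   gene, tissue, log2FC, pct_A, pct_B, diff_pct) and `summary`
#'   (data.frame: gene, mean_log2FC, mean_diff_pct, z_diff_pct, p_z, fdr,
#'   n_tissues).
#' @export
differential_stats <- function(datasets, group_A, group_B) {
  stopifnot(length(datasets) >= 1, length(group_A) == length(datasets),
            length(group_B) == length(datasets))
  eps <- 1e-9
  per <- list()
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    if (is.null(d$normalized)) stop("normalized layer required (tissue ", i, ")")
    a <- group_A[[i]]; b <- group_B[[i]]
    tissue <- d$cell_meta$tissue[1]
    if (sum(a) == 0 || sum(b) == 0) {
      warning("tissue '", tissue, "' lacks cells in one group; skipped")
      next
    }
    norm <- d$normalized
    expd <- norm
    expd@x <- expm1(expd@x)
    mean_a <- Matrix::colMeans(expd[a, , drop = FALSE])
    mean_b <- Matrix::colMeans(expd[b, , drop = FALSE])
    pct_a <- Matrix::colSums(norm[a, , drop = FALSE] > 0) / sum(a)
    pct_b <- Matrix::colSums(norm[b, , drop = FALSE] > 0) / sum(b)
    per[[length(per) + 1]] <- data.frame(
      gene = colnames(norm), tissue = tissue,
      log2FC = log2((mean_a + eps) / (mean_b + eps)),
      pct_A = pct_a, pct_B = pct_b, diff_pct = pct_a - pct_b,
      row.names = NULL)
  }
  if (!length(per)) stop("all tissues lacked one of the groups")
  long <- do.call(rbind, per)
  mean_lfc <- tapply(long$log2FC, long$gene, mean)
  mean_dp <- tapply(long$diff_pct, long$gene, mean)
  n_tis <- tapply(long$log2FC, long$gene, length)
  genes <- names(mean_lfc)
  s <- sd(mean_dp)
  z <- if (is.na(s) || s == 0) rep(0, length(mean_dp)) else
    (mean_dp - mean(mean_dp)) / s
  summary <- data.frame(gene = genes,
                        mean_log2FC = as.numeric(mean_lfc),
                        mean_diff_pct = as.numeric(mean_dp),
                        z_diff_pct = as.numeric(z),
                        p_z = pnorm(as.numeric(z), lower.tail = FALSE),
                        n_tissues = as.integer(n_tis), row.names = NULL)
  summary$fdr <- p.adjust(summary$p_z, "BH")
  structure(list(per_tissue = long, summary = summary), class = "diff_stats")
}

#' Derive a cross-tissue signature from differential statistics
#'
#' Direction `"up"` keeps genes with `mean_log2FC > lfc_thresh` and
#' `z_diff_pct > z_thresh`; direction `"down"` keeps `mean_log2FC <
#' -lfc_thresh` and `z_diff_pct < -z_thresh` (all inequalities strict).  An
#' optional FDR cutoff (used for the homeostatic-signature variant) is
#' applied on top.
#'
#' @param stats a `diff_stats` object from [differential_stats()].
#' @param lfc_thresh log2 fold-change threshold.
#' @param z_thresh threshold on the z-scaled mean diff.pct.
#' @param direction `"up"` or `"down"`.
#' @param fdr_thresh optional FDR cutoff (strict `<`); `NULL` to skip.
#' @param name name of the returned gene set.
#' @return a [gene_set()]; empty selection yields a zero-gene set (class
#'   `gene_set` with empty `genes`) with a warning.
#' @export
derive_cross_tissue_signature <- function(stats, lfc_thresh = 0.5,
                                          z_thresh = 1.96,
                                          direction = c("up", "down"),
                                          fdr_thresh = NULL,
                                          name = NULL) {
  direction <- match.arg(direction)
  s <- stats$summary
  keep <- if (direction == "up") {
    s$mean_log2FC > lfc_thresh & s$z_diff_pct > z_thresh
  } else {
    s$mean_log2FC < -lfc_thresh & s$z_diff_pct < -z_thresh
  }
  if (!is.null(fdr_thresh)) keep <- keep & s$fdr < fdr_thresh
  genes <- s$gene[keep]
  if (is.null(name)) name <- paste0("signature_", direction)
  if (!length(genes)) {
    warning("no gene passes the ", direction, " signature cutoffs")
    return(structure(list(name = name, tf = NULL, genes = character(0)),
                     class = "gene_set"))
  }
  gene_set(name, genes)
}

#' Expression-matched module score
#'
#' For each gene of the set, `n_ctrl` control genes are drawn (seeded,
#' without replacement) from the gene's expression bin, where genes are
#' binned into `n_bins` equal-frequency bins by dataset-wide mean normalized
#' expression; bins smaller than needed are topped up from adjacent bins.
#' Set genes are excluded from every control pool, so a planted shift of
#' the set is never partially subtracted through its own controls.  The
#' score of a cell is the mean normalized expression over the set genes
#' minus the mean over the pooled control genes.
#'
#' @param dataset a [ged()] with a normalized layer.
#' @param set a [gene_set()]; genes absent from the dataset are dropped with
#'   a warning.
#' @param n_bins number of expression bins.
#' @param n_ctrl control genes per set gene.
#' @param seed RNG seed for the control draw.
#' @return numeric per-cell score vector (named by cell id) with attributes
#'   `set_name` and `control_genes`.
#' @export
module_score <- function(dataset, set, n_bins = 24, n_ctrl = 100, seed = 0) {
  validate_ged(dataset)
  if (is.null(dataset$normalized)) stop("normalized layer required")
  norm <- dataset$normalized
  genes <- intersect(set$genes, colnames(norm))
  if (!length(genes)) stop("no gene of set '", set$name,
                           "' is present in the dataset")
  if (length(genes) < length(set$genes)) {
    warning(length(set$genes) - length(genes), " gene(s) of set '",
            set$name, "' absent from the dataset; dropped")
  }
  avg <- Matrix::colMeans(norm)
  n_bins <- min(n_bins, ncol(norm))
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  ctrl <- with_seed(seed, {
    picked <- character(0)
    for (g in genes) {
      b <- bins[match(g, colnames(norm))]
      pool <- setdiff(colnames(norm)[bins == b], genes)
      width <- 1
      while (length(pool) < n_ctrl && width <= n_bins) {
        pool <- union(pool,
                      setdiff(colnames(norm)[abs(bins - b) <= width], genes))
        width <- width + 1
      }
      picked <- c(picked, sample(pool, min(n_ctrl, length(pool))))
    }
    unique(picked)
  })
  score <- Matrix::rowMeans(norm[, genes, drop = FALSE]) -
    Matrix::rowMeans(norm[, ctrl, drop = FALSE])
  score <- as.numeric(score)
  names(score) <- rownames(norm)
  attr(score, "set_name") <- set$name
  attr(score, "control_genes") <- ctrl
  score
}

#' Elbow-based marker selection from marker-panel predictions
#'
#' Counts how often each gene occurs across the supplied marker panels,
#' ranks genes by decreasing count, draws the line from the first to the
#' last point in (rank, count) space, and cuts at the gene with maximal
#' perpendicular distance to that line (ties toward the smaller rank),
#' keeping that gene and all better-ranked ones.  The kept genes are then
#' intersected with the signature.
#'
#' @param panels list of character vectors (marker panels, e.g. four-gene
#'   combinations from a panel-search tool).
#' @param signature a [gene_set()] to intersect with.
#' @return list with `markers` (a [gene_set()], possibly empty),
#'   `kept_genes` (the elbow-selected genes before intersection) and
#'   `occurrence` (data.frame: gene, count, rank, distance).
#' @export
elbow_select_markers <- function(panels, signature) {
  if (!length(panels)) stop("panels must be non-empty")
  counts <- sort(table(unlist(panels)), decreasing = TRUE)
  genes <- names(counts)
  # deterministic order: by count desc, then gene id
  ord <- order(-as.numeric(counts), genes)
  genes <- genes[ord]
  cnt <- as.numeric(counts)[ord]
  k <- length(cnt)
  if (k == 1 || all(cnt == cnt[1])) {
    warning("all occurrence counts equal; keeping only the top-ranked gene")
    kept <- genes[1]
    dist_v <- rep(0, k)
  } else {
    p1 <- c(1, cnt[1]); p2 <- c(k, cnt[k])
    dirv <- p2 - p1
    dist_v <- vapply(seq_len(k), function(i) {
      v <- c(i, cnt[i]) - p1
      abs(dirv[1] * v[2] - dirv[2] * v[1]) / sqrt(sum(dirv^2))
    }, numeric(1))
    cut_at <- which.max(dist_v)  # which.max takes the first (smallest rank)
    kept <- genes[seq_len(cut_at)]
  }
  final <- intersect(kept, signature$genes)
  markers <- if (length(final)) gene_set("elbow_markers", final) else
    structure(list(name = "elbow_markers", tf = NULL, genes = character(0)),
              class = "gene_set")
  list(markers = markers, kept_genes = kept,
       occurrence = data.frame(gene = genes, count = cnt, rank = seq_len(k),
                               distance = dist_v))
}

#' Hypergeometric enrichment of a query gene set against categories
#'
#' Upper-tail hypergeometric test `P(X >= overlap)` with population size
#' `|universe|`, success count `|category intersect universe|` and draw count
#' `|query|`.
#'
#' @param query a [gene_set()]; genes outside the universe are dropped with
#'   a warning.
#' @param categories list of [gene_set()] objects.
#' @param universe character vector of background genes (non-empty).
#' @return data.frame with columns category, overlap, p.
#' @export
hypergeometric_enrichment <- function(query, categories, universe) {
  if (!length(universe)) stop("universe is empty")
  universe <- unique(universe)
  q <- intersect(query$genes, universe)
  if (length(q) < length(unique(query$genes))) {
    warning(length(unique(query$genes)) - length(q),
            " query gene(s) outside the universe; dropped")
  }
  if (inherits(categories, "gene_set")) categories <- list(categories)
  rows <- lapply(categories, function(cat) {
    k <- intersect(cat$genes, universe)
    ov <- length(intersect(q, k))
    p <- phyper(ov - 1, length(k), length(universe) - length(k), length(q),
                lower.tail = FALSE)
    data.frame(category = cat$name, overlap = ov, p = p)
  })
  do.call(rbind, rows)
}

#' Pathway sub-signature from an enrichment table
#'
#' Takes the union of leading-edge genes over enrichment rows passing
#' `NES > nes_thresh` and `p_adjust < padj_thresh` (both strict) and
#' intersects it with the signature.
#'
#' @param signature a [gene_set()].
#' @param enrichment an [enrichment_table()].
#' @param nes_thresh NES cutoff (strict `>`).
#' @param padj_thresh adjusted-p cutoff (strict `<`).
#' @param name name for the resulting set.
#' @return a [gene_set()] (possibly empty, with a warning).
#' @export
derive_pathway_subsignature <- function(signature, enrichment,
                                        nes_thresh = 1.6,
                                        padj_thresh = 0.05,
                                        name = "pathway_subsignature") {
  pass <- enrichment$NES > nes_thresh & enrichment$p_adjust < padj_thresh
  le <- unique(unlist(enrichment$leading_edge[pass]))
  genes <- intersect(signature$genes, le)
  if (!length(genes)) {
    warning("no leading-edge gene overlaps the signature under the cutoffs")
    return(structure(list(name = name, tf = NULL, genes = character(0)),
                     class = "gene_set"))
  }
  gene_set(name, genes)
}
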