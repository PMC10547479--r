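#' PCA embedding on highly variable genes
#'
#' Selects `n_hvg` genes by highest standardized dispersion (dispersion =
#' variance/mean of the exponentiated normalized values, z-scored within 20
#' equal-frequency mean-expression bins), scales them to zero mean and unit
#' variance clipping at +/-10, and returns the top `n_pcs` principal-component
#' coordinates.  An externally supplied embedding (e.g. a batch-corrected
#' reduction) is returned verbatim, so integration methods can be plugged in
#' upstream.
#'
#' @param dataset a [ged()] with a normalized layer.
#' @param n_hvg number of highly variable genes (capped at the gene count
#'   with a warning).
#' @param n_pcs number of principal components.
#' @param external optional cells x k matrix used verbatim instead of PCA.
#' @return cells x `n_pcs` numeric matrix with cell ids as row names.
#' @export
embed_cells <- function(dataset, n_hvg = 2000, n_pcs = 30, external = NULL) {
  if (!is.null(external)) {
    external <- as.matrix(external)
    if (nrow(external) != n_cells(dataset)) {
      stop("external embedding has ", nrow(external), " rows but the dataset ",
           "has ", n_cells(dataset), " cells")
    }
    rownames(external) <- cell_ids(dataset)
    return(external)
  }
  if (is.null(dataset$normalized)) stop("normalized layer required; run log_normalize()")
  norm <- dataset$normalized
  if (n_hvg > ncol(norm)) {
    warning("n_hvg = ", n_hvg, " exceeds the gene count; using all ",
            ncol(norm), " genes")
    n_hvg <- ncol(norm)
  }
  hvg <- select_hvg(norm, n_hvg)
  x <- as.matrix(norm[, hvg, drop = FALSE])
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  x <- pmin(pmax(sweep(sweep(x, 2, mu), 2, sdv, "/"), -10), 10)
  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1)
  sv <- svd(scale(x, center = TRUE, scale = FALSE), nu = n_pcs, nv = 0)
  emb <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  dimnames(emb) <- list(cell_ids(dataset), paste0("PC", seq_len(n_pcs)))
  emb
}

# Standardized-dispersion HVG selection on the exponentiated normalized layer.
select_hvg <- function(norm, n_hvg, n_bins = 20) {
  x <- norm
  x@x <- expm1(x@x)
  mu <- Matrix::colMeans(x)
  ex2 <- Matrix::colMeans(x^2)
  v <- (ex2 - mu^2) * nrow(x) / max(1, nrow(x) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    i <- which(bins == b)
    s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  order(z, decreasing = TRUE)[seq_len(n_hvg)]
}

# k-nearest-neighbour indices (self excluded) by blocked Euclidean search.
knn_indices <- function(embedding, k) {
  n <- nrow(embedding)
  k <- min(k, n - 1)
  sq <- rowSums(embedding^2)
  nn_idx <- matrix(0L, n, k)
  nn_dist <- matrix(0, n, k)
  block <- max(1L, as.integer(2e7 / n))
  for (start in seq(1, n, by = block)) {
    rows <- start:min(n, start + block - 1)
    d2 <- outer(sq[rows], sq, "+") -
      2 * tcrossprod(embedding[rows, , drop = FALSE], embedding)
    d2[cbind(seq_along(rows), rows)] <- Inf
    ord <- t(apply(d2, 1, order))[, seq_len(k), drop = FALSE]
    nn_idx[rows, ] <- ord
    nn_dist[rows, ] <- sqrt(pmax(0, d2[cbind(rep(seq_along(rows), k),
                                             as.vector(ord))]))
  }
  list(idx = nn_idx, dist = nn_dist)
}

# Shared-nearest-neighbour graph (Jaccard weights, pruned below 1/15).
snn_graph <- function(embedding, k_neighbors = 20) {
  n <- nrow(embedding)
  if (n < 2) stop("need at least 2 cells to build a neighbour graph")
  if (k_neighbors >= n) {
    warning("k_neighbors capped at n - 1 = ", n - 1)
    k_neighbors <- n - 1
  }
  nn <- knn_indices(embedding, k_neighbors)$idx
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(nn)),
                              j = as.vector(nn), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  shared <- as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j
  i <- shared@i[keep] + 1L; j <- shared@j[keep] + 1L; s <- shared@x[keep]
  jac <- s / (2 * ncol(nn) - s)
  keep2 <- jac >= 1 / 15
  igraph::graph_from_data_frame(
    data.frame(from = i[keep2], to = j[keep2], weight = jac[keep2]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
}

#' Graph-based clustering at a given resolution
#'
#' Builds a shared-nearest-neighbour graph on the embedding and partitions it
#' with Leiden modularity optimisation at the given resolution.  Deterministic
#' for a fixed seed.
#'
#' @param embedding cells x d numeric matrix.
#' @param resolution modularity resolution parameter.
#' @param k_neighbors neighbours for the SNN graph (capped at n - 1 with a
#'   warning).
#' @param seed RNG seed.
#' @param graph optional precomputed SNN graph (as built internally),
#'   letting a resolution scan reuse one graph.
#' @return integer vector of 0-based, contiguous cluster labels.
#' @export
cluster_cells <- function(embedding, resolution, k_neighbors = 20, seed = 0,
                          graph = NULL) {
  stopifnot(all(is.finite(embedding)))
  if (is.null(graph)) graph <- snn_graph(embedding, k_neighbors)
  memb <- with_seed(seed, {
    igraph::cluster_leiden(graph, objective_function = "modularity",
                           resolution = resolution,
                           n_iterations = 5)$membership
  })
  as.integer(factor(memb, levels = unique(memb))) - 1L
}

#' Silhouette-guided clustering resolution selection
#'
#' Clusters the embedding at every candidate resolution, computes the mean
#' silhouette width (Euclidean distances on the embedding), and returns the
#' resolution maximising it among resolutions at or above `min_resolution`
#' (lower resolutions are treated as under-clustering).  Ties break toward
#' the lowest resolution; a resolution yielding a single cluster has
#' undefined silhouette (-Inf) and cannot win.
#'
#' @param embedding cells x d numeric matrix.
#' @param resolutions candidate resolutions (at least 2).
#' @param min_resolution smallest admissible winning resolution.
#' @param k_neighbors neighbours for the SNN graph.
#' @param seed RNG seed.
#' @return list with `resolution` (chosen), `labels` (its 0-based labels),
#'   and `silhouette_table` (resolution, n_clusters, mean_silhouette).
#' @export
select_resolution <- function(embedding,
                              resolutions = seq(0.20, 1.00, by = 0.05),
                              min_resolution = 0.30, k_neighbors = 20,
                              seed = 0) {
  if (length(resolutions) < 2) stop("need at least 2 candidate resolutions")
  graph <- snn_graph(embedding, k_neighbors)
  d <- dist(embedding)
  labels_list <- vector("list", length(resolutions))
  sil <- numeric(length(resolutions))
  n_clust <- integer(length(resolutions))
  for (i in seq_along(resolutions)) {
    lab <- cluster_cells(embedding, resolutions[i], k_neighbors, seed,
                         graph = graph)
    labels_list[[i]] <- lab
    n_clust[i] <- length(unique(lab))
    sil[i] <- mean_silhouette(lab, d)
  }
  tab <- data.frame(resolution = resolutions, n_clusters = n_clust,
                    mean_silhouette = sil)
  admissible <- which(resolutions >= min_resolution & is.finite(sil))
  if (!length(admissible)) stop("no admissible resolution yields >= 2 clusters")
  best <- admissible[which.max(sil[admissible])]  # ties: lowest resolution
  list(resolution = resolutions[best], labels = labels_list[[best]],
       silhouette_table = tab)
}

#' Mean silhouette width of a labelling
#'
#' @param labels cluster labels.
#' @param d a `dist` object over the same observations.
#' @return mean silhouette width in \[-1, 1\]; `-Inf` for a single cluster.
#' @export
mean_silhouette <- function(labels, d) {
  if (length(unique(labels)) < 2) return(-Inf)
  sil <- cluster::silhouette(as.integer(factor(labels)), d)
  mean(sil[, "sil_width"])
}

#' Merge transcriptionally similar clusters by pseudo-bulk correlation
#'
#' The pseudo-bulk profile of a cluster is the per-component mean of its
#' cells' top-30-PC coordinates; every cluster pair with Pearson correlation
#' strictly above `r_threshold` is merged, transitively, in a single pass
#' (no recomputation between merges), and labels are relabelled contiguously
#' from 0.
#'
#' @param embedding cells x d numeric matrix (the first `min(30, d)`
#'   components are used for the profiles).
#' @param labels cluster labels.
#' @param r_threshold Pearson threshold (strict `>`).
#' @return list with `labels` (merged, 0-based contiguous) and `history`
#'   (data.frame of merged pairs and their correlation).
#' @export
merge_clusters <- function(embedding, labels, r_threshold = 0.6) {
  labels <- as.integer(factor(labels)) - 1L
  k <- length(unique(labels))
  history <- data.frame(cluster_a = integer(0), cluster_b = integer(0),
                        r = numeric(0))
  if (k <= 1) return(list(labels = labels, history = history))
  use <- seq_len(min(30, ncol(embedding)))
  prof <- t(vapply(sort(unique(labels)), function(l) {
    colMeans(embedding[labels == l, use, drop = FALSE])
  }, numeric(length(use))))
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      r <- suppressWarnings(cor(prof[a, ], prof[b, ]))
      if (!is.na(r) && r > r_threshold) {
        history <- rbind(history,
                         data.frame(cluster_a = a - 1L, cluster_b = b - 1L,
                                    r = r))
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  new_lab <- as.integer(factor(roots, levels = unique(roots[order(roots)])))[
    labels + 1L] - 1L
  list(labels = new_lab, history = history)
}

#' Two-step myeloid filter
#'
#' Step 1 keeps clusters in which every keep marker (by default PTPRC and
#' CD68, the putative-myeloid criterion) is detected in at least
#' `detect_frac` of cells.  Step 2 reclusters the kept cells and removes
#' clusters in which any removal marker set (NK, dendritic, proliferating,
#' mesenchymal) has at least half of its markers detected in `detect_frac`
#' of cells.
#'
#' @param dataset a [ged()] with a normalized layer (reclustering runs on
#'   it).
#' @param labels cluster labels from the first-round clustering.
#' @param keep_markers markers that must all be detected for a cluster to
#'   pass step 1.
#' @param remove_marker_sets named list of marker sets identifying
#'   non-monocyte/macrophage clusters.
#' @param detect_frac detection-fraction threshold.
#' @param resolution,k_neighbors,seed reclustering parameters for step 2.
#' @return the filtered [ged()] containing the final monocyte/macrophages.
#' @export
myeloid_filter <- function(dataset, labels,
                           keep_markers = c("PTPRC", "CD68"),
                           remove_marker_sets = list(
                             NK = c("GZMB", "GNLY", "CCR7"),
                             DC = c("CD1C", "FCER1A"),
                             prolif = c("STMN1", "TUBB"),
                             mesen = c("DCN", "LUM")),
                           detect_frac = 0.25, resolution = 1.0,
                           k_neighbors = 20, seed = 0) {
  validate_ged(dataset)
  stopifnot(length(labels) == n_cells(dataset))
  present <- keep_markers %in% gene_ids(dataset)
  if (!all(present)) {
    warning("keep marker(s) absent and ignored: ",
            paste(keep_markers[!present], collapse = ", "))
    keep_markers <- keep_markers[present]
  }
  if (!length(keep_markers)) stop("no keep marker present in the dataset")
  det_frac <- function(ged_obj, cells, genes) {
    Matrix::colSums(ged_obj$counts[cells, genes, drop = FALSE] > 0) /
      length(cells)
  }
  keep_clusters <- Filter(function(l) {
    cells <- which(labels == l)
    all(det_frac(dataset, cells, keep_markers) >= detect_frac)
  }, unique(labels))
  if (!length(keep_clusters)) stop("no cluster passes the myeloid keep step")
  kept <- subset_ged(dataset, cells = which(labels %in% keep_clusters))

  kept <- log_normalize(kept)
  emb <- embed_cells(kept)
  lab2 <- cluster_cells(emb, resolution, k_neighbors, seed)
  remove_marker_sets <- lapply(remove_marker_sets, function(set) {
    miss <- setdiff(set, gene_ids(kept))
    if (length(miss)) warning("removal marker(s) absent and ignored: ",
                              paste(miss, collapse = ", "))
    intersect(set, gene_ids(kept))
  })
  remove_marker_sets <- Filter(length, remove_marker_sets)
  bad_clusters <- Filter(function(l) {
    cells <- which(lab2 == l)
    any(vapply(remove_marker_sets, function(set) {
      mean(det_frac(kept, cells, set) >= detect_frac) >= 0.5
    }, logical(1)))
  }, unique(lab2))
  subset_ged(kept, cells = which(!lab2 %in% bad_clusters))
}

#' Per-cluster marker ranking (cluster vs rest)
#'
#' For every gene and cluster computes `log2FC = log2((mean expm1 in-cluster
#' + eps) / (mean expm1 out-of-cluster + eps))` with `eps = 1e-9`, in/out
#' detection fractions, a Wilcoxon rank-sum p-value on the normalized values,
#' and a Benjamini-Hochberg FDR per cluster.  Rows are sorted by decreasing
#' log2FC within cluster.
#'
#' @param dataset a [ged()] with a normalized layer.
#' @param labels cluster labels (>= 2 clusters).
#' @return data.frame with columns gene, cluster, log2FC, pct_in, pct_out,
#'   p, fdr.  Clusters with fewer than 3 cells get `NA` p-values with a
#'   warning.
#' @export
rank_markers <- function(dataset, labels) {
  validate_ged(dataset)
  if (is.null(dataset$normalized)) stop("normalized layer required")
  stopifnot(length(labels) == n_cells(dataset))
  if (length(unique(labels)) < 2) stop("need >= 2 clusters")
  norm <- dataset$normalized
  eps <- 1e-9
  expd <- norm
  expd@x <- expm1(expd@x)
  out <- list()
  dense <- as.matrix(norm)
  ranks <- apply(dense, 2, rank)  # pooled ranks per gene
  tie_term <- apply(dense, 2, function(col) {
    t <- tabulate(match(col, unique(col)))
    sum(t^3 - t)
  })
  for (l in sort(unique(labels))) {
    inc <- labels == l
    m <- sum(inc); n_out <- sum(!inc)
    mean_in <- Matrix::colMeans(expd[inc, , drop = FALSE])
    mean_out <- Matrix::colMeans(expd[!inc, , drop = FALSE])
    lfc <- log2((mean_in + eps) / (mean_out + eps))
    pct_in <- Matrix::colSums(norm[inc, , drop = FALSE] > 0) / m
    pct_out <- Matrix::colSums(norm[!inc, , drop = FALSE] > 0) / n_out
    if (m < 3) {
      warning("cluster ", l, " has fewer than 3 cells; p-values set NA")
      p <- rep(NA_real_, ncol(norm))
    } else {
      p <- wilcox_vec(ranks, tie_term, inc)
    }
    tab <- data.frame(gene = colnames(norm), cluster = l, log2FC = lfc,
                      pct_in = pct_in, pct_out = pct_out, p = p,
                      fdr = p.adjust(p, "BH"), row.names = NULL)
    out[[as.character(l)]] <- tab[order(-tab$log2FC), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Vectorised tie-corrected normal-approximation Wilcoxon over all genes.
wilcox_vec <- function(ranks, tie_term, in_group) {
  m <- sum(in_group); n <- sum(!in_group); N <- m + n
  w <- colSums(ranks[in_group, , drop = FALSE]) - m * (m + 1) / 2
  mu <- m * n / 2
  sigma2 <- (m * n / 12) * ((N + 1) - tie_term / (N * (N - 1)))
  z <- ifelse(sigma2 > 0, (w - mu) / sqrt(sigma2), 0)
  p <- 2 * pnorm(-abs(z))
  p[sigma2 <= 0] <- 1
  pmin(1, p)
}
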