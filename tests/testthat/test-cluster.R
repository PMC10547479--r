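test_that("embedding exposes low-rank structure and passes externals through", {
  set.seed(1)
  # rank-2 data: cells mix two gene programmes
  w <- cbind(runif(80), runif(80))
  prog <- rbind(runif(40, 1, 3), runif(40, 1, 3))
  norm <- w %*% prog
  dimnames(norm) <- list(paste0("c", 1:80), paste0("g", 1:40))
  d <- make_norm_ged(norm)
  emb <- suppressWarnings(embed_cells(d, n_hvg = 40, n_pcs = 10))
  vars <- apply(emb, 2, var)
  expect_lt(sum(vars[3:10]), 1e-18 * sum(vars))

  emb2 <- suppressWarnings(embed_cells(d, n_hvg = 40, n_pcs = 10))
  expect_equal(abs(emb), abs(emb2), tolerance = 1e-12)  # sign-stable reruns

  ext <- matrix(rnorm(80 * 50), 80, 50)
  expect_identical(unname(embed_cells(d, external = ext)), ext)
  expect_error(embed_cells(d, external = ext[1:10, ]), "rows")
  expect_warning(embed_cells(d, n_hvg = 100, n_pcs = 5), "exceeds")
})

test_that("graph clustering separates blobs and is seed-deterministic", {
  blobs <- make_blobs(rbind(c(0, 0, 0, 0, 0), c(20, 0, 0, 0, 0)),
                      n_per = 60)
  lab <- cluster_cells(blobs$embedding, resolution = 0.8, seed = 3)
  expect_equal(length(unique(lab)), 2)
  expect_equal(adjusted_rand_index(lab, blobs$labels), 1)
  expect_identical(lab, cluster_cells(blobs$embedding, 0.8, seed = 3))

  one <- make_blobs(rbind(c(0, 0, 0, 0, 0)), n_per = 80)
  lab1 <- cluster_cells(one$embedding, resolution = 0.2, seed = 3)
  expect_equal(length(unique(lab1)), 1)

  tiny <- make_blobs(rbind(c(0, 0, 0, 0, 0)), n_per = 10)
  expect_warning(cluster_cells(tiny$embedding, 0.5, k_neighbors = 20,
                               seed = 1), "capped")
})

test_that("resolution selection maximises silhouette above the floor", {
  blobs <- make_blobs(rbind(c(0, 0, 0, 0, 0), c(15, 0, 0, 0, 0),
                            c(0, 15, 0, 0, 0)), n_per = 50)
  sel <- select_resolution(blobs$embedding, seed = 2)
  expect_equal(length(unique(sel$labels)), 3)
  expect_equal(adjusted_rand_index(sel$labels, blobs$labels), 1)
  # silhouette equals the brute-force definition
  i <- match(sel$resolution, sel$silhouette_table$resolution)
  expect_equal(sel$silhouette_table$mean_silhouette[i],
               brute_silhouette(sel$labels, blobs$embedding),
               tolerance = 1e-9)
  # stable labels across resolutions -> tie broken to the lowest admissible
  expect_equal(sel$resolution, 0.30)
  # raising the floor excludes lower resolutions from winning
  sel2 <- select_resolution(blobs$embedding, min_resolution = 0.50, seed = 2)
  expect_gte(sel2$resolution, 0.50)
  expect_error(select_resolution(blobs$embedding, resolutions = 0.5),
               "at least 2")
})

test_that("mean silhouette matches brute force on random labellings", {
  set.seed(7)
  for (rep in 1:3) {
    emb <- matrix(rnorm(120 * 4), 120, 4)
    labels <- sample(1:4, 120, replace = TRUE)
    expect_equal(mean_silhouette(labels, dist(emb)),
                 brute_silhouette(labels, emb), tolerance = 1e-9)
  }
  expect_identical(mean_silhouette(rep(1, 10), dist(matrix(rnorm(20), 10))),
                   -Inf)
})

test_that("cluster merging is strict, transitive and label-contiguous", {
  # one embedding point per cluster makes pseudo-bulk profiles explicit
  set.seed(11)
  basis <- qr.Q(qr(matrix(rnorm(30 * 3), 30, 3)))
  a <- basis[, 1]
  c <- basis[, 2]
  b <- sqrt(0.55) * a + sqrt(0.45) * c   # cor(a,b) ~ .74, cor(b,c) ~ .67
  emb <- rbind(a, b, c)
  labels <- c(0, 1, 2)
  r_ab <- cor(a, b); r_bc <- cor(b, c); r_ac <- cor(a, c)
  expect_gt(r_ab, 0.6); expect_gt(r_bc, 0.6); expect_lt(r_ac, 0.6)

  res <- merge_clusters(emb, labels, r_threshold = 0.6)
  expect_equal(length(unique(res$labels)), 1)   # transitive closure
  expect_true(all(res$history$r > 0.6))
  # independent oracle: connected components of the thresholded pair graph
  g <- igraph::graph_from_adjacency_matrix(
    (cor(t(emb)) > 0.6) * 1, mode = "undirected", diag = FALSE)
  expect_equal(length(unique(res$labels)),
               igraph::components(g)$no)

  # boundary semantics: a pair exactly at the threshold is NOT merged
  res_at <- merge_clusters(emb[c(1, 2), ], c(0, 1), r_threshold = r_ab)
  expect_equal(length(unique(res_at$labels)), 2)
  res_below <- merge_clusters(emb[c(1, 2), ], c(0, 1),
                              r_threshold = r_ab - 1e-6)
  expect_equal(length(unique(res_below$labels)), 1)

  # merging never increases the cluster count; labels stay contiguous
  blobs <- make_blobs(rbind(c(0, 0, 0, 0, 0), c(30, 0, 0, 0, 0)), n_per = 40)
  split4 <- rep(0:3, each = 20)
  merged <- merge_clusters(blobs$embedding, split4)
  expect_lte(length(unique(merged$labels)), 4)
  expect_identical(sort(unique(merged$labels)),
                   seq_len(length(unique(merged$labels))) - 1L)
  single <- merge_clusters(blobs$embedding, rep(0, 80))
  expect_identical(unique(single$labels), 0L)
})

test_that("clusters from one distribution merge while distinct ones do not", {
  # heterogeneous centroids: pseudo-bulk Pearson compares profile shapes
  blobs <- make_blobs(rbind(c(6, -4, 10, 0, -8), c(-10, 8, 0, 12, 4)),
                      n_per = 60)
  # artificially split the first blob in half
  labels <- c(rep(0:1, each = 30), rep(2, 60))
  res <- merge_clusters(blobs$embedding, labels)
  expect_equal(length(unique(res$labels)), 2)
  expect_equal(adjusted_rand_index(res$labels, blobs$labels), 1)
})

test_that("the two-step myeloid filter keeps macrophages and drops NK cells", {
  set.seed(5)
  n <- 240
  genes <- c("PTPRC", "CD68", "GZMB", "GNLY", "CCR7", paste0("g", 1:80))
  counts <- matrix(rpois(n * length(genes), 2), n, length(genes),
                   dimnames = list(paste0("c", 1:n), genes))
  grp <- rep(c("mac", "nk", "other"), each = 80)
  # macrophages: PTPRC+CD68+; NK contaminate the kept fraction: PTPRC+,
  # CD68+ (pass step 1 inside the mac cluster pool) but GZMB/GNLY-high
  counts[, "PTPRC"] <- ifelse(grp %in% c("mac", "nk"), 8L, 0L)
  counts[, "CD68"] <- ifelse(grp %in% c("mac", "nk"), 6L, 0L)
  counts[, c("GZMB", "GNLY")] <- 0L
  counts[grp == "nk", c("GZMB", "GNLY")] <- 60L
  counts[grp == "nk", paste0("g", 1:20)] <- 50L   # separates NK on recluster
  counts[, "CCR7"] <- 0L
  d <- make_ged(counts)
  first_round <- rep(c(0, 0, 1), each = 80)   # mac+nk together, other apart
  kept <- suppressWarnings(myeloid_filter(d, first_round,
                                          detect_frac = 0.25, seed = 1))
  expect_true(all(cell_ids(kept) %in% paste0("c", which(grp == "mac"))))
  expect_gt(n_cells(kept), 60)

  expect_error(suppressWarnings(
    myeloid_filter(d, first_round, keep_markers = c("ABSENT1"))),
    "no keep marker")
  w <- capture_warnings(
    myeloid_filter(d, first_round, keep_markers = c("PTPRC", "CD68", "NOPE"),
                   seed = 1))
  expect_true(any(grepl("NOPE", w)))
})

test_that("marker ranking reports exclusive genes and flips under swap", {
  set.seed(9)
  n <- 60
  norm <- matrix(abs(rnorm(n * 20, 1, 0.2)), n, 20,
                 dimnames = list(paste0("c", 1:n), paste0("g", 1:20)))
  labels <- rep(c(0, 1), each = 30)
  norm[labels == 1, "g1"] <- 0
  norm[labels == 0, "g1"] <- 3   # exclusive to cluster 0
  d <- make_norm_ged(norm)
  tab <- rank_markers(d, labels)
  row <- tab[tab$gene == "g1" & tab$cluster == 0, ]
  expect_equal(row$pct_in, 1)
  expect_equal(row$pct_out, 0)
  expect_gt(row$log2FC, 1)
  expect_lt(row$fdr, 0.05)
  # antisymmetry
  row1 <- tab[tab$gene == "g1" & tab$cluster == 1, ]
  expect_equal(row1$log2FC, -row$log2FC, tolerance = 1e-12)
  expect_gte(min(tab$fdr - tab$p, na.rm = TRUE), -1e-12)
  # rows sorted by log2FC within cluster
  for (cl in unique(tab$cluster)) {
    expect_false(is.unsorted(rev(tab$log2FC[tab$cluster == cl])))
  }
})

test_that("marker p-values match wilcox.test and behave under the null", {
  set.seed(13)
  norm <- matrix(abs(rnorm(50 * 30, 1, 0.5)), 50, 30,
                 dimnames = list(paste0("c", 1:50), paste0("g", 1:30)))
  norm[sample(length(norm), 300)] <- 0   # ties
  labels <- rep(c(0, 1), each = 25)
  d <- make_norm_ged(norm)
  tab <- rank_markers(d, labels)
  for (g in c("g1", "g7", "g23")) {
    ref <- wilcox.test(norm[labels == 0, g], norm[labels == 1, g],
                       exact = FALSE, correct = FALSE)$p.value
    expect_equal(tab$p[tab$gene == g & tab$cluster == 0], ref,
                 tolerance = 1e-9)
  }
  # under the null, few genes reach FDR < 0.05
  hits <- vapply(1:3, function(s) {
    set.seed(s)
    nm <- matrix(abs(rnorm(80 * 40, 1, 0.5)), 80, 40,
                 dimnames = list(paste0("c", 1:80), paste0("g", 1:40)))
    dd <- make_norm_ged(nm)
    tt <- rank_markers(dd, rep(c(0, 1), each = 40))
    sum(tt$fdr < 0.05, na.rm = TRUE) / 2
  }, numeric(1))
  expect_lte(mean(hits), 2)

  tiny <- make_norm_ged(norm[1:5, ])
  expect_warning(rank_markers(tiny, c(0, 0, 0, 1, 1)), "fewer than 3")
})
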