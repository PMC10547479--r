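two_group_toy <- function() {
  # tissue with 10 A cells and 10 B cells over 5 genes, explicit normalized
  norm <- matrix(1, 20, 5, dimnames = list(paste0("c", 1:20),
                                           paste0("g", 1:5)))
  norm[1:10, "g2"] <- 2                    # up in A
  norm[, "g3"] <- rep(c(1.5, 0.5), 10)     # equal in both groups
  norm[11:20, "g4"] <- 0                   # detected only in A
  d <- make_norm_ged(norm, tissue = "t1")
  list(d = d, A = rep(c(TRUE, FALSE), each = 10),
       B = rep(c(FALSE, TRUE), each = 10))
}

test_that("differential statistics match their definitions per tissue", {
  toy <- two_group_toy()
  st <- differential_stats(list(toy$d), list(toy$A), list(toy$B))
  s <- st$summary
  expect_equal(s$mean_log2FC[s$gene == "g1"], 0, tolerance = 1e-9)
  expect_equal(s$mean_log2FC[s$gene == "g3"], 0, tolerance = 1e-9)
  expect_gt(s$mean_log2FC[s$gene == "g2"], 0)
  expect_equal(s$mean_diff_pct[s$gene == "g4"], 1)
  long <- st$per_tissue
  expect_equal(long$diff_pct[long$gene == "g4"], 1)
  # z-scaled diff.pct has mean 0 and unit SD across genes
  expect_equal(mean(s$z_diff_pct), 0, tolerance = 1e-12)
  expect_equal(sd(s$z_diff_pct), 1, tolerance = 1e-12)
  # one-tailed upper p and BH FDR
  expect_equal(s$p_z, pnorm(s$z_diff_pct, lower.tail = FALSE))
  expect_gte(min(s$fdr - s$p_z), 0)
})

test_that("detection-fraction difference is pct_A minus pct_B", {
  norm <- matrix(0, 10, 1, dimnames = list(paste0("c", 1:10), "g1"))
  norm[c(1:4, 6), "g1"] <- 1    # 4/5 in A, 1/5 in B
  d <- make_norm_ged(norm)
  st <- differential_stats(list(d), list(rep(c(TRUE, FALSE), each = 5)),
                           list(rep(c(FALSE, TRUE), each = 5)))
  expect_equal(st$per_tissue$pct_A, 0.8)
  expect_equal(st$per_tissue$pct_B, 0.2)
  expect_equal(st$per_tissue$diff_pct, 0.6)
})

test_that("tissues missing a group are skipped; all skipped is an error", {
  toy <- two_group_toy()
  empty_mask <- rep(FALSE, 20)
  expect_warning(
    st <- differential_stats(list(toy$d, toy$d), list(toy$A, empty_mask),
                             list(toy$B, toy$B)),
    "lacks cells")
  expect_equal(unique(st$summary$n_tissues), 1L)
  expect_error(
    suppressWarnings(differential_stats(list(toy$d), list(empty_mask),
                                        list(toy$B))),
    "all tissues")
})

test_that("signature cutoffs are strict and directions disjoint", {
  fake <- structure(list(summary = data.frame(
    gene = paste0("g", 1:6),
    mean_log2FC = c(0.5, 0.51, 1.0, -1.0, -0.51, 2.0),
    mean_diff_pct = rnorm(6),
    z_diff_pct = c(2.5, 1.96, 2.5, -2.5, -2.0, 2.0),
    p_z = runif(6), fdr = c(0.2, 0.01, 0.01, 0.01, 0.01, 0.01),
    n_tissues = 6L)), class = "diff_stats")
  up <- derive_cross_tissue_signature(fake, direction = "up")
  expect_identical(up$genes, c("g3", "g6"))   # 0.5 and z=1.96 excluded
  dn <- derive_cross_tissue_signature(fake, direction = "down")
  expect_identical(dn$genes, c("g4", "g5"))
  expect_length(intersect(up$genes, dn$genes), 0)
  withfdr <- derive_cross_tissue_signature(fake, direction = "up",
                                           fdr_thresh = 0.05)
  expect_identical(withfdr$genes, c("g3", "g6"))
  fake$summary$fdr[3] <- 0.2
  expect_identical(derive_cross_tissue_signature(fake, direction = "up",
                                                 fdr_thresh = 0.05)$genes,
                   "g6")
  fake$summary$mean_log2FC <- abs(fake$summary$mean_log2FC) * 0.1
  expect_warning(res <- derive_cross_tissue_signature(fake,
                                                      direction = "up"),
                 "no gene")
  expect_length(res$genes, 0)
})

test_that("degenerate diff.pct spread defines z as zero everywhere", {
  norm <- matrix(1, 10, 4, dimnames = list(paste0("c", 1:10),
                                           paste0("g", 1:4)))
  d <- make_norm_ged(norm)
  st <- differential_stats(list(d), list(rep(c(TRUE, FALSE), each = 5)),
                           list(rep(c(FALSE, TRUE), each = 5)))
  expect_true(all(st$summary$z_diff_pct == 0))
  up <- suppressWarnings(derive_cross_tissue_signature(st, direction = "up"))
  expect_length(up$genes, 0)
})

test_that("module scores vanish on constants and ignore global shifts", {
  norm <- matrix(2, 30, 40, dimnames = list(paste0("c", 1:30),
                                            paste0("g", 1:40)))
  d <- make_norm_ged(norm)
  sc <- module_score(d, gene_set("s", c("g1", "g2")), n_bins = 4,
                     n_ctrl = 10, seed = 1)
  expect_true(all(abs(sc) < 1e-12))

  set.seed(2)
  norm2 <- matrix(abs(rnorm(30 * 40, 2, 0.5)), 30, 40,
                  dimnames = dimnames(norm))
  d2 <- make_norm_ged(norm2)
  d3 <- make_norm_ged(norm2 + 1)
  s2 <- module_score(d2, gene_set("s", c("g1", "g5")), n_bins = 4,
                     n_ctrl = 10, seed = 3)
  s3 <- module_score(d3, gene_set("s", c("g1", "g5")), n_bins = 4,
                     n_ctrl = 10, seed = 3)
  expect_equal(unname(s2), unname(s3), tolerance = 1e-12)
  # deterministic under a fixed seed
  expect_identical(s2, module_score(d2, gene_set("s", c("g1", "g5")),
                                    n_bins = 4, n_ctrl = 10, seed = 3))
  expect_warning(module_score(d2, gene_set("s", c("g1", "NOT_THERE")),
                              n_bins = 4, n_ctrl = 10, seed = 1), "absent")
  expect_error(module_score(d2, gene_set("s", "NOT_THERE"), seed = 1),
               "no gene")
})

test_that("module scores recover a planted population shift", {
  delta <- 0.6
  diffs <- vapply(1:5, function(seed) {
    set.seed(seed)
    norm <- matrix(abs(rnorm(200 * 100, 2, 0.4)), 200, 100,
                   dimnames = list(paste0("c", 1:200), paste0("g", 1:100)))
    shifted <- 1:100 %in% 1:10
    norm[1:100, shifted] <- norm[1:100, shifted] + delta
    d <- make_norm_ged(norm)
    sc <- module_score(d, gene_set("s", paste0("g", 1:10)), seed = seed)
    mean(sc[1:100]) - mean(sc[101:200])
  }, numeric(1))
  expect_lt(abs(mean(diffs) - delta), 0.05)
})

test_that("elbow selection matches brute-force perpendicular distances", {
  counts <- c(A = 100, B = 90, C = 80, D = 10, E = 9, F = 8)
  panels <- unlist(lapply(names(counts), function(g) {
    replicate(counts[[g]], g, simplify = FALSE)
  }), recursive = FALSE)
  res <- elbow_select_markers(panels, gene_set("sig", names(counts)))
  # brute-force distances from the (rank, count) line
  pts <- cbind(1:6, as.numeric(sort(counts, decreasing = TRUE)))
  v <- pts[6, ] - pts[1, ]
  dists <- apply(pts, 1, function(p) {
    w <- p - pts[1, ]
    abs(v[1] * w[2] - v[2] * w[1]) / sqrt(sum(v^2))
  })
  expect_equal(res$occurrence$distance, unname(dists), tolerance = 1e-12)
  expect_identical(res$kept_genes, names(counts)[seq_len(which.max(dists))])
  expect_identical(res$markers$genes, res$kept_genes)
})

test_that("elbow intersects with the signature and handles flat counts", {
  panels <- replicate(50, c("A", "B", "C", "D"), simplify = FALSE)
  res <- suppressWarnings(elbow_select_markers(panels,
                                               gene_set("sig", c("B", "Z"))))
  expect_true(all(res$kept_genes %in% c("A", "B", "C", "D")))
  expect_warning(
    flat <- elbow_select_markers(panels, gene_set("sig", c("A", "B"))),
    "equal")
  expect_identical(flat$kept_genes, "A")   # first by gene id
  # explicit intersection semantics
  res2 <- elbow_select_markers(list(c("X", "X2"), "X", "Y", "X"),
                               gene_set("sig", c("Y", "Z")))
  expect_true(all(res2$markers$genes %in% c("Y", "Z")))
  expect_error(elbow_select_markers(list(), gene_set("s", "A")), "non-empty")
})

test_that("hypergeometric enrichment equals the combinatorial tail", {
  uni <- paste0("g", 1:20)
  res <- hypergeometric_enrichment(gene_set("q", paste0("g", 1:5)),
                                   gene_set("cat", paste0("g", 1:10)), uni)
  expect_equal(res$overlap, 5)
  expect_equal(res$p, choose(10, 5) / choose(20, 5), tolerance = 1e-9)

  none <- hypergeometric_enrichment(gene_set("q", paste0("g", 1:5)),
                                    gene_set("cat", paste0("g", 11:15)), uni)
  expect_equal(none$overlap, 0)
  expect_equal(none$p, 1)

  all_cat <- hypergeometric_enrichment(gene_set("q", paste0("g", 1:5)),
                                       gene_set("cat", uni), uni)
  expect_equal(all_cat$overlap, 5)
  expect_equal(all_cat$p, 1)

  expect_warning(hypergeometric_enrichment(
    gene_set("q", c("g1", "OUTSIDE")), gene_set("cat", "g1"), uni),
    "outside")
  expect_error(hypergeometric_enrichment(gene_set("q", "g1"),
                                         gene_set("cat", "g1"),
                                         character(0)), "empty")
})

test_that("pathway sub-signatures respect strict NES/p cutoffs", {
  enr <- enrichment_table(
    term = c("at_cutoff", "passing", "weak_p"),
    NES = c(1.6, 1.8, 2.0),
    p_adjust = c(0.01, 0.01, 0.05),
    leading_edge = list(c("A", "B"), c("B", "C"), c("D")))
  sig <- gene_set("sig", c("A", "B", "C", "D"))
  sub <- derive_pathway_subsignature(sig, enr)
  expect_identical(sort(sub$genes), c("B", "C"))   # only "passing" qualifies
  expect_warning(
    none <- derive_pathway_subsignature(gene_set("sig", "Z"), enr),
    "no leading-edge")
  expect_length(none$genes, 0)
})
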