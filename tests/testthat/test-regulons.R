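ranked_ged <- function(expr_rows) {
  # expr_rows: cells x genes numeric, higher = more expressed
  d <- make_norm_ged(expr_rows)
  d
}

test_that("AUC hits its extremes when regulon genes top or miss the ranking", {
  G <- 20
  expr <- matrix(rep(G:1, each = 2), 2, G, byrow = FALSE,
                 dimnames = list(c("c1", "c2"), paste0("g", 1:G)))
  d <- ranked_ged(expr)
  top3 <- gene_set("top", paste0("g", 1:3))      # occupy ranks 1..3
  act <- aucell_score(d, top3, top_fraction = 0.25, seed = 1)
  expect_equal(unname(act$auc[, "top"]), c(1, 1))

  bottom <- gene_set("bottom", paste0("g", 16:20))  # outside top 5 ranks
  act2 <- aucell_score(d, bottom, top_fraction = 0.25, seed = 1)
  expect_equal(unname(act2$auc[, "bottom"]), c(0, 0))

  expect_error(aucell_score(d, top3, top_fraction = 0), "top_fraction")
  expect_warning(aucell_score(d, list(top3, gene_set("gone", "ZZ")),
                              top_fraction = 0.25, seed = 1), "skipped")
})

test_that("AUC equals the enumerated recovery-curve oracle", {
  set.seed(21)
  for (rep in 1:50) {
    G <- sample(10:50, 1)
    n_set <- sample(2:min(8, G - 1), 1)
    expr <- matrix(sample(G) + runif(G) * 0, 1, G,
                   dimnames = list("c1", paste0("g", 1:G)))
    set_genes <- paste0("g", sample(G, n_set))
    frac <- runif(1, 0.1, 0.9)
    act <- aucell_score(ranked_ged(expr), gene_set("r", set_genes),
                        top_fraction = frac, seed = rep)
    m <- ceiling(frac * G)
    ranking <- colnames(expr)[order(-expr[1, ])]
    expect_equal(unname(act$auc[1, 1]),
                 brute_auc(ranking, set_genes, m), tolerance = 1e-12)
  }
})

test_that("promoting a regulon gene into the top ranks never lowers the AUC", {
  set.seed(4)
  G <- 30
  expr <- matrix(runif(G), 1, G, dimnames = list("c", paste0("g", 1:G)))
  set_genes <- paste0("g", 1:4)
  base <- aucell_score(ranked_ged(expr), gene_set("r", set_genes),
                       top_fraction = 0.3, seed = 1)$auc[1, 1]
  expr2 <- expr
  expr2[1, "g1"] <- max(expr) + 1
  lifted <- aucell_score(ranked_ged(expr2), gene_set("r", set_genes),
                         top_fraction = 0.3, seed = 1)$auc[1, 1]
  expect_gte(lifted, base)
})

test_that("binarisation splits clear bimodal activity and flags degeneracy", {
  set.seed(6)
  auc <- c(rnorm(120, 0.1, 0.02), rnorm(80, 0.8, 0.02))
  res <- binarize_activity(auc)
  expect_identical(res$flag, "ok")
  expect_gt(res$threshold, 0.2)
  expect_lt(res$threshold, 0.7)
  expect_identical(unname(res$active), c(rep(FALSE, 120), rep(TRUE, 80)))
  # threshold monotonicity: anything above an active cell is active
  expect_true(all(auc[res$active] >= res$threshold))
  expect_true(all(auc[!res$active] < res$threshold))

  const <- binarize_activity(rep(0.4, 50))
  expect_identical(const$flag, "constant")
  expect_false(any(const$active))

  uni <- binarize_activity(rnorm(300, 0.5, 0.01))
  expect_identical(uni$flag, "unimodal")
  expect_false(any(uni$active))

  expect_error(binarize_activity(1:5 / 10), "at least 10")
})

test_that("the mixture threshold agrees with an independent mixture fit", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  set.seed(8)
  auc <- c(rnorm(150, 0.15, 0.05), rnorm(150, 0.7, 0.08))
  res <- binarize_activity(auc)
  fit <- mclust::Mclust(auc, G = 2, modelNames = "V", verbose = FALSE)
  agree <- mean((fit$classification == 2) == res$active)
  expect_gte(max(agree, 1 - agree), 0.98)
})

test_that("retention keeps regulons active in enough cells and tissues", {
  frac_mat <- function(fracs, n = 1000) {
    vapply(fracs, function(f) {
      c(rep(TRUE, round(f * n)), rep(FALSE, n - round(f * n)))
    }, logical(n))
  }
  # regulon A at exactly 10% in exactly 4 tissues -> kept;
  # regulon B at 9% everywhere -> dropped
  actives <- lapply(1:6, function(t) {
    m <- cbind(A = frac_mat(if (t <= 4) 0.10 else 0.05)[, 1],
               B = frac_mat(0.09)[, 1])
    m
  })
  kept <- retention_filter(actives, min_frac = 0.10, min_tissues = 4)
  expect_identical(kept, "A")
  expect_warning(
    kept2 <- retention_filter(actives[1:2], min_frac = 0.10,
                              min_tissues = 4),
    "requiring 2")
  expect_identical(kept2, "A")
})

test_that("DOR matches hand evaluation of the printed formula", {
  expect_equal(dor_from_counts(100, 100, 0, 0),
               (100.05 * 100.05) / (0.05 * 0.05))
  expect_equal(dor_from_counts(100, 100, 0, 0), 4004001, tolerance = 1e-9)
  expect_equal(dor_from_counts(37, 11, 37, 11), 1)
  expect_equal(dor_from_counts(0, 0, 0, 0), 1)

  # median across tissues and exclusion of tissues missing a class
  act <- cbind(R = c(TRUE, TRUE, FALSE, FALSE))
  lab_ok <- c("MAM_pos", "MAM_neg", "MAM_pos", "MAM_neg")
  lab_bad <- c("MAM_pos", "MAM_pos", "MAM_pos", "MAM_pos")
  counts <- list(act, act, act)
  labs <- list(lab_ok, lab_ok, lab_bad)
  expect_warning(res <- compute_dor(counts, labs), "misses")
  expect_true(is.na(res$per_tissue[3, "R"]))
  dor1 <- dor_from_counts(1, 1, 1, 1)
  expect_equal(unname(res$median_dor["R"]), dor1)
})

test_that("median DOR summarises per-tissue values", {
  mk <- function(tp, tn, fp, fn) {
    act <- c(rep(TRUE, tp), rep(FALSE, fn), rep(TRUE, fp), rep(FALSE, tn))
    lab <- c(rep("MAM_pos", tp + fn), rep("MAM_neg", fp + tn))
    list(active = cbind(R = act), labels = lab)
  }
  tissues <- list(mk(10, 10, 1, 1), mk(5, 5, 5, 5), mk(20, 20, 1, 1))
  res <- compute_dor(lapply(tissues, `[[`, "active"),
                     lapply(tissues, `[[`, "labels"))
  expect_equal(unname(res$median_dor["R"]),
               median(res$per_tissue[, "R"]))
})

test_that("specificity equals direct evaluation of the printed formula", {
  uni <- paste0("g", 1:200)
  up <- gene_set("up", paste0("g", 1:20))
  dn <- gene_set("dn", paste0("g", 21:40))
  reg <- gene_set("reg", paste0("g", c(1:5, 101:105)))   # overlaps up only
  lfc <- setNames(rep(0.8, 200), uni)
  got <- regulon_specificity(reg, up, dn, lfc, uni)
  p_up <- phyper(5 - 1, 20, 180, 10, lower.tail = FALSE)
  p_dn <- phyper(-1, 20, 180, 10, lower.tail = FALSE)
  manual <- ((-log(p_up)) - (-log(p_dn))) * (5 * 0.8 - 0) / 10
  expect_equal(got, manual, tolerance = 1e-12)

  # swapping the signatures flips the sign of BOTH factors, so the printed
  # product is swap-invariant; mirror-symmetric overlaps score exactly zero
  swapped <- regulon_specificity(reg, dn, up, lfc, uni)
  expect_equal(swapped, got, tolerance = 1e-12)
  mirror <- gene_set("mirror", paste0("g", c(1:5, 21:25)))
  expect_equal(regulon_specificity(mirror, up, dn, lfc, uni), 0,
               tolerance = 1e-12)

  # no overlap with either signature scores zero
  lone <- gene_set("lone", paste0("g", 150:160))
  expect_equal(regulon_specificity(lone, up, dn, lfc, uni), 0)
  expect_warning(
    out <- regulon_specificity(gene_set("off", "NOT_IN"), up, dn, lfc, uni),
    "no gene")
  expect_true(is.na(out))
})

test_that("two-segment regressions recover exact linear relations", {
  labels <- rep(c("transitional", "MAM_neg", "MAM_pos"), each = 10)
  score <- c(seq(0, 1, length.out = 10), seq(1, 2, length.out = 10),
             seq(2, 3, length.out = 10))
  auc <- 2 * score + 1
  res <- trajectory_slopes(auc, score, labels)
  expect_equal(res$slope1, 2, tolerance = 1e-9)
  expect_equal(res$intercept1, 1, tolerance = 1e-9)
  expect_equal(res$slope2, 2, tolerance = 1e-9)

  const <- trajectory_slopes(rep(0.5, 30), score, labels)
  expect_equal(const$slope1, 0, tolerance = 1e-12)

  expect_warning(
    degen <- trajectory_slopes(auc, rep(1, 30), labels),
    "zero")
  expect_true(is.na(degen$slope1))
  expect_error(trajectory_slopes(auc[1:3], score[1:3],
                                 c("transitional", "MAM_neg", "MAM_pos")),
               "fewer than 3")
})

test_that("a regulon driving the MAM+ transition steepens its second segment", {
  wins <- vapply(1:5, function(seed) {
    set.seed(seed)
    n <- 120
    labels <- rep(c("transitional", "MAM_neg", "MAM_pos"), each = n / 3)
    t <- c(runif(n / 3, 0, 1), runif(n / 3, 1, 2), runif(n / 3, 2, 3))
    score <- t + rnorm(n, 0, 0.1)
    auc <- pmax(0, t - 1.8) * 0.3 + rnorm(n, 0, 0.03)  # late activation
    res <- trajectory_slopes(auc, score, labels)
    res$slope2 > res$slope1
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("permuted labels send planted DOR back to neutral", {
  set.seed(30)
  n <- 600
  lab <- rep(c("MAM_pos", "MAM_neg"), each = n / 2)
  active <- cbind(R = c(rep(TRUE, 250), rep(FALSE, 50),
                        rep(TRUE, 30), rep(FALSE, 270)))
  planted <- compute_dor(list(active), list(lab))$median_dor["R"]
  expect_gt(planted, 10)
  inside <- vapply(1:40, function(i) {
    perm <- sample(lab)
    d <- compute_dor(list(active), list(perm))$median_dor["R"]
    d >= 0.5 && d <= 2
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})
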