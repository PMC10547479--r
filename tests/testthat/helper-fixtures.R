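# Shared fixture builders and independent oracles.

# Minimal dataset wrapper: counts is cells x genes (dense or sparse).
make_ged <- function(counts, tissue = "lung", condition = "control",
                     subject = "S1", population = NA_character_, ...) {
  n <- nrow(counts)
  if (is.null(rownames(counts)) && n > 0) {
    rownames(counts) <- paste0("c", seq_len(n))
  }
  if (is.null(colnames(counts))) colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  meta <- data.frame(tissue = rep_len(tissue, n),
                     subject_id = rep_len(subject, n),
                     condition = rep_len(condition, n),
                     population_label = rep_len(population, n),
                     stringsAsFactors = FALSE, ...)
  if (!anyDuplicated(rownames(counts))) rownames(meta) <- rownames(counts)
  ged(counts, meta)
}

# Dataset with an explicit normalized layer.
make_norm_ged <- function(norm_mat, ...) {
  d <- make_ged(matrix(1, nrow(norm_mat), ncol(norm_mat),
                       dimnames = dimnames(norm_mat)), ...)
  d$normalized <- mamscope:::as_csparse(norm_mat)
  dimnames(d$normalized) <- dimnames(d$counts)
  d
}

# Gaussian blob embedding with generative labels.
make_blobs <- function(centers, n_per = 50, d = 5, sd = 1, seed = 42) {
  set.seed(seed)
  emb <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    sweep(matrix(rnorm(n_per * d, sd = sd), n_per, d), 2,
          centers[i, ], "+")
  }))
  rownames(emb) <- paste0("c", seq_len(nrow(emb)))
  list(embedding = emb, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# Brute-force mean silhouette straight from the definition.
brute_silhouette <- function(labels, emb) {
  n <- nrow(emb)
  dm <- as.matrix(dist(emb))
  widths <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(dm[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(dm[i, labels == l])
    }, numeric(1)))
    if (sum(own) == 1) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  mean(widths)
}

# Brute-force recovery-curve AUC: enumerate the step curve explicitly.
brute_auc <- function(ranking, set_genes, m) {
  hits <- vapply(seq_len(m), function(r) {
    sum(ranking[seq_len(r)] %in% set_genes)
  }, numeric(1))
  s <- length(set_genes)
  max_area <- sum(pmin(seq_len(m), s))
  sum(hits) / max_area
}

# Exact two-sided rank-sum p by enumerating every split of the pooled data.
enum_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(m)])
  splits <- utils::combn(length(pooled), m)
  stats <- apply(splits, 2, function(idx) sum(r[idx]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Transition model with a hand-specified stochastic matrix.
make_model <- function(P, ids = NULL) {
  if (is.null(ids)) ids <- paste0("c", seq_len(nrow(P)))
  dimnames(P) <- list(ids, ids)
  structure(list(P = mamscope:::as_csparse(P), k = 2, n_pcs = ncol(P),
                 cell_ids = ids),
            class = "transition_model")
}

# Small simulation config reused across tests (fast but structurally valid).
small_sim_config <- function(seed = 1, ...) {
  sim_config(n_tissues = 2, cells_per_tissue = 150, n_genes = 600,
             seed = seed, ...)
}
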