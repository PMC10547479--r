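#' Random-walk transition matrix from a diffusion-map kernel
#'
#' Builds a symmetrised k-nearest-neighbour graph on the first `n_pcs`
#' embedding components, with `k = max(2, ceiling(k_frac * n))` (capped at
#' n - 1), applies a locally scaled Gaussian kernel `w_ij = exp(-d_ij^2 /
#' (sigma_i sigma_j))` where `sigma_i` is the distance to the
#' `ceiling(k/2)`-th neighbour (floored at machine-epsilon scale for
#' duplicate points), density-normalises the kernel (dividing by the row-sum
#' products) and row-normalises to a stochastic matrix.  Self-transitions
#' are excluded (zero diagonal).
#'
#' @param embedding cells x d numeric matrix with cell ids as row names.
#' @param n_pcs number of leading components to use (all, with a warning, if
#'   fewer are available).
#' @param k_frac neighbourhood size as a fraction of the cell count.
#' @return object of class `transition_model`: list with `P` (sparse
#'   row-stochastic matrix), `k`, `n_pcs`, `cell_ids`.
#' @export
transition_matrix <- function(embedding, n_pcs = 50, k_frac = 0.10) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n < 3) stop("need at least 3 cells")
  if (ncol(embedding) < n_pcs) {
    warning("embedding has only ", ncol(embedding), " components; using all")
    n_pcs <- ncol(embedding)
  }
  emb <- embedding[, seq_len(n_pcs), drop = FALSE]
  k <- min(max(2, ceiling(k_frac * n)), n - 1)
  nn <- knn_indices(emb, k)
  sigma <- nn$dist[, ceiling(k / 2)]
  floor_sigma <- sqrt(.Machine$double.eps)
  if (any(sigma < floor_sigma)) {
    warning("duplicate or near-duplicate points; local bandwidth floored")
    sigma <- pmax(sigma, floor_sigma)
  }
  i <- rep(seq_len(n), k)
  j <- as.vector(nn$idx)
  d <- as.vector(nn$dist)
  w <- exp(-d^2 / (sigma[i] * sigma[j]))
  W <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  W <- pmax_sparse(W, Matrix::t(W))  # symmetrise the kNN graph
  q <- Matrix::rowSums(W)
  if (any(q == 0)) {
    # numerically isolated cells (e.g. whose neighbours collapse to
    # duplicates): fall back to uniform weight over their kNN
    warning(sum(q == 0), " cell(s) with zero kernel mass; uniform fallback")
    for (z in which(q == 0)) W[z, nn$idx[z, ]] <- 1
    W <- pmax_sparse(W, Matrix::t(W))
    q <- Matrix::rowSums(W)
  }
  W <- Matrix::Diagonal(x = 1 / q) %*% W %*% Matrix::Diagonal(x = 1 / q)
  rs <- Matrix::rowSums(W)
  P <- Matrix::Diagonal(x = 1 / rs) %*% W
  P <- as(P, "CsparseMatrix")
  ids <- rownames(embedding)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  dimnames(P) <- list(ids, ids)
  structure(list(P = P, k = k, n_pcs = n_pcs, cell_ids = ids),
            class = "transition_model")
}

# elementwise maximum of two sparse matrices with identical dims
pmax_sparse <- function(A, B) {
  D <- A - B
  D@x <- pmax(D@x, 0)
  B + D
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model> ", length(x$cell_ids), " cells, k = ", x$k,
      ", n_pcs = ", x$n_pcs, "\n", sep = "")
  invisible(x)
}

#' Differentiation-propensity scores of MAM- cells
#'
#' For each MAM- cell `i`, `a = sum of P[i, j]` over MAM+ cells and `b` the
#' same over transitional cells; the propensity score is `a / (a + b)`: the
#' probability mass of transitioning to the MAM+ state relative to the mass
#' of transitioning to either destination.  Cells with `a + b = 0` are
#' flagged undefined (`NA`) and excluded from comparisons.  Scores are
#' additionally assigned to four equal-width display bins over \[0, 1\].
#'
#' @param model a [transition_matrix()] result.
#' @param labels character/factor per cell with values in
#'   `{"transitional", "MAM_neg", "MAM_pos"}`; any other value is an error.
#'   If the transitional class is absent, scores default to 1 wherever MAM+
#'   mass exists (with a warning).
#' @return object of class `propensity_result`: data.frame with `cell_id`,
#'   `score`, `bin`, plus attribute `n_undefined`.
#' @export
propensity_scores <- function(model, labels) {
  stopifnot(inherits(model, "transition_model"))
  labels <- as.character(labels)
  if (length(labels) != length(model$cell_ids)) {
    stop("labels length does not match the model's cell count")
  }
  allowed <- c("transitional", "MAM_neg", "MAM_pos")
  bad <- setdiff(unique(labels), allowed)
  if (length(bad)) stop("unknown label value(s): ", paste(bad, collapse = ", "))
  if (!"MAM_pos" %in% labels) stop("no MAM_pos cell present")
  if (!"MAM_neg" %in% labels) stop("no MAM_neg cell present")
  if (!"transitional" %in% labels) {
    warning("no transitional cell present; scores default to 1 where MAM+ ",
            "mass exists")
  }
  neg <- which(labels == "MAM_neg")
  a <- Matrix::rowSums(model$P[neg, labels == "MAM_pos", drop = FALSE])
  b <- Matrix::rowSums(model$P[neg, labels == "transitional", drop = FALSE])
  score <- ifelse(a + b > 0, a / (a + b), NA_real_)
  bin <- cut(score, breaks = seq(0, 1, by = 0.25), include.lowest = TRUE,
             labels = c("[0,0.25]", "(0.25,0.5]", "(0.5,0.75]", "(0.75,1]"))
  out <- data.frame(cell_id = model$cell_ids[neg], score = score, bin = bin,
                    stringsAsFactors = FALSE)
  attr(out, "n_undefined") <- sum(is.na(score))
  class(out) <- c("propensity_result", "data.frame")
  out
}

#' Compare propensity scores between conditions
#'
#' Two-sided Wilcoxon rank-sum test for every pair of condition labels
#' (exact for small tie-free samples, tie-corrected normal approximation
#' otherwise).  Undefined scores are excluded; groups with fewer than 2
#' defined scores are skipped with a warning.
#'
#' @param result a [propensity_scores()] result.
#' @param conditions per-MAM--cell condition labels aligned to
#'   `result$cell_id`.
#' @return data.frame with columns group_a, group_b, n_a, n_b, p.
#' @export
compare_conditions <- function(result, conditions) {
  stopifnot(length(conditions) == nrow(result))
  ok <- !is.na(result$score)
  groups <- split(result$score[ok], as.character(conditions)[ok])
  nms <- names(groups)
  small <- vapply(groups, length, integer(1)) < 2
  if (any(small)) {
    warning("group(s) with < 2 defined scores skipped: ",
            paste(nms[small], collapse = ", "))
    groups <- groups[!small]; nms <- names(groups)
  }
  if (length(groups) < 2) {
    return(data.frame(group_a = character(0), group_b = character(0),
                      n_a = integer(0), n_b = integer(0), p = numeric(0)))
  }
  rows <- list()
  for (i in seq_len(length(groups) - 1)) {
    for (j in (i + 1):length(groups)) {
      rows[[length(rows) + 1]] <- data.frame(
        group_a = nms[i], group_b = nms[j],
        n_a = length(groups[[i]]), n_b = length(groups[[j]]),
        p = rank_sum_p(groups[[i]], groups[[j]]))
    }
  }
  do.call(rbind, rows)
}

#' Uniform cell downsampling
#'
#' Samples cells uniformly without replacement down to `target`; datasets at
#' or below the target pass through unchanged.  Seeded and reproducible.
#'
#' @param dataset a [ged()].
#' @param target maximal cell count.
#' @param seed RNG seed.
#' @return the (possibly) downsampled [ged()].
#' @export
downsample_cells <- function(dataset, target = 25000, seed = 0) {
  stopifnot(target >= 1)
  if (n_cells(dataset) <= target) return(dataset)
  keep <- with_seed(seed, sort(sample.int(n_cells(dataset), target)))
  subset_ged(dataset, cells = keep)
}
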