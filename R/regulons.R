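#' Rank-recovery AUC regulon activity scores
#'
#' For every cell, genes are ranked by expression (normalized layer when
#' present, otherwise counts) in decreasing order, ties broken by a seeded
#' random permutation shared across cells.  With cutoff `m =
#' ceiling(top_fraction * G)`, the recovery curve counts regulon genes among
#' the top `r` ranks for `r = 1..m`; the AUC is the area under this step
#' curve divided by the maximal achievable area (all regulon genes occupying
#' the top ranks), so it lies in \[0, 1\].
#'
#' @param dataset a [ged()].
#' @param regulons list of [gene_set()] objects; a regulon with no gene in
#'   the dataset is skipped with a warning.
#' @param top_fraction fraction of the ranking considered (in (0, 1\]).
#' @param seed seed for the tie-breaking permutation.
#' @return object of class `regulon_activity`: list with `auc` (cells x
#'   regulons matrix), `top_fraction`, and empty `active`/`thresholds`
#'   slots to be filled by [binarize_activity()].
#' @export
aucell_score <- function(dataset, regulons, top_fraction = 0.05, seed = 0) {
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must lie in (0, 1]")
  }
  if (inherits(regulons, "gene_set")) regulons <- list(regulons)
  expr <- if (!is.null(dataset$normalized)) dataset$normalized else
    dataset$counts
  G <- ncol(expr)
  n <- nrow(expr)
  m <- ceiling(top_fraction * G)
  keep <- vapply(regulons, function(r) {
    any(r$genes %in% colnames(expr))
  }, logical(1))
  if (!all(keep)) {
    warning("regulon(s) without any dataset gene skipped: ",
            paste(vapply(regulons[!keep], `[[`, character(1), "name"),
                  collapse = ", "))
    regulons <- regulons[keep]
  }
  if (!length(regulons)) stop("no scorable regulon")
  tie_break <- with_seed(seed, sample.int(G))
  reg_cols <- lapply(regulons, function(r) {
    match(intersect(r$genes, colnames(expr)), colnames(expr))
  })
  dense <- as.matrix(expr)
  auc <- matrix(0, n, length(regulons),
                dimnames = list(rownames(expr),
                                vapply(regulons, `[[`, character(1), "name")))
  rank_of <- integer(G)
  for (c in seq_len(n)) {
    o <- order(-dense[c, ], tie_break)
    rank_of[o] <- seq_len(G)
    for (r in seq_along(reg_cols)) {
      rk <- rank_of[reg_cols[[r]]]
      rk <- rk[rk <= m]
      s <- length(reg_cols[[r]])
      max_area <- sum(pmin(seq_len(m), s))
      auc[c, r] <- if (length(rk)) sum(m - rk + 1) / max_area else 0
    }
  }
  structure(list(auc = auc, top_fraction = top_fraction, active = NULL,
                 thresholds = NULL, flags = NULL),
            class = "regulon_activity")
}

#' @export
print.regulon_activity <- function(x, ...) {
  cat("<regulon_activity> ", nrow(x$auc), " cells x ", ncol(x$auc),
      " regulons", if (!is.null(x$active)) " (binarised)", "\n", sep = "")
  invisible(x)
}

# Deterministic univariate 2-component Gaussian mixture EM, quantile init.
fit_gmm2 <- function(x, max_iter = 200, tol = 1e-8) {
  mu <- quantile(x, c(0.25, 0.75), names = FALSE)
  s <- rep(max(sd(x), 1e-6), 2)
  pi_k <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pi_k[1] * dnorm(x, mu[1], s[1])
    d2 <- pi_k[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    pi_k <- c(mean(g), 1 - mean(g))
    if (any(pi_k < 1e-8)) break
    mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    s <- sqrt(c(sum(g * (x - mu[1])^2) / sum(g),
                sum((1 - g) * (x - mu[2])^2) / sum(1 - g)))
    s <- pmax(s, 1e-6)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, sd = s, pi = pi_k)
}

#' Binarise an AUC activity column
#'
#' Fits a two-component Gaussian mixture to the AUC values and thresholds at
#' the point between the component means where the posterior
#' responsibilities are equal; cells at or above the threshold are active.
#' If the fitted component means differ by less than `min_sep` the
#' distribution is declared unimodal and all cells are inactive (degenerate
#' flag set); a constant vector is likewise flagged.
#'
#' @param auc numeric AUC vector (>= 10 cells).
#' @param min_sep minimal separation of component means.
#' @return list with `threshold` (`NA` when degenerate), `active` (logical
#'   vector) and `flag` (`"ok"`, `"unimodal"` or `"constant"`).
#' @export
binarize_activity <- function(auc, min_sep = 0.05) {
  if (length(auc) < 10) stop("need at least 10 cells to binarise")
  if (max(auc) - min(auc) < 1e-12) {
    return(list(threshold = NA_real_,
                active = rep(FALSE, length(auc)), flag = "constant"))
  }
  fit <- fit_gmm2(auc)
  lo <- which.min(fit$mu); hi <- which.max(fit$mu)
  if (abs(diff(fit$mu)) < min_sep || any(fit$pi < 1e-6)) {
    return(list(threshold = NA_real_,
                active = rep(FALSE, length(auc)), flag = "unimodal"))
  }
  post_diff <- function(t) {
    fit$pi[hi] * dnorm(t, fit$mu[hi], fit$sd[hi]) -
      fit$pi[lo] * dnorm(t, fit$mu[lo], fit$sd[lo])
  }
  grid <- seq(fit$mu[lo], fit$mu[hi], length.out = 512)
  vals <- vapply(grid, post_diff, numeric(1))
  cross <- which(diff(sign(vals)) != 0)
  threshold <- if (length(cross)) {
    stats::uniroot(post_diff, c(grid[cross[1]], grid[cross[1] + 1]))$root
  } else {
    mean(fit$mu)  # no crossing between the means: fall back to the midpoint
  }
  list(threshold = threshold, active = auc >= threshold, flag = "ok")
}

#' Binarise all regulons of an activity object
#'
#' @param activity a [aucell_score()] result.
#' @param min_sep see [binarize_activity()].
#' @return the activity object with `active`, `thresholds` and `flags`
#'   filled in.
#' @export
binarize_all <- function(activity, min_sep = 0.05) {
  stopifnot(inherits(activity, "regulon_activity"))
  res <- apply(activity$auc, 2, binarize_activity, min_sep = min_sep,
               simplify = FALSE)
  activity$active <- vapply(res, `[[`, logical(nrow(activity$auc)), "active")
  dimnames(activity$active) <- dimnames(activity$auc)
  activity$thresholds <- vapply(res, `[[`, numeric(1), "threshold")
  activity$flags <- vapply(res, `[[`, character(1), "flag")
  activity
}

#' Cross-tissue regulon retention filter
#'
#' Keeps a regulon if its activation fraction is at least `min_frac` in at
#' least `min_tissues` tissues (both boundaries inclusive).  With fewer
#' tissues than `min_tissues` the requirement adapts to the number supplied,
#' with a warning.
#'
#' @param active_list list (one per tissue) of cells x regulons logical
#'   matrices with shared column names.
#' @param min_frac minimal activation fraction.
#' @param min_tissues minimal number of qualifying tissues.
#' @return character vector of retained regulon names.
#' @export
retention_filter <- function(active_list, min_frac = 0.10, min_tissues = 4) {
  stopifnot(length(active_list) >= 1)
  need <- min(min_tissues, length(active_list))
  if (need < min_tissues) {
    warning("only ", length(active_list), " tissue(s) supplied; requiring ",
            need)
  }
  fracs <- vapply(active_list, colMeans,
                  numeric(ncol(active_list[[1]])))
  if (is.null(dim(fracs))) fracs <- matrix(fracs, nrow = 1,
                                           dimnames = list(
                                             colnames(active_list[[1]]), NULL))
  qualifying <- rowSums(fracs >= min_frac)
  rownames(fracs)[qualifying >= need]
}

#' Diagnostic odds ratio from confusion counts
#'
#' `DOR = (TP + c)(TN + c) / ((FP + c)(FN + c))` with pseudocount
#' `c = 0.05`, where a "positive test" is regulon activation, cases are
#' MAM+ cells and controls MAM- cells.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @param pseudocount additive pseudocount.
#' @return the DOR (always finite and positive).
#' @export
dor_from_counts <- function(tp, tn, fp, fn, pseudocount = 0.05) {
  ((tp + pseudocount) * (tn + pseudocount)) /
    ((fp + pseudocount) * (fn + pseudocount))
}

#' Per-tissue and median diagnostic odds ratios of regulon activation
#'
#' For each tissue, TP is the number of MAM+ cells with the regulon active,
#' TN the MAM- cells inactive, FP the MAM- cells active and FN the MAM+
#' cells inactive; the tissue DORs are summarised by their median.  Tissues
#' missing either label class are excluded from the median with a warning.
#'
#' @param active_list list (per tissue) of cells x regulons logical
#'   matrices.
#' @param labels_list list (per tissue) of per-cell labels containing
#'   `"MAM_pos"` / `"MAM_neg"` (other labels' cells are ignored).
#' @param pseudocount see [dor_from_counts()].
#' @return list with `per_tissue` (tissues x regulons DOR matrix) and
#'   `median_dor` (named vector).
#' @export
compute_dor <- function(active_list, labels_list, pseudocount = 0.05) {
  stopifnot(length(active_list) == length(labels_list))
  regs <- colnames(active_list[[1]])
  per <- matrix(NA_real_, length(active_list), length(regs),
                dimnames = list(names(active_list), regs))
  for (t in seq_along(active_list)) {
    lab <- as.character(labels_list[[t]])
    pos <- lab == "MAM_pos"; neg <- lab == "MAM_neg"
    if (!any(pos) || !any(neg)) {
      warning("tissue ", t, " misses a label class; excluded from the median")
      next
    }
    act <- active_list[[t]]
    for (r in regs) {
      tp <- sum(act[pos, r]); fn <- sum(pos) - tp
      fp <- sum(act[neg, r]); tn <- sum(neg) - fp
      per[t, r] <- dor_from_counts(tp, tn, fp, fn, pseudocount)
    }
  }
  med <- apply(per, 2, median, na.rm = TRUE)
  list(per_tissue = per, median_dor = med)
}

#' Regulon specificity score for the MAM+ signature
#'
#' Combines the significance of the regulon's overlap with the up- and
#' down-regulated signatures (upper-tail hypergeometric p-values over the
#' differential-analysis universe, natural log) with the summed mean log2
#' fold changes of the overlapping genes:
#' `specificity = ((-ln p_up) - (-ln p_dn)) * (S_up - S_dn) / |regulon|`,
#' where `|regulon|` counts the regulon genes inside the universe.  Both
#' factors flip sign when the two signatures are swapped, so the product is
#' swap-invariant; mirror-symmetric overlaps score exactly zero.
#'
#' @param regulon a [gene_set()].
#' @param up_signature,down_signature [gene_set()] objects.
#' @param mean_log2FC named numeric vector of cross-tissue mean log2 fold
#'   changes (names = genes).
#' @param universe genes tested in the differential analysis.
#' @return the specificity score, or `NA` (with a warning) when the regulon
#'   has no gene in the universe.
#' @export
regulon_specificity <- function(regulon, up_signature, down_signature,
                                mean_log2FC, universe) {
  universe <- unique(universe)
  reg <- intersect(regulon$genes, universe)
  if (!length(reg)) {
    warning("regulon '", regulon$name, "' has no gene in the universe")
    return(NA_real_)
  }
  tail_p <- function(sig) {
    k <- intersect(sig$genes, universe)
    ov <- length(intersect(reg, k))
    phyper(ov - 1, length(k), length(universe) - length(k), length(reg),
           lower.tail = FALSE)
  }
  sum_lfc <- function(sig) {
    ov <- intersect(reg, intersect(sig$genes, universe))
    if (!length(ov)) return(0)
    sum(mean_log2FC[ov], na.rm = TRUE)
  }
  p_up <- tail_p(up_signature); p_dn <- tail_p(down_signature)
  s_up <- sum_lfc(up_signature); s_dn <- sum_lfc(down_signature)
  ((-log(p_up)) - (-log(p_dn))) * (s_up - s_dn) / length(reg)
}

#' Two-segment trajectory regressions of regulon activity
#'
#' Ordinary least squares of per-cell regulon AUC on the per-cell MAM+
#' signature score, fitted separately on the transitional + MAM- pool
#' (segment 1) and the MAM- + MAM+ pool (segment 2).  A regulon driving the
#' MAM- to MAM+ transition shows a steeper second-segment slope.
#'
#' @param regulon_auc numeric per-cell AUC vector.
#' @param signature_score numeric per-cell signature score.
#' @param segment_labels per-cell labels in
#'   `{"transitional", "MAM_neg", "MAM_pos"}`.
#' @return list with `slope1`, `intercept1`, `slope2`, `intercept2` (slopes
#'   `NA`, with a warning, when a pool's score variance is zero).
#' @export
trajectory_slopes <- function(regulon_auc, signature_score, segment_labels) {
  stopifnot(length(regulon_auc) == length(signature_score),
            length(regulon_auc) == length(segment_labels))
  lab <- as.character(segment_labels)
  pools <- list(seg1 = lab %in% c("transitional", "MAM_neg"),
                seg2 = lab %in% c("MAM_neg", "MAM_pos"))
  fit_one <- function(mask) {
    if (sum(mask) < 3) stop("segment pool has fewer than 3 cells")
    x <- signature_score[mask]; y <- regulon_auc[mask]
    if (var(x) == 0) {
      warning("zero signature-score variance in a segment pool; slope NA")
      return(c(slope = NA_real_, intercept = NA_real_))
    }
    co <- coef(lm(y ~ x))
    c(slope = unname(co[2]), intercept = unname(co[1]))
  }
  f1 <- fit_one(pools$seg1); f2 <- fit_one(pools$seg2)
  list(slope1 = f1[["slope"]], intercept1 = f1[["intercept"]],
       slope2 = f2[["slope"]], intercept2 = f2[["intercept"]])
}
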