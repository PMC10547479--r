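#' Per-subject pseudo-bulk signature scores
#'
#' Scores every cell for each signature with [module_score()], takes the
#' per-subject median, excludes subjects contributing fewer than `min_cells`
#' cells, and z-scales the medians across the retained subjects.  Both the
#' raw medians (`score_<name>`) and the z-scaled versions (`z_<name>`) are
#' returned: regressions on the module-score scale use the raw columns, the
#' z columns standardise cross-signature display.
#'
#' @param dataset a [ged()] with a normalized layer and per-cell `subject_id`
#'   (plus optional `age`, `sex`, `smoking`) metadata.
#' @param signatures a [gene_set()] or list of them.
#' @param min_cells minimal cells per subject (subjects below are excluded).
#' @param n_bins,n_ctrl,seed passed to [module_score()].
#' @return data.frame of class `subject_scores`: one row per retained
#'   subject with `subject_id`, `n_cells`, `age`, `sex`, `smoking`, and the
#'   score columns.
#' @export
pseudobulk_scores <- function(dataset, signatures, min_cells = 10,
                              n_bins = 24, n_ctrl = 100, seed = 0) {
  validate_ged(dataset)
  if (inherits(signatures, "gene_set")) signatures <- list(signatures)
  subj <- dataset$cell_meta$subject_id
  counts <- table(subj)
  keep_subj <- names(counts)[counts >= min_cells]
  if (length(keep_subj) < 2) {
    stop("fewer than 2 subjects retain >= ", min_cells, " cells")
  }
  first <- match(keep_subj, subj)
  out <- data.frame(subject_id = keep_subj,
                    n_cells = as.integer(counts[keep_subj]),
                    age = dataset$cell_meta$age[first],
                    sex = dataset$cell_meta$sex[first],
                    smoking = dataset$cell_meta$smoking[first],
                    stringsAsFactors = FALSE)
  for (sig in signatures) {
    sc <- module_score(dataset, sig, n_bins = n_bins, n_ctrl = n_ctrl,
                       seed = seed)
    med <- tapply(sc, subj, median)[keep_subj]
    raw <- as.numeric(med)
    z <- if (sd(raw) > 0) (raw - mean(raw)) / sd(raw) else raw * 0
    out[[paste0("score_", sig$name)]] <- raw
    out[[paste0("z_", sig$name)]] <- z
  }
  class(out) <- c("subject_scores", "data.frame")
  out
}

#' Regression of a subject-level signature score on age and covariates
#'
#' Ordinary least squares with intercept.  Categorical covariates are
#' one-hot encoded dropping one level; covariates constant across subjects
#' are dropped with a warning; a design singular after the drops is an error
#' naming the collinear columns.
#'
#' @param table a [pseudobulk_scores()] result (or any data.frame).
#' @param response name of the response column (e.g. `"score_<signature>"`).
#' @param covariates covariate column names to include.
#' @return data.frame with term, estimate, se, p, ci_lo, ci_hi (95%).
#' @export
covariate_regression <- function(table, response,
                                 covariates = c("age", "sex", "smoking")) {
  stopifnot(response %in% names(table))
  used <- character(0)
  for (cv in covariates) {
    if (!cv %in% names(table)) {
      warning("covariate '", cv, "' absent; dropped")
      next
    }
    v <- table[[cv]]
    if (all(is.na(v)) || length(unique(v[!is.na(v)])) < 2) {
      warning("covariate '", cv, "' is constant or missing; dropped")
      next
    }
    used <- c(used, cv)
  }
  if (!length(used)) stop("no usable covariate")
  dat <- table[, c(response, used), drop = FALSE]
  for (cv in used) if (is.character(dat[[cv]])) dat[[cv]] <- factor(dat[[cv]])
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < length(used) + 2) {
    stop("need at least ", length(used) + 2, " complete subjects")
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(used, collapse = " + ")))
  fit <- lm(fml, data = dat)
  if (any(is.na(coef(fit)))) {
    stop("singular design; collinear column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  ci <- confint(fit)
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             p = sm[, 4], ci_lo = ci[, 1], ci_hi = ci[, 2],
             row.names = NULL)
}

#' Map a gene set to another species via an ortholog table
#'
#' Each source gene is replaced by all of its mapped targets; unmapped genes
#' are dropped and counted; the result is deduplicated.
#'
#' @param set a [gene_set()].
#' @param ortholog_table data.frame whose first two columns are source and
#'   target gene symbols (see [read_ortholog_table()]).
#' @return a [gene_set()] in the target namespace, with attribute
#'   `n_dropped` (number of unmapped source genes).
#' @export
map_orthologs <- function(set, ortholog_table) {
  src <- as.character(ortholog_table[[1]])
  tgt <- as.character(ortholog_table[[2]])
  hits <- set$genes %in% src
  mapped <- tgt[src %in% set$genes]
  n_dropped <- sum(!hits)
  if (!length(mapped)) stop("no gene of '", set$name,
                            "' maps through the ortholog table")
  if (n_dropped) message(n_dropped, " gene(s) of '", set$name, "' unmapped")
  out <- gene_set(set$name, mapped, tf = set$tf)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Young-versus-aged group comparison of signature scores
#'
#' Two-sided Wilcoxon rank-sum test per signature score column between the
#' two groups (exact for small tie-free samples, tie-corrected normal
#' approximation otherwise).  Works on per-subject tables
#' ([pseudobulk_scores()]) or per-cell score data.frames alike.
#'
#' @param table data.frame of scores.
#' @param group per-row group labels with exactly two levels (e.g.
#'   `"young"` / `"aged"`).
#' @param score_cols score column names; defaults to every `score_*` column.
#' @return data.frame with signature, n per group, and p.
#' @export
group_compare <- function(table, group, score_cols = NULL) {
  stopifnot(length(group) == nrow(table))
  group <- as.character(group)
  lev <- unique(group[!is.na(group)])
  if (length(lev) != 2) stop("group must have exactly 2 levels")
  if (any(table(group) == 0)) stop("a group is empty")
  if (is.null(score_cols)) {
    score_cols <- grep("^score_", names(table), value = TRUE)
  }
  if (!length(score_cols)) stop("no score column found")
  rows <- lapply(score_cols, function(cl) {
    x <- table[[cl]][group == lev[1]]
    y <- table[[cl]][group == lev[2]]
    data.frame(signature = sub("^score_", "", cl),
               group_a = lev[1], group_b = lev[2],
               n_a = length(x), n_b = length(y),
               p = rank_sum_p(x, y))
  })
  do.call(rbind, rows)
}
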