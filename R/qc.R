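#' Quality-control filtering of cells and genes
#'
#' Keeps cells detecting between `min_genes` and `max_genes` genes
#' (inclusive), with a mitochondrial read fraction below the cutoff (20% by
#' default, 40% with `lenient = TRUE` for tissues with constitutively higher
#' mitochondrial content) and a haemoglobin read fraction below `max_hb`.
#' Genes detected in no remaining cell are then dropped.  The filter is
#' idempotent.
#'
#' @param dataset a [ged()].
#' @param min_genes,max_genes detected-gene bounds (inclusive).
#' @param max_mito default mitochondrial-fraction cutoff (strict `<`).
#' @param max_hb haemoglobin-fraction cutoff (strict `<`).
#' @param lenient_mito mitochondrial cutoff used when `lenient = TRUE`.
#' @param lenient use the lenient mitochondrial cutoff.
#' @param mito_pattern regular expression identifying mitochondrial genes.
#' @param hb_genes haemoglobin gene ids.
#' @return the filtered [ged()]; 0-cell input passes through unchanged.
#' @export
apply_qc <- function(dataset, min_genes = 300, max_genes = 5000,
                     max_mito = 0.20, max_hb = 0.001, lenient_mito = 0.40,
                     lenient = FALSE, mito_pattern = "^MT-",
                     hb_genes = c("HBA", "HBB")) {
  validate_ged(dataset)
  if (n_cells(dataset) == 0) return(dataset)
  counts <- dataset$counts
  detected <- Matrix::rowSums(counts > 0)
  total <- Matrix::rowSums(counts)
  mito_idx <- grep(mito_pattern, colnames(counts))
  hb_idx <- which(colnames(counts) %in% hb_genes)
  mito_frac <- if (length(mito_idx)) {
    Matrix::rowSums(counts[, mito_idx, drop = FALSE]) / pmax(total, 1)
  } else rep(0, n_cells(dataset))
  hb_frac <- if (length(hb_idx)) {
    Matrix::rowSums(counts[, hb_idx, drop = FALSE]) / pmax(total, 1)
  } else rep(0, n_cells(dataset))
  mito_cut <- if (lenient) lenient_mito else max_mito
  keep <- detected >= min_genes & detected <= max_genes &
    mito_frac < mito_cut & hb_frac < max_hb
  out <- subset_ged(dataset, cells = which(keep))
  expressed <- Matrix::colSums(out$counts > 0) > 0
  if (!any(expressed)) stop("no gene remains expressed after QC filtering")
  subset_ged(out, genes = which(expressed))
}

#' Restrict pooled datasets to genes expressed in several of them
#'
#' When per-tissue datasets are pooled, genes are kept only if expressed (in
#' at least one cell) in `min_datasets` or more of the datasets.
#'
#' @param datasets list of [ged()] objects.
#' @param min_datasets minimal number of datasets a gene must be expressed
#'   in (inclusive).
#' @return the list of datasets, each restricted to the shared genes.
#' @export
filter_shared_genes <- function(datasets, min_datasets = 2) {
  stopifnot(length(datasets) >= 1)
  all_genes <- unique(unlist(lapply(datasets, gene_ids)))
  tally <- setNames(integer(length(all_genes)), all_genes)
  for (d in datasets) {
    expressed <- gene_ids(d)[Matrix::colSums(d$counts > 0) > 0]
    tally[expressed] <- tally[expressed] + 1L
  }
  keep <- names(tally)[tally >= min_datasets]
  if (!length(keep)) stop("no gene is expressed in >= ", min_datasets,
                          " datasets")
  lapply(datasets, function(d) {
    subset_ged(d, genes = intersect(gene_ids(d), keep))
  })
}

#' Library-size log-normalisation
#'
#' Sets `normalized[c, g] = ln(1 + scale_factor * counts[c, g] /
#' total counts of cell c)`.
#'
#' @param dataset a [ged()] with counts.
#' @param scale_factor library-size scale factor.
#' @return the dataset with its `normalized` layer populated.
#' @export
log_normalize <- function(dataset, scale_factor = 1e4) {
  validate_ged(dataset)
  total <- Matrix::rowSums(dataset$counts)
  zero <- which(total == 0)
  if (length(zero)) {
    stop("cell(s) with zero total counts: ",
         paste(head(cell_ids(dataset)[zero], 5), collapse = ", "))
  }
  norm <- Matrix::Diagonal(x = scale_factor / total) %*% dataset$counts
  norm <- as(norm, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(dataset$counts)
  dataset$normalized <- norm
  validate_ged(dataset)
  dataset
}
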