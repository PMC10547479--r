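#' Construct a gene-expression dataset
#'
#' The central container of the package: a sparse cells x genes matrix of UMI
#' counts, per-cell metadata, and an optional natural-log normalized layer of
#' the same shape.  Cells are rows and genes are columns throughout.
#'
#' @param counts cells x genes matrix of non-negative integer counts (dense or
#'   any Matrix sparse class); row names are cell ids, column names gene ids.
#'   Alternatively pass unnamed and supply ids via `cell_meta` rownames and
#'   `gene_ids`.
#' @param cell_meta data.frame with one row per cell.  Required columns:
#'   `tissue`, `subject_id`, `condition` (`"control"` or a disease label).
#'   Optional: `population_label`, `age`, `sex`, `smoking`; missing optional
#'   values stay `NA`, never imputed.
#' @param normalized optional real matrix, same shape as `counts`,
#'   elementwise >= 0 (natural-log normalized values).
#' @param gene_ids optional character vector of gene ids when `counts` lacks
#'   column names.
#' @return an object of class `ged` (list with elements `counts`,
#'   `normalized`, `cell_meta`).
#' @seealso [read_dataset()], [write_dataset()], [log_normalize()]
#' @export
ged <- function(counts, cell_meta, normalized = NULL, gene_ids = NULL) {
  counts <- as_csparse(counts)
  if (!is.null(gene_ids)) colnames(counts) <- gene_ids
  if (is.null(rownames(counts)) && nrow(counts) > 0) {
    if (!is.null(rownames(cell_meta)) &&
        !identical(rownames(cell_meta), as.character(seq_len(nrow(cell_meta))))) {
      rownames(counts) <- rownames(cell_meta)
    } else if ("cell_id" %in% names(cell_meta)) {
      rownames(counts) <- cell_meta$cell_id
    } else {
      stop("counts need row names (cell ids), or cell_meta must carry them")
    }
  }
  if (is.null(colnames(counts))) stop("counts need column names (gene ids)")
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate cell ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  cell_meta$cell_id <- NULL
  rownames(cell_meta) <- rownames(counts)
  for (col in c("population_label", "age", "sex", "smoking")) {
    if (!col %in% names(cell_meta)) {
      cell_meta[[col]] <- rep(if (col == "age") NA_real_ else NA_character_,
                              nrow(cell_meta))
    }
  }
  if (!is.null(normalized)) {
    normalized <- as_csparse(normalized)
    dimnames(normalized) <- dimnames(counts)
  }
  obj <- structure(list(counts = counts, normalized = normalized,
                        cell_meta = cell_meta), class = "ged")
  validate_ged(obj)
  obj
}

# numeric dgCMatrix from any dense/sparse numeric-ish input
as_csparse <- function(x) {
  if (is.matrix(x)) storage.mode(x) <- "double"
  as(as(as(Matrix::Matrix(x, sparse = TRUE), "dMatrix"), "generalMatrix"),
     "CsparseMatrix")
}

#' Validate a gene-expression dataset
#'
#' Checks every container invariant: metadata length matches the cell count,
#' counts are non-negative, ids are unique, and the normalized layer (when
#' present) matches the counts' shape and is non-negative.  Each violation
#' raises a distinct error.
#'
#' @param x a `ged` object.
#' @return `x`, invisibly, if valid.
#' @export
validate_ged <- function(x) {
  stopifnot(inherits(x, "ged"))
  counts <- x$counts
  if (nrow(x$cell_meta) != nrow(counts)) {
    stop("cell_meta has ", nrow(x$cell_meta), " rows but counts has ",
         nrow(counts), " cells")
  }
  req <- c("tissue", "subject_id", "condition")
  miss <- setdiff(req, names(x$cell_meta))
  if (length(miss)) stop("cell_meta lacks required column(s): ",
                         paste(miss, collapse = ", "))
  if (length(counts@x) && min(counts@x) < 0) {
    stop("counts contain negative values")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate cell ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate gene ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  }
  if (!is.null(x$normalized)) {
    if (!identical(dim(x$normalized), dim(counts))) {
      stop("normalized layer shape differs from counts")
    }
    if (length(x$normalized@x) && min(x$normalized@x) < 0) {
      stop("normalized layer contains negative values")
    }
  }
  invisible(x)
}

#' @export
print.ged <- function(x, ...) {
  cat("<ged> ", nrow(x$counts), " cells x ", ncol(x$counts), " genes",
      if (!is.null(x$normalized)) " (+normalized layer)", "\n", sep = "")
  cat("  tissues: ", paste(unique(x$cell_meta$tissue), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname ged
#' @param x a `ged` object.
#' @export
n_cells <- function(x) nrow(x$counts)

#' @rdname ged
#' @export
n_genes <- function(x) ncol(x$counts)

#' @rdname ged
#' @export
gene_ids <- function(x) colnames(x$counts)

#' @rdname ged
#' @export
cell_ids <- function(x) rownames(x$counts)

#' Subset a dataset by cells and/or genes
#'
#' @param x a `ged`.
#' @param cells,genes index vectors (logical, integer or character); `NULL`
#'   keeps everything.
#' @return the subset `ged`.
#' @export
subset_ged <- function(x, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_len(n_cells(x))
  if (is.null(genes)) genes <- seq_len(n_genes(x))
  ged(x$counts[cells, genes, drop = FALSE],
      x$cell_meta[cells, , drop = FALSE],
      normalized = if (!is.null(x$normalized))
        x$normalized[cells, genes, drop = FALSE])
}

#' Construct a gene set or regulon
#'
#' A named, ordered, deduplicated gene list.  When `tf` is set the gene set
#' is a regulon: a transcription factor together with its inferred targets.
#'
#' @param name set name.
#' @param genes character vector of gene ids; duplicates are removed keeping
#'   the first occurrence.
#' @param tf optional transcription-factor symbol anchoring a regulon.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, genes, tf = NULL) {
  genes <- as.character(genes)
  genes <- genes[!duplicated(genes)]
  if (!length(genes)) stop("gene set '", name, "' is empty")
  structure(list(name = as.character(name), tf = tf, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name,
      if (!is.null(x$tf)) paste0(" (TF: ", x$tf, ")"),
      ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Construct a gene-set enrichment table
#'
#' Holds externally computed enrichment results (one row per term) on which
#' the pipeline applies its NES / adjusted-p filter and leading-edge
#' intersection.  The enrichment algorithm itself is not part of the package.
#'
#' @param term character vector of term names.
#' @param NES numeric normalized enrichment scores.
#' @param p_adjust numeric adjusted p-values in \[0, 1\].
#' @param leading_edge list of character vectors (one gene list per term).
#' @return a data.frame of class `enrichment_table` with a `leading_edge`
#'   list column.
#' @export
enrichment_table <- function(term, NES, p_adjust, leading_edge) {
  stopifnot(length(term) == length(NES),
            length(term) == length(p_adjust),
            length(term) == length(leading_edge))
  if (length(p_adjust) && (min(p_adjust) < 0 || max(p_adjust) > 1)) {
    stop("p_adjust values must lie in [0, 1]")
  }
  out <- data.frame(term = as.character(term), NES = as.numeric(NES),
                    p_adjust = as.numeric(p_adjust),
                    stringsAsFactors = FALSE)
  out$leading_edge <- lapply(leading_edge, as.character)
  class(out) <- c("enrichment_table", "data.frame")
  out
}
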