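#' Read a dataset from MatrixMarket triplet files
#'
#' Reads the conventional on-disk triplet (coordinate MatrixMarket counts,
#' one-barcode-per-line and one-feature-per-line TSVs) plus a cell metadata
#' TSV keyed by `cell_id`.  On disk the matrix is stored features x barcodes
#' (10x convention, 1-based coordinates); in memory it is transposed to
#' cells x genes.  Coordinates absent from the file are zero.
#'
#' @param matrix_path path to the `.mtx` counts file.
#' @param barcodes_path path to the barcodes file (one cell id per line).
#' @param features_path path to the features file (one gene id per line).
#' @param meta_path path to a TSV with header containing a `cell_id` column
#'   and the per-cell metadata columns.
#' @param normalized_path optional path to a sidecar `.mtx` with the
#'   normalized layer (same shape as counts on disk).
#' @return a [ged()] object.
#' @export
read_dataset <- function(matrix_path, barcodes_path, features_path, meta_path,
                         normalized_path = NULL) {
  for (p in c(matrix_path, barcodes_path, features_path, meta_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  barcodes <- readLines(barcodes_path)
  features <- readLines(features_path)
  if (anyDuplicated(barcodes)) {
    stop("duplicate barcode(s): ",
         paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  }
  if (anyDuplicated(features)) {
    stop("duplicate feature(s): ",
         paste(unique(features[duplicated(features)]), collapse = ", "))
  }
  m <- Matrix::readMM(matrix_path)
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    stop("matrix is ", nrow(m), " x ", ncol(m), " but ", length(features),
         " features and ", length(barcodes), " barcodes were supplied")
  }
  counts <- Matrix::t(m)
  dimnames(counts) <- list(barcodes, features)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE,
                     colClasses = c(cell_id = "character"))
  if (!"cell_id" %in% names(meta)) stop("metadata lacks a cell_id column")
  missing <- setdiff(barcodes, meta$cell_id)
  if (length(missing)) {
    stop("metadata missing cell id(s): ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...")
  }
  meta <- meta[match(barcodes, meta$cell_id), , drop = FALSE]
  normalized <- NULL
  if (!is.null(normalized_path)) {
    if (!file.exists(normalized_path)) stop("file not found: ", normalized_path)
    normalized <- Matrix::t(Matrix::readMM(normalized_path))
    dimnames(normalized) <- list(barcodes, features)
  }
  ged(counts, meta, normalized = normalized)
}

#' Write a dataset as MatrixMarket triplet files
#'
#' Inverse of [read_dataset()]: writes `matrix.mtx` (features x barcodes on
#' disk), `barcodes.tsv`, `features.tsv`, `cell_meta.tsv`, and, when a
#' normalized layer is present, a `normalized.mtx` sidecar.  Reading the
#' output reproduces the input exactly.
#'
#' @param dataset a valid [ged()].
#' @param out_dir output directory (created if absent).
#' @return named character vector of the written file paths, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  validate_ged(dataset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    stop("output directory not writable: ", out_dir)
  }
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             barcodes = file.path(out_dir, "barcodes.tsv"),
             features = file.path(out_dir, "features.tsv"),
             cell_meta = file.path(out_dir, "cell_meta.tsv"))
  Matrix::writeMM(Matrix::t(dataset$counts), paths[["matrix"]])
  writeLines(as.character(cell_ids(dataset)), paths[["barcodes"]])
  writeLines(as.character(gene_ids(dataset)), paths[["features"]])
  meta <- dataset$cell_meta
  meta <- cbind(cell_id = as.character(cell_ids(dataset)), meta)
  write.table(meta, paths[["cell_meta"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(dataset$normalized)) {
    paths <- c(paths, normalized = file.path(out_dir, "normalized.mtx"))
    Matrix::writeMM(Matrix::t(dataset$normalized), paths[["normalized"]])
  }
  invisible(paths)
}

#' Read gene sets or regulons from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.  Genes are
#' deduplicated preserving first occurrence.  A description of the form
#' `TF:<symbol>` marks the set as a regulon anchored to that transcription
#' factor.
#'
#' @param gmt_path path to a GMT file.
#' @return a named list of [gene_set()] objects.
#' @export
read_gene_sets <- function(gmt_path) {
  if (!file.exists(gmt_path)) stop("file not found: ", gmt_path)
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has ", length(fields),
           " field(s); need name, description and at least one gene")
    }
    tf <- NULL
    if (grepl("^TF:", fields[[2]])) tf <- sub("^TF:", "", fields[[2]])
    sets[[i]] <- gene_set(fields[[1]], fields[-(1:2)], tf = tf)
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a list of [gene_set()] objects.
#' @param gmt_path output path.
#' @return `gmt_path`, invisibly.
#' @export
write_gene_sets <- function(sets, gmt_path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    desc <- if (!is.null(s$tf)) paste0("TF:", s$tf) else "na"
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, gmt_path)
  invisible(gmt_path)
}

#' Read a two-column ortholog mapping table
#'
#' @param path TSV with a header and at least two columns: source gene,
#'   target gene.
#' @return data.frame with columns `source` and `target`.
#' @export
read_ortholog_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("ortholog table needs two columns (source, target)")
  data.frame(source = as.character(tab[[1]]), target = as.character(tab[[2]]),
             stringsAsFactors = FALSE)
}
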