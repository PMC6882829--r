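#' Read a count matrix from Matrix Market or dense TSV
#'
#' Matrix Market input (`.mtx`) expects `genes.tsv` and `barcodes.tsv`
#' sidecar files next to the matrix (first column of each is the id);
#' the matrix may be stored either genes x cells (the common exchange
#' orientation) or cells x genes -- the orientation is resolved from
#' the sidecar lengths. Dense TSV input expects a header row of gene
#' ids and a first column of cell ids.
#'
#' @param path path to the `.mtx` or `.tsv` file.
#' @param count_kind `"umi"` or `"read"`.
#' @param genes_path,barcodes_path sidecar paths (defaults: `genes.tsv`
#'   and `barcodes.tsv` in the same directory).
#' @return A [count_matrix()] (cells x genes).
#' @export
read_counts <- function(path, count_kind = c("umi", "read"),
                        genes_path = NULL, barcodes_path = NULL) {
  count_kind <- match.arg(count_kind)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    read_counts_mtx(path, count_kind, genes_path, barcodes_path)
  } else {
    read_counts_tsv(path, count_kind)
  }
}

read_counts_mtx <- function(path, count_kind, genes_path = NULL,
                            barcodes_path = NULL) {
  if (is.null(genes_path)) genes_path <- file.path(dirname(path), "genes.tsv")
  if (is.null(barcodes_path))
    barcodes_path <- file.path(dirname(path), "barcodes.tsv")
  for (f in c(path, genes_path, barcodes_path)) {
    if (!file.exists(f)) stop(sprintf("file not found: %s", f))
  }
  m <- Matrix::readMM(path)
  genes <- utils::read.delim(genes_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.delim(barcodes_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    m <- Matrix::t(m)     # stored genes x cells
  } else if (!(nrow(m) == length(cells) && ncol(m) == length(genes))) {
    stop(sprintf(
      "matrix is %d x %d but sidecars list %d genes and %d barcodes",
      nrow(m), ncol(m), length(genes), length(cells)))
  }
  count_matrix(methods::as(m, "CsparseMatrix"), gene_ids = genes,
               cell_ids = cells, count_kind = count_kind)
}

read_counts_tsv <- function(path, count_kind) {
  tab <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
  count_matrix(as.matrix(tab), gene_ids = colnames(tab),
               cell_ids = rownames(tab), count_kind = count_kind)
}

#' Write / read an embedding as TSV
#'
#' Three columns: `cell_id`, `x`, `y`. Coordinates are written in full
#' precision so a round trip is lossless.
#'
#' @param y n x 2 coordinate matrix or a `"tsne_embedding"`.
#' @param path output file.
#' @param cell_ids optional ids (default `cell_1..n`).
#' @return `write_embedding`: the path, invisibly. `read_embedding`:
#'   an n x 2 matrix with cell ids as row names.
#' @export
write_embedding <- function(y, path, cell_ids = NULL) {
  if (inherits(y, "tsne_embedding")) y <- y$Y
  y <- as.matrix(y)
  if (is.null(cell_ids)) cell_ids <- rownames(y)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(nrow(y)))
  df <- data.frame(cell_id = cell_ids,
                   x = sprintf("%.17g", y[, 1]),
                   y = sprintf("%.17g", y[, 2]))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "x", "y") %in% names(tab))) {
    stop("embedding file must have columns cell_id, x, y")
  }
  m <- cbind(x = as.numeric(tab$x), y = as.numeric(tab$y))
  rownames(m) <- tab$cell_id
  m
}

#' Write / read a dense numeric matrix as TSV (no header)
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `write_matrix_tsv`: the path, invisibly;
#'   `read_matrix_tsv`: a numeric matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(format(as.matrix(m), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Read per-cell labels
#'
#' A TSV with a header; uses the `type` column when present (as written
#' by [write_mixture()]), otherwise the second column.
#'
#' @param path label file path.
#' @return A vector of labels.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if ("type" %in% names(tab)) tab$type else tab[[min(2, ncol(tab))]]
}
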