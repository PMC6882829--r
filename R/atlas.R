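#' Reference atlas for out-of-sample positioning
#'
#' Bundles a reference embedding with the log-transformed expression
#' of the genes used to build it (typically the selected most variable
#' genes), so that new cells can be placed on the embedding by
#' expression similarity.
#'
#' @param embedding n_ref x 2 reference coordinates.
#' @param log_expression n_ref x L matrix of log2-transformed counts.
#' @param gene_ids character vector of the L gene ids (defaults to the
#'   column names).
#' @param cell_ids optional reference cell ids.
#' @return An object of class `"reference_atlas"`.
#' @export
reference_atlas <- function(embedding, log_expression,
                            gene_ids = colnames(log_expression),
                            cell_ids = rownames(log_expression)) {
  embedding <- as.matrix(embedding)
  log_expression <- as.matrix(log_expression)
  stopifnot(nrow(embedding) == nrow(log_expression), ncol(embedding) == 2,
            ncol(log_expression) >= 1)
  if (is.null(gene_ids))
    gene_ids <- sprintf("gene_%d", seq_len(ncol(log_expression)))
  if (is.null(cell_ids))
    cell_ids <- sprintf("cell_%d", seq_len(nrow(log_expression)))
  structure(list(embedding = embedding, log_expression = log_expression,
                 gene_ids = as.character(gene_ids),
                 cell_ids = as.character(cell_ids)),
            class = "reference_atlas")
}

#' @export
print.reference_atlas <- function(x, ...) {
  cat(sprintf("reference_atlas: %d cells, %d genes\n",
              nrow(x$embedding), length(x$gene_ids)))
  invisible(x)
}

# shared-gene view of query expression, aligned to atlas columns
match_genes <- function(atlas, query, query_genes) {
  query <- as.matrix(query)
  if (is.null(query_genes)) query_genes <- colnames(query)
  if (is.null(query_genes)) {
    if (ncol(query) != length(atlas$gene_ids)) {
      stop("query has no gene ids and its width differs from the atlas")
    }
    return(list(query = query, ref_cols = seq_along(atlas$gene_ids)))
  }
  shared <- intersect(atlas$gene_ids, query_genes)
  if (length(shared) == 0) stop("no genes shared between query and atlas")
  list(query = query[, match(shared, query_genes), drop = FALSE],
       ref_cols = match(shared, atlas$gene_ids))
}

# correlation distance between query rows and reference rows over the
# given gene columns; returns n_query x n_ref
correlation_distance <- function(ref_expr, query_expr) {
  qs <- apply(query_expr, 1, stats::sd)
  if (any(qs == 0)) {
    stop(sprintf("query cell %d has zero-variance expression; %s",
                 which(qs == 0)[1], "correlation distance undefined"))
  }
  rs <- apply(ref_expr, 1, stats::sd)
  if (any(rs == 0)) {
    # constant reference profiles correlate with nothing; treat as
    # maximally distant rather than failing the whole mapping
    warning(sprintf("%d reference cell(s) have zero-variance expression",
                    sum(rs == 0)))
  }
  cc <- suppressWarnings(stats::cor(t(query_expr), t(ref_expr)))
  cc[!is.finite(cc)] <- -1
  1 - cc
}

position_on <- function(embedding, D, k, exclude = NULL) {
  n_query <- nrow(D)
  pos <- matrix(NA_real_, n_query, 2)
  nbrs <- matrix(NA_integer_, n_query, k)
  for (i in seq_len(n_query)) {
    d <- D[i, ]
    if (!is.null(exclude) && !is.na(exclude[i])) d[exclude[i]] <- Inf
    ord <- order(d)[seq_len(k)]   # stable: ties by reference index
    nbrs[i, ] <- ord
    pos[i, ] <- apply(embedding[ord, , drop = FALSE], 2, stats::median)
  }
  list(positions = pos, neighbor_ids = nbrs)
}

#' Position new cells on a reference embedding
#'
#' Each query cell is matched to its k most similar reference cells --
#' distance 1 minus Pearson correlation across the shared
#' log-expression values -- and placed at the coordinate-wise median
#' of their embedding coordinates. Correlation distance is used for
#' robustness to between-protocol batch effects.
#'
#' @param atlas a [reference_atlas()].
#' @param query_log_expr n_query x G matrix of log2-transformed query
#'   counts.
#' @param query_genes gene ids of the query columns (defaults to its
#'   column names); only genes shared with the atlas are used.
#' @param k number of reference neighbours (default 10).
#' @param exclude optional integer vector (one entry per query row) of
#'   a reference cell index to exclude from the neighbour search, as
#'   in leave-one-out validation; NA entries exclude nothing.
#' @return An object of class `"mapping_result"`: list with
#'   `positions` (n_query x 2), `neighbor_ids` (n_query x k reference
#'   row indices), `k`, and `genes_used`.
#' @export
position_cells <- function(atlas, query_log_expr, query_genes = NULL,
                           k = 10, exclude = NULL) {
  stopifnot(inherits(atlas, "reference_atlas"))
  mg <- match_genes(atlas, query_log_expr, query_genes)
  ref <- atlas$log_expression[, mg$ref_cols, drop = FALSE]
  D <- correlation_distance(ref, mg$query)
  res <- position_on(atlas$embedding, D, k, exclude)
  structure(list(positions = res$positions,
                 neighbor_ids = res$neighbor_ids, k = k,
                 genes_used = atlas$gene_ids[mg$ref_cols]),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("mapping_result: %d cells positioned (k = %d, %d genes)\n",
              nrow(x$positions), x$k, length(x$genes_used)))
  if (!is.null(x$hulls)) {
    cat(sprintf("  bootstrap: B = %d, hulls over %d retained positions\n",
                x$B, x$B_retained))
  }
  invisible(x)
}

#' Leave-one-out validation of atlas positioning
#'
#' Re-positions reference cells on their own atlas with the cell
#' itself excluded from the neighbour search, and reports the
#' Euclidean displacement from the original embedding location. Small
#' displacements indicate consistent positioning.
#'
#' @param atlas a [reference_atlas()].
#' @param cells integer indices of reference cells to validate
#'   (default: all).
#' @param k neighbours (default 10).
#' @return Numeric vector of displacements (one per validated cell),
#'   with the [position_cells()] result as attribute `"mapping"`.
#' @export
loo_validation <- function(atlas, cells = NULL, k = 10) {
  stopifnot(inherits(atlas, "reference_atlas"))
  if (is.null(cells)) cells <- seq_len(nrow(atlas$embedding))
  query <- atlas$log_expression[cells, , drop = FALSE]
  res <- position_cells(atlas, query, query_genes = atlas$gene_ids,
                        k = k, exclude = cells)
  disp <- sqrt(rowSums((res$positions -
                          atlas$embedding[cells, , drop = FALSE])^2))
  attr(disp, "mapping") <- res
  disp
}

#' Bootstrap uncertainty of atlas positions
#'
#' Repeats the positioning B times, each on a with-replacement
#' resample of the shared genes; per cell, the positions farthest from
#' the original (non-bootstrap) mapping are trimmed (5 of 100 at the
#' default trim) and a convex hull of the remainder is returned as a
#' 2D confidence region. Collinear bootstrap positions degenerate to a
#' segment and are returned as such.
#'
#' @inheritParams position_cells
#' @param B bootstrap iterations (default 100).
#' @param seed seed for the gene resampling.
#' @param trim fraction of farthest positions discarded before the
#'   hull (default 0.05).
#' @return A `"mapping_result"` with additional fields
#'   `bootstrap_positions` (n_query x B x 2 array), `hulls` (list of
#'   vertex matrices, counter-clockwise), `hull_area`, `B`,
#'   `B_retained`, `seed`.
#' @export
bootstrap_positions <- function(atlas, query_log_expr, query_genes = NULL,
                                B = 100, k = 10, seed = 42, trim = 0.05) {
  stopifnot(inherits(atlas, "reference_atlas"), B >= 1)
  B <- as.integer(B)
  mg <- match_genes(atlas, query_log_expr, query_genes)
  L <- length(mg$ref_cols)
  if (L < 2) stop("bootstrapping requires at least 2 shared genes")
  ref <- atlas$log_expression[, mg$ref_cols, drop = FALSE]
  base <- position_on(atlas$embedding,
                      correlation_distance(ref, mg$query), k)
  n_query <- nrow(mg$query)
  boot <- array(NA_real_, c(n_query, B, 2))
  set.seed(seed)
  for (b in seq_len(B)) {
    gs <- sample.int(L, L, replace = TRUE)
    Db <- correlation_distance(ref[, gs, drop = FALSE],
                               mg$query[, gs, drop = FALSE])
    boot[, b, ] <- position_on(atlas$embedding, Db, k)$positions
  }
  n_drop <- as.integer(floor(trim * B))
  n_keep <- B - n_drop
  hulls <- vector("list", n_query)
  areas <- numeric(n_query)
  for (i in seq_len(n_query)) {
    pts <- boot[i, , , drop = TRUE]
    dim(pts) <- c(B, 2)
    d <- sqrt((pts[, 1] - base$positions[i, 1])^2 +
                (pts[, 2] - base$positions[i, 2])^2)
    keep <- order(d)[seq_len(n_keep)]
    kept <- pts[keep, , drop = FALSE]
    h <- grDevices::chull(kept[, 1], kept[, 2])
    hulls[[i]] <- kept[h, , drop = FALSE]
    areas[i] <- polygon_area(hulls[[i]])
  }
  structure(list(positions = base$positions,
                 neighbor_ids = base$neighbor_ids, k = k,
                 genes_used = atlas$gene_ids[mg$ref_cols],
                 bootstrap_positions = boot, hulls = hulls,
                 hull_area = areas, B = B, B_retained = n_keep,
                 seed = seed),
            class = "mapping_result")
}

# shoelace area; 0 for degenerate (point/segment) hulls
polygon_area <- function(v) {
  if (nrow(v) < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Aligned-embedding initialisation from a reference atlas
#'
#' Positions every cell of a new data set on the reference embedding
#' and rescales the layout to the standard initialisation scale (first
#' coordinate sd 1e-4). Running the optimiser from this init produces
#' an embedding aligned with the reference, enabling side-by-side
#' comparison of two data sets.
#'
#' @inheritParams position_cells
#' @return An n_query x 2 matrix ready to pass as a custom init to
#'   [tsne_optimize()] / [tsne_embed()].
#' @export
aligned_init <- function(atlas, query_log_expr, query_genes = NULL, k = 10) {
  res <- position_cells(atlas, query_log_expr, query_genes, k = k)
  tsne_init_rescale(res$positions)
}
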