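#' Construct a cell x gene count matrix
#'
#' A light container for raw counts plus identifiers. Counts may be a
#' base matrix or any [Matrix::Matrix] (sparse input is kept sparse).
#'
#' @param counts n_cells x n_genes nonnegative matrix.
#' @param gene_ids character vector, one per column.
#' @param cell_ids character vector, one per row.
#' @param count_kind `"umi"` or `"read"`; controls the depth
#'   normalisation target and the default near-zero threshold.
#' @return An object of class `"count_matrix"`.
#' @export
count_matrix <- function(counts, gene_ids = colnames(counts),
                         cell_ids = rownames(counts),
                         count_kind = c("umi", "read")) {
  count_kind <- match.arg(count_kind)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(ncol(counts)))
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(nrow(counts)))
  stopifnot(length(gene_ids) == ncol(counts),
            length(cell_ids) == nrow(counts))
  if (min_value(counts) < 0) stop("counts must be nonnegative")
  structure(list(counts = counts, gene_ids = as.character(gene_ids),
                 cell_ids = as.character(cell_ids), count_kind = count_kind),
            class = "count_matrix")
}

min_value <- function(m) {
  if (methods::is(m, "sparseMatrix")) {
    x <- m@x
    if (length(x) == 0) 0 else min(0, min(x))
  } else {
    min(m)
  }
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes (%s counts)\n",
              nrow(x$counts), ncol(x$counts), x$count_kind))
  invisible(x)
}

#' Sequencing-depth normalisation
#'
#' Divides each cell's counts by its sequencing depth (total count) and
#' rescales: read counts to counts per million (CPM), UMI counts to the
#' median sequencing depth across all cells. The median target avoids
#' the distortion that a fixed 1e6 scale introduces in the subsequent
#' log transform of shallow UMI libraries.
#'
#' @param x a [count_matrix()], or a plain matrix together with `kind`.
#' @param kind `"umi"` or `"read"`; taken from `x` when it is a
#'   `count_matrix`.
#' @return A matrix (dense or sparse, as the input) of normalised
#'   counts; each row sums to 1e6 (read) or to the median depth (umi).
#' @export
normalize_depth <- function(x, kind = NULL) {
  if (inherits(x, "count_matrix")) {
    kind <- x$count_kind
    ids <- x$cell_ids
    m <- x$counts
  } else {
    if (is.null(kind)) stop("kind must be given for a bare matrix")
    kind <- match.arg(kind, c("umi", "read"))
    ids <- rownames(x)
    if (is.null(ids)) ids <- sprintf("cell_%d", seq_len(nrow(x)))
    m <- x
  }
  depth <- row_sums(m)
  if (any(depth <= 0)) {
    bad <- which(depth <= 0)[1]
    stop(sprintf("cell '%s' has zero sequencing depth", ids[bad]))
  }
  target <- if (kind == "read") 1e6 else stats::median(depth)
  scale_rows(m, target / depth)
}

row_sums <- function(m) {
  if (methods::is(m, "Matrix")) Matrix::rowSums(m) else rowSums(m)
}

scale_rows <- function(m, f) {
  if (methods::is(m, "Matrix")) {
    Matrix::Diagonal(x = f) %*% m
  } else {
    m * f
  }
}

#' Per-gene dropout and mean expression statistics
#'
#' For each gene `g`, computes the fraction of near-zero counts
#' `d_g = mean(X[, g] <= t)` and the mean log2 expression over counts
#' strictly above `t`. Genes with fewer than `n_min` cells above `t`
#' are flagged as discarded (their `d`/`m` are still reported where
#' defined). Statistics are meant to be computed on raw counts, before
#' depth normalisation.
#'
#' @param x a [count_matrix()] or a plain counts matrix.
#' @param t near-zero count threshold; defaults to 0 for UMI data and
#'   32 for read-count data (where lowly expressed markers otherwise
#'   fail to be selected).
#' @param n_min minimum number of expressing cells (default 10).
#' @return An object of class `"gene_stats"`: data frame with columns
#'   `gene`, `d`, `m`, `n_expressing`, `retained`, plus attributes
#'   `t` and `n_min`.
#' @export
gene_stats <- function(x, t = NULL, n_min = 10) {
  if (inherits(x, "count_matrix")) {
    if (is.null(t)) t <- if (x$count_kind == "umi") 0 else 32
    genes <- x$gene_ids
    m <- x$counts
  } else {
    if (is.null(t)) t <- 0
    genes <- colnames(x)
    if (is.null(genes)) genes <- sprintf("gene_%d", seq_len(ncol(x)))
    m <- x
  }
  m <- as.matrix(m)
  n <- nrow(m)
  above <- m > t
  n_expr <- colSums(above)
  d <- colMeans(m <= t)
  lm2 <- log2(m)
  lm2[!above] <- NA
  mg <- suppressWarnings(colMeans(lm2, na.rm = TRUE))
  mg[n_expr == 0] <- NA_real_
  out <- data.frame(gene = genes, d = d, m = mg,
                    n_expressing = as.integer(n_expr),
                    retained = n_expr >= n_min,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "t") <- t
  attr(out, "n_min") <- n_min
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' Dropout-based feature selection
#'
#' Selects the `M` most informative genes by their position in the
#' dropout-vs-mean-expression plane: a gene is selected when
#' `d_g > exp(-a * (m_g - b)) + 0.02`, with the offset `b` found by
#' binary search so that exactly `M` retained genes satisfy the
#' condition. Genes discarded by the `n_min` filter never qualify.
#' When ties or plateaus make exactly `M` unattainable, the nearest
#' achievable count is returned with a warning.
#'
#' @param stats a [gene_stats()] result.
#' @param M number of genes to select.
#' @param a steepness of the selection boundary (default 1.5; 1.0 suits
#'   data with flatter dropout curves).
#' @return A list with `selected` (integer column indices into the
#'   original matrix), `genes` (their ids), `b` (the boundary offset)
#'   and `n_selected`.
#' @export
select_features <- function(stats, M, a = 1.5) {
  stopifnot(inherits(stats, "gene_stats"), M >= 1)
  ok <- stats$retained & !is.na(stats$m) & stats$d > 0.02
  if (M > sum(stats$retained)) {
    stop(sprintf("M = %d exceeds the %d retained genes", M,
                 sum(stats$retained)))
  }
  d <- stats$d[ok]
  m <- stats$m[ok]
  idx <- which(ok)

  count_at <- function(b) sum(d > exp(-a * (m - b)) + 0.02)

  # the selected count is non-increasing in b; bracket then bisect
  lo <- min(m) - 60 / a   # count(lo) is maximal
  hi <- max(m) + 60 / a   # count(hi) == 0
  if (count_at(lo) < M) {
    warning(sprintf("only %d genes can ever satisfy the criterion; %s",
                    count_at(lo), "returning nearest achievable count"))
    b <- lo
  } else {
    stopifnot(count_at(lo) >= count_at(hi))
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (count_at(mid) >= M) lo <- mid else hi <- mid
    }
    # smallest b attaining M genes lies at the bracket; prefer a point
    # whose count is exactly M
    b <- if (count_at(lo) == M) lo else hi
    if (count_at(b) != M) {
      # tie/plateau: counts jump past M
      cl <- count_at(lo); ch <- count_at(hi)
      b <- if (abs(cl - M) <= abs(ch - M)) lo else hi
      warning(sprintf(
        "no offset selects exactly %d genes (tie); selected %d instead",
        M, count_at(b)))
    }
  }
  sel <- idx[d > exp(-a * (m - b)) + 0.02]
  list(selected = sel, genes = stats$gene[sel], b = b,
       n_selected = length(sel))
}

#' Log transform for count data
#'
#' Entrywise `log2(x + 1)`; zeros map to zeros, so sparse input stays
#' sparse.
#'
#' @param m nonnegative matrix.
#' @return Transformed matrix of the same shape.
#' @export
log_transform <- function(m) {
  if (min_value(m) < 0) stop("log_transform requires nonnegative input")
  if (methods::is(m, "sparseMatrix")) {
    m@x <- log2(m@x + 1)
    m
  } else {
    log2(m + 1)
  }
}

#' Inverse hyperbolic sine transform
#'
#' Entrywise `asinh(x / r)`, the variance-stabilising transformation of
#' a negative binomial with dispersion parameter `r`. An alternative to
#' [log_transform()]; not part of the default pipeline.
#'
#' @param m nonnegative matrix.
#' @param r scale parameter (default 5).
#' @return Transformed matrix.
#' @export
arsinh_transform <- function(m, r = 5) {
  if (methods::is(m, "sparseMatrix")) {
    m@x <- asinh(m@x / r)
    m
  } else {
    asinh(m / r)
  }
}

#' Column standardisation
#'
#' Centres every column to mean zero and scales to unit variance.
#' Constant columns are centred but left unscaled (they become all
#' zeros), with a warning.
#'
#' @param m numeric matrix.
#' @return Dense matrix of z-scored columns.
#' @export
standardize_columns <- function(m) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  const <- s == 0 | !is.finite(s)
  if (any(const)) {
    warning(sprintf("%d constant column(s) centred but not scaled",
                    sum(const)))
    s[const] <- 1
  }
  sweep(sweep(m, 2, mu, "-"), 2, s, "/")
}

#' Principal component analysis with a reproducible sign convention
#'
#' Reduces an n x p matrix to its `n_components` leading principal
#' components. The sign of each component is fixed so that the entries
#' of its loading vector sum to a nonnegative value, which makes scores
#' (and any embedding initialised from them) reproducible across runs
#' and platforms.
#'
#' @param m numeric matrix (rows are observations).
#' @param n_components number of components (default 50, capped at
#'   `min(n, p)`).
#' @return An object of class `"pc_space"`: list with `scores`
#'   (n x n_components), `rotation` (p x n_components orthonormal
#'   loadings), `explained_variance`, and `center`.
#' @export
reduce_pca <- function(m, n_components = 50) {
  m <- as.matrix(m)
  n <- nrow(m)
  p <- ncol(m)
  k <- min(n_components, n, p)
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu, "-")
  sv <- svd(xc, nu = 0, nv = k)
  rot <- sv$v[, seq_len(k), drop = FALSE]
  flip <- colSums(rot) < 0
  rot[, flip] <- -rot[, flip]
  scores <- xc %*% rot
  ev <- (sv$d[seq_len(k)]^2) / (n - 1)
  structure(list(scores = scores, rotation = rot,
                 explained_variance = ev, center = mu),
            class = "pc_space")
}

#' @export
print.pc_space <- function(x, ...) {
  cat(sprintf("pc_space: %d observations x %d components\n",
              nrow(x$scores), ncol(x$scores)))
  tot <- sum(x$explained_variance)
  cat(sprintf("  leading components explain %.1f%% ... %.1f%% of their span\n",
              100 * x$explained_variance[1] / tot,
              100 * x$explained_variance[length(x$explained_variance)] / tot))
  invisible(x)
}

#' Standard preprocessing pipeline for count data
#'
#' Runs, in fixed order: dropout-based feature selection on the raw
#' counts, depth normalisation of the selected genes, `log2(x+1)` (or
#' arsinh) transform, optional column standardisation, and PCA to
#' `n_components` components.
#'
#' @param x a [count_matrix()].
#' @param M number of genes to select (default 1000).
#' @param a selection-boundary steepness, see [select_features()].
#' @param t near-zero threshold, see [gene_stats()].
#' @param n_min minimum expressing cells (default 10).
#' @param standardize standardise columns after the transform
#'   (default `FALSE`: log counts are already on a common scale).
#' @param n_components PCA dimensionality (default 50).
#' @param transform `"log2"` (default) or `"arsinh"`.
#' @return A list with `pcs` (the [reduce_pca()] result), `selected`
#'   (gene column indices), `genes` (their ids), `b`, and `log_expression`
#'   (the n x M transformed matrix of selected genes, useful as a
#'   reference-atlas expression table).
#' @export
preprocess_counts <- function(x, M = 1000, a = 1.5, t = NULL, n_min = 10,
                              standardize = FALSE, n_components = 50,
                              transform = c("log2", "arsinh")) {
  stopifnot(inherits(x, "count_matrix"))
  transform <- match.arg(transform)
  stats <- gene_stats(x, t = t, n_min = n_min)
  sel <- select_features(stats, M = M, a = a)
  norm <- normalize_depth(x)
  sub <- as.matrix(norm[, sel$selected, drop = FALSE])
  expr <- if (transform == "log2") log_transform(sub) else
    arsinh_transform(sub)
  mat <- if (standardize) standardize_columns(expr) else expr
  pcs <- reduce_pca(mat, n_components = n_components)
  list(pcs = pcs, selected = sel$selected, genes = sel$genes, b = sel$b,
       log_expression = expr)
}
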