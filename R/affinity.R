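#' Exact k-nearest-neighbour search
#'
#' Blocked exact search by squared Euclidean distance. Ties are broken
#' by point index (ascending), and the query point itself is excluded.
#'
#' @param x numeric matrix, one observation per row.
#' @param k number of neighbours, `1 <= k <= n - 1`.
#' @return A list with `idx` (n x k neighbour indices, 1-based) and
#'   `dist2` (n x k squared distances), each row sorted by distance.
#' @export
knn_search <- function(x, k) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  stopifnot(k >= 1, k <= n - 1)
  .knn_exact_cpp(x, as.integer(k))
}

#' Calibrate a Gaussian kernel row to a target perplexity
#'
#' Finds the bandwidth `sigma` for which the neighbour distribution
#' `p_j ~ exp(-d2_j / (2 sigma^2))` attains the target perplexity
#' (exponentiated entropy), by bisection on `log(sigma^2)` over
#' `[log 1e-20, log 1e20]`. The largest attainable perplexity equals
#' the number of candidates (uniform distribution at infinite
#' bandwidth).
#'
#' @param sq_distances vector of squared distances to candidate
#'   neighbours.
#' @param perplexity target perplexity, `< length(sq_distances) + 1`.
#' @param tol tolerance on the achieved perplexity (default 1e-5).
#' @param max_iter maximum bisection iterations (default 200).
#' @return A list with `p` (the calibrated probability vector) and
#'   `sigma`.
#' @export
calibrate_kernel <- function(sq_distances, perplexity, tol = 1e-5,
                             max_iter = 200) {
  d2 <- as.numeric(sq_distances)
  m <- length(d2)
  stopifnot(m >= 1, perplexity > 0)
  if (perplexity > m) {
    stop(sprintf("perplexity %g exceeds the %d candidate neighbours",
                 perplexity, m))
  }
  res <- .calibrate_rows_cpp(matrix(d2, nrow = 1), perplexity,
                             tol, as.integer(max_iter))
  if (is.na(res$sigma[1])) {
    stop(sprintf(paste0("degenerate row: perplexity %g unreachable ",
                        "(achieved %.6g with %d candidates)"),
                 perplexity, res$achieved[1], m))
  }
  list(p = as.numeric(res$P[1, ]), sigma = res$sigma[1])
}

calibrate_matrix <- function(dist2, perplexity, tol = 1e-5, max_iter = 200) {
  res <- .calibrate_rows_cpp(dist2, perplexity, tol, as.integer(max_iter))
  bad <- which(is.na(res$sigma))
  if (length(bad) > 0) {
    stop(sprintf(paste0("degenerate row %d: perplexity %g unreachable ",
                        "(achieved %.6g)"),
                 bad[1], perplexity, res$achieved[bad[1]]))
  }
  res
}

#' Perplexity-calibrated conditional affinities
#'
#' Computes the directional similarities `p_{j|i}` of t-SNE: each
#' point's Gaussian kernel is calibrated so its neighbour distribution
#' has the target perplexity, and all mass beyond the `3 * perplexity`
#' nearest neighbours is truncated to zero (those tail probabilities
#' are negligible at any perplexity). Each row sums to 1.
#'
#' @param x data matrix (rows are points), typically PC scores.
#' @param perplexity target perplexity; must satisfy
#'   `3 * perplexity < n`.
#' @param knn optional precomputed [knn_search()] result with at least
#'   `floor(3 * perplexity)` neighbours per row (extra columns are
#'   ignored); avoids repeating the search across perplexities.
#' @param tol perplexity tolerance (default 1e-5).
#' @return An object of class `"conditional_affinities"`: list with
#'   `P` (n x n sparse row-stochastic [Matrix::dgCMatrix]), `sigmas`,
#'   `perplexities`, and the neighbour index matrix `knn_idx`.
#' @export
conditional_affinities <- function(x, perplexity, knn = NULL, tol = 1e-5) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- floor(3 * perplexity)
  if (k >= n) stop(sprintf("3 * perplexity = %d must be < n = %d", k, n))
  k <- max(k, 2L)
  if (is.null(knn)) knn <- knn_search(x, k)
  if (ncol(knn$idx) < k) {
    stop(sprintf("precomputed knn has %d neighbours; need %d",
                 ncol(knn$idx), k))
  }
  idx <- knn$idx[, seq_len(k), drop = FALSE]
  d2 <- knn$dist2[, seq_len(k), drop = FALSE]
  cal <- calibrate_matrix(d2, perplexity, tol = tol)
  P <- Matrix::sparseMatrix(i = rep(seq_len(n), times = k),
                            j = as.vector(idx),
                            x = as.vector(cal$P),
                            dims = c(n, n))
  structure(list(P = P, sigmas = as.numeric(cal$sigma),
                 perplexities = perplexity, knn_idx = idx),
            class = "conditional_affinities")
}

#' Multi-scale conditional affinities
#'
#' Calibrates conditional affinities at each perplexity in
#' `perplexities` and averages the resulting distributions row-wise,
#' capturing local and mesoscopic neighbourhood scales at once. All
#' components share the neighbour support of the largest scale
#' (`3 * max(perplexities)` nearest neighbours), so the average is an
#' elementwise mean of aligned sparse matrices and every row still
#' sums to 1.
#'
#' @inheritParams conditional_affinities
#' @param perplexities numeric vector of target perplexities.
#' @return A `"conditional_affinities"` object; `sigmas` is a matrix
#'   with one column per perplexity.
#' @export
multiscale_affinities <- function(x, perplexities, knn = NULL, tol = 1e-5) {
  stopifnot(length(perplexities) >= 1)
  x <- as.matrix(x)
  n <- nrow(x)
  k <- floor(3 * max(perplexities))
  if (k >= n) stop(sprintf("3 * max(perplexity) = %d must be < n = %d", k, n))
  k <- max(k, 2L)
  if (is.null(knn)) knn <- knn_search(x, k)
  idx <- knn$idx[, seq_len(k), drop = FALSE]
  d2 <- knn$dist2[, seq_len(k), drop = FALSE]
  pm <- matrix(0, n, k)
  sigmas <- matrix(NA_real_, n, length(perplexities))
  for (s in seq_along(perplexities)) {
    cal <- calibrate_matrix(d2, perplexities[s], tol = tol)
    pm <- pm + cal$P
    sigmas[, s] <- cal$sigma
  }
  pm <- pm / length(perplexities)
  P <- Matrix::sparseMatrix(i = rep(seq_len(n), times = k),
                            j = as.vector(idx),
                            x = as.vector(pm),
                            dims = c(n, n))
  structure(list(P = P, sigmas = sigmas, perplexities = perplexities,
                 knn_idx = idx),
            class = "conditional_affinities")
}

#' @export
print.conditional_affinities <- function(x, ...) {
  cat(sprintf(
    "conditional_affinities: n = %d, perplexities {%s}, <= %d nnz/row\n",
    nrow(x$P), paste(x$perplexities, collapse = ", "), ncol(x$knn_idx)))
  invisible(x)
}

#' Symmetrise conditional affinities
#'
#' Forms the joint similarities `p_ij = (p_{i|j} + p_{j|i}) / (2n)`,
#' a symmetric probability distribution over all point pairs
#' (total sum 1, zero diagonal).
#'
#' @param cond a `"conditional_affinities"` object (or a row-stochastic
#'   sparse matrix).
#' @return A sparse symmetric [Matrix::dgCMatrix] with attribute
#'   `"perplexities"`.
#' @export
symmetrize_affinities <- function(cond) {
  if (inherits(cond, "conditional_affinities")) {
    C <- cond$P
    perp <- cond$perplexities
  } else {
    C <- cond
    perp <- NULL
  }
  n <- nrow(C)
  P <- (C + Matrix::t(C)) / (2 * n)
  P <- methods::as(P, "generalMatrix")
  P <- methods::as(P, "CsparseMatrix")
  attr(P, "perplexities") <- perp
  P
}

#' High-dimensional affinities in one call
#'
#' Convenience wrapper: multi-scale (or single-scale) conditional
#' affinities followed by symmetrisation.
#'
#' @inheritParams multiscale_affinities
#' @return A sparse symmetric affinity matrix summing to 1.
#' @export
affinity_matrix <- function(x, perplexities, knn = NULL, tol = 1e-5) {
  symmetrize_affinities(
    multiscale_affinities(x, perplexities, knn = knn, tol = tol))
}
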