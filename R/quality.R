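#' K-nearest-neighbour preservation (microscopic structure)
#'
#' The mean, over all points, of the fraction of each point's k
#' nearest neighbours in the high-dimensional data that are also among
#' its k nearest neighbours in the embedding. Neighbours are by
#' Euclidean distance, the point itself excluded; exact ties are
#' broken by point index. 1 means perfect local preservation.
#'
#' @param x high-dimensional matrix, the representation handed to the
#'   embedder (PC scores in the standard pipeline).
#' @param y embedding coordinates (same row order).
#' @param k neighbourhood size (default 10).
#' @param x_knn optional precomputed [knn_search()] result for `x`
#'   with at least k neighbours, to amortise the search across several
#'   embeddings of the same data.
#' @return A value in [0, 1].
#' @export
knn_preservation <- function(x, y, k = 10, x_knn = NULL) {
  y <- as.matrix(y)
  n <- nrow(y)
  stopifnot(k < n)
  if (is.null(x_knn)) x_knn <- knn_search(as.matrix(x), k)
  stopifnot(nrow(x_knn$idx) == n, ncol(x_knn$idx) >= k)
  idx_x <- x_knn$idx[, seq_len(k), drop = FALSE]
  idx_y <- knn_search(y, k)$idx
  shared <- vapply(seq_len(n), function(i) {
    length(intersect(idx_x[i, ], idx_y[i, ]))
  }, integer(1))
  mean(shared) / k
}

#' K-nearest-classes preservation (mesoscopic structure)
#'
#' Class means are computed in the high-dimensional data and in the
#' embedding; for every class, the fraction of its k nearest class
#' means (by Euclidean distance) that coincide between the two spaces
#' is recorded, then averaged over classes. 1 means the between-class
#' arrangement is preserved.
#'
#' @inheritParams knn_preservation
#' @param labels class label per row (any atomic vector).
#' @param k number of neighbouring class means, `<` number of classes.
#' @return A value in [0, 1].
#' @export
knc_preservation <- function(x, y, labels, k = 10) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  stopifnot(length(labels) == nrow(x), nrow(x) == nrow(y))
  labels <- as.factor(labels)
  if (any(table(labels) == 0)) stop("class with zero members")
  cls <- levels(labels)
  stopifnot(k < length(cls))
  mx <- class_means(x, labels)
  my <- class_means(y, labels)
  nb_x <- neighbour_sets(mx, k)
  nb_y <- neighbour_sets(my, k)
  mean(vapply(seq_along(cls), function(i) {
    length(intersect(nb_x[[i]], nb_y[[i]])) / k
  }, numeric(1)))
}

class_means <- function(m, labels) {
  g <- rowsum(m, labels)
  g / as.vector(table(labels)[rownames(g)])
}

neighbour_sets <- function(means, k) {
  d <- as.matrix(stats::dist(means))
  lapply(seq_len(nrow(d)), function(i) {
    ord <- order(d[i, -i])         # ties: index order via stable sort
    setdiff(seq_len(nrow(d)), i)[ord][seq_len(k)]
  })
}

#' Correlation of pairwise distances (macroscopic structure)
#'
#' Spearman rank correlation between high-dimensional and embedded
#' pairwise Euclidean distances, over all pairs among `n_sample`
#' points drawn without replacement (all points when `n <= n_sample`).
#' Ranks use average-rank tie handling. 1 means distance ordering is
#' perfectly preserved.
#'
#' @inheritParams knn_preservation
#' @param n_sample subsample size (default 1000; 1000 points give
#'   499,500 pairs).
#' @param seed seed for the subsample draw.
#' @param full return a list with evaluation details instead of the
#'   bare value.
#' @return The correlation in [-1, 1], or (if `full`) a list with
#'   `value`, `n_sample`, `n_pairs`, `seed`.
#' @export
cpd <- function(x, y, n_sample = 1000, seed = 42, full = FALSE) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  stopifnot(nrow(y) == n)
  if (n > n_sample) {
    set.seed(seed)
    keep <- sample.int(n, n_sample)
  } else {
    keep <- seq_len(n)
  }
  dx <- as.numeric(stats::dist(x[keep, , drop = FALSE]))
  dy <- as.numeric(stats::dist(y[keep, , drop = FALSE]))
  value <- stats::cor(dx, dy, method = "spearman")
  if (!full) return(value)
  list(value = value, n_sample = length(keep), n_pairs = length(dx),
       seed = seed)
}

#' Micro/meso/macro quality report for an embedding
#'
#' Evaluates [knn_preservation()], [knc_preservation()] (when labels
#' are given) and [cpd()] with their evaluation parameters recorded.
#'
#' @inheritParams knn_preservation
#' @param labels optional class labels for KNC.
#' @param knn_k,knc_k,cpd_sample metric parameters.
#' @param seed seed for the CPD subsample.
#' @return An object of class `"quality_report"`.
#' @export
quality_report <- function(x, y, labels = NULL, knn_k = 10, knc_k = 10,
                           cpd_sample = 1000, seed = 42, x_knn = NULL) {
  cp <- cpd(x, y, n_sample = cpd_sample, seed = seed, full = TRUE)
  structure(list(
    knn = knn_preservation(x, y, k = knn_k, x_knn = x_knn),
    knn_k = knn_k,
    knc = if (is.null(labels)) NA_real_ else
      knc_preservation(x, y, labels, k = knc_k),
    knc_k = knc_k,
    cpd = cp$value, cpd_sample = cp$n_sample, cpd_pairs = cp$n_pairs,
    seed = seed), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("embedding quality: KNN(k=%d) = %.3f", x$knn_k, x$knn))
  if (!is.na(x$knc)) cat(sprintf(", KNC(k=%d) = %.3f", x$knc_k, x$knc))
  cat(sprintf(", CPD(%d pts) = %.3f\n", x$cpd_sample, x$cpd))
  invisible(x)
}

#' @export
format.quality_report <- function(x, ...) {
  sprintf("KNN %.2f / KNC %.2f / CPD %.2f", x$knn, x$knc, x$cpd)
}
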