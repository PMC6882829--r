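#' Kullback-Leibler divergence of an embedding
#'
#' The t-SNE loss: `sum p_ij log(p_ij / q_ij)` over pairs with
#' `p_ij > 0`, where `q_ij = w_ij / Z` is the Cauchy-kernel similarity
#' of the layout. Computed exactly with dense pairwise weights, so
#' intended for moderate n.
#'
#' @param P symmetric affinity matrix (sparse or dense) summing to 1.
#' @param Y n x 2 embedding coordinates.
#' @return The divergence (nonnegative).
#' @export
kl_divergence <- function(P, Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(nrow(P) == n, ncol(P) == n)
  W <- cauchy_weights(Y)
  Z <- sum(W)
  Pm <- as.matrix(P)
  pos <- Pm > 0
  sum(Pm[pos] * log(Pm[pos] / (W[pos] / Z)))
}

cauchy_weights <- function(Y) {
  d2 <- as.matrix(stats::dist(Y))^2
  W <- 1 / (1 + d2)
  diag(W) <- 0
  W
}

#' Exact t-SNE gradient
#'
#' The analytic gradient of the exaggerated loss
#' `alpha * (attractive term) + (repulsive term)`,
#' i.e. `4 * (alpha * sum_j p_ij w_ij (y_i - y_j)
#' - (1/Z) * sum_j w_ij^2 (y_i - y_j))`.
#' At `alpha = 1` this is the gradient of [kl_divergence()]. Note the
#' optimiser ([tsne_optimize()]) follows the reference-implementation
#' convention of omitting the constant factor 4, which is folded into
#' the meaning of its learning rate (so eta = n/12 behaves as the
#' protocol intends).
#'
#' @param P symmetric affinity matrix summing to 1.
#' @param Y n x 2 coordinates.
#' @param exaggeration attractive-term multiplier `alpha >= 1`.
#' @return n x 2 gradient matrix; its columns sum to zero
#'   (translation invariance).
#' @export
tsne_gradient <- function(P, Y, exaggeration = 1) {
  stopifnot(exaggeration >= 1)
  Y <- as.matrix(Y)
  W <- cauchy_weights(Y)
  Z <- sum(W)
  Pm <- as.matrix(P)
  A <- exaggeration * Pm * W - (W * W) / Z
  # grad_i = 4 * sum_j A_ij (y_i - y_j)
  4 * (rowSums(A) * Y - A %*% Y)
}

#' Random embedding initialisation
#'
#' I.i.d. Gaussian coordinates with standard deviation 1e-4. Small
#' initial magnitudes are required for reliable convergence.
#'
#' @param n number of points.
#' @param seed integer seed (default 42).
#' @return n x 2 matrix.
#' @export
tsne_init_random <- function(n, seed = 42) {
  set.seed(seed)
  matrix(stats::rnorm(2 * n, sd = 1e-4), ncol = 2)
}

#' PCA embedding initialisation
#'
#' The first two principal-component scores, divided by the standard
#' deviation of PC1 and multiplied by 1e-4, so the layout starts at
#' the same scale as the random initialisation but already carries the
#' data's global geometry. Deterministic thanks to the PCA sign
#' convention (see [reduce_pca()]).
#'
#' @param x a `"pc_space"` from [reduce_pca()], or a data matrix
#'   (PCA is computed on the fly).
#' @return n x 2 matrix whose first column has standard deviation
#'   exactly 1e-4.
#' @export
tsne_init_pca <- function(x) {
  if (!inherits(x, "pc_space")) x <- reduce_pca(as.matrix(x), 2)
  stopifnot(ncol(x$scores) >= 2)
  tsne_init_rescale(x$scores[, 1:2, drop = FALSE])
}

#' Rescale a layout to the initialisation scale
#'
#' Divides both coordinates by the standard deviation of the first
#' coordinate and multiplies by 1e-4 -- the scaling convention shared
#' by PCA, downsampling-based, and aligned initialisations.
#'
#' @param Y n x 2 coordinates.
#' @return Rescaled n x 2 matrix (first column sd = 1e-4).
#' @export
tsne_init_rescale <- function(Y) {
  Y <- as.matrix(Y)
  s <- stats::sd(Y[, 1])
  if (s == 0) stop("cannot rescale: first coordinate is constant")
  Y / s * 1e-4
}

#' Data-size-dependent learning rate
#'
#' `max(200, n / 12)`: the default 200 of most implementations is kept
#' for small data, and grows linearly with n (12 being the early
#' exaggeration factor) to avoid poorly converged, fragmented
#' embeddings at large n.
#'
#' @param n number of points.
#' @return The learning rate.
#' @export
tsne_learning_rate <- function(n) {
  stopifnot(n >= 1)
  max(200, n / 12)
}

#' Optimiser configuration
#'
#' Collects the gradient-descent schedule: iteration count, learning
#' rate, the 0.5/0.8 momentum switch, early exaggeration (alpha = 12
#' for the first 250 iterations), the post-early exaggeration level
#' (1 = plain t-SNE; ~4 counteracts cluster over-expansion in very
#' large embeddings), the Barnes-Hut accuracy parameter theta
#' (0 = exact; `NULL` resolves to 0 for n <= 5000 and 0.5 above), and
#' the seed used by random initialisation.
#'
#' @param n_iter total iterations (default 1000).
#' @param eta learning rate; `NULL` resolves to [tsne_learning_rate()]
#'   at run time (use 200 to force the common default).
#' @param momentum_early,momentum_late momentum before/after the switch.
#' @param momentum_switch_iter iteration of the momentum switch.
#' @param early_exaggeration alpha for the early phase (default 12).
#' @param early_exaggeration_iter length of the early phase; the
#'   default 250 is clamped to `n_iter` for short runs.
#' @param exaggeration alpha after the early phase (default 1).
#' @param theta Barnes-Hut accuracy (see above).
#' @param seed integer seed (default 42).
#' @return An object of class `"tsne_config"`.
#' @export
tsne_config <- function(n_iter = 1000, eta = NULL,
                        momentum_early = 0.5, momentum_late = 0.8,
                        momentum_switch_iter = 250,
                        early_exaggeration = 12,
                        early_exaggeration_iter = min(250, n_iter),
                        exaggeration = 1, theta = NULL, seed = 42) {
  stopifnot(n_iter >= 0, is.null(eta) || eta > 0,
            early_exaggeration >= 1, exaggeration >= 1,
            early_exaggeration_iter <= max(n_iter, 1),
            momentum_switch_iter >= 0,
            is.null(theta) || theta >= 0)
  structure(list(n_iter = as.integer(n_iter), eta = eta,
                 momentum_early = momentum_early,
                 momentum_late = momentum_late,
                 momentum_switch_iter = as.integer(momentum_switch_iter),
                 early_exaggeration = early_exaggeration,
                 early_exaggeration_iter = as.integer(early_exaggeration_iter),
                 exaggeration = exaggeration,
                 theta = theta, seed = as.integer(seed)),
            class = "tsne_config")
}

#' @export
print.tsne_config <- function(x, ...) {
  cat("tsne_config:\n")
  cat(sprintf("  %d iterations, eta = %s, theta = %s, seed = %d\n",
              x$n_iter,
              if (is.null(x$eta)) "auto (max(200, n/12))" else
                format(x$eta),
              if (is.null(x$theta)) "auto (0 if n <= 5000 else 0.5)" else
                format(x$theta), x$seed))
  cat(sprintf("  momentum %g -> %g at iter %d\n", x$momentum_early,
              x$momentum_late, x$momentum_switch_iter))
  cat(sprintf("  exaggeration %g for %d iters, then %g\n",
              x$early_exaggeration, x$early_exaggeration_iter,
              x$exaggeration))
  invisible(x)
}

resolve_theta <- function(theta, n) {
  if (!is.null(theta)) theta else if (n <= 5000) 0 else 0.5
}

#' Run the t-SNE gradient descent
#'
#' Adaptive gradient descent with momentum on the (exaggerated) t-SNE
#' loss: per-coordinate gains start at 1, grow by 0.2 when gradient
#' and velocity agree in descent direction, shrink by the factor 0.8
#' otherwise, floored at 0.01. Early exaggeration multiplies the
#' attractive forces during the first phase; momentum switches from
#' 0.5 to 0.8 at `momentum_switch_iter`. Repulsive forces use the
#' exact pairwise sums (`theta = 0`) or the Barnes-Hut quadtree
#' approximation. The run is deterministic given its inputs.
#'
#' @param P symmetric sparse affinity matrix summing to 1 (from
#'   [affinity_matrix()] / [symmetrize_affinities()]).
#' @param init n x 2 initial coordinates (see [tsne_init_pca()],
#'   [tsne_init_random()]); a warning is issued if their scale is far
#'   from the intended 1e-4.
#' @param config a [tsne_config()].
#' @param record_cost record the (unexaggerated) KL divergence at each
#'   iteration (adds an exact-Z pass; meant for diagnostics at small n).
#' @return n x 2 matrix of final coordinates, with attribute `"config"`
#'   (resolved parameters) and, if requested, `"cost"`.
#' @export
tsne_optimize <- function(P, init, config = tsne_config(),
                          record_cost = FALSE) {
  init <- as.matrix(init)
  n <- nrow(init)
  stopifnot(nrow(P) == n, ncol(P) == n, ncol(init) == 2)
  if (max(abs(init)) > 0.1) {
    warning("initial coordinates have large magnitude; ",
            "the optimiser expects an init on the 1e-4 scale")
  }
  eta <- if (is.null(config$eta)) tsne_learning_rate(n) else config$eta
  theta <- resolve_theta(config$theta, n)
  if (config$n_iter == 0) return(init)

  csr <- affinity_csr(P)
  res <- .tsne_optimize_cpp(csr$indptr, csr$indices, csr$values, init,
                            config$n_iter, eta,
                            config$momentum_early, config$momentum_late,
                            config$momentum_switch_iter,
                            config$early_exaggeration,
                            config$early_exaggeration_iter,
                            config$exaggeration, theta, record_cost)
  if (res$diverged_at > 0) {
    stop(sprintf(
      "t-SNE diverged (non-finite coordinates) at iteration %d with eta = %g",
      res$diverged_at, eta))
  }
  Y <- res$Y
  resolved <- config
  resolved$eta <- eta
  resolved$theta <- theta
  attr(Y, "config") <- resolved
  if (record_cost) attr(Y, "cost") <- as.numeric(res$cost)
  Y
}

# CSR view of a symmetric sparse matrix (CSC of a symmetric matrix is
# its own CSR).
affinity_csr <- function(P) {
  P <- methods::as(methods::as(P, "CsparseMatrix"), "generalMatrix")
  list(indptr = P@p, indices = P@i, values = P@x)
}

#' Approximate repulsive forces of a layout
#'
#' Quadtree-based Barnes-Hut evaluation of the repulsive force field
#' `(1/Z) sum_j w_ij^2 (y_i - y_j)` and of the normaliser
#' `Z = sum_{k != l} w_kl`. Distant groups of points are replaced by
#' their centre of mass whenever cell size / distance < `theta`;
#' `theta = 0` computes the exact sums.
#'
#' @param Y n x 2 coordinates.
#' @param theta accuracy parameter, >= 0 (default 0.5).
#' @return List with `forces` (n x 2 repulsive gradient component) and
#'   `Z`.
#' @export
tsne_repulsion <- function(Y, theta = 0.5) {
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) == 2, theta >= 0)
  res <- .bh_repulsion_cpp(Y, theta)
  list(forces = res$forces / res$Z, Z = res$Z)
}

#' Embed a data matrix with t-SNE
#'
#' High-level interface: builds (multi-scale) affinities, chooses the
#' initialisation, and runs the optimiser. Returns a
#' `"tsne_embedding"` object carrying the coordinates and every
#' resolved parameter.
#'
#' @param x numeric matrix (rows are points), typically 50 PC scores.
#' @param perplexity one or more perplexities; several values are
#'   combined multi-scale.
#' @param init `"pca"` (default), `"random"`, or an n x 2 matrix used
#'   as a custom initialisation (rescaled to the 1e-4 convention
#'   unless already at that scale).
#' @param config a [tsne_config()].
#' @param knn optional precomputed [knn_search()] result.
#' @return A `"tsne_embedding"`: list with `Y`, `perplexity`, `init`,
#'   `config` (resolved), and `n`.
#' @export
#' @examples
#' xs <- simulate_mixture(mixture_spec(points_per_type = c(60, 30, 15),
#'                                     dimension = 20))
#' emb <- tsne_embed(xs$data, perplexity = 10,
#'                   config = tsne_config(n_iter = 150))
#' plot(emb, col = xs$class)
tsne_embed <- function(x, perplexity = 30, init = "pca",
                       config = tsne_config(), knn = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  P <- affinity_matrix(x, perplexity, knn = knn)
  if (is.character(init)) {
    init_kind <- match.arg(init, c("pca", "random"))
    Y0 <- if (init_kind == "pca") tsne_init_pca(x) else
      tsne_init_random(n, seed = config$seed)
  } else {
    init_kind <- "custom"
    Y0 <- as.matrix(init)
    stopifnot(nrow(Y0) == n, ncol(Y0) == 2)
    if (max(abs(Y0)) > 0.1) Y0 <- tsne_init_rescale(Y0)
  }
  Y <- tsne_optimize(P, Y0, config)
  structure(list(Y = strip_attrs(Y), perplexity = perplexity,
                 init = init_kind, config = attr(Y, "config"), n = n),
            class = "tsne_embedding")
}

strip_attrs <- function(Y) {
  attr(Y, "config") <- NULL
  attr(Y, "cost") <- NULL
  Y
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat(sprintf("tsne_embedding: n = %d, perplexity {%s}, %s init\n",
              x$n, paste(x$perplexity, collapse = ", "), x$init))
  cat(sprintf("  eta = %g, exaggeration %g, %d iterations, theta = %g\n",
              x$config$eta, x$config$exaggeration, x$config$n_iter,
              x$config$theta))
  invisible(x)
}

#' @export
plot.tsne_embedding <- function(x, col = NULL, pch = 16, cex = 0.4, ...) {
  graphics::plot(x$Y[, 1], x$Y[, 2], col = if (is.null(col)) "grey30" else
    col, pch = pch, cex = cex, asp = 1,
    xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  invisible(x)
}

#' Rigid rotation of a layout
#'
#' Rotates (and optionally reflects) an embedding about its centroid.
#' Rigid transforms do not change inter-point distances, hence leave
#' all quality metrics unchanged; axes are never stretched
#' independently.
#'
#' @param Y n x 2 coordinates.
#' @param degrees rotation angle, counter-clockwise.
#' @param flip_x reflect the first axis after rotation.
#' @return Transformed n x 2 matrix.
#' @export
rotate_embedding <- function(Y, degrees = 0, flip_x = FALSE) {
  Y <- as.matrix(Y)
  ctr <- colMeans(Y)
  a <- degrees * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  out <- sweep(Y, 2, ctr) %*% R
  if (flip_x) out[, 1] <- -out[, 1]
  sweep(out, 2, ctr, "+")
}
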