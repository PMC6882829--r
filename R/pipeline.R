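#' Protocol parameters
#'
#' Tunables of the end-to-end recipes. `multiscale_threshold` is the
#' sample size from which the large perplexity `n/100` is combined with
#' 30 (the rule targets `n/100` well above 30; at the default it
#' activates once `n/100 >= 60`). The large-data recipe embeds a
#' `subsample_size` subsample first, positions the remaining cells on
#' it, and re-optimises everything with `exaggeration_large`.
#'
#' @param multiscale_threshold activate multi-scale from this n
#'   (default 6000).
#' @param subsample_size subsample of the large-data recipe
#'   (default 25000).
#' @param large_n_threshold sample size from which [run_large()] is
#'   intended (default 1e5).
#' @param exaggeration_large post-early exaggeration of the final
#'   large-data run (default 4).
#' @param k_position neighbours for the positioning step (default 10).
#' @param seed seed for subsampling and random init (default 42).
#' @param quiet suppress progress messages.
#' @return An object of class `"protocol_params"`.
#' @export
protocol_params <- function(multiscale_threshold = 6000,
                            subsample_size = 25000,
                            large_n_threshold = 100000,
                            exaggeration_large = 4,
                            k_position = 10,
                            seed = 42,
                            quiet = FALSE) {
  stopifnot(multiscale_threshold > 0, subsample_size > 0,
            large_n_threshold > 0, exaggeration_large >= 1,
            k_position >= 1)
  structure(list(multiscale_threshold = multiscale_threshold,
                 subsample_size = as.integer(subsample_size),
                 large_n_threshold = large_n_threshold,
                 exaggeration_large = exaggeration_large,
                 k_position = as.integer(k_position),
                 seed = as.integer(seed), quiet = isTRUE(quiet)),
            class = "protocol_params")
}

#' Perplexities used by the standard protocol at sample size n
#'
#' `{30, floor(n/100)}` once `n` reaches the multi-scale threshold;
#' plain `{30}` below it.
#'
#' @param n sample size.
#' @param params a [protocol_params()].
#' @return Numeric vector of perplexities.
#' @export
protocol_perplexities <- function(n, params = protocol_params()) {
  if (n >= params$multiscale_threshold) c(30, floor(n / 100)) else 30
}

say <- function(params, fmt, ...) {
  if (!isTRUE(params$quiet)) {
    message(format(Sys.time(), "[%H:%M:%S] "), sprintf(fmt, ...))
  }
}

#' The standard embedding protocol
#'
#' Multi-scale affinities (perplexity 30 combined with `n/100` for
#' large enough n), PCA initialisation, learning rate `max(200, n/12)`,
#' 1000 iterations with early exaggeration 12 for the first 250 and no
#' exaggeration afterwards. PCA initialisation makes the run
#' deterministic: repeated runs are identical. All resolved parameters
#' are returned so any run can be reconstructed.
#'
#' @param x n x d matrix, typically 50 PC scores from
#'   [preprocess_counts()].
#' @param labels optional class labels; enables KNC in the quality
#'   report.
#' @param params a [protocol_params()].
#' @param quality compute the [quality_report()] (default `TRUE`).
#' @param knc_k KNC neighbourhood size (default 10; the hierarchical
#'   synthetic benchmark is evaluated with 4).
#' @param knn optional precomputed [knn_search()] result.
#' @return A list of class `"protocol_run"` with `embedding`
#'   (`"tsne_embedding"`), `quality` (or `NULL`) and `parameters`
#'   (perplexities, eta, exaggeration schedule, seed).
#' @export
run_standard <- function(x, labels = NULL, params = protocol_params(),
                         quality = TRUE, knc_k = 10, knn = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n >= params$large_n_threshold) {
    warning("n is at or above large_n_threshold; consider run_large()")
  }
  perp <- protocol_perplexities(n, params)
  eta <- tsne_learning_rate(n)
  say(params, "standard protocol: n = %d, perplexities {%s}, eta = %g",
      n, paste(perp, collapse = ", "), eta)
  cfg <- tsne_config(eta = eta, seed = params$seed)
  emb <- tsne_embed(x, perplexity = perp, init = "pca", config = cfg,
                    knn = knn)
  qr <- NULL
  if (quality) {
    say(params, "computing quality metrics")
    qr <- quality_report(x, emb$Y, labels = labels, knc_k = knc_k,
                         seed = params$seed)
  }
  structure(list(embedding = emb, quality = qr,
                 parameters = list(n = n, perplexities = perp, eta = eta,
                                   early_exaggeration = 12,
                                   early_exaggeration_iter = 250,
                                   exaggeration = 1, n_iter = cfg$n_iter,
                                   init = "pca", seed = params$seed)),
            class = "protocol_run")
}

#' @export
print.protocol_run <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("protocol_run: n = %d, perplexities {%s}, eta = %g, %s\n",
              p$n, paste(p$perplexities, collapse = ", "), p$eta,
              if (!is.null(p$subsample_size))
                sprintf("large recipe (subsample %d, exaggeration %g)",
                        p$subsample_size, p$exaggeration)
              else sprintf("%s init", p$init)))
  if (!is.null(x$quality)) print(x$quality)
  invisible(x)
}

# blocked cross-set k nearest neighbours (squared Euclidean)
cross_knn <- function(query, ref, k, block = 1024) {
  query <- as.matrix(query)
  ref <- as.matrix(ref)
  stopifnot(k <= nrow(ref))
  rq <- rowSums(ref^2)
  nq <- nrow(query)
  idx <- matrix(NA_integer_, nq, k)
  for (start in seq(1, nq, by = block)) {
    rows <- start:min(nq, start + block - 1)
    qb <- query[rows, , drop = FALSE]
    d2 <- outer(rowSums(qb^2), rq, "+") - 2 * tcrossprod(qb, ref)
    for (r in seq_along(rows)) {
      idx[rows[r], ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  idx
}

#' The large-data embedding protocol
#'
#' Four steps: (i) draw a uniform random subsample of
#' `subsample_size` cells; (ii) embed it with [run_standard()];
#' (iii) position every remaining cell at the coordinate-wise median
#' of its k nearest subsample neighbours (Euclidean distance in the
#' input space -- PC scores -- since no batch effect is involved);
#' (iv) rescale the full layout to the initialisation convention and
#' run t-SNE on all n points with perplexity 30, learning rate `n/12`
#' and exaggeration `exaggeration_large` to counteract cluster
#' over-expansion.
#'
#' @inheritParams run_standard
#' @param force run even when `n < large_n_threshold` (for reduced-
#'   scale experiments).
#' @return A `"protocol_run"` whose `embedding` covers all n points;
#'   `subsample` holds the step-(ii) run and the subsample indices.
#' @export
run_large <- function(x, labels = NULL, params = protocol_params(),
                      quality = FALSE, knc_k = 10, force = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < params$large_n_threshold && !force) {
    stop("n below large_n_threshold; use run_standard() or force = TRUE")
  }
  stopifnot(params$subsample_size <= n)
  set.seed(params$seed)
  sub <- sort(sample.int(n, params$subsample_size))
  say(params, "large recipe: n = %d, subsample %d", n, length(sub))
  sub_run <- run_standard(x[sub, , drop = FALSE], params = params,
                          quality = FALSE)

  say(params, "positioning %d remaining cells (k = %d)",
      n - length(sub), params$k_position)
  init <- matrix(NA_real_, n, 2)
  init[sub, ] <- sub_run$embedding$Y
  rest <- setdiff(seq_len(n), sub)
  if (length(rest) > 0) {
    nb <- cross_knn(x[rest, , drop = FALSE], x[sub, , drop = FALSE],
                    params$k_position)
    for (r in seq_along(rest)) {
      init[rest[r], ] <- apply(
        sub_run$embedding$Y[nb[r, ], , drop = FALSE], 2, stats::median)
    }
  }
  init <- tsne_init_rescale(init)

  eta <- tsne_learning_rate(n)
  say(params, "final run: perplexity 30, eta = %g, exaggeration %g",
      eta, params$exaggeration_large)
  cfg <- tsne_config(eta = eta, exaggeration = params$exaggeration_large,
                     seed = params$seed)
  emb <- tsne_embed(x, perplexity = 30, init = init, config = cfg)
  qr <- NULL
  if (quality) {
    qr <- quality_report(x, emb$Y, labels = labels, knc_k = knc_k,
                         seed = params$seed)
  }
  structure(list(embedding = emb, quality = qr,
                 subsample = list(indices = sub, run = sub_run),
                 parameters = list(n = n, perplexities = 30, eta = eta,
                                   early_exaggeration = 12,
                                   early_exaggeration_iter = 250,
                                   exaggeration = params$exaggeration_large,
                                   n_iter = cfg$n_iter,
                                   init = "downsampling",
                                   subsample_size = length(sub),
                                   k_position = params$k_position,
                                   seed = params$seed)),
            class = "protocol_run")
}
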