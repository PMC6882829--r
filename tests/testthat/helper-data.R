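# Shared fixtures and independent oracles. Everything is generated in
# code; the heavier objects (the full benchmark, its neighbour graphs,
# embeddings reused by several tests) are memoised for the session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# the full 15,500-point hierarchical benchmark
bench <- function(seed = 1) {
  memo(paste0("bench_", seed), simulate_mixture(mixture_spec(seed = seed)))
}

# exact kNN of the benchmark in 50-d, with at least k columns
bench_knn <- function(seed = 1, k = 10) {
  key <- paste0("bench_knn_", seed)
  cur <- .fixtures[[key]]
  if (is.null(cur) || ncol(cur$idx) < k) {
    .fixtures[[key]] <- knn_search(bench(seed)$data, k)
  }
  .fixtures[[key]]
}

# small labelled Gaussian blobs in d dimensions
make_blobs <- function(n_per = 50, centers = 3, d = 2, sep = 10, sd = 1,
                       seed = 7) {
  set.seed(seed)
  ctr <- matrix(0, centers, d)
  for (i in seq_len(centers)) ctr[i, ((i - 1) %% d) + 1] <- (i - 1) * sep
  x <- do.call(rbind, lapply(seq_len(centers), function(i) {
    matrix(stats::rnorm(n_per * d, sd = sd), n_per, d) +
      matrix(ctr[i, ], n_per, d, byrow = TRUE)
  }))
  list(x = x, labels = rep(seq_len(centers), each = n_per))
}

# brute-force k nearest neighbours by double loop (ties by index)
brute_knn <- function(x, k) {
  n <- nrow(x)
  idx <- matrix(NA_integer_, n, k)
  d2m <- as.matrix(dist(x))^2
  for (i in seq_len(n)) {
    ord <- setdiff(order(d2m[i, ]), i)   # order() is stable
    idx[i, ] <- ord[seq_len(k)]
  }
  idx
}

# independent conditional-affinity oracle: per-row bisection on
# log(sigma^2) over the given candidate set, all in R
oracle_calibrate <- function(d2, target, tol = 1e-10) {
  probs <- function(ls2) {
    p <- exp(-(d2 - min(d2)) / (2 * exp(ls2)))
    p / sum(p)
  }
  # perplexity = exp(entropy in nats)
  perp <- function(p) exp(-sum(p[p > 0] * log(p[p > 0])))
  lo <- log(1e-20); hi <- log(1e20)
  for (it in 1:300) {
    mid <- (lo + hi) / 2
    pe <- perp(probs(mid))
    if (abs(pe - target) < tol) break
    if (pe > target) hi <- mid else lo <- mid
  }
  list(p = probs(mid), sigma = sqrt(exp(mid)))
}

# dense conditional affinities over all n-1 candidates (no truncation)
oracle_conditional <- function(x, perplexity) {
  n <- nrow(x)
  d2m <- as.matrix(dist(x))^2
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    P[i, cand] <- oracle_calibrate(d2m[i, cand], perplexity)$p
  }
  P
}

# is each point inside (or on) the convex hull of pts?
in_convex_hull <- function(query, pts) {
  h <- grDevices::chull(pts[, 1], pts[, 2])
  poly <- pts[h, , drop = FALSE]   # counter-clockwise
  m <- nrow(poly)
  apply(query, 1, function(q) {
    s <- vapply(seq_len(m), function(i) {
      a <- poly[i, ]; b <- poly[if (i == m) 1 else i + 1, ]
      (b[1] - a[1]) * (q[2] - a[2]) - (b[2] - a[2]) * (q[1] - a[1])
    }, numeric(1))
    all(s <= 1e-9) || all(s >= -1e-9)
  })
}

# toy count matrix with heterogeneous depths and dropout structure
make_counts <- function(n_cells = 60, n_genes = 50, seed = 11,
                        kind = "umi") {
  set.seed(seed)
  mu <- exp(stats::runif(n_genes, 0, 5))          # mean expression
  drop <- stats::runif(n_genes, 0.05, 0.95)       # extra dropout
  m <- sapply(seq_len(n_genes), function(g) {
    x <- stats::rpois(n_cells, mu[g])
    x[stats::runif(n_cells) < drop[g]] <- 0
    x
  })
  count_matrix(m, gene_ids = sprintf("g%02d", seq_len(n_genes)),
               cell_ids = sprintf("c%02d", seq_len(n_cells)),
               count_kind = kind)
}
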