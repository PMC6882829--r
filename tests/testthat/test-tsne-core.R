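# A small affinity/layout fixture shared by the gradient tests.
grad_fixture <- function(seed = 20, n_per = 15) {
  b <- make_blobs(n_per = n_per, centers = 3, d = 4, seed = seed)
  P <- affinity_matrix(b$x, 5)
  set.seed(seed)
  Y <- matrix(rnorm(2 * nrow(b$x)), ncol = 2)
  list(P = P, Y = Y, x = b$x, labels = b$labels)
}

test_that("KL divergence matches its definition and is nonnegative", {
  f <- grad_fixture()
  Pm <- as.matrix(f$P)
  W <- 1 / (1 + as.matrix(dist(f$Y))^2)
  diag(W) <- 0
  Q <- W / sum(W)
  pos <- Pm > 0
  expect_equal(kl_divergence(f$P, f$Y),
               sum(Pm[pos] * log(Pm[pos] / Q[pos])), tolerance = 1e-12)
  expect_gt(kl_divergence(f$P, f$Y), 0)
  expect_equal(kl_divergence(f$P, f$Y * 5e3),
               kl_divergence(Pm, f$Y * 5e3), tolerance = 1e-12)
})

test_that("the analytic gradient matches finite differences of the loss", {
  f <- grad_fixture(seed = 21, n_per = 8)
  g <- tsne_gradient(f$P, f$Y)
  h <- 1e-5
  num <- matrix(NA_real_, 6, 2)
  for (r in 1:6) {
    for (cc in 1:2) {
      Yp <- f$Y; Yp[r, cc] <- Yp[r, cc] + h
      Ym <- f$Y; Ym[r, cc] <- Ym[r, cc] - h
      num[r, cc] <- (kl_divergence(f$P, Yp) - kl_divergence(f$P, Ym)) /
        (2 * h)
    }
  }
  expect_equal(unname(g[1:6, ]), num, tolerance = 1e-5)
  # translation invariance: columns sum to zero
  expect_equal(colSums(g), c(0, 0), tolerance = 1e-12)
})

test_that("exaggeration multiplies only the attractive term", {
  f <- grad_fixture(seed = 22, n_per = 10)
  Pm <- as.matrix(f$P)
  W <- 1 / (1 + as.matrix(dist(f$Y))^2)
  diag(W) <- 0
  Z <- sum(W)
  attr_part <- function(M) 4 * (rowSums(M) * f$Y - M %*% f$Y)
  attraction <- attr_part(Pm * W)
  repulsion <- attr_part(W * W / Z)
  for (alpha in c(1, 4, 12)) {
    expect_equal(tsne_gradient(f$P, f$Y, exaggeration = alpha),
                 alpha * attraction - repulsion, tolerance = 1e-10)
  }
  expect_error(tsne_gradient(f$P, f$Y, exaggeration = 0.5))
})

test_that("initialisations follow the 1e-4 scale conventions", {
  Y <- tsne_init_random(5000, seed = 1)
  expect_equal(dim(Y), c(5000L, 2L))
  expect_equal(sd(as.vector(Y)), 1e-4, tolerance = 0.05)
  expect_identical(Y, tsne_init_random(5000, seed = 1))
  expect_false(identical(Y, tsne_init_random(5000, seed = 2)))

  set.seed(23)
  x <- matrix(rnorm(300 * 6), 300, 6) %*% diag(c(8, 4, 2, 1, 1, 1))
  Yp <- tsne_init_pca(x)
  expect_equal(sd(Yp[, 1]), 1e-4, tolerance = 1e-12)
  pcs <- reduce_pca(x, 2)
  expect_equal(abs(cor(Yp[, 1], pcs$scores[, 1])), 1, tolerance = 1e-12)
  expect_identical(Yp, tsne_init_pca(x))          # deterministic
  expect_equal(tsne_init_pca(pcs), Yp)

  r <- tsne_init_rescale(cbind(rnorm(50, sd = 7), rnorm(50)))
  expect_equal(sd(r[, 1]), 1e-4, tolerance = 1e-12)
  expect_error(tsne_init_rescale(cbind(rep(1, 10), rnorm(10))),
               "constant")
})

test_that("the learning rate is max(200, n / 12)", {
  expect_equal(tsne_learning_rate(100), 200)
  expect_equal(tsne_learning_rate(2400), 200)
  expect_equal(tsne_learning_rate(2401), 2401 / 12)
  expect_equal(tsne_learning_rate(1e6), 1e6 / 12)
})

test_that("configuration defaults encode the optimisation schedule", {
  cf <- tsne_config()
  expect_equal(cf$n_iter, 1000L)
  expect_null(cf$eta)
  expect_equal(cf$momentum_early, 0.5)
  expect_equal(cf$momentum_late, 0.8)
  expect_equal(cf$momentum_switch_iter, 250L)
  expect_equal(cf$early_exaggeration, 12)
  expect_equal(cf$early_exaggeration_iter, 250L)
  expect_equal(cf$exaggeration, 1)
  expect_null(cf$theta)
  expect_equal(cf$seed, 42L)
  expect_output(print(cf), "momentum 0.5 -> 0.8 at iter 250")
  expect_error(tsne_config(early_exaggeration = 0.5))
})

test_that("one optimiser step reproduces the update rule exactly", {
  f <- grad_fixture(seed = 24, n_per = 12)
  Y0 <- tsne_init_random(nrow(f$Y), seed = 3)
  eta <- 150
  Y1 <- tsne_optimize(f$P, Y0,
                      tsne_config(n_iter = 1, eta = eta, theta = 0,
                                  early_exaggeration_iter = 1))
  # iteration 1: zero velocity, so all gains shrink to 0.8 and the
  # update is -eta * 0.8 * (alpha * attraction - repulsion), i.e. a
  # quarter of the true exaggerated gradient, followed by recentring
  g <- tsne_gradient(f$P, Y0, exaggeration = 12) / 4
  step <- Y0 - eta * 0.8 * g
  expected <- sweep(step, 2, colMeans(step))
  expect_equal(unname(Y1), unname(expected), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("theta resolution and config resolution are recorded", {
  f <- grad_fixture(seed = 25, n_per = 10)
  Y <- tsne_optimize(f$P, tsne_init_random(nrow(f$Y)),
                     tsne_config(n_iter = 5))
  cf <- attr(Y, "config")
  expect_equal(cf$theta, 0)                      # n <= 5000 -> exact
  expect_equal(cf$eta, 200)                      # max(200, 30/12)
  expect_identical(tsne_optimize(f$P, f$Y * 0, tsne_config(n_iter = 0)),
                   f$Y * 0)
  expect_warning(tsne_optimize(f$P, f$Y, tsne_config(n_iter = 1)),
                 "1e-4 scale")
})

test_that("full optimisation separates blobs and lowers the loss", {
  b <- make_blobs(n_per = 60, centers = 3, d = 5, seed = 26)
  P <- affinity_matrix(b$x, 15)
  Y0 <- tsne_init_random(180, seed = 42)
  Y <- tsne_optimize(P, Y0, tsne_config(), record_cost = TRUE)
  cost <- attr(Y, "cost")
  expect_length(cost, 1000)
  expect_lt(kl_divergence(P, Y), kl_divergence(P, Y0))
  # after early exaggeration the recorded loss keeps decreasing overall
  expect_lt(cost[1000], cost[300])
  expect_lt(cost[1000], 1.5)
  # every blob ends up spatially coherent and separated: neighbour
  # purity in the embedding is essentially perfect
  nb <- knn_search(unclass(Y), 10)$idx
  purity <- mean(matrix(b$labels[nb], nrow(nb)) == b$labels)
  expect_gt(purity, 0.99)
  # deterministic given identical inputs
  Y2 <- tsne_optimize(P, Y0, tsne_config())
  expect_equal(unname(Y), unname(Y2), ignore_attr = TRUE)
})

test_that("the recorded cost equals the exact KL at matching layouts", {
  f <- grad_fixture(seed = 27, n_per = 10)
  Y0 <- tsne_init_random(nrow(f$Y), seed = 5)
  Y <- tsne_optimize(f$P, Y0,
                     tsne_config(n_iter = 1, early_exaggeration_iter = 1,
                                 theta = 0),
                     record_cost = TRUE)
  # the single recorded value is the KL of the pre-update layout
  expect_equal(attr(Y, "cost"), kl_divergence(f$P, Y0), tolerance = 1e-10)
})

test_that("divergence is reported with the iteration and learning rate", {
  # the bounded Cauchy kernel makes finite learning rates remarkably
  # hard to break, so exercise the guard with an unbounded one
  f <- grad_fixture(seed = 28, n_per = 10)
  expect_error(
    tsne_optimize(f$P, tsne_init_random(nrow(f$Y)),
                  tsne_config(n_iter = 50, eta = Inf, theta = 0)),
    "diverged .*at iteration 1")
})

test_that("Barnes-Hut repulsion approximates the exact field", {
  set.seed(29)
  Y <- rbind(matrix(rnorm(400), 200, 2), matrix(rnorm(400, 15), 200, 2))
  ex <- tsne_repulsion(Y, theta = 0)
  # R oracle
  W <- 1 / (1 + as.matrix(dist(Y))^2)
  diag(W) <- 0
  Z <- sum(W)
  Fo <- 4 * (rowSums(W * W / Z) * Y - (W * W / Z) %*% Y) / 4
  expect_equal(ex$Z, Z, tolerance = 1e-10)
  expect_equal(ex$forces, unname(Fo), tolerance = 1e-10)
  bh <- tsne_repulsion(Y, theta = 0.5)
  expect_equal(bh$Z, Z, tolerance = 0.02)
  scale <- max(abs(ex$forces))
  expect_lt(max(abs(bh$forces - ex$forces)) / scale, 0.05)
  # smaller theta means a tighter approximation
  bh2 <- tsne_repulsion(Y, theta = 0.2)
  expect_lt(max(abs(bh2$forces - ex$forces)),
            max(abs(bh$forces - ex$forces)) + 1e-15)
})

test_that("Barnes-Hut handles coincident points", {
  Y <- rbind(matrix(0, 50, 2), matrix(rnorm(100, 5), 50, 2))
  ex <- tsne_repulsion(Y, theta = 0)
  bh <- tsne_repulsion(Y, theta = 0.5)
  expect_true(all(is.finite(bh$forces)))
  expect_equal(bh$Z, ex$Z, tolerance = 0.02)
})

test_that("exact and Barnes-Hut optimisation agree closely", {
  b <- make_blobs(n_per = 50, centers = 3, d = 4, seed = 30)
  P <- affinity_matrix(b$x, 10)
  Y0 <- tsne_init_random(150, seed = 42)
  Ye <- tsne_optimize(P, Y0, tsne_config(theta = 0))
  Yb <- tsne_optimize(P, Y0, tsne_config(theta = 0.5))
  # same loss level and same neighbourhood structure
  expect_equal(kl_divergence(P, Yb), kl_divergence(P, Ye),
               tolerance = 0.1)
  expect_gt(knn_preservation(unclass(Ye), unclass(Yb), k = 10), 0.75)
})

test_that("tsne_embed wires affinities, init, and optimiser together", {
  b <- make_blobs(n_per = 40, centers = 3, d = 5, seed = 31)
  emb <- tsne_embed(b$x, perplexity = 10,
                    config = tsne_config(n_iter = 300))
  expect_s3_class(emb, "tsne_embedding")
  expect_equal(dim(emb$Y), c(120L, 2L))
  expect_equal(emb$init, "pca")
  expect_equal(emb$config$eta, 200)
  expect_output(print(emb), "perplexity \\{10\\}, pca init")
  # custom init at data scale is rescaled, not rejected
  emb2 <- tsne_embed(b$x, perplexity = 10, init = b$x[, 1:2],
                     config = tsne_config(n_iter = 50))
  expect_equal(emb2$init, "custom")
  # reproducible end to end
  emb3 <- tsne_embed(b$x, perplexity = 10,
                     config = tsne_config(n_iter = 300))
  expect_identical(emb$Y, emb3$Y)
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(emb, col = b$labels))
})

test_that("rigid rotation preserves distances and quality metrics", {
  b <- make_blobs(n_per = 30, centers = 3, d = 4, seed = 32)
  set.seed(32)
  Y <- matrix(rnorm(180), 90, 2)
  R <- rotate_embedding(Y, degrees = 73, flip_x = TRUE)
  expect_equal(as.numeric(dist(R)), as.numeric(dist(Y)),
               tolerance = 1e-12)
  expect_equal(knn_preservation(b$x, R), knn_preservation(b$x, Y))
  expect_equal(cpd(b$x, R), cpd(b$x, Y), tolerance = 1e-12)
  expect_equal(rotate_embedding(Y, 360), Y, tolerance = 1e-12)
})
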