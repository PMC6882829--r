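# A reference data set with three expression programmes whose
# correlation structure separates them cleanly: each programme has its
# own set of high genes, plus shared noise.
atlas_fixture <- function(n_per = 30, n_genes = 30, seed = 50) {
  set.seed(seed)
  prog <- matrix(0, 3, n_genes)
  for (p in 1:3) prog[p, ((p - 1) * 10 + 1):(p * 10)] <- 5
  expr <- do.call(rbind, lapply(1:3, function(p) {
    matrix(prog[p, ], n_per, n_genes, byrow = TRUE) +
      matrix(rnorm(n_per * n_genes, sd = 0.5), n_per, n_genes)
  }))
  colnames(expr) <- sprintf("g%02d", seq_len(n_genes))
  centers <- matrix(c(0, 0, 20, 0, 10, 17), 3, 2, byrow = TRUE)
  emb <- centers[rep(1:3, each = n_per), ] +
    matrix(rnorm(6 * n_per, sd = 0.8), 3 * n_per, 2)
  list(atlas = reference_atlas(emb, expr),
       labels = rep(1:3, each = n_per), prog = prog,
       centers = centers)
}

test_that("reference_atlas validates and fills in identifiers", {
  f <- atlas_fixture()
  a <- f$atlas
  expect_s3_class(a, "reference_atlas")
  expect_equal(a$gene_ids, sprintf("g%02d", 1:30))
  expect_equal(a$cell_ids, sprintf("cell_%d", 1:90))
  expect_output(print(a), "90 cells, 30 genes")
  expect_error(reference_atlas(a$embedding[1:5, ], a$log_expression))
})

test_that("correlation distance is 1 minus Pearson, rowwise", {
  set.seed(51)
  q <- matrix(rnorm(40), 4, 10)
  r <- matrix(rnorm(60), 6, 10)
  D <- correlation_distance(r, q)
  for (i in 1:4) for (j in 1:6) {
    expect_equal(D[i, j], 1 - cor(q[i, ], r[j, ]), tolerance = 1e-12)
  }
  expect_error(correlation_distance(r, rbind(q, 3)), "zero-variance")
  expect_warning(D2 <- correlation_distance(rbind(r, 1), q),
                 "reference")
  expect_equal(D2[, 7], rep(2, 4))
})

test_that("a query identical to a reference cell lands on it (k = 1)", {
  f <- atlas_fixture()
  res <- position_cells(f$atlas, f$atlas$log_expression[13, , drop = FALSE],
                        k = 1)
  expect_s3_class(res, "mapping_result")
  expect_equal(res$neighbor_ids[1, 1], 13L)
  expect_equal(res$positions[1, ], f$atlas$embedding[13, ],
               tolerance = 1e-12)
})

test_that("positions are coordinate-wise medians of the k neighbours", {
  f <- atlas_fixture(seed = 52)
  q <- f$atlas$log_expression[c(5, 40), ] +
    matrix(rnorm(60, sd = 0.1), 2, 30)
  res <- position_cells(f$atlas, q, k = 7)
  D <- correlation_distance(f$atlas$log_expression, q)
  for (i in 1:2) {
    nb <- order(D[i, ])[1:7]
    expect_equal(res$neighbor_ids[i, ], nb)
    expect_equal(res$positions[i, ],
                 apply(f$atlas$embedding[nb, ], 2, median))
  }
})

test_that("queries map into the embedding region of their programme", {
  f <- atlas_fixture(seed = 53)
  set.seed(53)
  # fresh cells from programme 2, noisier than the reference
  q <- matrix(f$prog[2, ], 12, 30, byrow = TRUE) +
    matrix(rnorm(360, sd = 1), 12, 30)
  res <- position_cells(f$atlas, q, colnames(f$atlas$log_expression))
  d_to <- function(ctr) sqrt(rowSums(sweep(res$positions, 2, ctr)^2))
  expect_true(all(d_to(f$centers[2, ]) < d_to(f$centers[1, ])))
  expect_true(all(d_to(f$centers[2, ]) < d_to(f$centers[3, ])))
  expect_true(all(d_to(f$centers[2, ]) < 4))
})

test_that("gene matching is by id and order-independent", {
  f <- atlas_fixture(seed = 54)
  q <- f$atlas$log_expression[7, , drop = FALSE]
  shuf <- sample(30)
  res_a <- position_cells(f$atlas, q, k = 3)
  res_b <- position_cells(f$atlas, q[, shuf, drop = FALSE],
                          query_genes = colnames(q)[shuf], k = 3)
  expect_equal(res_a$positions, res_b$positions)
  # a query carrying extra unknown genes uses only the shared ones
  q_ext <- cbind(q, junk1 = 1, junk2 = 2)
  res_c <- position_cells(f$atlas, q_ext, colnames(q_ext), k = 3)
  expect_equal(res_c$positions, res_a$positions)
  expect_length(res_c$genes_used, 30)
  expect_error(position_cells(f$atlas, q_ext[, 31:32, drop = FALSE],
                              c("junk1", "junk2")), "no genes shared")
})

test_that("the exclude argument removes a reference cell per query", {
  f <- atlas_fixture(seed = 55)
  q <- f$atlas$log_expression[22, , drop = FALSE]
  res <- position_cells(f$atlas, q, k = 1, exclude = 22L)
  expect_false(res$neighbor_ids[1, 1] == 22L)
  res_na <- position_cells(f$atlas, q, k = 1, exclude = NA_integer_)
  expect_equal(res_na$neighbor_ids[1, 1], 22L)
})

test_that("leave-one-out displacements are small within dense clusters", {
  f <- atlas_fixture(seed = 56)
  disp <- loo_validation(f$atlas, k = 10)
  expect_length(disp, 90)
  # each cluster spans a few units; consistent positioning keeps the
  # re-mapped location well within the cluster
  expect_lt(median(disp), 2)
  expect_lt(max(disp), 8)
  expect_s3_class(attr(disp, "mapping"), "mapping_result")
  sub <- loo_validation(f$atlas, cells = 1:5, k = 10)
  expect_equal(as.numeric(sub), as.numeric(disp[1:5]), tolerance = 1e-12)
})

test_that("gene bootstrap yields hulls around the mapped position", {
  f <- atlas_fixture(seed = 57)
  set.seed(57)
  q <- matrix(f$prog[1, ], 3, 30, byrow = TRUE) +
    matrix(rnorm(90, sd = 0.8), 3, 30)
  colnames(q) <- colnames(f$atlas$log_expression)
  bt <- bootstrap_positions(f$atlas, q, B = 40, k = 5, seed = 9)
  expect_equal(dim(bt$bootstrap_positions), c(3L, 40L, 2L))
  expect_equal(bt$B_retained, 38L)   # trim 0.05 -> floor(2) dropped
  expect_length(bt$hulls, 3)
  expect_true(all(bt$hull_area >= 0))
  # the base position equals the non-bootstrap mapping
  base <- position_cells(f$atlas, q, k = 5)
  expect_equal(bt$positions, base$positions)
  # all retained bootstrap positions lie inside (or on) their hull
  for (i in 1:3) {
    pts <- bt$bootstrap_positions[i, , ]
    d <- sqrt(colSums((t(pts) - bt$positions[i, ])^2))
    kept <- pts[order(d)[1:38], , drop = FALSE]
    expect_true(all(in_convex_hull(kept, bt$hulls[[i]])))
  }
  # reproducible for a fixed seed, different otherwise
  bt2 <- bootstrap_positions(f$atlas, q, B = 40, k = 5, seed = 9)
  expect_equal(bt$hull_area, bt2$hull_area)
  bt3 <- bootstrap_positions(f$atlas, q, B = 40, k = 5, seed = 10)
  expect_false(identical(bt$hull_area, bt3$hull_area))
  expect_output(print(bt), "bootstrap: B = 40")
})

test_that("degenerate bootstrap clouds give zero-area hulls", {
  # all reference cells of one programme share identical expression, so
  # every gene resample returns the same neighbour set and position
  emb <- rbind(matrix(0, 5, 2), matrix(10, 5, 2))
  expr <- rbind(matrix(rep(c(5, 4, 0, 1, 2, 3), each = 5), 5),
                matrix(rep(c(0, 1, 5, 4, 3, 2), each = 5), 5))
  colnames(expr) <- sprintf("g%d", 1:6)
  atl <- reference_atlas(emb, expr)
  q <- expr[1, , drop = FALSE]
  bt <- bootstrap_positions(atl, q, B = 20, k = 3, seed = 1)
  expect_equal(bt$hull_area, 0)
  expect_lt(nrow(bt$hulls[[1]]), 3)
})

test_that("aligned initialisation is a rescaled mapping", {
  f <- atlas_fixture(seed = 58)
  q <- f$atlas$log_expression[c(2, 35, 70), ]
  init <- aligned_init(f$atlas, q, k = 5)
  expect_equal(sd(init[, 1]), 1e-4, tolerance = 1e-12)
  pos <- position_cells(f$atlas, q, k = 5)$positions
  expect_equal(init, pos / sd(pos[, 1]) * 1e-4, tolerance = 1e-12)
})
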