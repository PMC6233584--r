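test_that("the QP quadratic term is a symmetric PSD Gram matrix", {
  cl <- cluster_logexpr(n_per = 8, n_genes = 40, seed = 11)
  prob <- build_qp(cl$X, 1, c(2:6), fitting_genes = 1:40)
  expect_equal(prob$P, t(prob$P))
  ev <- eigen(prob$P, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
})

test_that("a single-candidate pool gives the clipped scalar minimizer", {
  set.seed(12)
  X <- as_logexpr(matrix(rnorm(3 * 30), 3, 30))
  prob <- build_qp(X, 1, 2, fitting_genes = 1:30)
  expect_equal(prob$type, "scalar")
  w <- solve_simplex_qp(prob)
  y <- X$X[2, ]
  expect_equal(as.numeric(w),
               min(1, max(0, sum(y * X$X[1, ]) / sum(y * y))))
})

test_that("QP objective differences equal residual sum-of-squares differences", {
  set.seed(13)
  X <- as_logexpr(matrix(rnorm(6 * 50), 6, 50))
  prob <- build_qp(X, 1, 2:6, fitting_genes = 1:50)
  qp_f <- function(b) 0.5 * sum(b * (prob$P %*% b)) - sum(prob$q * b)
  to_full <- function(b) {
    w <- numeric(5)
    w[-prob$ref_pos] <- b
    w[prob$ref_pos] <- 1 - sum(b)
    w
  }
  for (i in 1:5) {
    b1 <- diff(c(0, sort(runif(3)), 1))  # random simplex point, dim 4
    b2 <- diff(c(0, sort(runif(3)), 1))
    s1 <- prediction_sse(X, 1, prob$pool_cells, to_full(b1), 1:50)
    s2 <- prediction_sse(X, 1, prob$pool_cells, to_full(b2), 1:50)
    expect_equal(s1 - s2, 2 * (qp_f(b1) - qp_f(b2)), tolerance = 1e-9)
  }
})

test_that("an exact duplicate of the target receives all the weight", {
  set.seed(14)
  X <- as_logexpr(rbind(c(rnorm(40)),
                        matrix(rnorm(4 * 40), 4, 40)))
  X$X[3, ] <- X$X[1, ]       # candidate 3 duplicates the target
  prob <- build_qp(X, 1, 2:5, fitting_genes = 1:40)
  w <- solve_simplex_qp(prob)
  expect_equal(unname(w[match(3, prob$pool_cells)]), 1, tolerance = 1e-6)
  expect_equal(sum(w), 1, tolerance = 1e-8)
})

test_that("an exact convex combination is recovered to 1e-6", {
  set.seed(15)
  X <- as_logexpr(matrix(rnorm(3 * 60), 3, 60))
  X$X[1, ] <- 0.3 * X$X[2, ] + 0.7 * X$X[3, ]
  w <- solve_simplex_qp(build_qp(X, 1, 2:3, fitting_genes = 1:60))
  expect_equal(as.numeric(w), c(0.3, 0.7), tolerance = 1e-6)
})

test_that("solver matches a brute-force simplex grid search", {
  set.seed(16)
  for (rep in 1:20) {
    k <- sample(2:3, 1)
    X <- as_logexpr(matrix(rnorm((k + 1) * 30, sd = 1.5), k + 1, 30))
    prob <- build_qp(X, 1, 2:(k + 1), fitting_genes = 1:30)
    w <- solve_simplex_qp(prob)
    sse_solver <- prediction_sse(X, 1, prob$pool_cells, as.numeric(w), 1:30)
    grid <- grid_search_weights(X, 1, 2:(k + 1), fitting_genes = 1:30,
                                step = 0.01)
    expect_lte(sse_solver, grid$objective + 1e-6)
  }
})

test_that("hard thresholding zeroes small weights and renormalizes", {
  nb <- threshold_and_renormalize(c(0.9995, 0.0005), t = 0.001,
                                  pool_cells = c(7L, 9L), target_cell = 1L)
  expect_equal(nb$neighbors, 7L)
  expect_equal(nb$weights, 1)

  nb2 <- threshold_and_renormalize(c(0.5, 0.5), t = 0.001,
                                   pool_cells = c(2L, 3L))
  expect_equal(nb2$weights, c(0.5, 0.5))

  nb3 <- threshold_and_renormalize(c(0.6, 0.3995, 0.0005), t = 0.001,
                                   pool_cells = 2:4)
  expect_equal(nb3$weights, c(0.6, 0.3995) / 0.9995)
  expect_equal(nb3$neighbors, c(2L, 3L))

  expect_warning(
    nb4 <- threshold_and_renormalize(c(0.0004, 0.0006) / 0.001,
                                     t = 2, pool_cells = c(5L, 6L)),
    "below threshold")
  expect_equal(nb4$neighbors, 6L)
  expect_equal(nb4$weights, 1)
})

test_that("final neighbourhood weights live on the truncated simplex", {
  cl <- cluster_logexpr(n_per = 15, n_genes = 80, seed = 17)
  for (target in c(1L, 20L)) {
    pool <- setdiff(which(cl$labels == cl$labels[target]), target)
    nb <- estimate_weights(cl$X, target, pool, fitting_genes = 1:80)
    expect_true(all(nb$weights >= 0.001))
    expect_equal(sum(nb$weights), 1, tolerance = 1e-8)
    expect_false(target %in% nb$neighbors)
    expect_gte(nb$objective, 0)
  }
})

test_that("neighbourhoods are asymmetric by construction", {
  set.seed(18)
  base <- rnorm(50)
  X <- as_logexpr(rbind(base,                        # cell 1: l
                        base,                        # cell 2: exact duplicate
                        base + rnorm(50, sd = 0.8),  # cell 3: i, noisy copy
                        matrix(rnorm(4 * 50, sd = 2), 4, 50)))
  # i's neighbourhood (pool without the duplicate) contains l
  nb_i <- estimate_weights(X, 3, c(1, 4:7), fitting_genes = 1:50)
  expect_true(1 %in% nb_i$neighbors)
  # l's neighbourhood prefers its exact duplicate; i gets nothing
  nb_l <- estimate_weights(X, 1, c(2, 3, 4:7), fitting_genes = 1:50)
  expect_true(2 %in% nb_l$neighbors)
  expect_false(3 %in% nb_l$neighbors)
})
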