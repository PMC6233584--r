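test_that("config validates, serializes and round-trips losslessly", {
  cfg <- viper_config(preselect = "enet", weight_threshold = 0.002,
                      seed = 42, screen_cells = 123)
  f <- withr::local_tempfile(fileext = ".cfg")
  write_config(cfg, f)
  expect_identical(read_config(f), cfg)
  expect_error(viper_config(min_expressed_fraction = 0), "invalid config")
  expect_error(viper_config(cv_folds = 1), "invalid config")
  expect_error(viper_config(weight_threshold = 1), "invalid config")
})

test_that("a cell without zeros passes through untouched", {
  set.seed(31)
  m <- matrix(rpois(40, 20) + 1L, 4, 10)
  cm <- count_matrix(m)
  X <- log_transform(compute_rpm(cm)$rpm, depths = rowSums(m), counts = cm)
  nb <- structure(list(target_cell = 1L, neighbors = c(2L, 3L),
                       weights = c(0.5, 0.5), objective = 0),
                  class = "cell_neighborhood")
  out <- impute_cell(X, cm, 1, nb)
  expect_equal(out$row, X$X[1, ])
  expect_false(any(out$mask))
})

test_that("a weight-one duplicate neighbour imputes its own values", {
  m <- matrix(c(0L, 5L, 0L, 2L,
                7L, 5L, 3L, 2L,
                1L, 1L, 1L, 1L), 3, 4, byrow = TRUE)
  cm <- count_matrix(m)
  X <- log_transform(compute_rpm(cm)$rpm, depths = rowSums(m), counts = cm)
  nb <- structure(list(target_cell = 1L, neighbors = 2L, weights = 1,
                       objective = 0), class = "cell_neighborhood")
  out <- impute_cell(X, cm, 1, nb)
  expect_equal(out$row[c(1, 3)], X$X[2, c(1, 3)])
  expect_equal(out$row[c(2, 4)], X$X[1, c(2, 4)])
  expect_equal(which(out$mask), c(1L, 3L))
})

test_that("imputed values are the exact weighted sum of adjusted predictors", {
  m <- rbind(c(0L, 4L, 0L, 1L),
             c(3L, 2L, 0L, 2L),
             c(5L, 1L, 2L, 0L),
             c(2L, 3L, 1L, 4L))
  cm <- count_matrix(m)
  X <- log_transform(compute_rpm(cm)$rpm, depths = rowSums(m), counts = cm)
  w <- c(0.2, 0.5, 0.3)
  nb <- structure(list(target_cell = 1L, neighbors = 2:4, weights = w,
                       objective = 0), class = "cell_neighborhood")
  out <- impute_cell(X, cm, 1, nb)
  # gene 1: all neighbours non-zero -> plain weighted sum of X
  expect_equal(unname(out$row[1]), sum(w * X$X[2:4, 1]), tolerance = 1e-12)
  # gene 3: neighbour 2 (count 0) uses the model-adjusted predictor,
  # computed through the one-gene API as an independent path
  fit <- suppressWarnings(fit_zip_pmm(m[2:4, 3], rowSums(m)[2:4]))
  xstar <- c(adjusted_predictor(fit$lambda_hat[1]), X$X[3:4, 3])
  expect_equal(unname(out$row[3]), sum(w * xstar), tolerance = 1e-10)
  # with adjustment off, the raw log(0.1) predictor is used instead
  out2 <- impute_cell(X, cm, 1, nb, config = viper_config(dropout_adjust = FALSE))
  expect_equal(unname(out2$row[3]), sum(w * X$X[2:4, 3]), tolerance = 1e-12)
})

test_that("observed non-zero entries are never altered", {
  sim <- simulate_counts(n_cells = 40, n_genes = 150, n_subpops = 2,
                         depth_range = c(1e4, 3e4), seed = 32)
  cfg <- viper_config(fitting_gene_floor = 40, preselect_genes = 80,
                      cv_folds = 5, seed = 7)
  res <- suppressWarnings(impute_matrix(sim$counts, cfg))
  expect_true(all(res$imputed[!res$imputed_mask] == res$X$X[!res$imputed_mask]))
  expect_true(all(res$counts$counts[res$imputed_mask] == 0))
  expect_true(all(Matrix::diag(res$weights) == 0))
  rs <- Matrix::rowSums(res$weights)
  expect_true(all(abs(rs - 1) < 1e-8 | rs == 0))
})

test_that("runs are deterministic and invariant to cell order", {
  sim <- simulate_counts(n_cells = 30, n_genes = 120, n_subpops = 2,
                         depth_range = c(1e4, 3e4), seed = 33)
  cfg <- viper_config(fitting_gene_floor = 30, preselect_genes = 60,
                      cv_folds = 5, seed = 9)
  r1 <- suppressWarnings(impute_matrix(sim$counts, cfg))
  r2 <- suppressWarnings(impute_matrix(sim$counts, cfg))
  expect_identical(r1$imputed, r2$imputed)
  expect_identical(as.matrix(r1$weights), as.matrix(r2$weights))

  perm <- sample(seq_len(30))
  cmp <- count_matrix(sim$counts$counts[perm, ])
  r3 <- suppressWarnings(impute_matrix(cmp, cfg))
  # internal processing is canonicalized on cell identifiers, so results
  # are identical whatever the row order of the input
  expect_identical(r3$imputed[r1$counts$cell_ids, ], r1$imputed)
})

test_that("imputation recovers planted dropouts better than no imputation", {
  sim <- simulate_counts(n_cells = 60, n_genes = 300, n_subpops = 2,
                         depth_range = c(2e4, 6e4), seed = 34)
  cfg <- viper_config(fitting_gene_floor = 80, preselect_genes = 200,
                      cv_folds = 5, seed = 3)
  res <- suppressWarnings(impute_matrix(sim$counts, cfg))
  truth <- log_transform(compute_rpm(sim$truth_counts)$rpm)
  kg <- match(res$counts$gene_ids, sim$counts$gene_ids)
  kc <- match(res$counts$cell_ids, sim$counts$cell_ids)
  ents <- which(sim$dropout_mask[kc, kg], arr.ind = TRUE)
  cor_imp <- metric_correlation_median(res$imputed, truth$X[kc, kg], ents)
  cor_raw <- metric_correlation_median(res$X$X, truth$X[kc, kg], ents)
  if (is.na(cor_raw)) cor_raw <- 0
  expect_gt(cor_imp, 0.5)
  expect_gt(cor_imp, cor_raw)
})

test_that("the RPM back-transform inverts the log transform", {
  set.seed(35)
  R <- matrix(runif(50, 0, 1e4), 5, 10)
  expect_equal(to_rpm(log(R + 0.1)), R, tolerance = 1e-9)
})
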