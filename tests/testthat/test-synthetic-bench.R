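test_that("the simulator honours its bookkeeping invariants", {
  sim <- simulate_counts(n_cells = 50, n_genes = 100, n_subpops = 3,
                         depth_range = c(1e4, 2e4), seed = 41)
  expect_identical(sim$counts$counts[!sim$dropout_mask],
                   sim$truth_counts$counts[!sim$dropout_mask])
  expect_true(all(sim$counts$counts[sim$dropout_mask] == 0))
  expect_setequal(unique(sim$cell_labels), 1:3)
  expect_length(sim$cell_labels, 50)

  sim2 <- simulate_counts(n_cells = 50, n_genes = 100, n_subpops = 3,
                          depth_range = c(1e4, 2e4), seed = 41)
  expect_identical(sim2$counts$counts, sim$counts$counts)
  expect_identical(sim2$dropout_mask, sim$dropout_mask)

  nodrop <- simulate_counts(n_cells = 20, n_genes = 50,
                            dropout_logistic_params = c(-Inf, 0), seed = 42)
  expect_false(any(nodrop$dropout_mask))
  expect_identical(nodrop$counts$counts, nodrop$truth_counts$counts)

  expect_error(simulate_counts(n_cells = 0), ">= 1")
  expect_error(simulate_counts(dispersion = -1), "dispersion")
})

test_that("per-gene truth proportions match the generating parameters", {
  sim <- simulate_counts(n_cells = 2000, n_genes = 60, n_subpops = 2,
                         depth_range = c(2e4, 4e4), dispersion = 0.2,
                         dropout_logistic_params = c(-Inf, 0), seed = 43)
  for (s in 1:2) {
    cells <- which(sim$cell_labels == s)
    depths <- sim$depths[cells]     # intended depths: E[count/depth] = prop
    expected <- sim$proportions[s, ]
    # mean over cells of count/depth estimates the expected proportion;
    # SE from the negative binomial variance mu + dispersion * mu^2
    obs <- colMeans(sim$truth_counts$counts[cells, ] / depths)
    v <- outer(1 / depths, expected) +
      0.2 * matrix(expected^2, length(cells), length(expected),
                   byrow = TRUE)
    se <- sqrt(colSums(v)) / length(cells)
    expect_gt(mean(abs(obs - expected) < 3 * se + 1e-12), 0.95)
  }
})

test_that("masking hits the exact count and is reconstructible", {
  sim <- simulate_counts(n_cells = 25, n_genes = 60, seed = 44)
  nz <- sum(sim$counts$counts > 0)
  mk <- mask_nonzero(sim$counts, 0.05, seed = 2)
  expect_equal(nrow(mk$index), round(0.05 * nz))
  expect_true(all(mk$masked$counts[cbind(mk$index$cell, mk$index$gene)] == 0))
  rebuilt <- mk$masked$counts
  rebuilt[cbind(mk$index$cell, mk$index$gene)] <- mk$index$value
  expect_identical(rebuilt, sim$counts$counts)
  expect_error(mask_nonzero(tiny_counts(), 0.001), "at least one")
})

test_that("mask selection is uniform over non-zero entries", {
  m <- matrix(5L, 10, 10)
  cm <- count_matrix(m)
  hits <- vapply(1:400, function(s) {
    mk <- mask_nonzero(cm, 0.10, seed = s)
    any(mk$index$cell == 3 & mk$index$gene == 7)
  }, logical(1))
  se <- sqrt(0.1 * 0.9 / 400)
  expect_lt(abs(mean(hits) - 0.1), 3 * se)
})

test_that("multinomial down-sampling preserves totals and expectations", {
  sim <- simulate_counts(n_cells = 15, n_genes = 40, seed = 45)
  full <- multinomial_downsample(sim$counts, 1.0, seed = 3)
  expect_equal(colSums(full$counts), colSums(sim$counts$counts))

  small <- count_matrix(matrix(c(40L, 10L, 0L, 30L, 20L, 0L), 3, 2))
  reps <- vapply(1:300, function(s) {
    multinomial_downsample(small, 0.6, seed = s)$counts[1, 1]
  }, numeric(1))
  expected <- 0.6 * 40
  se <- sd(reps) / sqrt(300)
  expect_lt(abs(mean(reps) - expected), 3 * se + 1e-9)
  # all-zero gene stays all-zero
  z <- count_matrix(cbind(small$counts, gZ = c(0L, 0L, 0L)))
  expect_true(all(multinomial_downsample(z, 0.5, 1)$counts[, 3] == 0))
})

test_that("logistic dropout coefficients are recovered from planted data", {
  set.seed(46)
  n <- 200; G <- 3000
  a <- 1.2; b <- -0.08
  nzmean <- runif(G, 1, 60)
  zf <- plogis(a + b * nzmean)
  m <- matrix(0L, n, G)
  for (g in seq_len(G)) {
    nzero <- round(n * zf[g])
    vals <- rep(round(nzmean[g]), n)
    vals[sample(n, nzero)] <- 0L
    m[, g] <- vals
  }
  m[, 1] <- pmax(m[, 1], 1L)   # keep all depths positive
  model <- fit_logistic_dropout(count_matrix(m), rep(1, n))
  expect_equal(unname(model$coefficients[1, 1]), a, tolerance = 0.1 * abs(a))
  expect_equal(unname(model$coefficients[1, 2]), b, tolerance = 0.1 * abs(b))
  expect_lt(model$coefficients[1, 2], 0)
})

test_that("a flat zero-fraction profile fits an intercept-only curve", {
  set.seed(47)
  n <- 100; G <- 500
  m <- matrix(0L, n, G)
  for (g in seq_len(G)) {
    vals <- rep(5L + (g %% 40L), n)
    vals[sample(n, n / 2)] <- 0L
    m[, g] <- vals
  }
  m[, 1] <- pmax(m[, 1], 1L)
  model <- fit_logistic_dropout(count_matrix(m), rep("s1", n))
  expect_lt(abs(model$coefficients[1, 2]), 0.01)
  p50 <- plogis(model$coefficients[1, 1] + model$coefficients[1, 2] * 20)
  expect_equal(unname(p50), 0.5, tolerance = 0.05)
})

test_that("degenerate subpopulations are reported by name", {
  m <- matrix(3L, 10, 20)
  expect_error(fit_logistic_dropout(count_matrix(m), rep("all_nz", 10)),
               "all_nz")
  set.seed(53)
  m2 <- matrix(rbinom(200, 1, 0.6) * 4L, 10, 20)
  m2[, 1] <- 1L
  expect_error(fit_logistic_dropout(count_matrix(m2),
                                    c("solo", rep("b", 9))),
               "solo")
})

test_that("dropout injection matches its Bernoulli model", {
  sim <- simulate_counts(n_cells = 100, n_genes = 500,
                         dropout_logistic_params = c(-Inf, 0), seed = 48)
  none <- apply_dropout(sim$counts, fixed_dropout(0), seed = 1)
  expect_identical(none$counts$counts, sim$counts$counts)

  fixed <- apply_dropout(sim$counts, fixed_dropout(0.8), seed = 2)
  nnz <- sum(sim$counts$counts > 0)
  frac <- sum(fixed$dropout_mask) / nnz
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / nnz))

  expect_error(fixed_dropout(1.2), "0, 1")
})

test_that("down-sampling provenance labels partition the matrix", {
  sim <- simulate_counts(n_cells = 40, n_genes = 120, seed = 49)
  model <- fixed_dropout(0.5)
  ds <- downsample_counts(sim$counts, 0.7, model, seed = 5)
  prov <- ds$zero_provenance
  expect_setequal(unique(as.vector(prov)),
                  c("nonzero", "original_zero", "downsampling_zero",
                    "dropout_zero"))
  expect_true(all((prov == "nonzero") == (ds$downsampled$counts > 0)))
  expect_true(all(sim$counts$counts[prov == "original_zero"] == 0))
  expect_true(all(ds$downsampled$counts[prov != "nonzero"] == 0))
})

test_that("accuracy metrics match direct formula recomputation", {
  set.seed(50)
  imp <- matrix(rnorm(200), 10, 20)
  tru <- matrix(rnorm(200), 10, 20)
  ents <- cbind(sample(10, 60, TRUE), sample(20, 60, TRUE))

  manual <- vapply(1:10, function(i) {
    idx <- ents[, 1] == i
    if (sum(idx) < 3) return(NA_real_)
    cor(imp[ents[idx, , drop = FALSE]], tru[ents[idx, , drop = FALSE]])
  }, numeric(1))
  expect_equal(metric_correlation_median(imp, tru, ents),
               median(manual, na.rm = TRUE), tolerance = 1e-12)
  expect_equal(metric_correlation_median(tru, tru, ents), 1.0)
  # per-cell anti-correlation gives -1
  anti <- -tru + matrix(rnorm(10), 10, 20)[, rep(1, 20)]
  expect_equal(metric_correlation_median(anti, tru, ents), -1.0)
  expect_equal(metric_correlation_median(imp, tru, ents, mode = "pooled"),
               cor(imp[ents], tru[ents]), tolerance = 1e-12)

  expect_equal(unname(metric_losses(tru, tru, ents)), c(0, 0))
  expect_equal(unname(metric_losses(tru + 2, tru, ents)), c(4, 2))
  expect_equal(unname(metric_losses(imp, tru, ents)),
               c(mean((imp[ents] - tru[ents])^2),
                 mean(abs(imp[ents] - tru[ents]))),
               tolerance = 1e-12)
})

test_that("CV pairs follow sd/mean with the documented conventions", {
  before <- cbind(c(1, 2, 3, 0), c(5, 5, 5, 5), c(2, 4, 0, 0))
  after <- cbind(c(1, 2, 3, 2), c(5, 5, 5, 5), c(2, 4, 1, 1))
  cvp <- metric_cv_pairs(before, after)
  expect_equal(cvp$cv_before[1], sd(1:3) / 2, tolerance = 1e-12)
  expect_equal(cvp$cv_after[1], sd(c(1, 2, 3, 2)) / 2, tolerance = 1e-12)
  expect_equal(cvp$cv_before[2], 0)
  expect_equal(cvp$cv_after[3], sd(c(2, 4, 1, 1)) / 2, tolerance = 1e-12)
  # scale invariance
  cvp10 <- metric_cv_pairs(before * 10, after * 10)
  expect_equal(cvp10$cv_before, cvp$cv_before, tolerance = 1e-12)
  expect_equal(cvp10$cv_after, cvp$cv_after, tolerance = 1e-12)
})

test_that("the Jaccard index follows set arithmetic", {
  expect_equal(metric_jaccard_topk(letters[1:5], letters[1:5], 5), 1.0)
  expect_equal(metric_jaccard_topk(letters[1:5], letters[6:10], 5), 0.0)
  expect_equal(metric_jaccard_topk(c("a", "b", "c"), c("b", "c", "d"), 3),
               0.5)
  expect_error(metric_jaccard_topk(letters[1:3], letters[1:3], 5),
               "exceeds")
})

test_that("split-half reproducibility has the right limits", {
  sim <- simulate_counts(n_cells = 60, n_genes = 300, n_subpops = 2,
                         seed = 51)
  fixed_rank <- function(counts, labels) counts$gene_ids
  out <- split_half_reproducibility(sim$counts, sim$cell_labels,
                                    pair = c(1, 2), rank_fn = fixed_rank,
                                    n_splits = 3, k = c(10, 50), seed = 6)
  expect_equal(unname(out), c(1, 1))

  # independent random orderings: mean Jaccard near the hypergeometric null
  G <- 10000
  rnd_rank <- function(counts, labels) sample(paste0("g", 1:G))
  big <- count_matrix(matrix(1L, 20, 4,
                             dimnames = list(NULL, paste0("gg", 1:4))))
  out2 <- split_half_reproducibility(big, rep(1:2, each = 10), c(1, 2),
                                     rank_fn = rnd_rank, n_splits = 10,
                                     k = 100, seed = 7)
  exp_overlap <- 100^2 / G                 # ~1 shared gene
  exp_j <- exp_overlap / (200 - exp_overlap)
  expect_lt(abs(out2 - exp_j), 0.01)

  # label permutation control runs and stays in [0, 1]
  out3 <- split_half_reproducibility(sim$counts, sim$cell_labels, c(1, 2),
                                     n_splits = 2, k = 20, seed = 8,
                                     permute_labels = TRUE)
  expect_true(all(out3 >= 0 & out3 <= 1))
})

test_that("the built-in rank statistic finds planted differential genes", {
  set.seed(52)
  n <- 40; G <- 200
  m <- matrix(rpois(n * G, 20), n, G)
  de <- 1:10
  m[1:20, de] <- rpois(20 * 10, 120)      # strong shift in group 1
  cm <- count_matrix(m)
  ranked <- rank_genes_wilcoxon(cm, rep(1:2, each = 20))
  expect_gte(length(intersect(ranked[1:10], paste0("gene", de))), 9)
})
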