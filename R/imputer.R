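#' Imputation pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the method's published settings where one exists (10% expression filter,
#' zero-rate < 10% fitting genes, 5,000-gene pre-selection subset, tenfold
#' CV, weight threshold 0.001); the remaining knobs are package choices
#' documented in the methods vignette.
#'
#' @param min_expressed_fraction Gene filter: minimum fraction of cells with
#'   a non-zero count (inclusive), default 0.10.
#' @param min_library_size Cell filter: minimum total depth (strict),
#'   default 0.
#' @param fitting_zero_rate Fitting genes must have zero rate strictly below
#'   this, default 0.10.
#' @param fitting_gene_floor Relax the zero-rate threshold until at least
#'   this many fitting genes qualify, default 500.
#' @param preselect `"lasso"` or `"enet"` pre-selection penalty.
#' @param preselect_genes Size of the random gene subset for pre-selection,
#'   default 5000.
#' @param cv_folds Cross-validation folds over genes, default 10.
#' @param fallback_k Correlation-ranked pool size when pre-selection returns
#'   nothing, default 50.
#' @param screen_cells Correlation sure-screen size before the lasso
#'   (`Inf` disables), default 500.
#' @param resample_per_cell Redraw the pre-selection gene subset per cell
#'   (default `FALSE`: one subset per run).
#' @param nlambda,dfmax,glmnet_thresh glmnet path controls.
#' @param weight_threshold Hard threshold `t` on weights, default 0.001.
#' @param qp_tol,qp_max_iter QP solver controls.
#' @param dropout_adjust Adjust zero-count predictors with the dropout model
#'   (default `TRUE`); `FALSE` keeps the raw `log(0.1)` predictors.
#' @param em_tol,em_max_iter EM controls.
#' @param seed Integer run seed; all per-cell randomness derives from it.
#' @param threads Reserved; execution is currently serial and results are
#'   independent of this value.
#' @param verbose Emit progress messages.
#' @return A `viper_config` list.
#' @export
viper_config <- function(min_expressed_fraction = 0.10,
                         min_library_size = 0,
                         fitting_zero_rate = 0.10,
                         fitting_gene_floor = 500,
                         preselect = c("lasso", "enet"),
                         preselect_genes = 5000,
                         cv_folds = 10,
                         fallback_k = 50,
                         screen_cells = 500,
                         resample_per_cell = FALSE,
                         nlambda = 30,
                         dfmax = 100,
                         glmnet_thresh = 1e-5,
                         weight_threshold = 0.001,
                         qp_tol = 1e-8,
                         qp_max_iter = 10000,
                         dropout_adjust = TRUE,
                         em_tol = 1e-6,
                         em_max_iter = 500,
                         seed = 1,
                         threads = 1,
                         verbose = FALSE) {
  preselect <- match.arg(preselect)
  cfg <- list(min_expressed_fraction = min_expressed_fraction,
              min_library_size = min_library_size,
              fitting_zero_rate = fitting_zero_rate,
              fitting_gene_floor = as.integer(fitting_gene_floor),
              preselect = preselect,
              preselect_genes = as.integer(preselect_genes),
              cv_folds = as.integer(cv_folds),
              fallback_k = as.integer(fallback_k),
              screen_cells = screen_cells,
              resample_per_cell = isTRUE(resample_per_cell),
              nlambda = as.integer(nlambda),
              dfmax = as.integer(dfmax),
              glmnet_thresh = glmnet_thresh,
              weight_threshold = weight_threshold,
              qp_tol = qp_tol,
              qp_max_iter = as.integer(qp_max_iter),
              dropout_adjust = isTRUE(dropout_adjust),
              em_tol = em_tol,
              em_max_iter = as.integer(em_max_iter),
              seed = as.integer(seed),
              threads = as.integer(threads),
              verbose = isTRUE(verbose))
  validate_config(cfg)
  structure(cfg, class = "viper_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  chk(cfg$min_expressed_fraction > 0 && cfg$min_expressed_fraction <= 1,
      "min_expressed_fraction must lie in (0, 1]")
  chk(cfg$min_library_size >= 0, "min_library_size must be >= 0")
  chk(cfg$fitting_zero_rate > 0 && cfg$fitting_zero_rate <= 1,
      "fitting_zero_rate must lie in (0, 1]")
  chk(cfg$preselect_genes > 0, "preselect_genes must be positive")
  chk(cfg$cv_folds >= 3, "cv_folds must be >= 3")
  chk(cfg$fallback_k >= 1, "fallback_k must be >= 1")
  chk(cfg$weight_threshold >= 0 && cfg$weight_threshold < 1,
      "weight_threshold must lie in [0, 1)")
  chk(cfg$qp_tol > 0 && cfg$em_tol > 0, "tolerances must be positive")
  chk(cfg$qp_max_iter >= 1 && cfg$em_max_iter >= 1,
      "iteration caps must be >= 1")
  invisible(cfg)
}

#' Write / read a configuration as a flat key-value file
#'
#' One `key = value` pair per line; round-trips losslessly through
#' [read_config()].
#'
#' @param config A `viper_config`.
#' @param path File path.
#' @return Invisibly, `path` (write) or the restored `viper_config` (read).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "viper_config"))
  vals <- vapply(config, function(v) {
    if (is.character(v)) v else format(v, digits = 17, scientific = TRUE)
  }, character(1))
  writeLines(paste(names(config), vals, sep = " = "), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  keys <- trimws(sub("=.*", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  args <- stats::setNames(as.list(vals), keys)
  defaults <- viper_config()
  for (k in names(args)) {
    if (!k %in% names(defaults)) stop("unknown config key: ", k)
    old <- defaults[[k]]
    args[[k]] <- if (is.character(old)) args[[k]] else
      if (is.logical(old)) as.logical(args[[k]]) else as.numeric(args[[k]])
  }
  do.call(viper_config, args)
}

#' Impute the zero counts of one cell
#'
#' For every gene with a zero count in the target cell, the imputed
#' log-expression is the weighted sum `sum_l xstar[l, j] * b[l]` over the
#' cell's neighbours, where `xstar` is the neighbour's observed
#' log-expression for non-zero counts and, when dropout adjustment is on,
#' the model-based [adjusted_predictor()] for zero counts. Genes observed
#' as non-zero in the target cell pass through unchanged.
#'
#' @param X A `logexpr_matrix`.
#' @param counts The matching [count_matrix].
#' @param target_cell Integer cell index.
#' @param neighborhood A `cell_neighborhood` from [estimate_weights()].
#' @param lambda_hat Optional pre-computed rate matrix
#'   (neighbours x imputed genes); missing fits are computed on demand.
#' @param config A [viper_config()].
#' @return List with `row` (imputed log-expression for the cell) and `mask`
#'   (logical vector, `TRUE` where a value was imputed).
#' @export
impute_cell <- function(X, counts, target_cell, neighborhood,
                        lambda_hat = NULL, config = viper_config()) {
  stopifnot(inherits(neighborhood, "cell_neighborhood"))
  row <- X$X[target_cell, ]
  mask <- rep(FALSE, length(row))
  genes0 <- which(counts$counts[target_cell, ] == 0)
  if (length(genes0) == 0) return(list(row = row, mask = mask))

  nb <- neighborhood$neighbors
  wts <- neighborhood$weights
  xstar <- X$X[nb, genes0, drop = FALSE]
  if (config$dropout_adjust) {
    cnb <- counts$counts[nb, genes0, drop = FALSE]
    zero_nb <- cnb == 0
    if (any(zero_nb)) {
      if (is.null(lambda_hat)) {
        need <- which(colSums(zero_nb) > 0)
        fit <- fit_zip_pmm_batch(cnb[, need, drop = FALSE], X$depths[nb],
                                 tol = config$em_tol,
                                 max_iter = config$em_max_iter)
        lambda_hat <- matrix(NA_real_, nrow(cnb), ncol(cnb))
        lambda_hat[, need] <- fit$lambda_hat
      }
      xstar[zero_nb] <- adjusted_predictor(lambda_hat[zero_nb])
    }
  }
  row[genes0] <- as.numeric(crossprod(xstar, wts))
  mask[genes0] <- TRUE
  list(row = row, mask = mask)
}

#' Impute a count matrix
#'
#' Runs the full pipeline: preprocessing (filters, RPM, log transform,
#' fitting-gene selection), then per cell the penalized pre-selection of
#' candidate neighbours, simplex-constrained QP weight estimation with hard
#' thresholding, dropout adjustment of zero-count predictors, and weighted
#' imputation of the cell's zero counts. Cells are processed independently,
#' each with a seed derived deterministically from `config$seed`, so
#' results do not depend on processing order.
#'
#' @param counts A [count_matrix].
#' @param config A [viper_config()].
#' @return An `imputation_result`: list with `imputed` (cells x genes
#'   log-RPM matrix), `imputed_mask` (logical, `TRUE` where replaced),
#'   `weights` (sparse cells x cells `dgCMatrix` of final weights, zero
#'   diagonal), `counts` (the filtered input), `X` (the `logexpr_matrix`),
#'   `failed_cells` and `report` (per-cell candidate/neighbour counts).
#' @export
impute_matrix <- function(counts, config = viper_config()) {
  stopifnot(inherits(counts, "count_matrix"))
  validate_config(config)
  pre <- preprocess_counts(counts, config)
  counts <- pre$counts
  X <- pre$X
  n <- nrow(X$X)
  m <- ncol(X$X)
  method <- if (config$preselect == "lasso") "l1" else "l1+l2"

  run_subset <- sample_gene_subset(X$fitting_genes, config$preselect_genes,
                                   seed = config$seed)
  imputed <- X$X
  mask <- matrix(FALSE, n, m, dimnames = dimnames(X$X))
  trip_i <- vector("list", n)
  trip_j <- vector("list", n)
  trip_x <- vector("list", n)
  n_candidates <- integer(n)
  n_neighbors <- integer(n)
  failed <- character(0)

  for (i in seq_len(n)) {
    seed_i <- derive_seed(config$seed, counts$cell_ids[i])
    gs <- if (config$resample_per_cell) {
      sample_gene_subset(X$fitting_genes, config$preselect_genes,
                         seed = seed_i)
    } else run_subset
    res <- tryCatch({
      pool <- preselect_candidates(X, i, gs, method = method,
                                   folds = config$cv_folds, seed = seed_i,
                                   screen_cells = config$screen_cells,
                                   nlambda = config$nlambda,
                                   dfmax = config$dfmax,
                                   thresh = config$glmnet_thresh)
      if (length(pool$candidates) == 0) {
        vlog(config, "cell ", i, ": empty pre-selection, using fallback pool")
        pool <- fallback_candidates(X, i, k = config$fallback_k)
      }
      nb <- estimate_weights(X, i, pool,
                             weight_threshold = config$weight_threshold,
                             tol = config$qp_tol,
                             max_iter = config$qp_max_iter)
      cell <- impute_cell(X, counts, i, nb, config = config)
      list(pool = pool, nb = nb, cell = cell)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, counts$cell_ids[i])
      vlog(config, "cell ", i, " failed: ", conditionMessage(res))
      next
    }
    n_candidates[i] <- length(res$pool$candidates)
    n_neighbors[i] <- length(res$nb$neighbors)
    imputed[i, ] <- res$cell$row
    mask[i, ] <- res$cell$mask
    trip_i[[i]] <- rep.int(i, length(res$nb$neighbors))
    trip_j[[i]] <- res$nb$neighbors
    trip_x[[i]] <- res$nb$weights
  }

  if (length(failed) > n / 2) {
    stop("more than half of all cells failed (",
         length(failed), " of ", n, "); aborting")
  }
  weights <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                                  x = unlist(trip_x), dims = c(n, n),
                                  dimnames = list(counts$cell_ids,
                                                  counts$cell_ids))
  structure(list(imputed = imputed, imputed_mask = mask, weights = weights,
                 counts = counts, X = X, failed_cells = failed,
                 report = list(n_candidates = n_candidates,
                               n_neighbors = n_neighbors,
                               seed = config$seed,
                               preselect = config$preselect)),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf(
    "<imputation_result> %d cells x %d genes; %d imputed entries; %d failed cells\n",
    nrow(x$imputed), ncol(x$imputed), sum(x$imputed_mask),
    length(x$failed_cells)))
  cat(sprintf("  median candidates %.0f -> median neighbours %.0f\n",
              stats::median(x$report$n_candidates),
              stats::median(x$report$n_neighbors)))
  invisible(x)
}

#' Back-transform imputed log-RPM values to the RPM scale
#'
#' Inverse of the `log(RPM + 0.1)` transform: `exp(X) - 0.1`, floored at 0.
#'
#' @param imputed Matrix of log-RPM values.
#' @return Matrix of RPM values.
#' @export
to_rpm <- function(imputed) {
  pmax(exp(imputed) - 0.1, 0)
}
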