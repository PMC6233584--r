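#' Sample the gene subset used for candidate pre-selection
#'
#' The pre-selection regression runs on a random subset of the fitting genes
#' (default 5,000) to keep the per-cell lasso affordable. When fewer fitting
#' genes exist than requested, all of them are used.
#'
#' @param fitting_genes Integer vector of eligible gene indices.
#' @param size Number of genes to draw (default 5000).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Sorted integer vector of gene indices.
#' @export
sample_gene_subset <- function(fitting_genes, size = 5000, seed = 1) {
  if (length(fitting_genes) == 0) stop("fitting_genes is empty")
  if (size <= 0) stop("size must be positive")
  if (length(fitting_genes) <= size) return(sort(fitting_genes))
  with_seed(seed, sort(sample(fitting_genes, size)))
}

#' Pre-select candidate neighbour cells by penalized regression
#'
#' For one target cell, regresses its log expression over `gene_subset`
#' (genes are the observations) on the expression of other cells, with an
#' L1 (lasso) or L1+L2 (elastic net, mixing 0.5) penalty chosen by k-fold
#' cross-validation over genes. Cells with a non-zero coefficient (either
#' sign) at the CV-optimal penalty become the candidate pool for the
#' quadratic-programming estimation step.
#'
#' For large data sets the other cells are first sure-screened to the
#' `screen_cells` most correlated with the target; this bounds the lasso
#' design size without affecting which strongly predictive cells survive.
#'
#' @param X A `logexpr_matrix`.
#' @param target_cell Integer cell index.
#' @param gene_subset Integer gene indices (from [sample_gene_subset()]).
#' @param method `"l1"` (lasso, default) or `"l1+l2"` (elastic net).
#' @param folds Number of CV folds over genes (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param screen_cells Correlation sure-screen size; `Inf` disables.
#' @param nlambda,dfmax,thresh glmnet path controls.
#' @return A `candidate_pool`: list with `target_cell`, `candidates`
#'   (integer cell indices, possibly empty), `method`, `penalty`,
#'   `gene_subset`, `fallback` flag.
#' @export
preselect_candidates <- function(X, target_cell, gene_subset,
                                 method = c("l1", "l1+l2"), folds = 10,
                                 seed = 1, screen_cells = 500,
                                 nlambda = 30, dfmax = 100, thresh = 1e-5) {
  stopifnot(inherits(X, "logexpr_matrix"))
  method <- match.arg(method)
  n <- nrow(X$X)
  if (n < 3) stop("need at least 3 cells")
  if (length(gene_subset) < folds) {
    stop("gene_subset smaller than the number of CV folds")
  }
  y <- X$X[target_cell, gene_subset]
  # canonical cell order (by identifier): makes the design matrix, and
  # hence the whole selection path, invariant to the input row order
  others <- setdiff(seq_len(n), target_cell)
  others <- others[order(rownames(X$X)[others])]

  if (stats::sd(y) == 0) {
    # degenerate all-constant target: penalized fit is meaningless
    return(new_pool(target_cell, integer(0), method, NA_real_, gene_subset))
  }

  if (is.finite(screen_cells) && length(others) > screen_cells) {
    co <- abs(suppressWarnings(stats::cor(y, t(X$X[others, gene_subset,
                                                   drop = FALSE]))))
    co[is.na(co)] <- 0
    keep <- sort(order(-as.numeric(co))[seq_len(screen_cells)])
    others <- others[keep]
  }

  design <- t(X$X[others, gene_subset, drop = FALSE])  # genes x cells
  keep <- which(apply(design, 2, stats::sd) > 0)
  if (length(keep) == 0) {
    return(new_pool(target_cell, integer(0), method, NA_real_, gene_subset))
  }
  design <- design[, keep, drop = FALSE]
  others <- others[keep]

  alpha <- if (method == "l1") 1 else 0.5
  foldid <- with_seed(seed,
                      sample(rep_len(seq_len(folds), length(gene_subset))))
  fit <- tryCatch(
    glmnet::cv.glmnet(design, y, alpha = alpha, foldid = foldid,
                      nlambda = nlambda, dfmax = dfmax, thresh = thresh,
                      intercept = TRUE, standardize = TRUE),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_pool(target_cell, integer(0), method, NA_real_, gene_subset))
  }
  beta <- as.numeric(stats::coef(fit, s = "lambda.min"))[-1]
  cand <- others[beta != 0]        # stays in canonical (identifier) order
  new_pool(target_cell, cand, method, fit$lambda.min, gene_subset)
}

new_pool <- function(target_cell, candidates, method, penalty, gene_subset,
                     fallback = FALSE) {
  structure(list(target_cell = target_cell, candidates = candidates,
                 method = method, penalty = penalty,
                 gene_subset = gene_subset, fallback = fallback),
            class = "candidate_pool")
}

#' Fallback candidate pool from correlation ranking
#'
#' Used when the penalized pre-selection returns no candidates (e.g. a
#' near-constant target cell): returns the `k` cells with the highest
#' Pearson correlation to the target over the fitting genes.
#'
#' @param X A `logexpr_matrix` with `fitting_genes` set.
#' @param target_cell Integer cell index.
#' @param k Pool size (default 50); capped at `n - 1`.
#' @return A `candidate_pool` with `fallback = TRUE`.
#' @export
fallback_candidates <- function(X, target_cell, k = 50) {
  stopifnot(inherits(X, "logexpr_matrix"))
  genes <- if (is.null(X$fitting_genes)) seq_len(ncol(X$X)) else
    X$fitting_genes
  n <- nrow(X$X)
  others <- setdiff(seq_len(n), target_cell)
  y <- X$X[target_cell, genes]
  co <- suppressWarnings(stats::cor(y, t(X$X[others, genes, drop = FALSE])))
  co[is.na(co)] <- -Inf
  k <- min(k, length(others))
  cand <- others[order(-as.numeric(co), rownames(X$X)[others])[seq_len(k)]]
  cand <- cand[order(rownames(X$X)[cand])]
  new_pool(target_cell, cand, "fallback", NA_real_,
           genes, fallback = TRUE)
}
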