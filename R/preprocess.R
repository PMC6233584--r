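#' Normalize counts to reads per million
#'
#' `R[i, j] = C[i, j] / N_i * 1e6`, where `N_i` is the total read depth of
#' cell `i`. Every cell's RPM row therefore sums to exactly one million.
#'
#' @param counts A [count_matrix]. All cells must have positive depth;
#'   filter with [filter_cells_by_library()] first.
#' @return List with `rpm` (cells x genes real matrix) and `depths`
#'   (named per-cell totals).
#' @export
compute_rpm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  depths <- library_sizes(counts)
  if (any(depths == 0)) {
    stop("cells with zero depth must be filtered before RPM: ",
         paste(counts$cell_ids[depths == 0], collapse = ", "))
  }
  rpm <- counts$counts / depths * 1e6
  list(rpm = rpm, depths = depths)
}

#' Log-transform normalized expression
#'
#' `X[i, j] = log(R[i, j] + 0.1)` (natural log), so a zero count maps to
#' `log(0.1)`. Returns the full log-expression container used by the
#' imputation pipeline.
#'
#' @param rpm Non-negative real matrix in RPM units (cells x genes).
#' @param depths Per-cell read depths (optional, carried through).
#' @param counts Optional [count_matrix] the RPM values came from; used to
#'   record which entries were exact zero counts.
#' @return A `logexpr_matrix`: list with `X`, `depths`, `zero_mask` and
#'   (once [select_fitting_genes()] has run) `fitting_genes`.
#' @export
log_transform <- function(rpm, depths = NULL, counts = NULL) {
  if (any(rpm < 0)) stop("RPM values must be non-negative")
  X <- log(rpm + 0.1)
  zero_mask <- if (!is.null(counts)) counts$counts == 0 else rpm == 0
  structure(list(X = X, depths = depths, zero_mask = zero_mask,
                 fitting_genes = NULL),
            class = "logexpr_matrix")
}

#' @export
print.logexpr_matrix <- function(x, ...) {
  cat(sprintf("<logexpr_matrix> %d cells x %d genes (log-RPM), %d fitting genes\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$fitting_genes)) NA_integer_
              else length(x$fitting_genes)))
  invisible(x)
}

#' Filter genes by expression prevalence
#'
#' Keeps genes expressed (count > 0) in at least `min_expressed_fraction` of
#' cells; the boundary is inclusive. Gene order is preserved.
#'
#' @param counts A [count_matrix].
#' @param min_expressed_fraction Fraction in (0, 1]; default 0.10.
#' @return Filtered [count_matrix].
#' @export
filter_genes_by_expression <- function(counts, min_expressed_fraction = 0.10) {
  stopifnot(inherits(counts, "count_matrix"))
  if (min_expressed_fraction <= 0 || min_expressed_fraction > 1) {
    stop("min_expressed_fraction must lie in (0, 1]")
  }
  frac <- colMeans(counts$counts > 0)
  subset_count_matrix(counts, genes = which(frac >= min_expressed_fraction))
}

#' Filter cells by library size
#'
#' Keeps cells whose total read depth is strictly greater than `min_total`.
#'
#' @param counts A [count_matrix].
#' @param min_total Non-negative depth cutoff (e.g. `1e6` for full-length
#'   protocols).
#' @return Filtered [count_matrix].
#' @export
filter_cells_by_library <- function(counts, min_total = 0) {
  stopifnot(inherits(counts, "count_matrix"))
  if (min_total < 0) stop("min_total must be >= 0")
  subset_count_matrix(counts, cells = which(library_sizes(counts) > min_total))
}

#' Select genes eligible for weight estimation
#'
#' Neighbour weights are estimated only on genes with few zeros so that
#' missing values do not distort the fit: a gene qualifies when its zero
#' fraction across all cells is strictly below `max_zero_fraction`.
#' If fewer than `min_genes` qualify, the threshold is relaxed in steps of
#' 0.05 (with a warning) until the floor is met; an error is raised only if
#' even a threshold of 1 yields nothing.
#'
#' @param X A `logexpr_matrix` from [log_transform()].
#' @param max_zero_fraction Strict upper bound on the per-gene zero rate;
#'   default 0.10.
#' @param min_genes Minimum acceptable number of fitting genes before the
#'   threshold is relaxed (default 500).
#' @return The `logexpr_matrix` with `fitting_genes` set (integer gene
#'   indices).
#' @export
select_fitting_genes <- function(X, max_zero_fraction = 0.10,
                                 min_genes = 500) {
  stopifnot(inherits(X, "logexpr_matrix"))
  if (max_zero_fraction <= 0 || max_zero_fraction > 1) {
    stop("max_zero_fraction must lie in (0, 1]")
  }
  zf <- unname(colMeans(X$zero_mask))
  thr <- max_zero_fraction
  idx <- which(zf < thr)
  while (length(idx) < min(min_genes, ncol(X$X)) && thr < 1) {
    thr <- min(1, thr + 0.05)
    idx <- which(zf < thr)
    if (length(idx) >= min(min_genes, ncol(X$X))) {
      warning(sprintf(
        "fitting-gene zero-rate threshold relaxed from %.2f to %.2f to reach %d genes",
        max_zero_fraction, thr, length(idx)))
    }
  }
  if (length(idx) == 0) {
    stop("no gene passes the zero-rate threshold even after relaxation; ",
         "relax max_zero_fraction or filter the data less aggressively")
  }
  X$fitting_genes <- idx
  X
}

#' Run the full preprocessing chain
#'
#' Cell library filter, gene prevalence filter, RPM normalization, log
#' transform and fitting-gene selection, in that order.
#'
#' @param counts A [count_matrix].
#' @param config A [viper_config()].
#' @return List with `counts` (filtered [count_matrix]) and `X`
#'   (`logexpr_matrix` with fitting genes set).
#' @export
preprocess_counts <- function(counts, config = viper_config()) {
  counts <- filter_cells_by_library(counts, config$min_library_size)
  counts <- filter_genes_by_expression(counts, config$min_expressed_fraction)
  if (nrow(counts$counts) < 3) stop("fewer than 3 cells after filtering")
  nr <- compute_rpm(counts)
  X <- log_transform(nr$rpm, depths = nr$depths, counts = counts)
  X <- select_fitting_genes(X, config$fitting_zero_rate,
                            config$fitting_gene_floor)
  list(counts = counts, X = X)
}
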