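#' Construct a count matrix container
#'
#' The canonical container for raw scRNA-seq counts used throughout the
#' package. Internally the orientation is always cells in rows, genes in
#' columns, regardless of how the data were laid out on disk.
#'
#' @param counts Numeric matrix of non-negative integer counts, cells in
#'   rows and genes in columns. A `Matrix` sparse matrix is densified.
#' @param cell_ids Character vector of unique cell identifiers, one per row.
#'   Defaults to `rownames(counts)`.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   column. Defaults to `colnames(counts)`.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (dense base matrix with dimnames), `cell_ids` and `gene_ids`.
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts)) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix")
  }
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(counts)) {
    stop("length(cell_ids) must equal nrow(counts)")
  }
  if (length(gene_ids) != ncol(counts)) {
    stop("length(gene_ids) must equal ncol(counts)")
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyNA(counts)) stop("counts contain NA values")
  if (any(counts < 0)) stop("counts contain negative entries")
  if (any(counts != round(counts))) {
    stop("counts contain non-integer entries")
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d genes, %.1f%% zero\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(x$counts == 0)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Per-cell library sizes
#'
#' Total read depth `N_i` of every cell (row sum of the count matrix).
#'
#' @param x A `count_matrix`.
#' @return Named numeric vector of per-cell totals.
#' @export
library_sizes <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  rowSums(x$counts)
}

subset_count_matrix <- function(x, cells = NULL, genes = NULL) {
  cts <- x$counts
  if (!is.null(cells)) cts <- cts[cells, , drop = FALSE]
  if (!is.null(genes)) cts <- cts[, genes, drop = FALSE]
  count_matrix(cts)
}
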