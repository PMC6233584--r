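#' Read a count matrix from disk
#'
#' Reads dense TSV/CSV (header row + id column) or MatrixMarket coordinate
#' files into the canonical cells-by-genes [count_matrix]. For MatrixMarket
#' input, two sidecar files must sit next to the `.mtx` file: `<stem>.genes.txt`
#' and `<stem>.cells.txt` (or pass the paths explicitly), one identifier per
#' line. Nothing is filtered on read: all-zero rows/columns are retained.
#'
#' @param path File path.
#' @param layout Orientation of the file: `"genes_by_cells"` (rows are genes,
#'   the common convention for dense expression tables) or
#'   `"cells_by_genes"`.
#' @param format One of `"tsv"`, `"csv"`, `"matrixmarket"`. Default guesses
#'   from the file extension.
#' @param gene_file,cell_file Optional explicit sidecar paths
#'   (MatrixMarket only).
#'
#' @return A [count_matrix].
#' @export
read_counts <- function(path,
                        layout = c("genes_by_cells", "cells_by_genes"),
                        format = NULL, gene_file = NULL, cell_file = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv",
                     mtx = "matrixmarket",
                     stop("cannot guess format from extension of ", path))
  }
  format <- match.arg(format, c("tsv", "csv", "matrixmarket"))

  if (format == "matrixmarket") {
    stem <- sub("\\.mtx$", "", path)
    if (is.null(gene_file)) gene_file <- paste0(stem, ".genes.txt")
    if (is.null(cell_file)) cell_file <- paste0(stem, ".cells.txt")
    for (f in c(gene_file, cell_file)) {
      if (!file.exists(f)) stop("missing sidecar id file: ", f)
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    if (layout == "genes_by_cells") {
      if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
        stop("matrix dimensions do not match sidecar id files")
      }
      m <- t(m)
    } else {
      if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
        stop("matrix dimensions do not match sidecar id files")
      }
    }
    dimnames(m) <- list(cells, genes)
    return(validate_read(m, path))
  }

  sep <- if (format == "tsv") "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    stop("non-numeric column in ", path, ": ", colnames(df)[bad])
  }
  if (layout == "genes_by_cells") m <- t(m)
  validate_read(m, path)
}

validate_read <- function(m, path) {
  if (anyNA(m)) {
    stop("validation error in ", path, ": NA entries")
  }
  if (any(m < 0)) {
    ij <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("validation error in ", path, ": negative entry at row ", ij[1],
         ", column ", ij[2])
  }
  if (any(m != round(m))) {
    ij <- which(m != round(m), arr.ind = TRUE)[1, ]
    stop("validation error in ", path, ": non-integer entry at row ", ij[1],
         ", column ", ij[2])
  }
  count_matrix(m)
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]; `layout` and `format` have the same meaning.
#' MatrixMarket output writes the two id sidecars next to the `.mtx` file.
#'
#' @param x A [count_matrix].
#' @inheritParams read_counts
#' @return Invisibly, the main output path.
#' @export
write_counts <- function(x, path,
                         layout = c("genes_by_cells", "cells_by_genes"),
                         format = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  layout <- match.arg(layout)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv",
                     mtx = "matrixmarket",
                     stop("cannot guess format from extension of ", path))
  }
  format <- match.arg(format, c("tsv", "csv", "matrixmarket"))
  m <- x$counts
  if (layout == "genes_by_cells") m <- t(m)

  if (format == "matrixmarket") {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(x$gene_ids, paste0(stem, ".genes.txt"))
    writeLines(x$cell_ids, paste0(stem, ".cells.txt"))
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  write_dense(m, path, sep)
  invisible(path)
}

write_dense <- function(m, path, sep, digits = NULL) {
  if (!is.null(digits)) m <- signif(m, digits)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  tryCatch(
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE),
    error = function(e) stop("cannot write ", path, ": ",
                             conditionMessage(e)))
}

#' Write an imputation result to disk
#'
#' Writes the imputed log-RPM matrix (cells x genes on disk for
#' `format = "tsv"`, with at least 7 significant digits), the imputation
#' mask, and the neighbour weights as a three-column triplet file
#' `target_cell <tab> neighbor_cell <tab> weight` containing one line per
#' non-zero weight (cells whose estimation failed have no lines).
#'
#' @param result An `imputation_result` from [impute_matrix()].
#' @param path Output path for the imputed matrix; the mask and weights are
#'   written next to it as `<stem>.mask.tsv` and `<stem>.weights.tsv`.
#' @param format `"tsv"` or `"matrixmarket"` for the imputed matrix.
#' @return Invisibly, a character vector of the files written.
#' @export
write_imputed <- function(result, path, format = c("tsv", "matrixmarket")) {
  stopifnot(inherits(result, "imputation_result"))
  format <- match.arg(format)
  stem <- sub("\\.(tsv|mtx)$", "", path)
  if (format == "matrixmarket") {
    Matrix::writeMM(methods::as(Matrix::Matrix(result$imputed, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(colnames(result$imputed), paste0(stem, ".genes.txt"))
    writeLines(rownames(result$imputed), paste0(stem, ".cells.txt"))
  } else {
    write_dense(signif(result$imputed, 9), path, "\t")
  }
  mask_path <- paste0(stem, ".mask.tsv")
  write_dense(result$imputed_mask * 1L, mask_path, "\t")

  w_path <- paste0(stem, ".weights.tsv")
  tw <- Matrix::summary(result$weights)
  cells <- rownames(result$imputed)
  df <- data.frame(target_cell = cells[tw$i], neighbor_cell = cells[tw$j],
                   weight = signif(tw$x, 9))
  utils::write.table(df, w_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, mask_path, w_path))
}
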