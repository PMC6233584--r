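#' Simulate a multi-subpopulation scRNA-seq count matrix
#'
#' Generates the statistical structure the imputation model assumes:
#' distinct cell subpopulations with gene-level fold changes, per-cell
#' library-size variation, over-dispersed (negative binomial) counts, and
#' expression-dependent dropout injected with a decreasing logistic function
#' of the underlying mean. Both the pre-dropout truth and the dropout mask
#' are recorded, so every injected zero is attributable.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param n_subpops Number of cell subpopulations (default 3).
#' @param depth_range Range of per-cell total depths, sampled uniformly
#'   (default `c(5e4, 2e5)`).
#' @param logmean_spread SD of the per-subpopulation log fold changes
#'   applied to differential genes (default 1).
#' @param de_fraction Fraction of genes receiving subpopulation fold
#'   changes (default 0.3).
#' @param base_logmean_sd SD of the baseline gene log-abundance
#'   distribution (default 1.5).
#' @param dispersion Negative binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts. Default 0.3.
#' @param dropout_logistic_params `c(intercept, slope)` of the dropout
#'   logistic on `log1p(mean)`: an entry with underlying mean `m` is zeroed
#'   with probability `plogis(intercept + slope * log1p(m))`. The slope
#'   should be negative (dropout hits low expression hardest); use
#'   `c(-Inf, 0)` for no dropout. Default `c(1.5, -0.6)`.
#' @param seed Integer seed; the dataset is reproducible bit-for-bit.
#' @return A `synthetic_dataset`: list with `counts` ([count_matrix] after
#'   dropout), `truth_counts` (before dropout), `cell_labels` (integer
#'   subpopulation per cell), `dropout_mask` (logical matrix of injected
#'   dropout events), `proportions` (subpopulations x genes matrix of the
#'   expected per-read expression proportions), `depths` (intended per-cell
#'   depth parameter) and `params`.
#' @export
simulate_counts <- function(n_cells = 1000, n_genes = 2000, n_subpops = 3,
                            depth_range = c(5e4, 2e5),
                            logmean_spread = 1, de_fraction = 0.3,
                            base_logmean_sd = 1.5, dispersion = 0.3,
                            dropout_logistic_params = c(1.5, -0.6),
                            seed = 1) {
  if (n_cells < 1 || n_genes < 1 || n_subpops < 1) {
    stop("n_cells, n_genes and n_subpops must be >= 1")
  }
  if (n_subpops > n_cells) stop("more subpopulations than cells")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (length(depth_range) != 2 || any(depth_range <= 0) ||
      depth_range[1] > depth_range[2]) {
    stop("depth_range must be an increasing pair of positive depths")
  }
  if (length(dropout_logistic_params) != 2) {
    stop("dropout_logistic_params must be c(intercept, slope)")
  }
  params <- list(n_cells = n_cells, n_genes = n_genes,
                 n_subpops = n_subpops, depth_range = depth_range,
                 logmean_spread = logmean_spread, de_fraction = de_fraction,
                 base_logmean_sd = base_logmean_sd, dispersion = dispersion,
                 dropout_logistic_params = dropout_logistic_params,
                 seed = seed)
  with_seed(seed, {
    base <- stats::rnorm(n_genes, 0, base_logmean_sd)
    lfc <- matrix(0, n_subpops, n_genes)
    de <- sample(n_genes, round(de_fraction * n_genes))
    if (length(de) > 0 && n_subpops > 1) {
      lfc[, de] <- stats::rnorm(n_subpops * length(de), 0, logmean_spread)
    }
    rel <- exp(sweep(lfc, 2, base, "+"))
    rel <- rel / rowSums(rel)                       # per-subpop proportions
    labels <- sort(rep_len(seq_len(n_subpops), n_cells))
    depths <- round(stats::runif(n_cells, depth_range[1], depth_range[2]))
    mu <- depths * rel[labels, , drop = FALSE]
    truth <- if (dispersion > 0) {
      matrix(stats::rnbinom(n_cells * n_genes, mu = mu, size = 1 / dispersion),
             n_cells, n_genes)
    } else {
      matrix(stats::rpois(n_cells * n_genes, lambda = mu), n_cells, n_genes)
    }
    a <- dropout_logistic_params[1]
    b <- dropout_logistic_params[2]
    pdrop <- stats::plogis(a + b * log1p(mu))
    drop <- matrix(stats::runif(n_cells * n_genes) < pdrop,
                   n_cells, n_genes) & truth > 0
    obs <- truth
    obs[drop] <- 0L
    ids <- list(paste0("cell", seq_len(n_cells)),
                paste0("gene", seq_len(n_genes)))
    dimnames(obs) <- dimnames(truth) <- dimnames(drop) <- ids
    structure(list(counts = count_matrix(obs),
                   truth_counts = count_matrix(truth),
                   cell_labels = labels,
                   dropout_mask = drop,
                   proportions = rel,
                   depths = depths,
                   params = params),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d cells x %d genes, %d subpopulations, %.1f%% dropout events\n",
    nrow(x$counts$counts), ncol(x$counts$counts), x$params$n_subpops,
    100 * mean(x$dropout_mask)))
  invisible(x)
}
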