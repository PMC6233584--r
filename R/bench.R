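#' Mask a fraction of non-zero entries
#'
#' Sets exactly `round(pct * #nonzero)` uniformly sampled non-zero entries
#' to zero and records their positions and true values, so imputation
#' accuracy can be measured against known truth.
#'
#' @param counts A [count_matrix] with at least one non-zero entry.
#' @param pct Fraction of non-zero entries to mask (the published
#'   experiments use 0.02, 0.05 and 0.10).
#' @param seed Integer seed.
#' @return List with `masked` (the new [count_matrix]) and `index`
#'   (data.frame `cell`, `gene` (integer indices), `value` (true count)).
#' @export
mask_nonzero <- function(counts, pct, seed = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  if (pct <= 0 || pct >= 1) stop("pct must lie in (0, 1)")
  nz <- which(counts$counts > 0)
  if (length(nz) == 0) stop("matrix has no non-zero entries")
  k <- round(pct * length(nz))
  if (k < 1) {
    stop("pct * number of non-zero entries rounds to zero; ",
         "need at least one maskable entry")
  }
  sel <- with_seed(seed, sample(nz, k))
  ij <- arrayInd(sel, dim(counts$counts))
  m <- counts$counts
  vals <- m[sel]
  m[sel] <- 0L
  list(masked = count_matrix(m),
       index = data.frame(cell = ij[, 1], gene = ij[, 2], value = vals))
}

#' Multinomially down-sample reads per gene
#'
#' For each gene in turn, redraws the gene's reads across cells from a
#' multinomial with total `round(retain_fraction * gene total)` and
#' probabilities equal to each cell's share of the gene's reads, so each
#' cell's expected expression proportion is unchanged. `retain_fraction` is
#' the RETAINED fraction of reads: 0.5 halves every gene's depth.
#'
#' @param counts A [count_matrix].
#' @param retain_fraction Fraction of reads retained, in (0, 1]. The
#'   published experiments use 0.5, 0.6, 0.7, 0.8, 0.9 and 0.95.
#' @param seed Integer seed.
#' @return The down-sampled [count_matrix].
#' @export
multinomial_downsample <- function(counts, retain_fraction, seed = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  if (retain_fraction <= 0 || retain_fraction > 1) {
    stop("retain_fraction must lie in (0, 1]")
  }
  m <- counts$counts
  with_seed(seed, {
    out <- m
    for (g in seq_len(ncol(m))) {
      tot <- sum(m[, g])
      if (tot == 0) next
      out[, g] <- stats::rmultinom(1, round(retain_fraction * tot),
                                   prob = m[, g] / tot)
    }
    count_matrix(out)
  })
}

#' Fit per-subpopulation logistic dropout curves
#'
#' Within each subpopulation, computes for every gene the zero fraction
#' across cells and the mean of its non-zero values, then fits the zero
#' fraction on the non-zero mean with a fractional-response logistic
#' regression (quasi-binomial GLM). The fitted curves drive
#' expression-dependent dropout in [apply_dropout()].
#'
#' @param counts A [count_matrix].
#' @param cell_labels Subpopulation label per cell.
#' @return A `dropout_model` of type `"logistic"`: coefficients matrix
#'   (one row per subpopulation: intercept, slope) plus the labels.
#' @export
fit_logistic_dropout <- function(counts, cell_labels) {
  stopifnot(inherits(counts, "count_matrix"))
  if (length(cell_labels) != nrow(counts$counts)) {
    stop("cell_labels must align with cells")
  }
  labs <- sort(unique(cell_labels))
  coefs <- matrix(NA_real_, length(labs), 2,
                  dimnames = list(as.character(labs),
                                  c("intercept", "slope")))
  for (s in seq_along(labs)) {
    cells <- which(cell_labels == labs[s])
    if (length(cells) < 2) {
      stop("subpopulation ", labs[s], " has fewer than 2 cells")
    }
    sub <- counts$counts[cells, , drop = FALSE]
    nzmean <- apply(sub, 2, function(v) if (any(v > 0)) mean(v[v > 0])
                    else NA_real_)
    zfrac <- colMeans(sub == 0)
    ok <- !is.na(nzmean)
    if (sum(ok) < 10) {
      stop("subpopulation ", labs[s],
           " has fewer than 10 genes with a non-zero mean")
    }
    if (all(zfrac[ok] == 0) || all(zfrac[ok] == 1)) {
      stop("degenerate subpopulation ", labs[s],
           ": zero fractions are all 0 or all 1")
    }
    fit <- stats::glm(zfrac[ok] ~ nzmean[ok],
                      family = stats::quasibinomial())
    coefs[s, ] <- stats::coef(fit)
  }
  structure(list(type = "logistic", coefficients = coefs, labels = labs),
            class = "dropout_model")
}

#' Fixed-rate dropout model
#'
#' @param rate Dropout probability applied to every non-zero entry; the
#'   published down-sampling experiments use 0.8.
#' @return A `dropout_model` of type `"fixed"`.
#' @export
fixed_dropout <- function(rate = 0.8) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  structure(list(type = "fixed", rate = rate), class = "dropout_model")
}

#' Inject dropout events into non-zero entries
#'
#' Each non-zero entry is independently set to zero with its model-given
#' probability: a fixed rate, or a per-subpopulation logistic function of
#' the entry's value (from [fit_logistic_dropout()]).
#'
#' @param counts A [count_matrix].
#' @param model A `dropout_model`.
#' @param cell_labels Required for logistic models: subpopulation per cell.
#' @param seed Integer seed.
#' @return List with `counts` (after dropout) and `dropout_mask` (logical,
#'   `TRUE` where an entry was zeroed).
#' @export
apply_dropout <- function(counts, model, cell_labels = NULL, seed = 1) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(model, "dropout_model"))
  m <- counts$counts
  rates <- matrix(0, nrow(m), ncol(m))
  nz <- m > 0
  if (model$type == "fixed") {
    rates[nz] <- model$rate
  } else {
    if (is.null(cell_labels)) stop("logistic dropout needs cell_labels")
    for (s in seq_along(model$labels)) {
      cells <- which(cell_labels == model$labels[s])
      a <- model$coefficients[s, 1]
      b <- model$coefficients[s, 2]
      sub <- m[cells, , drop = FALSE]
      r <- stats::plogis(a + b * sub)
      r[sub == 0] <- 0
      rates[cells, ] <- r
    }
  }
  with_seed(seed, {
    drop <- matrix(stats::runif(length(m)) < rates, nrow(m), ncol(m)) & nz
    out <- m
    out[drop] <- 0L
    list(counts = count_matrix(out), dropout_mask = drop)
  })
}

#' Two-step down-sampling experiment
#'
#' Multinomial read thinning followed by extra dropout events on the
#' surviving non-zero values, with per-entry provenance: `nonzero`,
#' `original_zero` (zero in the input), `downsampling_zero` (lost in the
#' multinomial step) or `dropout_zero` (non-zero after thinning, zeroed by
#' the dropout step).
#'
#' @param counts A [count_matrix] (the "original truth").
#' @param retain_fraction Retained read fraction for the multinomial step.
#' @param model A `dropout_model` ([fixed_dropout()] or
#'   [fit_logistic_dropout()]).
#' @param cell_labels Subpopulation labels (logistic models).
#' @param seed Integer seed.
#' @return A `downsample_result`: list with `downsampled` ([count_matrix]),
#'   `zero_provenance` (character matrix), `retain_fraction`,
#'   `dropout_model`.
#' @export
downsample_counts <- function(counts, retain_fraction, model,
                              cell_labels = NULL, seed = 1) {
  thinned <- multinomial_downsample(counts, retain_fraction, seed = seed)
  dropped <- apply_dropout(thinned, model, cell_labels = cell_labels,
                           seed = seed + 1L)
  prov <- matrix("nonzero", nrow(counts$counts), ncol(counts$counts),
                 dimnames = dimnames(counts$counts))
  prov[thinned$counts == 0] <- "downsampling_zero"
  prov[counts$counts == 0] <- "original_zero"
  prov[dropped$dropout_mask] <- "dropout_zero"
  prov[dropped$counts$counts > 0] <- "nonzero"
  structure(list(downsampled = dropped$counts, zero_provenance = prov,
                 retain_fraction = retain_fraction, dropout_model = model),
            class = "downsample_result")
}

# ---- metrics -------------------------------------------------------------

as_entry_matrix <- function(entries) {
  if (is.data.frame(entries)) entries <- cbind(entries$cell, entries$gene)
  if (!is.matrix(entries) || ncol(entries) != 2) {
    stop("entries must be a two-column (cell, gene) index matrix")
  }
  entries
}

#' Median per-cell correlation between imputed and true values
#'
#' Pearson correlation of (imputed, truth) over the evaluated entries
#' within each cell — cells with fewer than 3 entries are skipped and cells
#' with zero variance yield `NA` — then the median across cells. The pooled
#' variant correlates all entries at once.
#'
#' @param imputed,truth Matrices of identical shape.
#' @param entries Two-column (cell, gene) index matrix of evaluated entries.
#' @param mode `"per_cell_median"` (default) or `"pooled"`.
#' @return Scalar correlation, or `NA` if no cell is evaluable.
#' @export
metric_correlation_median <- function(imputed, truth, entries,
                                      mode = c("per_cell_median", "pooled")) {
  mode <- match.arg(mode)
  entries <- as_entry_matrix(entries)
  if (nrow(entries) < 2) stop("need at least 2 evaluated entries")
  iv <- imputed[entries]
  tv <- truth[entries]
  if (mode == "pooled") {
    if (stats::sd(iv) == 0 || stats::sd(tv) == 0) return(NA_real_)
    return(stats::cor(iv, tv))
  }
  cors <- vapply(split(seq_len(nrow(entries)), entries[, 1]), function(idx) {
    if (length(idx) < 3) return(NA_real_)
    x <- iv[idx]; y <- tv[idx]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  if (all(is.na(cors))) return(NA_real_)
  stats::median(cors, na.rm = TRUE)
}

#' Squared and L1 imputation losses
#'
#' Mean squared error and mean absolute deviation between imputed and true
#' values over the evaluated entries.
#'
#' @inheritParams metric_correlation_median
#' @return Named numeric vector `c(squared_loss =, l1_loss =)`.
#' @export
metric_losses <- function(imputed, truth, entries) {
  entries <- as_entry_matrix(entries)
  if (nrow(entries) == 0) stop("entries is empty")
  d <- imputed[entries] - truth[entries]
  c(squared_loss = mean(d^2), l1_loss = mean(abs(d)))
}

#' Per-gene coefficient of variation before and after imputation
#'
#' For each gene, the CV (sd/mean) of the non-zero cells before imputation
#' and the CV across all cells after imputation, on whatever expression
#' scale the caller supplies (the package's experiments use the
#' back-transformed RPM scale, [to_rpm()]). Genes with fewer than 2
#' non-zero cells before, fewer than 2 cells after, or zero mean yield
#' `NA`.
#'
#' @param before Expression matrix before imputation (cells x genes).
#' @param after Matrix after imputation, same shape.
#' @param nonzero_mask Logical matrix marking the entries that count as
#'   observed (non-zero) before imputation; defaults to `before > 0`.
#' @return data.frame `gene`, `cv_before`, `cv_after`.
#' @export
metric_cv_pairs <- function(before, after, nonzero_mask = before > 0) {
  stopifnot(all(dim(before) == dim(after)))
  cv <- function(v) {
    if (length(v) < 2) return(NA_real_)
    m <- mean(v)
    if (m == 0) return(NA_real_)
    stats::sd(v) / m
  }
  nb <- ncol(before)
  cv_before <- cv_after <- numeric(nb)
  for (g in seq_len(nb)) {
    cv_before[g] <- cv(before[nonzero_mask[, g], g])
    cv_after[g] <- cv(after[, g])
  }
  data.frame(gene = if (!is.null(colnames(before))) colnames(before)
             else seq_len(nb),
             cv_before = cv_before, cv_after = cv_after)
}

#' Jaccard index of two top-k gene lists
#'
#' `|top_k(a) intersect top_k(b)| / |top_k(a) union top_k(b)|`.
#'
#' @param list_a,list_b Ranked gene identifier vectors (best first).
#' @param k Depth of the comparison (the published experiments use 100,
#'   200, 500 and 1000).
#' @return Scalar in `[0, 1]`.
#' @export
metric_jaccard_topk <- function(list_a, list_b, k) {
  if (k > length(list_a) || k > length(list_b)) {
    stop("k exceeds the length of a ranked list")
  }
  a <- list_a[seq_len(k)]
  b <- list_b[seq_len(k)]
  length(intersect(a, b)) / length(union(a, b))
}

#' Rank genes by a two-group rank-sum statistic
#'
#' Built-in per-gene ranking function for the reproducibility experiment: a
#' standardized Wilcoxon rank-sum z statistic on log-RPM expression between
#' two groups, genes ranked by `|z|` (most differential first). A simple
#' stand-in for external differential-expression engines, which can be
#' plugged into [split_half_reproducibility()] instead.
#'
#' @param counts A [count_matrix].
#' @param labels Two-level group label per cell.
#' @return Character vector of gene ids, best first.
#' @export
rank_genes_wilcoxon <- function(counts, labels) {
  stopifnot(inherits(counts, "count_matrix"))
  g <- factor(labels)
  if (nlevels(g) != 2) stop("labels must have exactly two levels")
  keep <- library_sizes(counts) > 0
  cts <- counts$counts[keep, , drop = FALSE]
  g <- g[keep]
  X <- log(cts / rowSums(cts) * 1e6 + 0.1)
  n1 <- sum(g == levels(g)[1])
  n2 <- sum(g == levels(g)[2])
  R <- apply(X, 2, rank)
  w <- colSums(R[g == levels(g)[1], , drop = FALSE])
  mu <- n1 * (n1 + n2 + 1) / 2
  sdv <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  z <- (w - mu) / sdv
  counts$gene_ids[order(-abs(z))]
}

#' Split-half reproducibility of top differential genes
#'
#' Randomly halves the cells of two subpopulations, applies a per-gene
#' ranking function to each half independently, and measures the Jaccard
#' overlap of the top-`k` gene lists; repeated over `n_splits` random
#' splits and averaged. A label-permutation control (labels shuffled within
#' the pair before splitting) is available via `permute_labels`.
#'
#' @param counts A [count_matrix].
#' @param cell_labels Subpopulation label per cell.
#' @param pair Length-2 vector naming the two subpopulations to compare.
#' @param rank_fn `function(counts, labels)` returning ranked gene ids;
#'   default [rank_genes_wilcoxon()]. May run imputation internally.
#' @param n_splits Number of random splits (default 10).
#' @param k Vector of list depths (default `c(100, 200, 500, 1000)`).
#' @param seed Integer seed.
#' @param permute_labels Shuffle the pair's labels before splitting.
#' @return Named numeric vector: mean Jaccard index per `k`.
#' @export
split_half_reproducibility <- function(counts, cell_labels, pair,
                                       rank_fn = rank_genes_wilcoxon,
                                       n_splits = 10,
                                       k = c(100, 200, 500, 1000),
                                       seed = 1, permute_labels = FALSE) {
  stopifnot(inherits(counts, "count_matrix"), length(pair) == 2)
  sel <- which(cell_labels %in% pair)
  labs <- cell_labels[sel]
  if (min(table(labs)) < 4) {
    stop("each subpopulation in the pair needs at least 4 cells")
  }
  jac <- matrix(NA_real_, n_splits, length(k))
  for (r in seq_len(n_splits)) {
    with_seed(derive_seed(seed, r), {
      labs_r <- if (permute_labels) sample(labs) else labs
      half1 <- integer(0)
      for (p in pair) {
        cp <- which(labs_r == p)
        half1 <- c(half1, sample(cp, floor(length(cp) / 2)))
      }
      half2 <- setdiff(seq_along(sel), half1)
      ranked <- lapply(list(half1, half2), function(h) {
        sub <- subset_count_matrix(counts, cells = sel[h])
        tryCatch(rank_fn(sub, labs_r[h]),
                 error = function(e) stop("rank_fn failed on split ", r,
                                          ": ", conditionMessage(e)))
      })
      for (ki in seq_along(k)) {
        jac[r, ki] <- metric_jaccard_topk(ranked[[1]], ranked[[2]], k[ki])
      }
    })
  }
  stats::setNames(colMeans(jac), paste0("k", k))
}

#' Run the non-zero masking experiment
#'
#' Masks a fraction of the non-zero entries of a count matrix, runs the
#' imputation pipeline on the masked matrix, and scores the imputed values
#' against the original (pre-masking) log expression at the masked
#' positions. Two reference strategies are scored on the same entries: the
#' zero baseline (masked entries left at `log(0.1)`, i.e. no imputation)
#' and a gene-mean baseline (masked entries replaced by the gene's mean
#' log expression over non-zero cells). Constant predictions have no
#' defined Pearson correlation; such cells yield `NA` and a baseline whose
#' median is `NA` is reported as 0, the no-information value.
#'
#' @param counts A [count_matrix] (treated as ground truth).
#' @param pct Fraction of non-zero entries to mask.
#' @param config A [viper_config()] for the imputation run.
#' @param seed Seed for the masking draw.
#' @param mode Correlation aggregation, see [metric_correlation_median()].
#' @return List with `correlation`, `correlation_zero_baseline`,
#'   `correlation_genemean_baseline`, `losses` (imputed), `losses_zero`,
#'   `losses_genemean`, `n_masked_scored`, and the `result` object.
#' @export
masking_experiment <- function(counts, pct, config = viper_config(),
                               seed = 1, mode = "per_cell_median") {
  mk <- mask_nonzero(counts, pct, seed = seed)
  res <- impute_matrix(mk$masked, config)

  truth_X <- log_transform(compute_rpm(counts)$rpm)$X
  kc <- match(res$counts$cell_ids, counts$cell_ids)
  kg <- match(res$counts$gene_ids, counts$gene_ids)
  keep <- mk$index$cell %in% kc & mk$index$gene %in% kg
  ents <- cbind(match(mk$index$cell[keep], kc),
                match(mk$index$gene[keep], kg))
  truth <- truth_X[kc, kg, drop = FALSE]

  zero_base <- res$X$X
  genemean <- res$X$X
  for (g in unique(ents[, 2])) {
    rows <- ents[ents[, 2] == g, 1]
    nzv <- res$X$X[res$counts$counts[, g] > 0, g]
    genemean[rows, g] <- if (length(nzv) > 0) mean(nzv) else log(0.1)
  }
  med0 <- function(x) if (is.na(x)) 0 else x
  list(correlation = metric_correlation_median(res$imputed, truth, ents,
                                               mode = mode),
       correlation_zero_baseline =
         med0(metric_correlation_median(zero_base, truth, ents, mode = mode)),
       correlation_genemean_baseline =
         med0(metric_correlation_median(genemean, truth, ents, mode = mode)),
       losses = metric_losses(res$imputed, truth, ents),
       losses_zero = metric_losses(zero_base, truth, ents),
       losses_genemean = metric_losses(genemean, truth, ents),
       n_masked_scored = nrow(ents),
       result = res)
}

#' Summarize coefficient-of-variation preservation after imputation
#'
#' For an imputation run, computes per-gene CV pairs on the back-transformed
#' RPM scale ([to_rpm()]): before-CV over cells observed non-zero,
#' after-CV over all cells. Reports the fraction of evaluable genes whose
#' CV stayed within a relative band of the before-CV and the fraction whose
#' CV did not decrease.
#'
#' @param result An `imputation_result`.
#' @param band Relative half-width of the preservation band (default 0.25).
#' @param genes Optional subset of gene indices to evaluate.
#' @return List with `frac_within_band`, `frac_not_decreased`, `n_genes`
#'   and the per-gene `cv` data.frame.
#' @export
cv_preservation <- function(result, band = 0.25, genes = NULL) {
  stopifnot(inherits(result, "imputation_result"))
  before <- to_rpm(result$X$X)
  after <- to_rpm(result$imputed)
  nzmask <- result$counts$counts > 0
  if (!is.null(genes)) {
    before <- before[, genes, drop = FALSE]
    after <- after[, genes, drop = FALSE]
    nzmask <- nzmask[, genes, drop = FALSE]
  }
  cvp <- metric_cv_pairs(before, after, nonzero_mask = nzmask)
  ok <- is.finite(cvp$cv_before) & is.finite(cvp$cv_after) &
    cvp$cv_before > 0
  rel <- cvp$cv_after[ok] / cvp$cv_before[ok]
  list(frac_within_band = mean(abs(rel - 1) <= band),
       frac_not_decreased = mean(rel >= 1 - 1e-9),
       n_genes = sum(ok),
       cv = cvp)
}
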