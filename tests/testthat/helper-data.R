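# Fixtures are generated in code; no data files.

# Wrap a bare log-expression matrix as a logexpr_matrix (all genes fitting).
as_logexpr <- function(X, depths = NULL) {
  if (is.null(rownames(X))) rownames(X) <- paste0("cell", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("gene", seq_len(ncol(X)))
  structure(list(X = X, depths = depths,
                 zero_mask = matrix(FALSE, nrow(X), ncol(X)),
                 fitting_genes = seq_len(ncol(X))),
            class = "logexpr_matrix")
}

# Two well-separated cell clusters in log-expression space.
cluster_logexpr <- function(n_per = 15, n_genes = 60, sep = 4, noise = 0.5,
                            seed = 1) {
  set.seed(seed)
  prof <- matrix(rnorm(2 * n_genes, sd = 1), 2, n_genes)
  prof[2, ] <- prof[2, ] + sep * sample(c(-1, 1), n_genes, replace = TRUE)
  lab <- rep(1:2, each = n_per)
  X <- prof[lab, ] + matrix(rnorm(2 * n_per * n_genes, sd = noise),
                            2 * n_per, n_genes)
  list(X = as_logexpr(X), labels = lab)
}

# Small deterministic count matrix.
tiny_counts <- function() {
  m <- matrix(c(2L, 0L, 8L,
                1L, 3L, 0L,
                0L, 0L, 5L,
                4L, 2L, 1L), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  count_matrix(m)
}

# Simulate ZIP Poisson-lognormal neighbour counts for one gene.
sim_zip_counts <- function(L, p, mu, psi, depth_range = c(1e5, 1e6)) {
  depths <- runif(L, depth_range[1], depth_range[2])
  lam <- exp(mu + rnorm(L, 0, sqrt(psi)))
  cc <- rpois(L, depths * lam)
  cc[runif(L) < p] <- 0L
  list(counts = cc, depths = depths)
}
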