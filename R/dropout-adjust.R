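# Gauss-Hermite rule, memoized (nodes from pracma).
gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(n = 31) {
  key <- as.character(n)
  if (is.null(gh_cache[[key]])) gh_cache[[key]] <- pracma::gaussHermite(n)
  gh_cache[[key]]
}

#' Fit the zero-inflated Poisson log-normal dropout model for one gene
#'
#' Among the neighbours of a target cell, a gene's counts are modelled as a
#' mixture of a point mass at zero (a dropout, with probability `p`) and an
#' over-dispersed Poisson: `C_l ~ p * delta_0 +
#' (1 - p) * Poisson(N_l * exp(mu + eps_l))` with `eps_l ~ N(0, psi)`.
#' Parameters are estimated by an EM algorithm whose E-step computes the
#' posterior dropout responsibility of each zero count and whose M-step
#' updates `p` in closed form and `(mu, psi)` by damped Newton ascent; the
#' integral over `eps` uses 31-point Gauss-Hermite quadrature. The
#' observed-data log-likelihood is non-decreasing across iterations.
#'
#' @param counts Non-negative integer counts, one per neighbour cell.
#' @param depths Positive total read depths `N_l`, aligned with `counts`.
#' @param tol EM convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter EM iteration cap (default 500).
#' @param p_cap Upper bound on the dropout probability (default 0.99),
#'   preventing the degenerate all-dropout solution.
#' @return A `dropout_fit`: list with `p`, `mu`, `psi`, `lambda_hat`
#'   (posterior-mean rate for zero counts, `NA` for non-zero counts),
#'   `loglik_trace`, `converged`, `degenerate` and `n_iter`.
#' @export
fit_zip_pmm <- function(counts, depths, tol = 1e-6, max_iter = 500,
                        p_cap = 0.99) {
  if (length(counts) < 2) stop("need at least 2 neighbours")
  if (length(depths) != length(counts)) {
    stop("depths must align with counts")
  }
  if (any(depths <= 0)) stop("depths must be positive")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  gh <- gh_rule(31)
  res <- .zip_pmm_em(matrix(as.numeric(counts), ncol = 1),
                     as.numeric(depths), gh$x, gh$w,
                     tol = tol, max_iter = max_iter, p_cap = p_cap,
                     want_trace = TRUE)
  if (res$degenerate[1]) {
    warning("all neighbour counts are zero; dropout probability capped at ",
            p_cap)
  } else if (!res$converged[1]) {
    warning("EM did not converge within ", max_iter, " iterations")
  }
  structure(list(p = res$p[1], mu = res$mu[1], psi = res$psi[1],
                 lambda_hat = res$lambda_hat[, 1],
                 loglik = res$loglik[1],
                 loglik_trace = res$trace[[1]],
                 converged = res$converged[1],
                 degenerate = res$degenerate[1],
                 n_iter = res$iterations[1]),
            class = "dropout_fit")
}

# Batched fit over many genes sharing one neighbour set; counts is an
# L x G matrix. Returns the raw list from the C++ routine.
fit_zip_pmm_batch <- function(counts, depths, tol = 1e-6, max_iter = 500,
                              p_cap = 0.99, want_trace = FALSE) {
  gh <- gh_rule(31)
  .zip_pmm_em(counts, as.numeric(depths), gh$x, gh$w, tol = tol,
              max_iter = max_iter, p_cap = p_cap, want_trace = want_trace)
}

#' Posterior mean expression rate for a zero count
#'
#' Under a fitted dropout model, the posterior mean of the underlying rate
#' `lambda = exp(mu + eps)` for a neighbour with observed count zero,
#' marginalizing over the dropout indicator: with responsibility
#' `r = p / (p + (1 - p) g(0))`, the estimate is
#' `r * exp(mu + psi / 2) + (1 - r) * E[lambda | C = 0, no dropout]`.
#' For a non-zero count the model is not used and the plug-in rate
#' `count / depth` is returned.
#'
#' @param fit A `dropout_fit` (or any list with `p`, `mu`, `psi`).
#' @param observed_count The neighbour's count for this gene.
#' @param depth The neighbour's total read depth `N_l`.
#' @param gh_n Number of Gauss-Hermite nodes (default 31).
#' @return Scalar rate estimate `lambda_hat >= 0`.
#' @export
posterior_lambda <- function(fit, observed_count, depth, gh_n = 31) {
  if (observed_count > 0) return(observed_count / depth)
  gh <- gh_rule(gh_n)
  s <- sqrt(2 * fit$psi)
  nu <- depth * exp(fit$mu + s * gh$x)
  p0 <- gh$w * exp(-nu)
  g0 <- sum(p0) / sqrt(pi)
  cond_mean <- sum(p0 * exp(fit$mu + s * gh$x)) / sum(p0)
  r <- fit$p / (fit$p + (1 - fit$p) * g0)
  r * exp(fit$mu + fit$psi / 2) + (1 - r) * cond_mean
}

#' Place a rate estimate on the log-RPM expression scale
#'
#' `lambda` is a per-read rate, so `1e6 * lambda` is its RPM and the value
#' on the scale of the normalized expression matrix is
#' `log(1e6 * lambda + 0.1)`. A rate of zero maps to `log(0.1)`, the
#' expression value of an unexpressed gene.
#'
#' @param lambda_hat Non-negative rate estimate(s).
#' @return Log-RPM-scale value(s).
#' @export
adjusted_predictor <- function(lambda_hat) {
  if (any(lambda_hat < 0)) stop("lambda_hat must be non-negative")
  log(1e6 * lambda_hat + 0.1)
}
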