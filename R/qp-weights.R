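#' Build the per-cell weight-estimation quadratic program
#'
#' The imputation weights of a target cell solve a nonnegative least-squares
#' problem on the probability simplex: minimize the sum of squared prediction
#' errors over the fitting genes subject to weights being nonnegative and
#' summing to one. The sum-to-one constraint is handled by eliminating a
#' designated reference candidate `r` (the pool cell most correlated with
#' the target, ties broken by lowest index): with
#' `W_j = X[i, j] - X[r, j]` and `Y[l, j] = X[l, j] - X[r, j]` the problem
#' becomes `min 0.5 * t(beta) P beta - t(q) beta` over
#' `beta >= 0, sum(beta) <= 1`, where `P = Y %*% t(Y)` and `q = Y %*% W`,
#' and the eliminated weight is `b_r = 1 - sum(beta)`. Correlation ties in
#' the reference choice break to the earliest cell in the pool's canonical
#' (identifier) order.
#'
#' A pool of a single candidate degenerates to a scalar box-constrained QP
#' on the raw (undifferenced) expression.
#'
#' @param X A `logexpr_matrix`.
#' @param target_cell Integer cell index.
#' @param pool A `candidate_pool` or integer vector of candidate cell
#'   indices.
#' @param fitting_genes Integer gene indices used in the fit; defaults to
#'   `X$fitting_genes`.
#' @return A `simplex_qp`: list with `P`, `q`, `pool_cells`, `ref_pos`
#'   (position of the reference inside `pool_cells`, `NA` for the scalar
#'   case), `target_cell`, `const` (the beta-independent additive constant
#'   of the sum of squared errors) and `type` (`"eliminated"` or
#'   `"scalar"`).
#' @export
build_qp <- function(X, target_cell, pool, fitting_genes = X$fitting_genes) {
  stopifnot(inherits(X, "logexpr_matrix"))
  cells <- if (inherits(pool, "candidate_pool")) pool$candidates else
    as.integer(pool)
  if (length(cells) == 0) stop("empty candidate pool")
  if (target_cell %in% cells) stop("target cell cannot be its own candidate")
  if (is.null(fitting_genes)) fitting_genes <- seq_len(ncol(X$X))
  if (length(fitting_genes) < length(cells)) {
    warning("fewer fitting genes than candidates; the QP may be rank-deficient")
  }
  x <- X$X[target_cell, fitting_genes]
  Ypool <- X$X[cells, fitting_genes, drop = FALSE]

  if (length(cells) == 1) {
    y <- as.numeric(Ypool)
    return(structure(list(P = matrix(sum(y * y), 1, 1),
                          q = matrix(sum(y * x), 1, 1),
                          pool_cells = cells, ref_pos = NA_integer_,
                          target_cell = target_cell,
                          const = sum(x * x), type = "scalar"),
                     class = "simplex_qp"))
  }

  co <- suppressWarnings(stats::cor(x, t(Ypool)))
  co[is.na(co)] <- -Inf
  ref_pos <- which(co == max(co))[1]          # ties -> first in pool order
  yr <- Ypool[ref_pos, ]
  W <- x - yr
  Y <- Ypool[-ref_pos, , drop = FALSE] - rep(yr, each = nrow(Ypool) - 1)
  P <- Y %*% t(Y)
  P <- (P + t(P)) / 2
  q <- Y %*% W
  structure(list(P = P, q = q, pool_cells = cells, ref_pos = ref_pos,
                 target_cell = target_cell, const = sum(W * W),
                 type = "eliminated"),
            class = "simplex_qp")
}

# Euclidean projection onto { b >= 0, sum(b) <= 1 }.
project_capped_simplex <- function(b) {
  v <- pmax(b, 0)
  if (sum(v) <= 1) return(v)
  # project onto the simplex { b >= 0, sum(b) = 1 } (sorting algorithm)
  u <- sort(b, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(b - theta, 0)
}

# Exact stationary point on the face defined by the support of beta;
# returns NULL when infeasible or numerically singular.
polish_active_set <- function(P, q, beta, eps = 1e-10) {
  S <- which(beta > eps)
  if (length(S) == 0) return(NULL)
  sol <- tryCatch({
    if (sum(beta) > 1 - 1e-9) {
      d <- length(S)
      K <- rbind(cbind(P[S, S, drop = FALSE], rep(1, d)), c(rep(1, d), 0))
      z <- solve(K, c(q[S], 1))[seq_len(d)]
    } else {
      z <- solve(P[S, S, drop = FALSE], q[S])
    }
    z
  }, error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  if (any(sol < -1e-9) || sum(sol) > 1 + 1e-9) return(NULL)
  out <- numeric(length(beta))
  out[S] <- pmax(sol, 0)
  if (sum(out) > 1) out <- out / sum(out)
  out
}

#' Solve the simplex-constrained quadratic program
#'
#' Accelerated projected-gradient descent (FISTA) on the eliminated problem
#' from [build_qp()], with periodic active-set polish steps that solve the
#' stationarity system on the current support exactly. Convergence is
#' declared when the projected-gradient (KKT) residual falls below `tol`.
#'
#' @param problem A `simplex_qp`.
#' @param tol KKT residual tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 10000).
#' @return Numeric weight vector over the full candidate pool (aligned with
#'   `problem$pool_cells`), entries in `[0, 1]` and summing to one (scalar
#'   pools excepted: there the box-constrained minimizer is returned).
#'   Attributes: `iterations`, `kkt_residual`, `objective` (sum of squared
#'   prediction errors at the solution).
#' @export
solve_simplex_qp <- function(problem, tol = 1e-8, max_iter = 10000) {
  stopifnot(inherits(problem, "simplex_qp"))
  P <- problem$P
  q <- as.numeric(problem$q)

  if (problem$type == "scalar") {
    b <- if (P[1, 1] > 0) min(1, max(0, q / P[1, 1])) else 1
    obj <- problem$const - 2 * q * b + P[1, 1] * b^2
    return(structure(b, iterations = 0L, kkt_residual = 0,
                     objective = as.numeric(obj)))
  }

  d <- length(q)
  L <- max(eigen(P, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  fval <- function(b) as.numeric(0.5 * crossprod(b, P %*% b) - sum(q * b))
  kkt <- function(b, g) max(abs(b - project_capped_simplex(b - g / L)))

  beta <- project_capped_simplex(rep(1 / (d + 1), d))
  z <- beta
  tk <- 1
  it <- 0L
  res <- Inf
  while (it < max_iter) {
    it <- it + 1L
    g <- as.numeric(P %*% z) - q
    beta_new <- project_capped_simplex(z - g / L)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- beta_new + ((tk - 1) / tk_new) * (beta_new - beta)
    beta <- beta_new
    tk <- tk_new
    if (it %% 50 == 0 || it == max_iter) {
      pol <- polish_active_set(P, q, beta)
      if (!is.null(pol) && fval(pol) <= fval(beta) + 1e-15) {
        beta <- pol
        z <- beta
        tk <- 1
      }
      res <- kkt(beta, as.numeric(P %*% beta) - q)
      if (res <= tol) break
    }
  }
  pol <- polish_active_set(P, q, beta)
  if (!is.null(pol) && fval(pol) <= fval(beta) + 1e-15) beta <- pol
  res <- kkt(beta, as.numeric(P %*% beta) - q)
  if (res > tol) {
    stop(sprintf(
      "QP solver did not converge: %d iterations, KKT residual %.3g (tol %.1g)",
      it, res, tol))
  }
  beta <- pmin(pmax(beta, 0), 1)
  if (sum(beta) > 1) beta <- beta / sum(beta)
  w <- numeric(length(problem$pool_cells))
  w[-problem$ref_pos] <- beta
  w[problem$ref_pos] <- max(0, 1 - sum(beta))
  obj <- problem$const - 2 * sum(q * beta) +
    as.numeric(crossprod(beta, P %*% beta))
  structure(w, iterations = it, kkt_residual = res,
            objective = as.numeric(obj))
}

#' Hard-threshold and renormalize raw weights
#'
#' Weights below `t` (default 0.001) are set to exactly zero and the
#' survivors are rescaled to sum to one. If every weight falls below `t`
#' the single largest is kept at weight one, with a warning.
#'
#' @param weights Raw weight vector from [solve_simplex_qp()].
#' @param t Hard threshold (default 0.001).
#' @param pool_cells Integer cell indices aligned with `weights`.
#' @param target_cell Integer target cell index (bookkeeping only).
#' @param objective Optional objective value to carry through.
#' @return A `cell_neighborhood`: list with `target_cell`, `neighbors`
#'   (cell indices with non-zero final weight), `weights` (aligned to
#'   `neighbors`, summing to one) and `objective`.
#' @export
threshold_and_renormalize <- function(weights, t = 0.001,
                                      pool_cells = seq_along(weights),
                                      target_cell = NA_integer_,
                                      objective = NA_real_) {
  if (any(weights < -1e-8) || any(weights > 1 + 1e-8)) {
    stop("raw weights must lie in [0, 1]")
  }
  w <- pmin(pmax(weights, 0), 1)
  w[w < t] <- 0
  if (all(w == 0)) {
    warning("all weights below threshold; keeping the single largest at 1")
    w[which.max(weights)] <- 1
  }
  keep <- which(w > 0)
  w <- w[keep] / sum(w[keep])
  structure(list(target_cell = target_cell,
                 neighbors = as.integer(pool_cells[keep]),
                 weights = w, objective = objective),
            class = "cell_neighborhood")
}

#' Sum of squared prediction errors for a weighted neighbour fit
#'
#' Direct evaluation of the weight-estimation objective
#' `sum_j (X[i, j] - sum_l w_l X[l, j])^2` over the fitting genes, used to
#' compare solver output against brute-force search.
#'
#' @param X A `logexpr_matrix`.
#' @param target_cell Integer cell index.
#' @param cells Integer neighbour cell indices.
#' @param weights Weights aligned with `cells`.
#' @param fitting_genes Gene indices (default `X$fitting_genes`).
#' @return Scalar sum of squared errors.
#' @export
prediction_sse <- function(X, target_cell, cells, weights,
                           fitting_genes = X$fitting_genes) {
  if (is.null(fitting_genes)) fitting_genes <- seq_len(ncol(X$X))
  pred <- as.numeric(crossprod(X$X[cells, fitting_genes, drop = FALSE],
                               weights))
  sum((X$X[target_cell, fitting_genes] - pred)^2)
}

# All length-k nonnegative integer vectors summing to N, as a matrix.
# Memoized: the oracle reuses the same grid across many random instances.
composition_cache <- new.env(parent = emptyenv())
integer_compositions <- function(k, N) {
  key <- paste(k, N)
  hit <- composition_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (k == 1) {
    G <- matrix(N, 1, 1)
  } else {
    G <- matrix(0:N, ncol = 1)
    for (j in seq_len(k - 2)) {
      reps <- N - rowSums(G) + 1
      G <- cbind(G[rep(seq_len(nrow(G)), reps), , drop = FALSE],
                 sequence(reps) - 1)
    }
    G <- cbind(G, N - rowSums(G))
  }
  composition_cache[[key]] <- G
  G
}

#' Brute-force grid search over the weight simplex
#'
#' Exhaustively evaluates the prediction sum of squared errors on a regular
#' grid over the probability simplex (all weight vectors with entries that
#' are multiples of `step` and sum to one). Exponential in the pool size —
#' an independent oracle for validating [solve_simplex_qp()] on small pools,
#' not a production solver.
#'
#' @param X A `logexpr_matrix`.
#' @param target_cell Integer cell index.
#' @param pool_cells Integer candidate cell indices (keep below ~5).
#' @param fitting_genes Gene indices (default `X$fitting_genes`).
#' @param step Grid resolution (default 0.005; must divide 1).
#' @return List with `weights` (best grid point) and `objective` (its sum
#'   of squared errors).
#' @export
grid_search_weights <- function(X, target_cell, pool_cells,
                                fitting_genes = X$fitting_genes,
                                step = 0.005) {
  if (is.null(fitting_genes)) fitting_genes <- seq_len(ncol(X$X))
  k <- length(pool_cells)
  N <- round(1 / step)
  G <- integer_compositions(k, N) / N
  Y <- X$X[pool_cells, fitting_genes, drop = FALSE]
  x <- X$X[target_cell, fitting_genes]
  A <- Y %*% t(Y)
  cvec <- as.numeric(Y %*% x)
  sse <- sum(x * x) - 2 * as.numeric(G %*% cvec) + rowSums((G %*% A) * G)
  best <- which.min(sse)
  list(weights = G[best, ], objective = sse[best])
}

#' Estimate final neighbour weights for one cell
#'
#' Convenience wrapper chaining [build_qp()], [solve_simplex_qp()] and
#' [threshold_and_renormalize()]; the returned neighbourhood carries the
#' prediction sum of squared errors of the *final* (thresholded) weights.
#'
#' @inheritParams build_qp
#' @param weight_threshold Hard threshold `t` (default 0.001).
#' @param tol,max_iter Passed to [solve_simplex_qp()].
#' @return A `cell_neighborhood`.
#' @export
estimate_weights <- function(X, target_cell, pool,
                             fitting_genes = X$fitting_genes,
                             weight_threshold = 0.001, tol = 1e-8,
                             max_iter = 10000) {
  problem <- build_qp(X, target_cell, pool, fitting_genes)
  raw <- solve_simplex_qp(problem, tol = tol, max_iter = max_iter)
  nb <- threshold_and_renormalize(raw, t = weight_threshold,
                                  pool_cells = problem$pool_cells,
                                  target_cell = target_cell)
  nb$objective <- prediction_sse(X, target_cell, nb$neighbors, nb$weights,
                                 fitting_genes)
  nb
}
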