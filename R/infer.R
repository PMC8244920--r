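#' Penalty grid for sparse structure estimation
#'
#' Log-spaced decreasing grid from `lambda_max` (the largest absolute
#' off-diagonal correlation, at or above which both estimators return the
#' empty graph) down to `lambda_max * min_ratio`.
#'
#' @param corr p x p correlation matrix (unit diagonal).
#' @param n_lambda grid length (default 50).
#' @param min_ratio ratio of smallest to largest penalty (default 0.01).
#' @return strictly decreasing numeric vector of length `n_lambda`.
#' @export
lambda_grid <- function(corr, n_lambda = 50, min_ratio = 0.01) {
  stopifnot(nrow(corr) == ncol(corr), n_lambda >= 2, min_ratio > 0, min_ratio < 1)
  lmax <- max(abs(corr[upper.tri(corr)]))
  if (lmax == 0) stop("nothing to infer: all off-diagonal correlations are zero")
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Graphical-lasso solution path
#'
#' Estimates, for each penalty in a decreasing grid, the support of the
#' l1-penalized maximum-likelihood precision matrix of the latent layer,
#' using the empirical correlation matrix of `Z` and blockwise coordinate
#' descent, warm-started from the previous grid point. Grid points where the
#' solver fails to converge are skipped with a warning.
#'
#' @param latent n x p matrix of latent values (from [posterior_mean()], or
#'   transformed values directly for the no-imputation baseline).
#' @param grid decreasing penalty grid (default [lambda_grid()] of the
#'   empirical correlation).
#' @param tol,maxit solver convergence threshold and maximum outer sweeps.
#' @return object of class `ziln_path`: list with `lambdas`, `supports`
#'   (per-lambda data.frame of edges `a < b` with a `weight` column holding
#'   the absolute partial correlation), `method = "glasso"`.
#' @export
glasso_path <- function(latent, grid = NULL, tol = 1e-4, maxit = 100) {
  Z <- as.matrix(latent)
  stopifnot(nrow(Z) >= 3)
  R <- cor(Z)
  if (is.null(grid)) grid <- lambda_grid(R)
  stopifnot(all(diff(grid) < 0), all(grid > 0))
  p <- ncol(R)

  W <- R
  B <- matrix(0, p, p)
  lambdas <- numeric(0)
  supports <- list()
  for (lam in grid) {
    fit <- glasso_cd(R, lam, W, B, tol, maxit)
    if (!fit$converged) {
      warning(sprintf("glasso did not converge at lambda = %.4g; grid point skipped", lam))
      next
    }
    W <- fit$W
    B <- fit$B
    Theta <- fit$Theta
    pc <- -Theta / sqrt(outer(diag(Theta), diag(Theta)))
    sel <- which(upper.tri(Theta) & abs(Theta) > 1e-8, arr.ind = TRUE)
    sup <- data.frame(a = sel[, 1], b = sel[, 2], weight = abs(pc[sel]))
    lambdas <- c(lambdas, lam)
    supports <- c(supports, list(sup))
  }
  if (!length(lambdas)) stop("glasso failed to converge at every grid point")
  new_ziln_path(lambdas, supports, method = "glasso", p = p)
}

#' Neighborhood-selection (Meinshausen-Buhlmann) solution path
#'
#' Regresses each standardized column of the latent matrix on all others with
#' the lasso along a shared penalty grid (objective
#' `1/(2n) ||y - Xb||^2 + lambda ||b||_1`, solved by glmnet). An edge (j, k)
#' is in the support at a penalty when either regression coefficient is
#' nonzero (`symmetrization = "or"`, the default union rule) or both are
#' (`"and"`). Columns are standardized to zero mean and unit population
#' variance, making penalties comparable across variables and the estimated
#' support invariant to column scaling.
#'
#' @inheritParams glasso_path
#' @param symmetrization `"or"` (union) or `"and"` (intersection).
#' @return object of class `ziln_path` with per-edge `weight` equal to the
#'   largest absolute regression coefficient across the two directions.
#' @export
mb_path <- function(latent, grid = NULL, symmetrization = c("or", "and")) {
  symmetrization <- match.arg(symmetrization)
  Z <- standardize_cols(as.matrix(latent))
  n <- nrow(Z); p <- ncol(Z)
  stopifnot(n >= 3)
  if (is.null(grid)) grid <- lambda_grid(cor(Z))
  stopifnot(all(diff(grid) < 0), all(grid > 0))

  # coef_abs[[l]]: p x p matrix, entry (k, j) = |beta_k| in the regression of
  # column j on the others at grid[l]
  coef_abs <- lapply(seq_along(grid), function(l) matrix(0, p, p))
  for (j in seq_len(p)) {
    X <- Z[, -j, drop = FALSE]
    y <- Z[, j]
    beta <- if (p == 2) {
      # single-predictor lasso in closed form: soft-threshold the correlation
      r <- mean(X[, 1] * y)
      matrix(sign(r) * pmax(abs(r) - grid, 0), nrow = 1)
    } else {
      fit <- glmnet::glmnet(X, y, family = "gaussian", lambda = grid,
                            standardize = FALSE, intercept = FALSE,
                            thresh = 1e-10)
      as.matrix(fit$beta) # (p-1) x n_lambda
    }
    for (l in seq_along(grid)) {
      coef_abs[[l]][seq_len(p)[-j], j] <- abs(beta[, l])
    }
  }

  supports <- lapply(seq_along(grid), function(l) {
    cm <- coef_abs[[l]]
    present <- if (symmetrization == "or") (cm > 0) | t(cm > 0) else (cm > 0) & t(cm > 0)
    sel <- which(upper.tri(present) & present, arr.ind = TRUE)
    w <- pmax(cm[sel], t(cm)[sel])
    data.frame(a = sel[, 1], b = sel[, 2], weight = w)
  })
  new_ziln_path(grid, supports, method = "mb", p = p, symmetrization = symmetrization)
}

standardize_cols <- function(Z) {
  n <- nrow(Z)
  mu <- colMeans(Z)
  sd_pop <- sqrt(colMeans(Z^2) - mu^2)
  sd_pop[sd_pop == 0] <- 1
  sweep(sweep(Z, 2, mu, "-"), 2, sd_pop, "/")
}

new_ziln_path <- function(lambdas, supports, method, p, symmetrization = NULL) {
  structure(
    list(lambdas = lambdas, supports = supports, method = method,
         symmetrization = symmetrization, p = p),
    class = "ziln_path"
  )
}

#' @export
print.ziln_path <- function(x, ...) {
  sizes <- vapply(x$supports, nrow, integer(1))
  cat(sprintf("%s solution path: %d penalties in [%.3g, %.3g]; support sizes %d..%d\n",
              x$method, length(x$lambdas), min(x$lambdas), max(x$lambdas),
              min(sizes), max(sizes)))
  invisible(x)
}

#' Rank candidate edges by their solution-path entry point
#'
#' The decreasing-penalty solution path induces an (approximately) nested
#' family of edge sets; an edge that enters the path at a large penalty is
#' more reliable than one appearing only under weak regularization. Each
#' node pair is scored by the largest penalty at which it first appears in a
#' support (even if it later drops out); ties are broken by the edge weight
#' recorded at that penalty (absolute partial correlation for glasso,
#' largest absolute regression coefficient for MB), then by pair index.
#' Pairs never selected rank last, in index order, with score 0.
#'
#' @param path a `ziln_path` object.
#' @param p number of nodes; defaults to the largest index seen in the path.
#' @return data.frame of all `p(p-1)/2` pairs with columns `a`, `b`, `rank`,
#'   `first_entry_lambda` (`NA` if never selected), `score`.
#' @export
rank_edges <- function(path, p = NULL) {
  stopifnot(inherits(path, "ziln_path"))
  if (is.null(p)) p <- path$p
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  key <- function(a, b) (a - 1) * p + b
  first_lambda <- rep(NA_real_, nrow(pairs))
  score <- rep(0, nrow(pairs))
  names(first_lambda) <- names(score) <- key(pairs[, 1], pairs[, 2])

  # walk from largest penalty down; record first appearance only
  ord <- order(path$lambdas, decreasing = TRUE)
  for (l in ord) {
    sup <- path$supports[[l]]
    if (!nrow(sup)) next
    k <- as.character(key(sup$a, sup$b))
    new <- is.na(first_lambda[k])
    first_lambda[k][new] <- path$lambdas[l]
    score[k][new] <- sup$weight[new]
  }

  out <- data.frame(a = pairs[, 1], b = pairs[, 2],
                    first_entry_lambda = unname(first_lambda),
                    score = unname(score))
  o <- order(-ifelse(is.na(out$first_entry_lambda), -Inf, out$first_entry_lambda),
             -out$score, out$a, out$b)
  out <- out[o, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("a", "b", "rank", "first_entry_lambda", "score")]
}
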