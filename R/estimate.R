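#' Estimate per-taxon censoring thresholds
#'
#' The maximum-likelihood threshold for taxon j is the smallest transformed
#' value among its nonzero observations: every structural zero must lie below
#' it and every observed value above it. Taxa with no zero counts get
#' `-Inf` (the zero-inflation component is vacuous).
#'
#' @param transformed a `ziln_transform` object (from [zclr()] or [clr()]).
#' @return length-p numeric vector of thresholds.
#' @export
estimate_delta <- function(transformed) {
  stopifnot(inherits(transformed, "ziln_transform"))
  vals <- transformed$values
  mask <- transformed$zero_mask
  if (any(colSums(!mask) == 0)) stop("unobserved taxon; filter first")
  vapply(seq_len(ncol(vals)), function(j) {
    if (!any(mask[, j])) return(-Inf)
    min(vals[!mask[, j], j])
  }, numeric(1))
}

#' Fit zero-inflated normal marginals to transformed counts
#'
#' Under a diagonal latent covariance, each taxon's transformed values follow
#' a univariate zero-inflated normal: zeros occur with probability
#' `Phi((delta - mu) / sigma)` and nonzero values are draws from
#' `N(mu, sigma2)` above `delta`. The mixed likelihood for taxon j is
#' \deqn{\sum_{i: \tilde y_{ij} = 0} \log \Phi_{\mu,\sigma^2}(\hat\delta_j)
#'   + \sum_{i: \tilde y_{ij} \neq 0} \log f_{\mu,\sigma^2}(\tilde y_{ij})}
#' maximized by quasi-Newton (BFGS) over `(mu, log sigma2)` from moment-based
#' starting values (mean and variance of the nonzero entries); optimizing the
#' log variance keeps `sigma2` positive. Taxa with no zeros reduce exactly to
#' the Gaussian MLE (sample mean, 1/n variance). If the optimizer fails, the
#' moment estimates are returned with `converged = FALSE`. A taxon with a
#' single nonzero value has its variance floored at 1e-4.
#'
#' @param transformed a `ziln_transform` object.
#' @param delta_hat optional thresholds; default [estimate_delta()].
#' @return object of class `ziln_marginal_fit`: list of length-p vectors
#'   `mu_hat`, `sigma2_hat`, `delta_hat`, `loglik`, `converged`.
#' @export
fit_marginals <- function(transformed, delta_hat = NULL) {
  stopifnot(inherits(transformed, "ziln_transform"))
  if (is.null(delta_hat)) delta_hat <- estimate_delta(transformed)
  vals <- transformed$values
  mask <- transformed$zero_mask
  p <- ncol(vals)
  stopifnot(length(delta_hat) == p)

  mu_hat <- sigma2_hat <- loglik <- numeric(p)
  converged <- logical(p)
  for (j in seq_len(p)) {
    fit <- fit_marginal_one(vals[!mask[, j], j], sum(mask[, j]), delta_hat[j])
    mu_hat[j] <- fit$mu
    sigma2_hat[j] <- fit$sigma2
    loglik[j] <- fit$loglik
    converged[j] <- fit$converged
  }
  structure(
    list(mu_hat = mu_hat, sigma2_hat = sigma2_hat, delta_hat = delta_hat,
         loglik = loglik, converged = converged),
    class = "ziln_marginal_fit"
  )
}

# One-taxon zero-inflated normal MLE.
# y_nz: nonzero transformed values; n0: number of masked zeros; delta: threshold.
fit_marginal_one <- function(y_nz, n0, delta, sigma2_floor = 1e-4) {
  n1 <- length(y_nz)
  if (n1 == 0) stop("unobserved taxon; filter first")
  m <- mean(y_nz)
  v <- if (n1 > 1) max(var(y_nz) * (n1 - 1) / n1, sigma2_floor) else sigma2_floor

  if (n0 == 0 || !is.finite(delta)) {
    # no zero-inflation term: Gaussian MLE in closed form
    ll <- sum(dnorm(y_nz, m, sqrt(v), log = TRUE))
    return(list(mu = m, sigma2 = v, loglik = ll, converged = TRUE))
  }

  nll <- function(par) {
    mu <- par[1]
    sigma <- sqrt(exp(par[2]))
    -(n0 * pnorm(delta, mu, sigma, log.p = TRUE) +
        sum(dnorm(y_nz, mu, sigma, log = TRUE)))
  }
  opt <- tryCatch(
    optim(c(m, log(v)), nll, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL
  )
  if (is.null(opt) || !is.finite(opt$value)) {
    ll <- -nll(c(m, log(v)))
    return(list(mu = m, sigma2 = v, loglik = ll, converged = FALSE))
  }
  list(mu = opt$par[1],
       sigma2 = max(exp(opt$par[2]), sigma2_floor),
       loglik = -opt$value,
       converged = opt$convergence == 0)
}

#' @export
print.ziln_marginal_fit <- function(x, ...) {
  cat("Zero-inflated normal marginal fits for", length(x$mu_hat), "taxa;",
      sum(!x$converged), "non-converged\n")
  invisible(x)
}

#' Mean of a normal truncated from above
#'
#' Closed form for `E[z | z <= delta]` with `z ~ N(mu, sigma^2)`:
#' `mu - sigma * phi(alpha) / Phi(alpha)`, `alpha = (delta - mu) / sigma`.
#' The Mills ratio `phi/Phi` is evaluated on the log scale
#' (`exp(log phi - log Phi)`), which remains accurate far in the lower tail
#' where both factors underflow.
#'
#' @param mu,sigma normal mean and standard deviation.
#' @param delta upper truncation point (`Inf` returns `mu`).
#' @return the truncated mean, always strictly below `delta` (and below `mu`).
#' @export
#' @examples
#' truncated_normal_mean(0, 1, 0) # -sqrt(2/pi)
truncated_normal_mean <- function(mu, sigma, delta) {
  n <- max(length(mu), length(sigma), length(delta))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n); delta <- rep_len(delta, n)
  alpha <- (delta - mu) / sigma
  out <- mu - sigma * exp(dnorm(alpha, log = TRUE) - pnorm(alpha, log.p = TRUE))
  untruncated <- is.infinite(alpha) & alpha > 0
  out[untruncated] <- mu[untruncated]
  out
}

#' Posterior-mean reconstruction of the latent Gaussian layer
#'
#' The expectation step of the one-step EM: observed (nonzero) transformed
#' values are taken as the latent values themselves; structural zeros are
#' replaced by the conditional expectation of the latent coordinate given
#' that it lies below the censoring threshold,
#' `E[z_ij | z_ij <= delta_j] = mu_j - sigma_j * phi(alpha)/Phi(alpha)`.
#' With a diagonal covariance estimate every entry is independent, so the
#' reconstruction is entrywise.
#'
#' @param transformed a `ziln_transform` object.
#' @param fit a `ziln_marginal_fit` from [fit_marginals()].
#' @return n x p numeric matrix of latent values.
#' @export
posterior_mean <- function(transformed, fit) {
  stopifnot(inherits(transformed, "ziln_transform"),
            inherits(fit, "ziln_marginal_fit"))
  vals <- transformed$values
  mask <- transformed$zero_mask
  p <- ncol(vals)
  stopifnot(length(fit$mu_hat) == p)
  z <- vals
  for (j in seq_len(p)) {
    if (!any(mask[, j])) next
    z[mask[, j], j] <- truncated_normal_mean(
      fit$mu_hat[j], sqrt(fit$sigma2_hat[j]), fit$delta_hat[j]
    )
  }
  z
}
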