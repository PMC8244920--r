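#' Convert a target zero probability to a censoring threshold
#'
#' Under the zero-inflated log-normal model a taxon's abundance is zero when
#' its latent Gaussian value falls below a threshold delta. For a marginal
#' `N(mu, sigma2)` the threshold giving structural-zero probability `s` is
#' the `s`-quantile: `delta = qnorm(s, mu, sqrt(sigma2))`. `s = 0` maps to
#' `-Inf` (no structural zeros).
#'
#' @param s target per-taxon zero probability, in `[0, 1)`; vectorized.
#' @param mu latent marginal mean(s).
#' @param sigma2 latent marginal variance(s), > 0.
#' @return numeric vector of thresholds delta.
#' @export
#' @examples
#' sparsity_to_delta(0.5, mu = 2, sigma2 = 4) # the median: 2
sparsity_to_delta <- function(s, mu, sigma2) {
  if (any(s < 0 | s >= 1)) stop("s must lie in [0, 1): s = 1 is a degenerate all-zero taxon")
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  qnorm(s, mean = mu, sd = sqrt(sigma2))
}

#' Deterministic sparsity profile hitting a target global zero fraction
#'
#' Builds the per-taxon zero probabilities `s_j = (j/p)^t`, `j = 1..p`, with
#' the exponent `t > 0` solved numerically so that `mean(s)` equals
#' `target` to within 1e-6. Each `s_j` is capped at 0.99 (the last taxon
#' would otherwise be deterministically absent); the root is found for the
#' capped profile. `target = 0` returns the all-zero vector.
#'
#' @param p number of taxa.
#' @param target global zero-probability target in `[0, 1)`.
#' @return length-`p` non-decreasing vector of zero probabilities.
#' @export
#' @examples
#' s <- sparsity_profile(300, 0.5)
#' mean(s)
sparsity_profile <- function(p, target) {
  if (target >= 1) stop("target must be < 1")
  if (target < 0) stop("target must be >= 0")
  if (target == 0) return(rep(0, p))
  max_s <- 0.99
  prof <- function(t) pmin((seq_len(p) / p)^t, max_s)
  obj <- function(t) mean(prof(t)) - target
  # mean is decreasing in t: t -> 0 gives mean ~ max_s-ish cap, t -> Inf gives 0
  lo <- 1e-8
  if (obj(lo) < 0) stop("target exceeds the maximum attainable mean (cap ", max_s, ")")
  hi <- 1
  while (obj(hi) > 0) hi <- hi * 2
  t_star <- uniroot(obj, c(lo, hi), tol = 1e-12)$root
  prof(t_star)
}

#' Draw sequencing library sizes
#'
#' Library sizes (total reads per sample) are negative binomial with the
#' (mean, size) parameterization: variance `mean + mean^2 / size`. The
#' simulation studies use mean 1.5e6 and size 5, matching heavy-tailed
#' shotgun sequencing depths.
#'
#' @param n number of samples.
#' @param mean expected library size, > 0.
#' @param size NB dispersion parameter, > 0 (larger = closer to Poisson).
#' @param seed integer seed.
#' @return length-`n` integer-valued numeric vector.
#' @export
sample_library_sizes <- function(n, mean = 1.5e6, size = 5, seed = 1L) {
  stopifnot(mean > 0, size > 0, n >= 1)
  with_seed(seed, rnbinom(n, mu = mean, size = size))
}

#' Simulate counts under the zero-inflated log-normal model
#'
#' The generative model for each sample i:
#' \enumerate{
#'   \item draw the latent Gaussian `z_i ~ N(mu, Sigma)`;
#'   \item abundance `a_ij = exp(z_ij)` if `z_ij > delta_j`, else 0
#'     (a structural zero);
#'   \item proportions `pi_ij = a_ij / sum_k a_ik`;
#'   \item counts `y_i ~ Multinomial(N_i, pi_i)`.
#' }
#' Rows therefore sum exactly to the library sizes; additional sampling zeros
#' arise from the multinomial whenever `N_i * pi_ij` is small. A sample whose
#' abundances are all zero is redrawn once; a repeat is an error (the
#' configuration is degenerate).
#'
#' @param covariance p x p positive-definite latent covariance (e.g. from
#'   [graph_to_precision()]).
#' @param mu length-p latent mean vector.
#' @param delta length-p censoring thresholds (`-Inf` = never zero), e.g.
#'   from [sparsity_to_delta()].
#' @param n number of samples.
#' @param library_sizes length-n vector of totals; if `NULL`, drawn as
#'   NB(mean = `libsize_mean`, size = `libsize_size`).
#' @param libsize_mean,libsize_size negative-binomial library-size parameters.
#' @param seed integer seed.
#' @return object of class `ziln_counts`: list with `counts` (n x p integer
#'   matrix, rows = samples), `library_sizes`, `sample_ids`, `taxon_ids`,
#'   and the `mu`, `delta` used.
#' @export
#' @examples
#' g <- make_graph("erdos_renyi", p = 10, e = 10, seed = 1)
#' cp <- graph_to_precision(g, kappa = 100, seed = 1)
#' y <- ziln_counts(cp$covariance, mu = rep(1, 10), delta = rep(-Inf, 10),
#'                  n = 5, seed = 1)
#' rowSums(y$counts) == y$library_sizes
ziln_counts <- function(covariance, mu, delta, n,
                        library_sizes = NULL,
                        libsize_mean = 1.5e6, libsize_size = 5,
                        seed = 1L) {
  p <- length(mu)
  stopifnot(nrow(covariance) == p, ncol(covariance) == p, length(delta) == p, n >= 1)
  seeds <- split_seed(seed, 3L)
  if (is.null(library_sizes)) {
    library_sizes <- sample_library_sizes(n, libsize_mean, libsize_size, seed = seeds[1])
  }
  stopifnot(length(library_sizes) == n)

  counts <- with_seed(seeds[2], {
    z <- MASS::mvrnorm(n, mu = mu, Sigma = covariance)
    if (n == 1) z <- matrix(z, nrow = 1)
    a <- exp(z)
    a[sweep(z, 2, delta, "<=")] <- 0
    dead <- which(rowSums(a) == 0)
    if (length(dead)) {
      z2 <- MASS::mvrnorm(length(dead), mu = mu, Sigma = covariance)
      if (length(dead) == 1) z2 <- matrix(z2, nrow = 1)
      a2 <- exp(z2)
      a2[sweep(z2, 2, delta, "<=")] <- 0
      if (any(rowSums(a2) == 0)) {
        stop("degenerate configuration: a sample drew all-zero abundances twice")
      }
      a[dead, ] <- a2
    }
    pi_mat <- a / rowSums(a)
    y <- matrix(0, n, p)
    for (i in seq_len(n)) {
      y[i, ] <- rmultinom(1, size = library_sizes[i], prob = pi_mat[i, ])
    }
    storage.mode(y) <- "double"
    y
  })

  new_ziln_counts(counts, library_sizes, mu = mu, delta = delta)
}

new_ziln_counts <- function(counts, library_sizes = rowSums(counts),
                            sample_ids = NULL, taxon_ids = NULL,
                            mu = NULL, delta = NULL) {
  n <- nrow(counts); p <- ncol(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(p))
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(
    list(counts = counts, library_sizes = unname(library_sizes),
         sample_ids = sample_ids, taxon_ids = taxon_ids,
         mu = mu, delta = delta),
    class = "ziln_counts"
  )
}

#' @export
print.ziln_counts <- function(x, ...) {
  cat("Count matrix:", nrow(x$counts), "samples x", ncol(x$counts), "taxa;",
      sprintf("%.1f%% zeros", 100 * mean(x$counts == 0)), "\n")
  invisible(x)
}

#' Simulate a full Simulation-1-style dataset
#'
#' Convenience wrapper reproducing the first simulation protocol: a graph of
#' the requested topology with `e = p` edges, precision with condition number
#' `kappa`, latent means `mu_j ~ unif(0, 3)`, per-taxon zero probabilities
#' `s_j ~ unif(0, 0.9)` converted to thresholds via [sparsity_to_delta()]
#' (using the generated marginal variances), and NB library sizes
#' (mean 1.5e6, size 5). Under these settings roughly 45% of count cells are
#' zero. Pass an explicit `s` vector (e.g. from [sparsity_profile()]) to
#' reproduce the second, sparsity-sweep protocol instead.
#'
#' @param p number of taxa; `e = p` edges are used.
#' @param n number of samples.
#' @param topology graph topology, see [make_graph()].
#' @param kappa precision condition number.
#' @param s optional length-p zero-probability vector; default uniform(0, 0.9).
#' @param seed integer seed.
#' @return list with `graph`, `covpair`, `mu`, `s`, `delta`, and `data`
#'   (a `ziln_counts` object).
#' @export
simulate_dataset <- function(p = 100, n = 300, topology = "erdos_renyi",
                             kappa = 100, s = NULL, seed = 1L) {
  seeds <- split_seed(seed, 5L)
  graph <- make_graph(topology, p = p, e = p, seed = seeds[1])
  covpair <- graph_to_precision(graph, kappa = kappa, seed = seeds[2])
  pars <- with_seed(seeds[3], {
    mu <- runif(p, 0, 3)
    if (is.null(s)) s <- runif(p, 0, 0.9)
    list(mu = mu, s = s)
  })
  delta <- sparsity_to_delta(pars$s, pars$mu, diag(covpair$covariance))
  data <- ziln_counts(covpair$covariance, pars$mu, delta, n = n, seed = seeds[4])
  list(graph = graph, covpair = covpair, mu = pars$mu, s = pars$s,
       delta = delta, data = data)
}

#' Simulate counts under the NorTA zero-inflated negative binomial model
#'
#' The "Normal to Anything" comparator: draw `z ~ N(0, Sigma)`, push each
#' coordinate through its marginal normal cdf `Phi(0, Sigma_jj)` and then
#' through the inverse cdf of a zero-inflated negative binomial with mean
#' `exp(mu_j)`, size `nu`, and zero-inflation probability `s_j`. The copula
#' preserves the latent rank correlations; unlike the zero-inflated
#' log-normal generator there is no multinomial step, so this generator is
#' not compositional and row sums are unconstrained.
#'
#' @param covariance p x p positive-definite latent covariance.
#' @param mu length-p vector; marginal NB means are `exp(mu)`.
#' @param s length-p zero-inflation probabilities in `[0, 1)`.
#' @param nu NB size parameter (default 10).
#' @param n number of samples.
#' @param seed integer seed.
#' @return object of class `ziln_counts` (library sizes are the realized
#'   row sums).
#' @export
norta_counts <- function(covariance, mu, s, nu = 10, n, seed = 1L) {
  p <- length(mu)
  stopifnot(nrow(covariance) == p, length(s) == p, nu > 0,
            all(s >= 0 & s < 1))
  counts <- with_seed(seed, {
    z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = covariance)
    if (n == 1) z <- matrix(z, nrow = 1)
    u <- pnorm(z, mean = 0, sd = rep(sqrt(diag(covariance)), each = n))
    y <- matrix(0, n, p)
    for (j in seq_len(p)) {
      y[, j] <- qzinb(u[, j], mean = exp(mu[j]), size = nu, zero_prob = s[j])
    }
    y
  })
  new_ziln_counts(counts, mu = mu)
}

# Zero-inflated negative binomial quantile function.
# cdf: F(x) = s + (1 - s) * F_nb(x) for x >= 0.
qzinb <- function(u, mean, size, zero_prob) {
  out <- numeric(length(u))
  pos <- u > zero_prob
  out[pos] <- qnbinom((u[pos] - zero_prob) / (1 - zero_prob), mu = mean, size = size)
  out
}
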