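test_that("graph generators honor the requested edge count and topology", {
  # erdos-renyi: exactly e edges, symmetric 0/1, zero diagonal
  for (seed in 1:3) {
    g <- make_graph("erdos_renyi", p = 100, e = 100, seed = seed)
    expect_equal(g$edge_count, 100)
    expect_symmetric01(g$adjacency)
    expect_equal(sum(g$adjacency) / 2, 100)
  }

  # bandwidth-1 band graph on 4 nodes is the path graph
  g <- make_graph("band", p = 4, e = 3, seed = 0)
  expect_equal(graph_edges(g), cbind(a = 1:3, b = 2:4), ignore_attr = TRUE)

  # band trimming: e below a full band still gives exactly e edges
  g2 <- make_graph("band", p = 10, e = 13, seed = 0)
  expect_equal(g2$edge_count, 13)
  expect_symmetric01(g2$adjacency)

  # scale-free graphs reach e exactly and are heavier-tailed than ER
  max_deg <- function(topology, seed) {
    g <- make_graph(topology, p = 50, e = 50, seed = seed)
    expect_equal(g$edge_count, 50)
    max(rowSums(g$adjacency))
  }
  sf <- vapply(1:100, function(s) max_deg("scale_free", s), numeric(1))
  er <- vapply(1:100, function(s) max_deg("erdos_renyi", s), numeric(1))
  expect_gt(mean(sf), mean(er))

  expect_error(make_graph("erdos_renyi", p = 5, e = 11, seed = 1), "too many edges")
  expect_error(make_graph("ring", p = 5, e = 5, seed = 1))
})

test_that("precision matrices hit the requested condition number exactly", {
  for (topology in c("band", "erdos_renyi", "scale_free")) {
    for (seed in 1:3) {
      g <- make_graph(topology, p = 40, e = 40, seed = seed)
      cp <- graph_to_precision(g, kappa = 100, seed = seed + 10)
      expect_lt(abs(cp$condition_number - 100), 1e-6)
      ev <- eigen(cp$precision, symmetric = TRUE, only.values = TRUE)$values
      expect_lt(abs(max(ev) / min(ev) - 100), 1e-6)
      expect_gt(min(ev), 0)
      # inverse pair
      expect_lt(max(abs(cp$precision %*% cp$covariance - diag(40))), 1e-8)
      # support equals adjacency exactly
      sup <- (abs(cp$precision) > 1e-12) * 1 - diag(40)
      expect_identical(unname(sup), unname(g$adjacency * 1))
    }
  }
})

test_that("two-node condition-number targeting matches the closed form", {
  # precision [[c, w], [w, c]] has eigenvalues c +/- |w|; the shift solving
  # (|w| + c) / (-|w| + c) = kappa is c = |w| (kappa + 1) / (kappa - 1)
  g <- structure(list(adjacency = matrix(c(0, 1, 1, 0), 2), topology = "band",
                      edge_count = 1, p = 2, seed = 1L), class = "ziln_graph")
  cp <- graph_to_precision(g, kappa = 10, seed = 3)
  w <- abs(cp$precision[1, 2])
  expect_lt(abs(cp$precision[1, 1] - w * 11 / 9), 1e-10)
  expect_lt(abs(cp$condition_number - 10), 1e-6)
})

test_that("degenerate covariance requests are rejected or flagged", {
  g <- make_graph("band", p = 5, e = 4, seed = 1)
  expect_error(graph_to_precision(g, kappa = 1, seed = 1))
  empty <- structure(list(adjacency = matrix(0, 4, 4), topology = "band",
                          edge_count = 0, p = 4, seed = 1L), class = "ziln_graph")
  expect_warning(cp <- graph_to_precision(empty, kappa = 100, seed = 1), "no edges")
  expect_equal(cp$precision, diag(4))
  expect_equal(cp$condition_number, 1)
})

test_that("sparsity-to-threshold conversion is the normal quantile", {
  expect_equal(sparsity_to_delta(0.5, mu = 2, sigma2 = 4), 2)
  expect_equal(sparsity_to_delta(0, mu = 1, sigma2 = 1), -Inf)
  # 0.9-quantile of the standard normal
  expect_equal(sparsity_to_delta(0.9, mu = 0, sigma2 = 1), 1.2815516, tolerance = 1e-6)
  expect_error(sparsity_to_delta(1, mu = 0, sigma2 = 1))
  expect_error(sparsity_to_delta(0.5, mu = 0, sigma2 = 0))
})

test_that("deterministic sparsity profile hits the target mean", {
  expect_identical(sparsity_profile(300, 0), rep(0, 300))
  for (target in c(0.1, 0.5, 0.7, 0.9)) {
    s <- sparsity_profile(300, target)
    expect_lt(abs(mean(s) - target), 1e-6)
    expect_true(all(diff(s) >= 0))
    expect_true(all(s < 1))
  }
  # p = 2: the uncapped form has no finite solution at target 0.5 because
  # s_p = 1 for every exponent; the cap makes the root solvable
  s2 <- sparsity_profile(2, 0.5)
  expect_lt(abs(mean(s2) - 0.5), 1e-6)
  expect_lte(max(s2), 0.99)
  expect_error(sparsity_profile(10, 1))
})

test_that("library sizes follow the (mean, size) NB parameterization", {
  x <- sample_library_sizes(1e5, mean = 1.5e6, size = 5, seed = 3)
  expect_lt(abs(mean(x) - 1.5e6) / 1.5e6, 0.01)
  # variance identity: mean + mean^2 / size
  y <- sample_library_sizes(2e5, mean = 10, size = 5, seed = 4)
  expect_lt(abs(var(y) - 30) / 30, 0.03)
  # Poisson limit as size -> Inf
  z <- sample_library_sizes(2e5, mean = 10, size = 1e9, seed = 5)
  expect_lt(abs(var(z) / mean(z) - 1), 0.03)
})

test_that("generated counts are compositional with exact row sums", {
  sim <- simulate_dataset(p = 25, n = 60, seed = 11)
  y <- sim$data
  expect_identical(unname(rowSums(y$counts)), as.numeric(y$library_sizes))
  expect_true(all(y$counts >= 0))
  expect_true(all(y$counts == round(y$counts)))
})

test_that("per-taxon zero frequency matches the structural-zero probability", {
  # equal means and huge library sizes make sampling zeros negligible, so the
  # observed zero rate per taxon is Binomial(n, s_j)
  p <- 10; n <- 4000
  s <- seq(0.05, 0.85, length.out = p)
  mu <- rep(3, p)
  delta <- sparsity_to_delta(s, mu, 1)
  y <- ziln_counts(diag(p), mu, delta, n = n,
                   library_sizes = rep(1e6, n), seed = 21)
  f <- colMeans(y$counts == 0)
  chi2 <- sum((f - s)^2 * n / (s * (1 - s)))
  expect_gt(stats::pchisq(chi2, df = p, lower.tail = FALSE), 0.001)
})

test_that("the count distribution is invariant to latent location shifts", {
  # adding a constant to mu multiplies all abundances by a constant, which
  # the multinomial normalization removes: same seed => identical counts
  p <- 8
  mu <- runif(p, 0, 3)
  delta <- rep(-Inf, p)
  a <- ziln_counts(diag(p), mu, delta, n = 30, library_sizes = rep(1e5, 30), seed = 7)
  b <- ziln_counts(diag(p), mu + 2, delta, n = 30, library_sizes = rep(1e5, 30), seed = 7)
  expect_identical(a$counts, b$counts)
})

test_that("log-proportions are approximately Gaussian when nothing is censored", {
  p <- 6; n <- 3000
  y <- ziln_counts(diag(p), rep(2, p), rep(-Inf, p), n = n,
                   library_sizes = rep(1e7, n), seed = 13)
  expect_true(all(y$counts > 0))
  lp <- log(y$counts / rowSums(y$counts))
  # normal QQ correlation per taxon close to 1
  qq_cor <- apply(lp, 2, function(x) {
    q <- qnorm(stats::ppoints(length(x)))
    cor(sort(x), q)
  })
  expect_true(all(qq_cor > 0.99))
  # symmetric two-taxon case: expected proportion 1/2
  y2 <- ziln_counts(diag(2), c(0, 0), c(-Inf, -Inf), n = 2000,
                    library_sizes = rep(1e6, 2000), seed = 14)
  pi1 <- mean(y2$counts[, 1] / rowSums(y2$counts))
  expect_lt(abs(pi1 - 0.5), 0.02)
})

test_that("an all-zero sample is resampled once then raises an error", {
  # thresholds far above the latent mean force all-zero abundances
  expect_error(
    ziln_counts(diag(3), rep(0, 3), rep(20, 3), n = 5,
                library_sizes = rep(1000, 5), seed = 1),
    "degenerate"
  )
})

test_that("NorTA marginals carry the requested zero mass and NB mean", {
  p <- 5; n <- 1e4
  y <- norta_counts(diag(p), mu = rep(3, p), s = rep(0.5, p), nu = 10,
                    n = n, seed = 31)
  zf <- colMeans(y$counts == 0)
  # total zero mass = s + (1 - s) * P(NB = 0); the latter is ~1.7e-5 here
  expect_true(all(abs(zf - 0.5) < 0.02))

  # with no zero inflation the marginal mean is exp(mu)
  y2 <- norta_counts(diag(p), mu = rep(2, p), s = rep(0, p), nu = 10,
                     n = n, seed = 32)
  expect_true(all(abs(colMeans(y2$counts) - exp(2)) / exp(2) < 0.05))
})

test_that("the NorTA copula preserves rank correlation", {
  sigma <- diag(4)
  sigma[1, 2] <- sigma[2, 1] <- 0.9
  y <- norta_counts(sigma, mu = rep(3, 4), s = rep(0, 4), nu = 10,
                    n = 2000, seed = 33)
  rho <- stats::cor(y$counts[, 1], y$counts[, 2], method = "spearman")
  expect_gt(rho, 0.8)
  rho_null <- stats::cor(y$counts[, 3], y$counts[, 4], method = "spearman")
  expect_lt(abs(rho_null), 0.1)
})
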