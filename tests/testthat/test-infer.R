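test_that("penalty grids are log-spaced and validated", {
  corr <- diag(3)
  corr[1, 2] <- corr[2, 1] <- 0.8
  expect_equal(lambda_grid(corr, n_lambda = 3, min_ratio = 0.01),
               c(0.8, 0.08, 0.008))
  g <- lambda_grid(corr, n_lambda = 50, min_ratio = 0.01)
  expect_length(g, 50)
  expect_true(all(diff(g) < 0))
  expect_error(lambda_grid(diag(4)), "nothing to infer")
})

test_that("glasso solutions satisfy the KKT optimality conditions", {
  Z <- latent_from_precision(diag(8) + 0.3 * (abs(row(diag(8)) - col(diag(8))) == 1),
                             n = 300, seed = 1)
  S <- cor(Z)
  for (lam in c(0.3, 0.1, 0.05)) {
    f <- zilnet:::glasso_cd(S, lam, S, matrix(0, 8, 8), 1e-6, 200)
    expect_true(f$converged)
    Th <- f$Theta; W <- f$W
    off <- upper.tri(S)
    nz <- off & abs(Th) > 1e-8
    zero <- off & abs(Th) <= 1e-8
    if (any(nz)) expect_lt(max(abs(W[nz] - S[nz] - lam * sign(Th[nz]))), 1e-6)
    if (any(zero)) expect_lte(max(abs(W[zero] - S[zero])), lam + 1e-8)
    expect_equal(diag(W), diag(S) + lam, tolerance = 1e-10)
    expect_lt(max(abs(W %*% Th - diag(8))), 1e-6)
  }
})

test_that("glasso path runs from the empty to the complete graph", {
  Z <- latent_from_precision(solve(matrix(c(1, .4, .2, .4, 1, .3, .2, .3, 1), 3)),
                             n = 1000, seed = 2)
  # above lambda_max: full shrinkage
  lmax <- max(abs(cor(Z)[upper.tri(diag(3))]))
  path <- glasso_path(Z, grid = c(lmax * 1.001, lmax * 0.5, lmax * 0.001))
  expect_equal(nrow(path$supports[[1]]), 0)
  # well-conditioned input, tiny penalty: complete support
  expect_equal(nrow(path$supports[[3]]), 3)
})

test_that("the true edge enters both solution paths before null edges", {
  theta <- diag(3)
  theta[1, 2] <- theta[2, 1] <- 0.45
  Z <- latent_from_precision(theta, n = 2000, seed = 3)
  for (builder in list(glasso_path, mb_path)) {
    path <- builder(Z)
    ranked <- rank_edges(path)
    expect_equal(ranked[1, c("a", "b")], data.frame(a = 1, b = 2),
                 ignore_attr = TRUE)
    expect_gt(ranked$first_entry_lambda[1],
              max(ranked$first_entry_lambda[-1], 0, na.rm = TRUE))
  }
})

test_that("mb and glasso agree on the earliest edge for strong single-edge truths", {
  hits <- vapply(1:10, function(seed) {
    theta <- diag(5)
    theta[2, 4] <- theta[4, 2] <- 0.5
    Z <- latent_from_precision(theta, n = 5000, seed = seed)
    g <- rank_edges(glasso_path(Z))
    m <- rank_edges(mb_path(Z))
    identical(unlist(g[1, c("a", "b")]), unlist(m[1, c("a", "b")])) &&
      all(unlist(g[1, c("a", "b")]) == c(2, 4))
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("independent columns yield empty supports at moderate penalties", {
  Z <- latent_from_precision(diag(5), n = 500, seed = 4)
  path <- mb_path(Z)
  # the grid starts at the largest absolute correlation: empty or near-empty
  expect_lte(nrow(path$supports[[1]]), 1)
  sizes <- vapply(path$supports, nrow, integer(1))
  # approximately monotone growth along the decreasing grid
  expect_gte(mean(diff(sizes) >= 0), 0.95)
})

test_that("mb supports are invariant to column scaling", {
  Z <- latent_from_precision(diag(4) + 0.25 * (1 - diag(4)), n = 200, seed = 5)
  grid <- lambda_grid(cor(Z))
  a <- mb_path(Z, grid)
  Zs <- Z
  Zs[, 2] <- Zs[, 2] * 7
  Zs[, 4] <- Zs[, 4] * 0.01
  b <- mb_path(Zs, grid)
  for (l in seq_along(grid)) {
    expect_identical(a$supports[[l]][, c("a", "b")], b$supports[[l]][, c("a", "b")])
  }
})

test_that("mb symmetrization rules nest: and-supports within or-supports", {
  sim <- simulate_dataset(p = 15, n = 80, seed = 6)
  Z <- posterior_mean(zclr(sim$data), fit_marginals(zclr(sim$data)))
  grid <- lambda_grid(cor(zilnet:::standardize_cols(Z)))
  or_path <- mb_path(Z, grid, symmetrization = "or")
  and_path <- mb_path(Z, grid, symmetrization = "and")
  for (l in seq_along(grid)) {
    or_keys <- paste(or_path$supports[[l]]$a, or_path$supports[[l]]$b)
    and_keys <- paste(and_path$supports[[l]]$a, and_path$supports[[l]]$b)
    expect_true(all(and_keys %in% or_keys))
  }
})

test_that("warm-started glasso path matches cold starts", {
  Z <- latent_from_precision(solve(matrix(c(1, .4, .2, .4, 1, .3, .2, .3, 1), 3)),
                             n = 400, seed = 7)
  S <- cor(Z)
  grid <- lambda_grid(S, n_lambda = 8)
  path <- glasso_path(Z, grid)
  for (l in seq_along(grid)) {
    cold <- zilnet:::glasso_cd(S, grid[l], S, matrix(0, 3, 3), 1e-4, 100)
    sel <- which(upper.tri(cold$Theta) & abs(cold$Theta) > 1e-8, arr.ind = TRUE)
    expect_identical(path$supports[[l]][, c("a", "b")],
                     data.frame(a = sel[, 1], b = sel[, 2]),
                     info = paste("lambda index", l))
  }
})

test_that("edge ranking follows first-entry penalty with deterministic ties", {
  sup1 <- data.frame(a = 1, b = 3, weight = 0.9)
  sup2 <- data.frame(a = c(1, 2), b = c(3, 4), weight = c(0.8, 0.4))
  path <- manual_path(c(0.5, 0.05), list(sup1, sup2), p = 4)
  ranked <- rank_edges(path)
  expect_equal(unlist(ranked[1, c("a", "b")]), c(a = 1, b = 3))
  expect_equal(ranked$first_entry_lambda[1], 0.5)
  expect_equal(unlist(ranked[2, c("a", "b")]), c(a = 2, b = 4))
  # never-selected pairs close the list with score 0, in index order
  tail_pairs <- ranked[-(1:2), ]
  expect_true(all(is.na(tail_pairs$first_entry_lambda)))
  expect_true(all(tail_pairs$score == 0))
  expect_identical(order(tail_pairs$a * 10 + tail_pairs$b), seq_len(nrow(tail_pairs)))

  # empty path: every pair scores 0
  empty <- manual_path(c(0.5, 0.05),
                       list(sup1[0, ], sup1[0, ]), p = 4)
  r0 <- rank_edges(empty)
  expect_true(all(r0$score == 0))
  expect_equal(nrow(r0), 6)

  # ties on (lambda, score) resolve by index, stably across calls
  tie <- manual_path(0.3, list(data.frame(a = c(2, 1), b = c(3, 4),
                                          weight = c(0.5, 0.5))), p = 4)
  r1 <- rank_edges(tie)
  r2 <- rank_edges(tie)
  expect_identical(r1, r2)
  expect_equal(unlist(r1[1, c("a", "b")]), c(a = 1, b = 4))
})

test_that("an edge keeps its first-entry penalty even if it later drops out", {
  sup1 <- data.frame(a = 1, b = 2, weight = 0.7)
  sup2 <- data.frame(a = 3, b = 4, weight = 0.2) # (1,2) vanished
  path <- manual_path(c(0.4, 0.1), list(sup1, sup2), p = 4)
  ranked <- rank_edges(path)
  expect_equal(ranked$first_entry_lambda[ranked$a == 1 & ranked$b == 2], 0.4)
  expect_equal(ranked$rank[ranked$a == 1 & ranked$b == 2], 1)
})

test_that("full fits on zero-free data coincide across transform modes", {
  y <- matrix(rpois(80 * 6, 50) + 1, 80, 6)
  a <- ziln(y, method = "mb", transform = "ziln")
  b <- ziln(y, method = "mb", transform = "none")
  expect_identical(a$edges[, c("a", "b", "rank")], b$edges[, c("a", "b", "rank")])
})

test_that("two-taxon fits degenerate gracefully", {
  y <- matrix(rpois(120, 40), 60, 2)
  fit <- ziln(y, method = "mb", transform = "none")
  expect_equal(nrow(fit$edges), 1)
  expect_lte(max(vapply(fit$path$supports, nrow, integer(1))), 1)
})

test_that("all-zero taxa are excluded from inference and ranked last", {
  set.seed(8)
  y <- matrix(rpois(60 * 5, 30), 60, 5)
  y[, 3] <- 0
  expect_warning(fit <- ziln(y, method = "mb"), "all-zero")
  expect_equal(fit$p, 5)
  expect_equal(nrow(fit$edges), 10)
  involving3 <- fit$edges$a == 3 | fit$edges$b == 3
  expect_true(all(fit$edges$score[involving3] == 0))
  expect_true(all(is.na(fit$edges$first_entry_lambda[involving3])))
})
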