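# Shared fixture builders. Everything is generated in code under fixed seeds.

# A zero-inflated normal column: z ~ N(mu, sigma2) censored below delta.
# Returns a one-column ziln_transform-like object built through the package
# constructor, plus the raw latent draws.
zin_column <- function(n, mu, sigma2, delta, seed) {
  z <- zilnet:::with_seed(seed, rnorm(n, mu, sqrt(sigma2)))
  mask <- z <= delta
  vals <- ifelse(mask, 0, z)
  tr <- zilnet:::new_ziln_transform(matrix(vals, ncol = 1),
                                    matrix(mask, ncol = 1), method = "zclr")
  list(transform = tr, z = z, mask = mask)
}

# Latent Gaussian draws from a hand-built precision matrix.
latent_from_precision <- function(theta, n, seed) {
  zilnet:::with_seed(seed, MASS::mvrnorm(n, rep(0, nrow(theta)), solve(theta)))
}

# Random count rows with zeros for transform property tests (real-valued
# "abundances" are allowed: the transforms are maps on non-negative vectors).
random_count_rows <- function(n, p, zero_prob = 0.3, seed = 1) {
  zilnet:::with_seed(seed, {
    y <- matrix(runif(n * p, 0.5, 100), n, p)
    y[matrix(runif(n * p) < zero_prob, n, p)] <- 0
    # guarantee at least one nonzero per row
    fix <- rowSums(y > 0) == 0
    y[fix, 1] <- 1
    y
  })
}

# Build a ziln_path directly (for rank_edges unit tests).
manual_path <- function(lambdas, supports, p, method = "mb") {
  zilnet:::new_ziln_path(lambdas, supports, method = method, p = p)
}

# Build a ranking data.frame that places the given pairs first, in order,
# with strictly decreasing scores, followed by all remaining pairs as the
# never-selected block.
ranking_with_top <- function(top_pairs, p) {
  all_pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  key <- paste(all_pairs[, 1], all_pairs[, 2])
  top_key <- paste(top_pairs[, 1], top_pairs[, 2])
  rest <- all_pairs[!(key %in% top_key), , drop = FALSE]
  k <- nrow(top_pairs)
  data.frame(
    a = c(top_pairs[, 1], rest[, 1]),
    b = c(top_pairs[, 2], rest[, 2]),
    rank = seq_len(nrow(all_pairs)),
    first_entry_lambda = c(seq(1, 0.5, length.out = k), rep(NA, nrow(rest))),
    score = c(seq(k, 1), rep(0, nrow(rest)))
  )
}

expect_symmetric01 <- function(adj) {
  expect_true(all(adj %in% c(0, 1)))
  expect_identical(unname(adj), unname(t(adj)))
  expect_true(all(diag(adj) == 0))
}
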