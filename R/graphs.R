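#' Generate a ground-truth association graph
#'
#' Draws an undirected graph on `p` nodes with exactly `e` edges under one of
#' three topologies commonly used to benchmark microbial network inference:
#'
#' * `"erdos_renyi"`: `e` edges sampled uniformly without replacement from
#'   the `p(p-1)/2` node pairs.
#' * `"band"`: each node is linked to its `b` nearest index-neighbors, where
#'   `b` is the smallest bandwidth giving at least `e` edges; the band is then
#'   trimmed (outermost diagonal first, largest indices first) to exactly `e`.
#' * `"scale_free"`: Barabasi-Albert preferential attachment with one edge
#'   per arriving node (`p - 1` edges), topped up with uniformly random
#'   non-edges to reach `e`. For `e = p` this adds a single random edge,
#'   an approximation that keeps the heavy-tailed degree distribution.
#'
#' In the simulation studies the number of edges equals the number of taxa
#' (`e = p`), encoding the sparsity assumption that associations scale
#' linearly with the number of taxa.
#'
#' @param topology `"band"`, `"erdos_renyi"` or `"scale_free"`.
#' @param p number of nodes (taxa); at least 3.
#' @param e number of edges; at least 1 and at most `p(p-1)/2`.
#' @param seed integer seed.
#' @return an object of class `ziln_graph`: list with `adjacency` (p x p
#'   symmetric 0/1 matrix, zero diagonal), `topology`, `edge_count`.
#' @export
#' @examples
#' g <- make_graph("erdos_renyi", p = 20, e = 20, seed = 1)
#' g$edge_count
make_graph <- function(topology = c("band", "erdos_renyi", "scale_free"),
                       p, e, seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(p >= 3, e >= 1)
  max_e <- p * (p - 1) / 2
  if (e > max_e) stop("too many edges: e = ", e, " > p(p-1)/2 = ", max_e)

  adj <- with_seed(seed, switch(topology,
    erdos_renyi = {
      g <- igraph::sample_gnm(p, e, directed = FALSE)
      as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    },
    band = band_adjacency(p, e),
    scale_free = {
      g <- igraph::sample_pa(p, power = 1, m = 1, directed = FALSE)
      adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
      adj[adj > 1] <- 1
      extra <- e - sum(adj) / 2
      if (extra < 0) stop("scale-free attachment produced more than e edges")
      if (extra > 0) {
        free <- which(upper.tri(adj) & adj == 0)
        add <- sample(free, extra)
        adj[add] <- 1
        adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
      }
      adj
    }
  ))

  dimnames(adj) <- NULL
  structure(
    list(adjacency = adj, topology = topology, edge_count = sum(adj) / 2,
         p = p, seed = as.integer(seed)),
    class = "ziln_graph"
  )
}

band_adjacency <- function(p, e) {
  # smallest bandwidth b with sum_{k=1..b} (p - k) >= e
  b <- 1L
  while (sum(p - seq_len(b)) < e) b <- b + 1L
  adj <- matrix(0L, p, p)
  for (k in seq_len(b)) {
    idx <- seq_len(p - k)
    adj[cbind(idx, idx + k)] <- 1L
  }
  excess <- sum(adj) - e
  if (excess > 0) {
    # trim from the outermost diagonal, largest start index first
    drop_idx <- rev(seq_len(p - b))[seq_len(excess)]
    adj[cbind(drop_idx, drop_idx + b)] <- 0L
  }
  adj + t(adj)
}

#' Build a precision/covariance pair with controlled condition number
#'
#' Assigns each edge of a ground-truth graph a signed off-diagonal precision
#' weight (magnitude uniform on `[0.3, 0.7]`, random sign, symmetric), then
#' shifts the diagonal by the unique constant `c` solving
#' `(lambda_max + c) / (lambda_min + c) = kappa`, so the returned precision
#' matrix has condition number exactly `kappa`. The covariance is its inverse.
#' The matrix is not rescaled to correlation afterwards: rescaling would
#' change the condition number, which is the controlled quantity.
#'
#' @param graph a [make_graph()] result.
#' @param kappa target condition number (ratio of extreme eigenvalues), > 1.
#' @param seed integer seed for the edge weights.
#' @return object of class `ziln_covpair`: list with `precision`,
#'   `covariance`, `condition_number`.
#' @export
#' @examples
#' g <- make_graph("band", p = 10, e = 9, seed = 1)
#' cp <- graph_to_precision(g, kappa = 100, seed = 2)
#' cp$condition_number
graph_to_precision <- function(graph, kappa = 100, seed = 1L) {
  stopifnot(inherits(graph, "ziln_graph"))
  if (kappa <= 1) stop("kappa must be > 1")
  adj <- graph$adjacency
  p <- nrow(adj)

  if (graph$edge_count == 0) {
    warning("graph has no edges; returning identity precision (condition number 1)")
    return(structure(
      list(precision = diag(p), covariance = diag(p), condition_number = 1),
      class = "ziln_covpair"
    ))
  }

  omega <- with_seed(seed, {
    ut <- which(upper.tri(adj) & adj == 1)
    w <- runif(length(ut), 0.3, 0.7) * sample(c(-1, 1), length(ut), replace = TRUE)
    m <- matrix(0, p, p)
    m[ut] <- w
    m + t(m)
  })

  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(ev)
  lmin <- min(ev)
  # (lmax + c) / (lmin + c) = kappa  =>  c = (lmax - kappa * lmin) / (kappa - 1)
  c_shift <- (lmax - kappa * lmin) / (kappa - 1)
  prec <- omega + diag(c_shift, p)
  ev2 <- eigen(prec, symmetric = TRUE, only.values = TRUE)$values

  structure(
    list(precision = prec, covariance = solve(prec),
         condition_number = max(ev2) / min(ev2)),
    class = "ziln_covpair"
  )
}

#' @export
print.ziln_graph <- function(x, ...) {
  cat("Ground-truth graph:", x$topology, "topology,",
      x$p, "nodes,", x$edge_count, "edges\n")
  invisible(x)
}

#' @export
print.ziln_covpair <- function(x, ...) {
  cat("Precision/covariance pair: p =", nrow(x$precision),
      ", condition number =", format(x$condition_number), "\n")
  invisible(x)
}

#' Extract the edge list of a ground-truth graph
#'
#' @param graph a [make_graph()] result.
#' @return two-column integer matrix of node pairs (a < b), one row per edge.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "ziln_graph"))
  idx <- which(upper.tri(graph$adjacency) & graph$adjacency == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("a", "b")
  idx
}
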