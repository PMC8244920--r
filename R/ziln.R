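#' Fit a sparse microbial association network to a count table
#'
#' One-call interface running the full pipeline on a samples x taxa count
#' matrix:
#' \enumerate{
#'   \item zero-preserving centered log-ratio transform ([zclr()]);
#'   \item (ziln mode) per-taxon zero-inflated normal marginal fits
#'     ([fit_marginals()]) and truncated-normal posterior-mean reconstruction
#'     of the latent Gaussian layer ([posterior_mean()]);
#'   \item sparse precision-structure estimation along a decreasing penalty
#'     grid by graphical lasso or neighborhood selection;
#'   \item ranking of all candidate edges by solution-path entry point
#'     ([rank_edges()]).
#' }
#' `transform = "none"` skips step 2 and runs the estimators on the
#' transformed values directly — the "no transformation" baseline. On data
#' without zeros the two modes coincide (the posterior mean is the identity).
#'
#' @param counts a `ziln_counts` object or non-negative count matrix
#'   (rows = samples, columns = taxa).
#' @param method `"mb"` (neighborhood selection, default) or `"glasso"`.
#' @param transform `"ziln"` (posterior-mean latent reconstruction, default)
#'   or `"none"`.
#' @param nlambda,lambda_min_ratio penalty grid, see [lambda_grid()].
#' @param symmetrization MB symmetrization rule, see [mb_path()].
#' @return object of class `ziln`: list with `marginals`
#'   (`ziln_marginal_fit` or `NULL`), `latent` (n x p matrix), `path`
#'   (`ziln_path`), `edges` (ranked edge data.frame with taxon names),
#'   `method`, `transform`, `taxa`, `n`, `p`, `call`.
#' @export
#' @examples
#' sim <- simulate_dataset(p = 15, n = 100, seed = 1)
#' fit <- ziln(sim$data, method = "mb")
#' print(fit)
#' head(fit$edges)
ziln <- function(counts, method = c("mb", "glasso"),
                 transform = c("ziln", "none"),
                 nlambda = 50, lambda_min_ratio = 0.01,
                 symmetrization = c("or", "and")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  symmetrization <- match.arg(symmetrization)

  y <- count_values(counts)
  p_all <- ncol(y)
  taxa <- colnames(y)
  if (is.null(taxa)) taxa <- paste0("taxon", seq_len(p_all))

  # taxa never observed carry no signal: exclude from inference, rank their
  # pairs last (score 0) so the candidate universe still covers all pairs
  keep <- colSums(y > 0) > 0
  if (!any(keep)) stop("all taxa are entirely zero")
  if (!all(keep)) {
    warning(sum(!keep), " all-zero taxa excluded from inference and ranked last")
    y <- y[, keep, drop = FALSE]
  }

  tr <- zclr(y)
  if (transform == "ziln") {
    marginals <- fit_marginals(tr)
    latent <- posterior_mean(tr, marginals)
  } else {
    marginals <- NULL
    latent <- tr$values
  }

  grid <- lambda_grid(cor(latent), n_lambda = nlambda, min_ratio = lambda_min_ratio)
  path <- if (method == "glasso") {
    glasso_path(latent, grid)
  } else {
    mb_path(latent, grid, symmetrization = symmetrization)
  }
  edges <- rank_edges(path, p = ncol(y))
  if (!all(keep)) {
    idx <- which(keep)
    edges$a <- idx[edges$a]
    edges$b <- idx[edges$b]
    dropped_pairs <- which(
      upper.tri(matrix(0, p_all, p_all)) &
        (outer(!keep, rep(TRUE, p_all), "&") | outer(rep(TRUE, p_all), !keep, "&")),
      arr.ind = TRUE
    )
    extra <- data.frame(a = dropped_pairs[, 1], b = dropped_pairs[, 2],
                        rank = NA_integer_, first_entry_lambda = NA_real_,
                        score = 0)
    extra <- extra[order(extra$a, extra$b), ]
    edges <- rbind(edges, extra)
    edges$rank <- seq_len(nrow(edges))
  }
  edges$taxon_a <- taxa[edges$a]
  edges$taxon_b <- taxa[edges$b]

  structure(
    list(marginals = marginals, latent = latent, path = path, edges = edges,
         method = method, transform = transform, taxa = taxa, kept = keep,
         n = nrow(y), p = p_all, call = match.call()),
    class = "ziln"
  )
}

#' @export
print.ziln <- function(x, ...) {
  cat("Zero-inflated log-normal association network fit\n")
  cat(sprintf("  %d samples, %d taxa; estimator: %s; transform: %s\n",
              x$n, x$p, x$method, x$transform))
  n_sel <- sum(!is.na(x$edges$first_entry_lambda))
  cat(sprintf("  %d of %d candidate pairs enter the solution path (%d penalties)\n",
              n_sel, nrow(x$edges), length(x$path$lambdas)))
  invisible(x)
}

#' @export
summary.ziln <- function(object, top = 10, ...) {
  sizes <- vapply(object$path$supports, nrow, integer(1))
  structure(
    list(fit = object, support_sizes = sizes,
         top_edges = utils::head(object$edges, top),
         n_nonconverged = if (is.null(object$marginals)) 0L
                          else sum(!object$marginals$converged)),
    class = "summary.ziln"
  )
}

#' @export
print.summary.ziln <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$marginals)) {
    cat(sprintf("  marginal fits: %d taxa, %d non-converged\n",
                x$fit$p, x$n_nonconverged))
  }
  cat(sprintf("  support size along the path: %d .. %d edges\n",
              min(x$support_sizes), max(x$support_sizes)))
  cat("  most reliable edges:\n")
  print(x$top_edges[, c("taxon_a", "taxon_b", "rank", "first_entry_lambda", "score")],
        row.names = FALSE)
  invisible(x)
}

#' Plot a fitted solution path
#'
#' Support size (number of selected edges) against the penalty, on a log-x
#' scale. The curve is the sparsity trajectory from the empty graph (large
#' penalty) toward dense solutions.
#'
#' @param x a `ziln` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ziln <- function(x, ...) {
  sizes <- vapply(x$path$supports, nrow, integer(1))
  graphics::plot(x$path$lambdas, sizes, log = "x", type = "b", pch = 16,
                 xlab = expression(lambda), ylab = "selected edges",
                 main = sprintf("%s solution path", x$path$method), ...)
  invisible(x)
}

#' Top-ranked edges of a fit
#'
#' @param fit a `ziln` fit.
#' @param k number of edges.
#' @return the first `k` rows of the ranked edge table.
#' @export
top_edges <- function(fit, k = 50) {
  stopifnot(inherits(fit, "ziln"))
  utils::head(fit$edges, k)
}
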