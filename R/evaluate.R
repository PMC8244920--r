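#' Precision-recall and ROC metrics for a ranked edge list
#'
#' Scores an edge ranking against a ground-truth graph over all `p(p-1)/2`
#' candidate pairs. Pairs with identical `(first_entry_lambda, score)` form a
#' tie block: the precision-recall and ROC curves are evaluated at block
#' boundaries only, so the metrics do not depend on the arbitrary order
#' inside a block. Pairs never entering the path form the terminal block,
#' which lets recall reach 1. AUPR and AUROC are trapezoidal areas over
#' recall and false-positive rate respectively; AUPR is the headline metric
#' (edges are rare among pairs, so PR is more informative than ROC).
#' Precision-at-k uses the total (tie-broken) order.
#'
#' @param ranked a ranked edge data.frame from [rank_edges()] (or a `ziln`
#'   fit's `$edges`).
#' @param truth a `ziln_graph`, or a p x p 0/1 adjacency matrix.
#' @param k vector of prefix sizes for precision-at-k (default 50).
#' @return object of class `ziln_metrics`: list with `aupr`, `auroc`,
#'   `precision_at_k` (named numeric), `n_true_edges`, `n_candidate_pairs`.
#' @export
pr_metrics <- function(ranked, truth, k = 50) {
  adj <- if (inherits(truth, "ziln_graph")) truth$adjacency else as.matrix(truth)
  p <- nrow(adj)
  e <- sum(adj) / 2
  if (e == 0) stop("ground truth has zero edges")
  if (inherits(ranked, "ziln")) ranked <- ranked$edges
  stopifnot(all(c("a", "b", "rank", "score") %in% names(ranked)))
  n_pairs <- p * (p - 1) / 2
  if (nrow(ranked) != n_pairs) {
    stop("ranking must cover all ", n_pairs, " candidate pairs of the truth")
  }

  ranked <- ranked[order(ranked$rank), ]
  labels <- adj[cbind(ranked$a, ranked$b)]

  # tie blocks: identical (first_entry_lambda, score); NA lambda = terminal block
  lam <- ifelse(is.na(ranked$first_entry_lambda), -Inf, ranked$first_entry_lambda)
  block <- cumsum(!duplicated(data.frame(lam, ranked$score)))
  tp <- cumsum(labels)
  fp <- cumsum(!labels)
  ends <- which(!duplicated(block, fromLast = TRUE))

  recall <- tp[ends] / e
  precision <- tp[ends] / (tp[ends] + fp[ends])
  fpr <- fp[ends] / (n_pairs - e)

  aupr <- trapezoid(c(0, recall), c(precision[1], precision))
  auroc <- trapezoid(c(0, fpr, 1), c(0, recall, 1))

  pk <- vapply(k, function(kk) {
    if (kk > n_pairs) stop("k exceeds the number of ranked pairs")
    mean(labels[seq_len(kk)])
  }, numeric(1))
  names(pk) <- paste0("k", k)

  structure(
    list(aupr = aupr, auroc = auroc, precision_at_k = pk,
         n_true_edges = e, n_candidate_pairs = n_pairs),
    class = "ziln_metrics"
  )
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' @export
print.ziln_metrics <- function(x, ...) {
  cat(sprintf("AUPR = %.4f, AUROC = %.4f (%d true edges / %d pairs)\n",
              x$aupr, x$auroc, x$n_true_edges, x$n_candidate_pairs))
  for (nm in names(x$precision_at_k)) {
    cat(sprintf("  precision@%s = %.4f\n", sub("^k", "", nm), x$precision_at_k[[nm]]))
  }
  invisible(x)
}

#' Per-taxon Kolmogorov-Smirnov distance between two count matrices
#'
#' For each taxon present in both matrices, the two-sample KS statistic (the
#' largest absolute difference between the empirical cdfs of the taxon's
#' counts). The distribution of the per-feature statistics summarizes how
#' well one generator reproduces the marginals of the other dataset; two
#' draws from the same generative configuration give statistics near 0.
#'
#' @param counts_a,counts_b `ziln_counts` objects or count matrices with
#'   taxon column names.
#' @return named numeric vector of KS statistics over the shared taxa; taxa
#'   missing from one matrix are skipped with a warning.
#' @export
ks_feature_distance <- function(counts_a, counts_b) {
  ya <- count_values(counts_a)
  yb <- count_values(counts_b)
  ta <- colnames(ya); tb <- colnames(yb)
  if (is.null(ta)) ta <- colnames(ya) <- paste0("taxon", seq_len(ncol(ya)))
  if (is.null(tb)) tb <- colnames(yb) <- paste0("taxon", seq_len(ncol(yb)))
  shared <- intersect(ta, tb)
  missing <- union(setdiff(ta, tb), setdiff(tb, ta))
  if (length(missing)) {
    warning("skipping ", length(missing), " taxa absent from one matrix")
  }
  if (!length(shared)) stop("no shared taxa")
  vapply(shared, function(tx) {
    unname(suppressWarnings(ks.test(ya[, tx], yb[, tx])$statistic))
  }, numeric(1))
}

#' Categorical (Newman) assortativity of a labeled graph
#'
#' Measures homophily: the tendency of edges to join nodes carrying the same
#' categorical label (e.g. phylum). With `e_lm` the fraction of edge ends
#' joining labels l and m (each undirected edge counted in both directions)
#' and `a_l` the marginal fractions, the coefficient is
#' `(sum_l e_ll - sum_l a_l^2) / (1 - sum_l a_l^2)`: 1 for purely
#' within-group edges, negative for disassortative mixing (-1 for a perfect
#' bipartition between two equally-represented labels).
#'
#' @param edges two-column matrix/data.frame of node indices or names, one
#'   row per undirected edge.
#' @param node_labels vector of labels, indexed by node index, or named by
#'   node name.
#' @return assortativity coefficient in `[-1, 1]`.
#' @export
assortativity_cat <- function(edges, node_labels) {
  edges <- as.matrix(edges)
  if (nrow(edges) < 1) stop("need at least one edge")
  la <- label_of(edges[, 1], node_labels)
  lb <- label_of(edges[, 2], node_labels)
  cats <- sort(unique(c(la, lb)))
  if (length(cats) < 2) stop("assortativity undefined: all endpoints share one label")
  m <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (i in seq_along(la)) {
    m[la[i], lb[i]] <- m[la[i], lb[i]] + 1
    m[lb[i], la[i]] <- m[lb[i], la[i]] + 1
  }
  emix <- m / sum(m)
  ai <- rowSums(emix)
  bi <- colSums(emix)
  denom <- 1 - sum(ai * bi)
  if (denom == 0) stop("assortativity undefined: degenerate mixing matrix")
  (sum(diag(emix)) - sum(ai * bi)) / denom
}

label_of <- function(nodes, node_labels) {
  lab <- if (!is.null(names(node_labels))) {
    node_labels[as.character(nodes)]
  } else {
    node_labels[as.integer(nodes)]
  }
  if (any(is.na(lab))) stop("missing label for some edge endpoints")
  as.character(lab)
}

#' Overlap structure of several ranked edge sets
#'
#' Truncates each named edge set to its `top_k` highest-ranked edges and
#' counts, for every intersection region (each non-empty subset of the set
#' names), the edges belonging to exactly those sets — the counts behind a
#' Venn diagram. Also reports, per set, the number of unanimous edges (in
#' every set) and idiosyncratic edges (in that set only) and their ratio.
#'
#' @param edge_sets named list; each element a data.frame/matrix whose first
#'   two columns are node ids, ordered by decreasing reliability (e.g.
#'   [rank_edges()] output).
#' @param top_k edges retained per set; sets with fewer edges are used whole
#'   with a warning.
#' @return list with `regions` (named integer vector; names like `"A&B"`),
#'   and `per_set` (data.frame of unanimous / idiosyncratic counts and ratio).
#' @export
edge_overlap <- function(edge_sets, top_k = 1200) {
  stopifnot(is.list(edge_sets), length(edge_sets) >= 2, !is.null(names(edge_sets)))
  keysets <- lapply(names(edge_sets), function(nm) {
    es <- as.matrix(edge_sets[[nm]])
    if (nrow(es) < top_k) {
      warning(sprintf("set '%s' has %d < top_k = %d edges; using all", nm, nrow(es), top_k))
    }
    es <- es[seq_len(min(top_k, nrow(es))), , drop = FALSE]
    unique(paste(pmin(es[, 1], es[, 2]), pmax(es[, 1], es[, 2]), sep = "|"))
  })
  names(keysets) <- names(edge_sets)

  all_edges <- unique(unlist(keysets))
  member <- vapply(keysets, function(ks) all_edges %in% ks, logical(length(all_edges)))
  if (length(all_edges) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, names(keysets)))
  sig <- apply(member, 1, function(row) paste(names(keysets)[row], collapse = "&"))
  regions <- table(sig)
  regions <- stats::setNames(as.integer(regions), names(regions))

  unanimous <- sum(rowSums(member) == ncol(member))
  per_set <- data.frame(
    set = names(keysets),
    n_edges = vapply(keysets, length, integer(1)),
    unanimous = unanimous,
    idiosyncratic = vapply(seq_along(keysets), function(j) {
      sum(member[, j] & rowSums(member) == 1)
    }, integer(1)),
    row.names = NULL
  )
  per_set$ratio <- unanimous / pmax(per_set$idiosyncratic, 1)
  list(regions = regions, per_set = per_set)
}
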