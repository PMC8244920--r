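#' Read a count table from TSV
#'
#' Expected layout: tab-separated, header row of taxon ids, first column of
#' sample ids (samples in rows). Cells must be non-negative integers; the
#' first offending cell is named in the error.
#'
#' @param path file path.
#' @param transpose set `TRUE` for taxa-in-rows dialects.
#' @return a `ziln_counts` object (library sizes = row sums).
#' @export
read_counts <- function(path, transpose = FALSE) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  y <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(y)) stop("non-numeric cells in count table")
  bad <- which(y < 0 | y != round(y), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid count %s at row '%s', column '%s': counts must be non-negative integers",
                 format(y[bad[1, , drop = FALSE]]), ids[bad[1, 1]], colnames(y)[bad[1, 2]]))
  }
  storage.mode(y) <- "double"
  if (transpose) {
    taxa <- ids
    samples <- colnames(y)
    y <- t(y)
    new_ziln_counts(y, sample_ids = samples, taxon_ids = taxa)
  } else {
    new_ziln_counts(y, sample_ids = ids, taxon_ids = colnames(y))
  }
}

#' Write a count table to TSV
#'
#' Inverse of [read_counts()]: header row of taxon ids, first column
#' (`sample_id`) of sample ids.
#'
#' @param counts a `ziln_counts` object or count matrix.
#' @param path output file path.
#' @export
write_counts <- function(counts, path) {
  y <- count_values(counts)
  ids <- if (inherits(counts, "ziln_counts")) counts$sample_ids else rownames(y)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(y)))
  df <- data.frame(sample_id = ids, y, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ground-truth graph
#'
#' GraphML via igraph, or a two-column TSV edge list.
#'
#' @param graph a `ziln_graph`.
#' @param path output file path.
#' @param format `"graphml"` or `"tsv"`.
#' @export
write_graph_truth <- function(graph, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "ziln_graph"))
  if (format == "graphml") {
    g <- igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected")
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write.table(graph_edges(graph), path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = c("a", "b"))
  }
  invisible(path)
}

#' Write a ranked edge table to TSV
#'
#' Columns: `taxon_a`, `taxon_b`, `rank`, `first_entry_lambda`, `score`.
#'
#' @param edges ranked edge data.frame (a `ziln` fit's `$edges`, or
#'   [rank_edges()] output).
#' @param path output file path.
#' @export
write_edges <- function(edges, path) {
  if (inherits(edges, "ziln")) edges <- edges$edges
  cols <- intersect(c("taxon_a", "taxon_b", "a", "b", "rank",
                      "first_entry_lambda", "score"), names(edges))
  write.table(edges[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
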