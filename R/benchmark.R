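#' Replay a network-recovery simulation study
#'
#' Runs the full generate-infer-score loop over a grid of conditions: for
#' each (topology, p, n, zero target, replicate) cell a ground-truth graph
#' with `e = p` edges and a condition-number-100 precision are drawn, counts
#' are generated (zero-inflated log-normal by default, or the NorTA
#' zero-inflated negative binomial comparator), each requested method is fit,
#' and the ranked edges are scored against the truth (AUPR, AUROC,
#' precision@50). Methods are named `"<transform>-<estimator>"`:
#' `ziln-mb`, `ziln-glasso`, `none-mb`, `none-glasso`.
#'
#' Every cell derives its own child seed from `seed` via [split_seed()], so
#' the whole table is reproducible from one integer and a cell failure never
#' shifts another cell's stream. Failures are recorded in the `error` column
#' and the run continues.
#'
#' @param topologies character vector of [make_graph()] topologies.
#' @param p_list,n_list taxa and sample counts to sweep.
#' @param zero_targets `NA` for the uniform per-taxon sparsity protocol
#'   (`s_j ~ unif(0, 0.9)`), or numeric global zero-fraction targets in
#'   `[0, 1)` for the deterministic profile ([sparsity_profile()]).
#' @param replicates replicate datasets per cell.
#' @param methods subset of `ziln-mb`, `ziln-glasso`, `none-mb`, `none-glasso`.
#' @param generator `"ziln"` or `"norta"`.
#' @param kappa precision condition number.
#' @param nlambda penalty grid length.
#' @param seed master seed.
#' @return object of class `ziln_benchmark`: list with `results` (one row per
#'   cell x method) and `summary` (median and quartiles of each metric over
#'   replicates).
#' @export
#' @examples
#' \donttest{
#' bm <- run_benchmark(p_list = 30, n_list = 100, replicates = 2, seed = 1)
#' bm$summary
#' }
run_benchmark <- function(topologies = "erdos_renyi",
                          p_list = 100, n_list = 300,
                          zero_targets = NA, replicates = 10,
                          methods = c("ziln-mb", "none-mb"),
                          generator = c("ziln", "norta"),
                          kappa = 100, nlambda = 50, seed = 1L) {
  generator <- match.arg(generator)
  stopifnot(replicates >= 1, length(topologies) >= 1, length(p_list) >= 1,
            length(n_list) >= 1, length(zero_targets) >= 1, length(methods) >= 1)
  known <- c("ziln-mb", "ziln-glasso", "none-mb", "none-glasso")
  if (!all(methods %in% known)) stop("unknown method(s): ",
                                     paste(setdiff(methods, known), collapse = ", "))

  cells <- expand.grid(topology = topologies, p = p_list, n = n_list,
                       zeros = zero_targets, replicate = seq_len(replicates),
                       stringsAsFactors = FALSE)
  seeds <- split_seed(seed, nrow(cells))

  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    ds <- tryCatch(
      benchmark_dataset(cell$topology, cell$p, cell$n, cell$zeros,
                        generator, kappa, seeds[i]),
      error = function(e) e
    )
    for (m in methods) {
      row <- data.frame(cell, method = m, seed = seeds[i],
                        aupr = NA_real_, auroc = NA_real_, p_at_50 = NA_real_,
                        error = NA_character_, stringsAsFactors = FALSE)
      if (inherits(ds, "error")) {
        row$error <- conditionMessage(ds)
      } else {
        res <- tryCatch({
          parts <- strsplit(m, "-", fixed = TRUE)[[1]]
          fit <- ziln(ds$data, method = parts[2], transform = parts[1],
                      nlambda = nlambda)
          pr_metrics(fit$edges, ds$graph, k = 50)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          row$error <- conditionMessage(res)
        } else {
          row$aupr <- res$aupr
          row$auroc <- res$auroc
          row$p_at_50 <- res$precision_at_k[["k50"]]
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, summary = summarize_benchmark(results)),
            class = "ziln_benchmark")
}

benchmark_dataset <- function(topology, p, n, zeros, generator, kappa, seed) {
  seeds <- split_seed(seed, 5L)
  graph <- make_graph(topology, p = p, e = p, seed = seeds[1])
  covpair <- graph_to_precision(graph, kappa = kappa, seed = seeds[2])
  pars <- with_seed(seeds[3], {
    mu <- runif(p, 0, 3)
    s <- if (is.na(zeros)) runif(p, 0, 0.9) else sparsity_profile(p, zeros)
    list(mu = mu, s = s)
  })
  data <- if (generator == "ziln") {
    delta <- sparsity_to_delta(pars$s, pars$mu, diag(covpair$covariance))
    ziln_counts(covpair$covariance, pars$mu, delta, n = n, seed = seeds[4])
  } else {
    norta_counts(covpair$covariance, pars$mu, pars$s, nu = 10, n = n,
                 seed = seeds[4])
  }
  list(graph = graph, covpair = covpair, data = data)
}

summarize_benchmark <- function(results) {
  ok <- results[is.na(results$error), ]
  if (!nrow(ok)) return(data.frame())
  zeros_key <- ifelse(is.na(ok$zeros), "uniform", format(ok$zeros))
  groups <- split(ok, interaction(ok$topology, ok$p, ok$n, zeros_key,
                                  ok$method, drop = TRUE))
  out <- lapply(groups, function(g) {
    q <- function(x, probs) unname(stats::quantile(x, probs, na.rm = TRUE))
    data.frame(topology = g$topology[1], p = g$p[1], n = g$n[1],
               zeros = g$zeros[1], method = g$method[1],
               n_replicates = nrow(g),
               aupr_median = q(g$aupr, 0.5),
               aupr_q25 = q(g$aupr, 0.25), aupr_q75 = q(g$aupr, 0.75),
               auroc_median = q(g$auroc, 0.5),
               p_at_50_median = q(g$p_at_50, 0.5),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$topology, out$p, out$n, out$zeros, out$method), ]
}

#' @export
print.ziln_benchmark <- function(x, ...) {
  cat("Benchmark:", nrow(x$results), "method x cell runs;",
      sum(!is.na(x$results$error)), "failures\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write benchmark results
#'
#' The per-run table goes to `<stem>.tsv`, the aggregated summary to
#' `<stem>_summary.tsv`, and (when jsonlite is installed) both to
#' `<stem>.json`.
#'
#' @param bm a `ziln_benchmark`.
#' @param stem output path stem (no extension).
#' @export
write_benchmark <- function(bm, stem) {
  stopifnot(inherits(bm, "ziln_benchmark"))
  write.table(bm$results, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(bm$summary, paste0(stem, "_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(list(results = bm$results, summary = bm$summary),
                         paste0(stem, ".json"), dataframe = "rows", digits = NA)
  }
  invisible(stem)
}
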