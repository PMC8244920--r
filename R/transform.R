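#' Classical centered log-ratio transform (pseudocount baseline)
#'
#' The clr of a count row is `log(y_ij) - mean_k log(y_ik)`. It is
#' scale-invariant — multiplying a sample's counts by any constant leaves the
#' transform unchanged — which is essential for compositional sequencing
#' data. The clr is undefined at zero; the usual workaround of adding a fixed
#' pseudocount destroys scale invariance on rows containing zeros (the
#' pseudocount does not scale with the sample). This baseline is kept for
#' comparison; [zclr()] is the zero-preserving variant used by the pipeline.
#'
#' @param counts a `ziln_counts` object or a non-negative numeric matrix
#'   (rows = samples).
#' @param pseudocount value added to every cell before taking logs; must be
#'   positive if any cell is zero.
#' @return object of class `ziln_transform`: list with `values` (n x p),
#'   `zero_mask` (logical n x p marking original zeros), `method`.
#' @seealso [zclr()]
#' @export
#' @examples
#' clr(matrix(c(2, 8), 1), pseudocount = 0)$values # (-log 2, log 2)
clr <- function(counts, pseudocount = 1) {
  y <- count_values(counts)
  mask <- y == 0
  if (any(mask) && pseudocount <= 0) stop("clr undefined at zero: use a positive pseudocount")
  ly <- log(y + pseudocount)
  vals <- ly - rowMeans(ly)
  new_ziln_transform(vals, mask, method = "clr")
}

#' Zero-preserving centered log-ratio transform
#'
#' Nonzero entries are transformed to their log value minus the mean log over
#' the row's nonzero entries; zero entries stay exactly zero:
#' \deqn{\tilde y_{ij} = \log y_{ij} - \frac{1}{|k: y_{ik} \neq 0|}
#'   \sum_{k: y_{ik} \neq 0} \log y_{ik} \quad (y_{ij} \neq 0), \qquad
#'   \tilde y_{ij} = 0 \quad (y_{ij} = 0).}
#' Because the centering uses only nonzero entries, scale invariance holds
#' exactly even in the presence of zeros: `zclr(lambda * y) == zclr(y)` for
#' any `lambda > 0`. The zero mask, not the value, is authoritative for
#' "was zero": a count equal to the row's geometric mean also transforms
#' to 0.
#'
#' Real-valued (non-integer) inputs are accepted: the transform is a map on
#' positive vectors and its properties do not depend on integrality.
#'
#' @inheritParams clr
#' @return object of class `ziln_transform` (see [clr()]).
#' @export
#' @examples
#' zclr(matrix(c(2, 8, 0), 1))$values # (-log 2, log 2, 0)
zclr <- function(counts) {
  y <- count_values(counts)
  mask <- y == 0
  if (any(rowSums(!mask) == 0)) stop("empty sample: a row has no nonzero counts")
  ly <- y
  ly[!mask] <- log(y[!mask])
  ly[mask] <- 0
  nz_mean <- rowSums(ly) / rowSums(!mask)
  vals <- ly - nz_mean
  vals[mask] <- 0
  new_ziln_transform(vals, mask, method = "zclr")
}

new_ziln_transform <- function(values, zero_mask, method) {
  structure(
    list(values = values, zero_mask = zero_mask, method = method),
    class = "ziln_transform"
  )
}

#' @export
print.ziln_transform <- function(x, ...) {
  cat(sprintf("%s transform: %d samples x %d taxa; %.1f%% masked zeros\n",
              x$method, nrow(x$values), ncol(x$values), 100 * mean(x$zero_mask)))
  invisible(x)
}

count_values <- function(counts) {
  y <- if (inherits(counts, "ziln_counts")) counts$counts else as.matrix(counts)
  if (any(y < 0)) stop("counts must be non-negative")
  y
}
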