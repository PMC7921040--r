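# Replicate reproducibility via Spearman rank correlation of heatmap cells.

#' Spearman rank correlation with mid-rank ties
#'
#' The coefficient is the Pearson correlation of mid-ranks (average ranks on
#' ties).  The default p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom,
#' two-sided; `rho = +/-1` reports the smallest representable double.  A
#' seeded permutation p-value is available for small n.  Pairs with a
#' missing value in either vector are dropped and counted.
#'
#' @param a,b Numeric vectors of equal length.
#' @param p_method `"t"` (default) or `"permutation"`.
#' @param n_perm Number of permutations for `p_method = "permutation"`.
#' @param seed Seed for the permutation null.
#' @return Object of class `correlation_result`: `rho`, `p_value`,
#'   `n_pairs`, `dropped`, `p_method`.
#' @export
spearman_cor <- function(a, b, p_method = c("t", "permutation"),
                         n_perm = 10000L, seed = NULL) {
  p_method <- match.arg(p_method)
  if (length(a) != length(b)) {
    stop_elemap("vectors must have equal length", "elemap_shape_error")
  }
  ok <- !is.na(a) & !is.na(b)
  dropped <- sum(!ok)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n < 3L) {
    stop_elemap(sprintf("only %d complete pairs; need >= 3 for a defined p-value", n),
                "elemap_insufficient_data_error")
  }
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    stop_elemap("zero variance in ranks: correlation undefined",
                "elemap_undefined_correlation_error")
  }
  rho <- stats::cor(ra, rb)
  p <- if (p_method == "t") {
    if (abs(rho) >= 1) {
      .Machine$double.xmin
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    }
  } else {
    with_seed(seed %||% 0L, {
      null_rho <- replicate(n_perm, stats::cor(ra, sample(rb)))
      (1 + sum(abs(null_rho) >= abs(rho) - 1e-15)) / (n_perm + 1)
    })
  }
  structure(list(rho = rho, p_value = p, n_pairs = n, dropped = dropped,
                 p_method = p_method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rho = %.4f, p = %.3g (%s), n = %d (%d dropped)\n",
              x$rho, x$p_value, x$p_method, x$n_pairs, x$dropped))
  invisible(x)
}

#' Rank-correlate one layer of two heatmaps
#'
#' Flattens matched cells row-major, drops pairs where either heatmap has an
#' empty cell, and applies [spearman_cor()].  Requires the same cluster set
#' and ROI order in both heatmaps — canonicalize replicate labels first with
#' [canonical_relabel()].
#'
#' @param h1,h2 `elemap_heatmap` objects.
#' @param layer Layer name present in both.
#' @param ... Passed to [spearman_cor()].
#' @export
compare_heatmaps <- function(h1, h2, layer, ...) {
  if (!identical(h1$clusters, h2$clusters) || !identical(h1$rois, h2$rois)) {
    stop_elemap(paste(
      "heatmaps are not aligned (cluster sets or ROI order differ);",
      "renumber replicate labels with canonical_relabel() before comparing"),
      "elemap_alignment_error")
  }
  m1 <- h1$layers[[layer]]
  m2 <- h2$layers[[layer]]
  if (is.null(m1) || is.null(m2)) {
    stop_elemap(sprintf("layer '%s' missing from one of the heatmaps", layer),
                "elemap_alignment_error")
  }
  spearman_cor(as.vector(t(m1)), as.vector(t(m2)), ...)
}

#' Rank-correlate two element layers of one heatmap
#'
#' Compares the spatial distribution of two elements through their
#' mean-intensity layers over the same cluster-ROI cells.
#'
#' @param h An `elemap_heatmap`.
#' @param elem1,elem2 Element labels with mean-intensity layers.
#' @param ... Passed to [spearman_cor()].
#' @export
compare_elements <- function(h, elem1, elem2, ...) {
  l1 <- h$layers[[paste0("mean_intensity:", elem1)]]
  l2 <- h$layers[[paste0("mean_intensity:", elem2)]]
  if (is.null(l1) || is.null(l2)) {
    stop_elemap("both elements need a mean_intensity layer in the heatmap",
                "elemap_alignment_error")
  }
  spearman_cor(as.vector(t(l1)), as.vector(t(l2)), ...)
}

#' Pairwise correlation matrix over several replicate heatmaps
#'
#' @param heatmaps Named list of aligned `elemap_heatmap`s.
#' @param layer Layer to compare.
#' @param ... Passed to [spearman_cor()].
#' @return Data frame with one row per unordered pair: `a, b, rho, p_value,
#'   n_pairs, dropped`.
#' @export
pairwise_heatmap_cor <- function(heatmaps, layer, ...) {
  nms <- names(heatmaps) %||% as.character(seq_along(heatmaps))
  combos <- utils::combn(seq_along(heatmaps), 2)
  rows <- apply(combos, 2, function(ij) {
    r <- compare_heatmaps(heatmaps[[ij[1]]], heatmaps[[ij[2]]], layer, ...)
    data.frame(a = nms[ij[1]], b = nms[ij[2]], rho = r$rho,
               p_value = r$p_value, n_pairs = r$n_pairs, dropped = r$dropped)
  })
  do.call(rbind, rows)
}
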