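# Cluster x ROI cross-tabulation: the heatmap layers of the workflow.
#
# Conventions shared by all layers:
#   * rows are cluster labels ascending with -1 (noise) first, mirroring the
#     "cluster -1" tables of density-based segmentations;
#   * columns are ROIs in their declared order;
#   * N_total, the "ablation area", is the number of clustered pixels
#     (including noise, excluding missing-value pixels);
#   * a cell with zero overlapping pixels is NA ("empty"), never 0 — empty
#     cells are excluded pairwise from replicate correlations, since zero
#     filling would fabricate agreement.

clustered_ids <- function(labels) {
  sort(unique(labels$labels[!is.na(labels$labels)]))
}

check_alignment <- function(labels, rois) {
  if (length(labels$labels) != rois$n_pixels) {
    stop_elemap(sprintf("labels cover %d pixels but ROI masks cover %d",
                        length(labels$labels), rois$n_pixels),
                "elemap_shape_error")
  }
}

#' Cluster-by-ROI overlap as percentage of the ablation area
#'
#' `cell(c, r) = 100 * |cluster c intersect ROI r| / N_total` where
#' `N_total` counts every clustered pixel (noise included, excluded pixels
#' not).  Summed over clusters, each ROI column gives
#' `100 * |ROI| / N_total`; the `"total"` ROI column sums to 100.
#'
#' @param labels A [cluster_labels()].
#' @param rois A [roi_mask_set()] on the same grid.
#' @return Numeric matrix, clusters x ROIs.
#' @export
count_pct <- function(labels, rois) {
  check_alignment(labels, rois)
  lab <- labels$labels
  n_total <- sum(!is.na(lab))
  ids <- clustered_ids(labels)
  out <- matrix(0, length(ids), length(rois$order),
                dimnames = list(ids, rois$order))
  for (i in seq_along(ids)) {
    in_c <- !is.na(lab) & lab == ids[i]
    for (j in seq_along(rois$order)) {
      out[i, j] <- 100 * sum(in_c & rois$masks[[rois$order[j]]]) / n_total
    }
  }
  out
}

#' Mean element intensity per cluster-ROI cell
#'
#' Arithmetic mean of the element's intensity over the pixels in
#' `cluster c intersect ROI r`; cells with no overlapping pixel are `NA`.
#' Pixels with a missing intensity for this element are excluded from the
#' cell mean.
#'
#' @inheritParams count_pct
#' @param grid The [pixel_grid()].
#' @param element Element label.
#' @export
mean_intensity <- function(labels, rois, grid, element) {
  check_alignment(labels, rois)
  if (!element %in% grid$elements) {
    stop_elemap(sprintf("unknown element '%s'", element), "elemap_config_error")
  }
  lab <- labels$labels
  v <- grid$intensity[[element]]
  ids <- clustered_ids(labels)
  out <- matrix(NA_real_, length(ids), length(rois$order),
                dimnames = list(ids, rois$order))
  for (i in seq_along(ids)) {
    in_c <- !is.na(lab) & lab == ids[i]
    for (j in seq_along(rois$order)) {
      sel <- v[in_c & rois$masks[[rois$order[j]]]]
      sel <- sel[!is.na(sel)]
      if (length(sel)) out[i, j] <- mean(sel)
    }
  }
  out
}

#' Summed element amount per cluster-ROI cell
#'
#' Sum of per-pixel quantified amounts (ng) over each cluster-ROI overlap;
#' empty cells are `NA`.  Summed over all clusters against the `"total"`
#' ROI this conserves the grid-wide amount.
#'
#' @inheritParams count_pct
#' @param amounts Numeric vector of per-pixel amounts (from
#'   [quantify_pixels()] or [import_amounts()]).
#' @export
sum_amount <- function(labels, rois, amounts) {
  check_alignment(labels, rois)
  if (length(amounts) != rois$n_pixels) {
    stop_elemap("amounts must have one value per pixel", "elemap_shape_error")
  }
  lab <- labels$labels
  ids <- clustered_ids(labels)
  out <- matrix(NA_real_, length(ids), length(rois$order),
                dimnames = list(ids, rois$order))
  for (i in seq_along(ids)) {
    in_c <- !is.na(lab) & lab == ids[i]
    for (j in seq_along(rois$order)) {
      sel <- in_c & rois$masks[[rois$order[j]]]
      if (any(sel)) out[i, j] <- sum(amounts[sel], na.rm = TRUE)
    }
  }
  out
}

#' Per-cluster share of the ablation area
#'
#' Percentage of all clustered pixels falling in each cluster (noise first);
#' the shares sum to 100.
#'
#' @param labels A [cluster_labels()].
#' @return Named numeric vector.
#' @export
cluster_area_pct <- function(labels) {
  lab <- labels$labels[!is.na(labels$labels)]
  if (length(lab) == 0L) {
    stop_elemap("no clustered pixels", "elemap_empty_input")
  }
  ids <- sort(unique(lab))
  out <- vapply(ids, function(c) 100 * sum(lab == c) / length(lab), numeric(1))
  names(out) <- ids
  out
}

#' Assemble the full cluster-by-ROI heatmap
#'
#' Builds the requested layers: the count-percentage layer, one
#' mean-intensity layer per element, and one summed-amount layer per element
#' with amounts.
#'
#' @param labels A [cluster_labels()].
#' @param rois A [roi_mask_set()].
#' @param grid The [pixel_grid()].
#' @param elements Elements for mean-intensity layers (default: all in the
#'   grid).
#' @param amounts Optional named list `element -> per-pixel amounts` for
#'   summed-amount layers (defaults to the grid's imported amount columns).
#' @return Object of class `elemap_heatmap`: `clusters`, `rois`, `layers`
#'   (named list of matrices; names `count_pct`, `mean_intensity:<el>`,
#'   `sum_amount:<el>`), `provenance`.
#' @export
build_heatmap <- function(labels, rois, grid, elements = grid$elements,
                          amounts = NULL) {
  if (is.null(amounts) && !is.null(grid$amount)) {
    amounts <- as.list(grid$amount)
  }
  layers <- list(count_pct = count_pct(labels, rois))
  for (el in elements) {
    layers[[paste0("mean_intensity:", el)]] <-
      mean_intensity(labels, rois, grid, el)
  }
  for (el in names(amounts)) {
    layers[[paste0("sum_amount:", el)]] <-
      sum_amount(labels, rois, amounts[[el]])
  }
  structure(list(clusters = clustered_ids(labels), rois = rois$order,
                 layers = layers,
                 provenance = list(algorithm = labels$algorithm,
                                   params = labels$params,
                                   seed = labels$seed,
                                   grid = grid$source)),
            class = "elemap_heatmap")
}

#' @export
print.elemap_heatmap <- function(x, ...) {
  cat(sprintf("<elemap_heatmap> %d clusters x %d ROIs, layers: %s\n",
              length(x$clusters), length(x$rois),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

split_layer_name <- function(nm) {
  parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
  list(layer = parts[1], element = if (length(parts) > 1) parts[2] else NA_character_)
}

layer_rank <- function(nm) {
  match(split_layer_name(nm)$layer,
        c("count_pct", "mean_intensity", "sum_amount"))
}

#' Write a heatmap as a long-format CSV
#'
#' Columns `cluster, roi, layer, element, value` with a fixed ordering:
#' layers `count_pct`, `mean_intensity`, `sum_amount` (elements in layer
#' order), clusters ascending (-1 first), ROIs in declared order.  Empty
#' cells are written as the empty string.
#'
#' @param hm An `elemap_heatmap`.
#' @param path Output path.
#' @export
write_heatmap_csv <- function(hm, path) {
  if (length(hm$layers) < 1L) {
    stop_elemap("heatmap has no layers", "elemap_validation_error")
  }
  nms <- names(hm$layers)[order(vapply(names(hm$layers), layer_rank, numeric(1)),
                                seq_along(hm$layers))]
  rows <- list()
  for (nm in nms) {
    meta <- split_layer_name(nm)
    m <- hm$layers[[nm]]
    rows[[nm]] <- data.frame(
      cluster = rep(hm$clusters, times = length(hm$rois)),
      roi = rep(hm$rois, each = length(hm$clusters)),
      layer = meta$layer,
      element = if (is.na(meta$element)) "" else meta$element,
      value = as.vector(m)
    )
    # row-major emission: cluster varies slowest
    rows[[nm]] <- rows[[nm]][order(match(rows[[nm]]$cluster, hm$clusters),
                                   match(rows[[nm]]$roi, hm$rois)), ]
  }
  df <- do.call(rbind, rows)
  vals <- formatC(df$value, digits = 17, format = "g")
  vals[is.na(df$value)] <- ""
  out <- data.frame(cluster = df$cluster, roi = df$roi, layer = df$layer,
                    element = df$element, value = trimws(vals))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a heatmap written by [write_heatmap_csv()]
#' @param path CSV path.
#' @return An `elemap_heatmap`.
#' @export
read_heatmap_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(cluster = "integer",
                                             roi = "character",
                                             layer = "character",
                                             element = "character",
                                             value = "character"))
  clusters <- sort(unique(df$cluster))
  rois <- unique(df$roi)
  key <- ifelse(df$element == "", df$layer,
                paste(df$layer, df$element, sep = ":"))
  layers <- lapply(split(df, factor(key, levels = unique(key))), function(d) {
    m <- matrix(NA_real_, length(clusters), length(rois),
                dimnames = list(clusters, rois))
    v <- suppressWarnings(as.numeric(d$value))
    m[cbind(match(d$cluster, clusters), match(d$roi, rois))] <- v
    m
  })
  structure(list(clusters = clusters, rois = rois, layers = layers,
                 provenance = list(source = path)),
            class = "elemap_heatmap")
}

#' Plot one heatmap layer
#'
#' Base-graphics rendering: cluster rows by ROI columns, value-annotated.
#'
#' @param x An `elemap_heatmap`.
#' @param layer Layer name (default first).
#' @param ... Passed to [graphics::image()].
#' @export
plot.elemap_heatmap <- function(x, layer = names(x$layers)[1], ...) {
  m <- x$layers[[layer]]
  if (is.null(m)) {
    stop_elemap(sprintf("no layer '%s'", layer), "elemap_config_error")
  }
  z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), z, axes = FALSE,
                  xlab = "ROI", ylab = "cluster", main = layer, ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 1)
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (!is.na(m[i, j])) {
        graphics::text(j, nrow(m) - i + 1, signif(m[i, j], 3), cex = 0.7)
      }
    }
  }
  invisible(x)
}
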