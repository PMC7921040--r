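#' Point-in-polygon membership (even-odd rule, half-open boundary)
#'
#' Crossing-number test with the half-open convention: a point exactly on the
#' polygon boundary counts as inside for its lower/left edges only, so two
#' polygons sharing an edge never both claim a pixel centre.  Vectorized over
#' points; the edge loop is short (annotation contours have tens of
#' vertices).
#'
#' @param px,py Point coordinates.
#' @param vertices 2-column matrix of polygon vertices; the polygon is
#'   implicitly closed.
#' @return Logical vector over points.
#' @export
point_in_polygon <- function(px, py, vertices) {
  vx <- vertices[, 1]
  vy <- vertices[, 2]
  nv <- length(vx)
  inside <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    yi <- vy[i]; yj <- vy[j]
    if (yi != yj) {
      crosses <- (yi > py) != (yj > py)
      if (any(crosses)) {
        xint <- vx[i] + (py[crosses] - yi) * (vx[j] - vx[i]) / (yj - yi)
        inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
      }
    }
    j <- i
  }
  inside
}

polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  n <- nrow(vertices)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Rasterize a closed contour onto the grid
#'
#' A pixel belongs to the feature iff its centre (its stage coordinate) lies
#' inside the polygon under the even-odd rule with the half-open boundary
#' convention of [point_in_polygon()].  Membership is all-or-nothing: pixels
#' are 35 um ablation spots, and a centre test is deterministic.
#'
#' @param vertices 2-column matrix of polygon vertices in stage coordinates
#'   (micrometres), implicitly closed.
#' @param grid A [pixel_grid()].
#' @return Logical mask over the grid's pixels.
#' @export
rasterize_feature <- function(vertices, grid) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) {
    stop_elemap(sprintf("a contour needs at least 3 vertices, got %d",
                        nrow(vertices)), "elemap_validation_error")
  }
  if (polygon_area(vertices) == 0) {
    warn_elemap("zero-area polygon rasterizes to an empty mask",
                "elemap_empty_mask_warning")
    return(rep(FALSE, n_pixels(grid)))
  }
  point_in_polygon(grid$coords$x, grid$coords$y, vertices)
}

# Arc points around `centre` from angle a1 sweeping by `delta` (radians).
arc_points <- function(centre, radius, a1, delta, max_step = 0.2) {
  nstep <- max(2L, ceiling(abs(delta) / max_step))
  ang <- a1 + delta * seq(0, 1, length.out = nstep + 1L)
  cbind(centre[1] + radius * cos(ang), centre[2] + radius * sin(ang))
}

#' Buffer a polyline into a closed outline polygon
#'
#' Returns the (discretized) outline of all points within `halfwidth` of the
#' polyline, with rounded caps and joins — the shape of an ablated line
#' feature such as the notochord.  Arc discretization keeps the area within
#' about half a percent of the exact stadium for a straight segment; strongly
#' self-intersecting polylines are not supported.
#'
#' @param vertices 2-column matrix of polyline vertices (>= 2 distinct).
#' @param halfwidth Buffer half-width in micrometres (> 0); the natural
#'   default is one laser beam radius.
#' @return 2-column matrix: closed outline polygon.
#' @export
buffer_polyline <- function(vertices, halfwidth) {
  if (!is_scalar_number(halfwidth) || halfwidth <= 0) {
    stop_elemap("halfwidth must be a positive number", "elemap_validation_error")
  }
  v <- as.matrix(vertices)
  keep <- c(TRUE, rowSums(abs(diff(v)))[] > 0)
  v <- v[keep, , drop = FALSE]
  if (nrow(v) < 2L) {
    stop_elemap("polyline needs at least 2 distinct vertices",
                "elemap_validation_error")
  }
  m <- nrow(v) - 1L
  d <- diff(v)
  len <- sqrt(rowSums(d^2))
  dir <- d / len
  nrm <- cbind(-dir[, 2], dir[, 1])  # left normal
  ang <- function(p) atan2(p[2], p[1])
  wrap <- function(a) ((a + pi) %% (2 * pi)) - pi
  w <- halfwidth
  out <- list()
  # left side, forward
  for (i in seq_len(m)) {
    out[[length(out) + 1L]] <- rbind(v[i, ] + w * nrm[i, ],
                                     v[i + 1L, ] + w * nrm[i, ])
    if (i < m) {
      a1 <- ang(nrm[i, ]); a2 <- ang(nrm[i + 1L, ])
      out[[length(out) + 1L]] <- arc_points(v[i + 1L, ], w, a1, wrap(a2 - a1))
    }
  }
  # end cap: sweep half a turn through the forward direction
  out[[length(out) + 1L]] <- arc_points(v[m + 1L, ], w, ang(nrm[m, ]), -pi)
  # right side, backward
  for (i in rev(seq_len(m))) {
    out[[length(out) + 1L]] <- rbind(v[i + 1L, ] - w * nrm[i, ],
                                     v[i, ] - w * nrm[i, ])
    if (i > 1L) {
      a1 <- ang(-nrm[i, ]); a2 <- ang(-nrm[i - 1L, ])
      out[[length(out) + 1L]] <- arc_points(v[i, ], w, a1, wrap(a2 - a1))
    }
  }
  # start cap
  out[[length(out) + 1L]] <- arc_points(v[1L, ], w, ang(-nrm[1L, ]), -pi)
  poly <- do.call(rbind, out)
  dimnames(poly) <- NULL
  poly
}

#' Set-difference ROI: pixels of `a` not in `b`
#'
#' The derived "fish body" compartment is the fish contour minus the yolk.
#'
#' @param a,b Logical masks of equal length.
#' @param name Optional name attached to the result.
#' @export
derive_roi_difference <- function(a, b, name = NULL) {
  if (length(a) != length(b)) {
    stop_elemap("masks have different lengths", "elemap_shape_error")
  }
  out <- a & !b
  if (!is.null(name)) attr(out, "roi_name") <- name
  out
}

#' A set of named per-pixel ROI masks
#'
#' Masks may overlap (the fish contour contains the eyes and yolk). Order is
#' the declared reporting order used in heatmaps and summaries.
#'
#' @param masks Named list of logical vectors, all of length `n_pixels`.
#' @param n_pixels Pixel count of the underlying grid.
#' @param grid_ref Provenance string for the grid.
#' @export
roi_mask_set <- function(masks, n_pixels, grid_ref = NA_character_) {
  if (length(masks) < 1L) {
    stop_elemap("need at least one ROI", "elemap_validation_error")
  }
  if (is.null(names(masks)) || anyDuplicated(names(masks))) {
    stop_elemap("ROI names must be present and unique", "elemap_validation_error")
  }
  for (nm in names(masks)) {
    if (!is.logical(masks[[nm]]) || length(masks[[nm]]) != n_pixels) {
      stop_elemap(sprintf("ROI '%s': mask must be logical of length %d",
                          nm, n_pixels), "elemap_shape_error")
    }
  }
  structure(list(masks = masks, order = names(masks),
                 n_pixels = n_pixels, grid_ref = grid_ref),
            class = "roi_mask_set")
}

#' @export
print.roi_mask_set <- function(x, ...) {
  cat(sprintf("<roi_mask_set> %d ROIs over %d pixels\n",
              length(x$masks), x$n_pixels))
  for (nm in x$order) {
    cat(sprintf("  %-14s %6d px\n", nm, sum(x$masks[[nm]])))
  }
  invisible(x)
}

#' Build the full ROI mask set from transformed annotations
#'
#' Rasterizes every contour, buffers then rasterizes every polyline, applies
#' derived-ROI rules (difference/union over already-built masks), and appends
#' the implicit ROI `"total"` covering every pixel (the ablation area).
#'
#' @param ann [annotation_set()] already transformed to stage coordinates.
#' @param grid A [pixel_grid()].
#' @param polyline_halfwidth Buffer half-width for polylines, micrometres.
#'   The default is one beam diameter (35 um) as the annotation line itself
#'   carries no width.
#' @param derived Named list of rules, each
#'   `list(op = "difference", a = <roi>, b = <roi>)` or
#'   `list(op = "union", of = c(<roi>, ...))`, evaluated in order.
#' @param include_total Append the `"total"` ROI (default `TRUE`).
#' @return A [roi_mask_set()].
#' @export
build_roi_set <- function(ann, grid, polyline_halfwidth = 35,
                          derived = list(), include_total = TRUE) {
  masks <- list()
  for (f in ann$features) {
    poly <- if (f$kind == "polyline") {
      buffer_polyline(f$vertices, polyline_halfwidth)
    } else {
      f$vertices
    }
    m <- rasterize_feature(poly, grid)
    if (!any(m)) {
      warn_elemap(sprintf("ROI '%s' covers no pixel of the grid", f$name),
                  "elemap_empty_mask_warning")
    }
    masks[[f$name]] <- m
  }
  for (nm in names(derived)) {
    rule <- derived[[nm]]
    op <- rule$op %||% "difference"
    refs <- switch(op,
                   difference = c(rule$a, rule$b),
                   union = rule$of,
                   stop_elemap(sprintf("derived ROI '%s': unknown op '%s'", nm, op),
                               "elemap_config_error"))
    missing <- setdiff(refs, names(masks))
    if (length(missing)) {
      stop_elemap(sprintf("derived ROI '%s' references unknown ROI(s): %s",
                          nm, paste(missing, collapse = ", ")),
                  "elemap_config_error")
    }
    masks[[nm]] <- if (op == "difference") {
      derive_roi_difference(masks[[rule$a]], masks[[rule$b]])
    } else {
      Reduce(`|`, masks[rule$of])
    }
  }
  if (include_total) masks[["total"]] <- rep(TRUE, n_pixels(grid))
  roi_mask_set(masks, n_pixels(grid), grid_ref = grid$source)
}

#' Export ROI membership as a long CSV (pixel, roi, member)
#' @param rois A [roi_mask_set()].
#' @param path Output path.
#' @export
write_roi_csv <- function(rois, path) {
  df <- do.call(rbind, lapply(rois$order, function(nm) {
    data.frame(pixel = seq_len(rois$n_pixels), roi = nm,
               member = rois$masks[[nm]])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-ROI pixel counts
#' @param rois A [roi_mask_set()].
#' @export
roi_pixel_counts <- function(rois) {
  vapply(rois$masks[rois$order], sum, integer(1))
}
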