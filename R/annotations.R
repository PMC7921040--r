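#' Construct a set of annotated morphological features
#'
#' Named contours/polylines in source-image pixel coordinates, as produced by
#' a feature-detection tool on the reference microscope photo (fish contour,
#' yolk, eyes, notochord, ...). Coordinates use the raster convention:
#' u rightward, v downward, origin at the top-left pixel corner.
#'
#' @param features List of features, each `list(name, kind, vertices)` with
#'   `kind` `"contour"` (closed, >= 3 vertices) or `"polyline"` (>= 2
#'   vertices) and `vertices` a 2-column (u, v) matrix.
#' @param image_width,image_height Source image dimensions in pixels.
#' @param source Provenance string.
#' @export
annotation_set <- function(features, image_width, image_height,
                           source = NA_character_) {
  if (!is_scalar_number(image_width) || !is_scalar_number(image_height) ||
      image_width <= 0 || image_height <= 0) {
    stop_elemap("image dimensions must be positive numbers",
                "elemap_validation_error")
  }
  nms <- vapply(features, function(f) f$name %||% NA_character_, character(1))
  if (anyNA(nms) || anyDuplicated(nms)) {
    stop_elemap("feature names must be present and unique",
                "elemap_validation_error")
  }
  features <- lapply(features, function(f) {
    kind <- match.arg(f$kind, c("contour", "polyline"))
    v <- as.matrix(f$vertices)
    storage.mode(v) <- "double"
    if (ncol(v) != 2L) {
      stop_elemap(sprintf("feature '%s': vertices must be (u, v) pairs", f$name),
                  "elemap_validation_error")
    }
    min_v <- if (kind == "contour") 3L else 2L
    if (nrow(v) < min_v) {
      stop_elemap(sprintf("feature '%s': a %s needs at least %d vertices, got %d",
                          f$name, kind, min_v, nrow(v)),
                  "elemap_validation_error")
    }
    if (any(!is.finite(v))) {
      stop_elemap(sprintf("feature '%s': vertices must be finite", f$name),
                  "elemap_validation_error")
    }
    dimnames(v) <- NULL
    list(name = f$name, kind = kind, vertices = v)
  })
  names(features) <- nms
  structure(list(features = features,
                 image = c(width = image_width, height = image_height),
                 source = source),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d features on a %g x %g px image\n",
              length(x$features), x$image[["width"]], x$image[["height"]]))
  for (f in x$features) {
    cat(sprintf("  %-14s %-9s %d vertices\n", f$name, f$kind, nrow(f$vertices)))
  }
  invisible(x)
}

#' Read an annotation file
#'
#' The native dialect is a small versioned JSON schema:
#' `{"version": "1", "image": {"width": w, "height": h},
#'   "features": [{"name", "kind", "vertices": [[u, v], ...]}, ...]}`.
#'
#' `dialect = "fishinspector"` applies a best-effort mapping for
#' FishInspector-style exports (named features carrying `x`/`y` vertex arrays
#' and an optional `closed` flag). The real schema is not published, so this
#' import should be validated against actual files before relying on it.
#'
#' @param path JSON file.
#' @param dialect `"elemap"` (native, default) or `"fishinspector"`.
#' @return An [annotation_set()].
#' @export
read_annotation_json <- function(path, dialect = c("elemap", "fishinspector")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_elemap(sprintf("file not found: %s", path), "elemap_io_error")
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (dialect == "elemap") {
    if (!identical(as.character(doc$version %||% ""), "1")) {
      stop_elemap(sprintf("unknown annotation schema version '%s' (expected \"1\")",
                          doc$version %||% "<absent>"), "elemap_dialect_error")
    }
    feats <- lapply(doc$features, function(f) {
      list(name = f$name, kind = f$kind,
           vertices = do.call(rbind, lapply(f$vertices, unlist)))
    })
    annotation_set(feats, doc$image$width, doc$image$height, source = path)
  } else {
    img <- doc$image %||% doc$image_size %||% list(width = NA, height = NA)
    feats_raw <- doc$features %||% doc[setdiff(names(doc), c("image", "image_size", "version"))]
    feats <- lapply(names(feats_raw), function(nm) {
      f <- feats_raw[[nm]]
      u <- unlist(f$x %||% f$u)
      v <- unlist(f$y %||% f$v)
      if (is.null(u) || is.null(v) || length(u) != length(v)) {
        stop_elemap(sprintf("feature '%s': cannot map x/y vertex arrays", nm),
                    "elemap_dialect_error")
      }
      closed <- isTRUE(f$closed) || length(u) >= 3
      list(name = nm, kind = if (closed) "contour" else "polyline",
           vertices = cbind(u, v))
    })
    w <- img$width %||% max(vapply(feats, function(f) max(f$vertices[, 1]), numeric(1)))
    h <- img$height %||% max(vapply(feats, function(f) max(f$vertices[, 2]), numeric(1)))
    annotation_set(feats, w, h, source = path)
  }
}

#' Write an annotation set in the native JSON dialect
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @export
write_annotation_json <- function(ann, path) {
  doc <- list(
    version = "1",
    image = list(width = unname(ann$image[["width"]]),
                 height = unname(ann$image[["height"]])),
    features = lapply(unname(ann$features), function(f) {
      list(name = f$name, kind = f$kind,
           vertices = lapply(seq_len(nrow(f$vertices)),
                             function(i) unname(f$vertices[i, ])))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
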