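# Synthetic zebrafish-embryo phantom: annotation polygons, an element map
# with per-region intensity levels and counting noise, and ground-truth
# region labels, all deterministic given a seed.  The phantom makes every
# pipeline stage testable without instrument data; it does not model laser
# plume washout, drift, or partial-pixel ablation.

ellipse_polygon <- function(cu, cv, ru, rv, n = 60L) {
  a <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cu + ru * cos(a), cv + rv * sin(a))
}

#' Default geometry and intensity levels of the synthetic embryo scene
#'
#' The default scene approximates a laterally mounted ~3.5 mm x 1 mm
#' embryo rasterized at the 35 um beam pitch (100 x 30 pixels).  Annotated
#' features: fish contour, yolk, two eyes (contours), notochord (polyline)
#' and swim bladder.  Intensity is driven by four regions resolved with the
#' precedence eye > yolk > body > background; the notochord and bladder are
#' annotation-only features.  Per-region levels for the carbon channel are
#' spaced about tenfold so the planted partition is unambiguous relative to
#' the multiplicative noise.
#'
#' Annotation coordinates live in a synthetic 1000 x 300 px "microscope
#' image" frame related to the stage frame by a known affine (scale 3.5,
#' vertical flip), so registration is exercised nontrivially by default.
#'
#' @param image_width,image_height Annotation frame size, px.
#' @param n_cols,n_rows Grid size in pixels.
#' @param pitch Raster pitch, micrometres.
#' @param levels Matrix elements x regions (`background, body, yolk, eye`)
#'   of mean intensities in cps.
#' @param noise List: `sigma` (log-normal multiplicative sd, default 0.1),
#'   `poisson` (add Poisson resampling of the counts, default FALSE).
#' @param seed Integer seed fixing everything downstream.
#' @return Object of class `synth_scene`.
#' @export
synth_scene <- function(image_width = 1000, image_height = 300,
                        n_cols = 100L, n_rows = 30L, pitch = 35,
                        levels = default_levels(),
                        noise = list(sigma = 0.1, poisson = FALSE),
                        seed = 1L) {
  if (pitch <= 0) stop_elemap("pitch must be positive", "elemap_validation_error")
  geom <- list(
    body = list(kind = "contour",
                vertices = ellipse_polygon(500, 150, 430, 105)),
    yolk = list(kind = "contour",
                vertices = ellipse_polygon(320, 185, 95, 60, n = 40L)),
    eye_left = list(kind = "contour",
                    vertices = ellipse_polygon(135, 120, 32, 32, n = 24L)),
    eye_right = list(kind = "contour",
                     vertices = ellipse_polygon(135, 185, 30, 30, n = 24L)),
    notochord = list(kind = "polyline",
                     vertices = cbind(seq(260, 900, length.out = 8),
                                      150 + 12 * sin(seq(0, pi, length.out = 8)))),
    bladder = list(kind = "contour",
                   vertices = ellipse_polygon(430, 118, 25, 18, n = 24L))
  )
  for (nm in names(geom)) {
    geom[[nm]]$name <- nm
    v <- geom[[nm]]$vertices
    if (any(v[, 1] < 0 | v[, 1] > image_width |
            v[, 2] < 0 | v[, 2] > image_height)) {
      stop_elemap(sprintf("feature '%s' extends outside the image bounds", nm),
                  "elemap_validation_error")
    }
  }
  regions <- c("background", "body", "yolk", "eye")
  if (!identical(colnames(levels), regions)) {
    stop_elemap("levels must have columns background, body, yolk, eye",
                "elemap_validation_error")
  }
  if (any(levels < 0)) {
    stop_elemap("intensity levels must be >= 0", "elemap_validation_error")
  }
  # image frame (v down) -> stage frame (y up), uniform scale to micrometres
  s <- n_cols * pitch / image_width
  annotation_affine <- affine_transform(s, 0, 0, -s, 0, image_height * s)
  structure(list(image = c(width = image_width, height = image_height),
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 pitch = pitch, geometry = geom, levels = levels,
                 regions = regions, noise = noise,
                 annotation_affine = annotation_affine, seed = as.integer(seed)),
            class = "synth_scene")
}

#' @rdname synth_scene
#' @export
default_levels <- function() {
  m <- rbind(
    `12C`  = c(0, 1.2e5, 2.9e5, 7.0e5),
    `31P`  = c(0, 9.0e4, 1.1e5, 1.6e5),
    `39K`  = c(0, 1.5e5, 9.0e4, 2.7e6),
    `79Br` = c(0, 7.0e3, 1.4e3, 6.3e4),
    `127I` = c(0, 4.0e3, 3.6e4, 2.3e4)
  )
  colnames(m) <- c("background", "body", "yolk", "eye")
  m
}

#' Render a synthetic scene into a dataset
#'
#' Produces the pixel grid (with multiplicative log-normal and optional
#' Poisson noise), the annotation set in the image frame, and the
#' ground-truth region label of every pixel.  Truth labels and rasterized
#' annotation masks derive from the same polygons, so they agree exactly
#' under the region precedence eye > yolk > body > background.
#'
#' @param scene A [synth_scene()].
#' @return List with `grid` ([pixel_grid()]), `annotations`
#'   ([annotation_set()], image frame), `truth` (integer region index per
#'   pixel, 1 = background), `regions`, `scene`.
#' @export
render_scene <- function(scene) {
  centres_x <- (seq_len(scene$n_cols) - 0.5) * scene$pitch
  centres_y <- (seq_len(scene$n_rows) - 0.5) * scene$pitch
  gxy <- expand.grid(x = centres_x, y = centres_y)
  ann <- annotation_set(scene$geometry, scene$image[["width"]],
                        scene$image[["height"]], source = "synth_scene")
  ann_stage <- transform_annotations(ann, scene$annotation_affine)
  inpoly <- function(nm) {
    point_in_polygon(gxy$x, gxy$y, ann_stage$features[[nm]]$vertices)
  }
  body <- inpoly("body")
  yolk <- inpoly("yolk") & body
  eye <- (inpoly("eye_left") | inpoly("eye_right")) & body
  truth <- rep(1L, nrow(gxy))
  truth[body] <- 2L
  truth[yolk] <- 3L
  truth[eye] <- 4L

  sigma <- scene$noise$sigma %||% 0
  n <- nrow(gxy)
  intensity <- with_seed(scene$seed, {
    cols <- lapply(rownames(scene$levels), function(el) {
      base <- scene$levels[el, truth]
      v <- if (sigma > 0) base * exp(stats::rnorm(n, 0, sigma)) else base
      if (isTRUE(scene$noise$poisson)) v <- as.numeric(stats::rpois(n, v))
      v
    })
    names(cols) <- rownames(scene$levels)
    as.data.frame(cols, check.names = FALSE)
  })
  grid <- pixel_grid(gxy$x, gxy$y, intensity,
                     pitch = c(x = scene$pitch, y = scene$pitch),
                     source = sprintf("synth_scene(seed=%d)", scene$seed))
  list(grid = grid, annotations = ann, truth = truth,
       regions = scene$regions, scene = scene)
}

#' Write a synthetic dataset bundle to a directory
#'
#' Emits `intensities.tsv` (delimited intensity table), `annotations.json`
#' (native annotation dialect), `truth.csv` (pixel, region index, region
#' name) and `manifest.json` (seed and scene parameters, the single source
#' of truth for regeneration).  All files re-read with the io functions.
#'
#' @param dataset A [render_scene()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths.
#' @export
write_fixture_bundle <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(intensities = file.path(dir, "intensities.tsv"),
             annotations = file.path(dir, "annotations.json"),
             truth = file.path(dir, "truth.csv"),
             manifest = file.path(dir, "manifest.json"))
  write_intensity_table(dataset$grid, paths[["intensities"]])
  write_annotation_json(dataset$annotations, paths[["annotations"]])
  utils::write.csv(data.frame(pixel = seq_along(dataset$truth),
                              region = dataset$truth,
                              region_name = dataset$regions[dataset$truth]),
                   paths[["truth"]], row.names = FALSE)
  sc <- dataset$scene
  manifest <- list(
    generator = "elemap::synth_scene", seed = sc$seed,
    image = as.list(sc$image), n_cols = sc$n_cols, n_rows = sc$n_rows,
    pitch = sc$pitch, noise = sc$noise,
    levels = list(elements = rownames(sc$levels),
                  regions = colnames(sc$levels),
                  values = apply(sc$levels, 1, as.list))
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Rebuild the scene described by a bundle manifest
#' @param path Path to a `manifest.json` written by [write_fixture_bundle()].
#' @export
scene_from_manifest <- function(path) {
  m <- jsonlite::read_json(path)
  lv <- do.call(rbind, lapply(m$levels$values, function(r) unlist(r)))
  rownames(lv) <- unlist(m$levels$elements)
  colnames(lv) <- unlist(m$levels$regions)
  synth_scene(image_width = m$image$width, image_height = m$image$height,
              n_cols = m$n_cols, n_rows = m$n_rows, pitch = m$pitch,
              levels = lv,
              noise = list(sigma = m$noise$sigma,
                           poisson = isTRUE(m$noise$poisson)),
              seed = m$seed)
}
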