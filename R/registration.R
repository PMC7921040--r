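#' 2-D affine transform between the annotation frame and the laser stage
#'
#' Maps source-image pixel coordinates (u, v) onto stage coordinates in
#' micrometres: `x = a11 u + a12 v + tx`, `y = a21 u + a22 v + ty`.
#'
#' @param a11,a12,a21,a22 Matrix entries (unitless).
#' @param tx,ty Translation, micrometres.
#' @export
affine_transform <- function(a11 = 1, a12 = 0, a21 = 0, a22 = 1,
                             tx = 0, ty = 0) {
  vals <- c(a11, a12, a21, a22, tx, ty)
  if (any(!is.finite(vals))) {
    stop_elemap("affine entries must be finite", "elemap_validation_error")
  }
  det <- a11 * a22 - a12 * a21
  if (det == 0) {
    stop_elemap("affine transform is singular (zero determinant)",
                "elemap_degeneracy_error")
  }
  structure(list(a11 = a11, a12 = a12, a21 = a21, a22 = a22,
                 tx = tx, ty = ty),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("<affine2d> [%g %g | %g]  [%g %g | %g]\n",
              x$a11, x$a12, x$tx, x$a21, x$a22, x$ty))
  rms <- attr(x, "rms_residual")
  if (!is.null(rms)) cat(sprintf("  landmark RMS residual: %g um\n", rms))
  invisible(x)
}

#' Apply an affine transform to (u, v) points
#' @param T An [affine_transform()].
#' @param uv 2-column matrix of points.
#' @return 2-column matrix of transformed points.
#' @export
apply_affine <- function(T, uv) {
  uv <- matrix(as.numeric(uv), ncol = 2)
  cbind(T$a11 * uv[, 1] + T$a12 * uv[, 2] + T$tx,
        T$a21 * uv[, 1] + T$a22 * uv[, 2] + T$ty)
}

#' Estimate an affine transform from landmark pairs
#'
#' Least-squares fit of the six affine parameters to pairs of corresponding
#' points, minimizing the summed squared residual in the target (stage)
#' frame.  Exactly three non-collinear pairs give an exact interpolation.
#'
#' @param pairs Data frame (or matrix) with columns `u, v, x, y`: source-image
#'   and stage coordinates of the same landmarks.
#' @param warn_rms Warn when the RMS residual exceeds this value
#'   (micrometres; typically one pixel pitch). `NULL` disables the check.
#' @return An [affine_transform()] with attribute `rms_residual`.
#' @export
estimate_affine <- function(pairs, warn_rms = NULL) {
  pairs <- as.data.frame(pairs)
  if (!all(c("u", "v", "x", "y") %in% names(pairs))) {
    stop_elemap("landmark pairs need columns u, v, x, y",
                "elemap_validation_error")
  }
  n <- nrow(pairs)
  if (n < 3L) {
    stop_elemap(sprintf(
      "affine estimation is underdetermined: %d landmark pair(s), need >= 3", n),
      "elemap_underdetermined_error")
  }
  A <- cbind(pairs$u, pairs$v, 1)
  qa <- qr(A)
  if (qa$rank < 3L) {
    stop_elemap("source landmarks are collinear: affine fit is underdetermined",
                "elemap_underdetermined_error")
  }
  cx <- qr.coef(qa, pairs$x)
  cy <- qr.coef(qa, pairs$y)
  T <- affine_transform(cx[1], cx[2], cy[1], cy[2], cx[3], cy[3])
  res <- cbind(pairs$x, pairs$y) - apply_affine(T, cbind(pairs$u, pairs$v))
  rms <- sqrt(mean(rowSums(res^2)))
  attr(T, "rms_residual") <- rms
  if (!is.null(warn_rms) && rms > warn_rms) {
    warn_elemap(sprintf(
      "landmark RMS residual %.3g um exceeds %.3g um; check the overlay",
      rms, warn_rms), "elemap_registration_warning")
  }
  T
}

#' Extent-based fallback transform
#'
#' When no landmarks are available, maps the annotation image rectangle onto
#' the bounding box of the grid coordinates with an axis-aligned scale and
#' translation. With `flip_y` the image v axis (pointing down) is inverted so
#' that it maps onto a stage y axis pointing up.
#'
#' @param ann An [annotation_set()].
#' @param grid A [pixel_grid()].
#' @param flip_y Invert the vertical axis (default `TRUE`).
#' @return An [affine_transform()].
#' @export
default_transform_from_extents <- function(ann, grid, flip_y = TRUE) {
  xr <- range(grid$coords$x)
  yr <- range(grid$coords$y)
  if (diff(xr) <= 0 || diff(yr) <= 0) {
    stop_elemap("grid bounding box has zero area; extent-based transform undefined",
                "elemap_degeneracy_error")
  }
  w <- ann$image[["width"]]
  h <- ann$image[["height"]]
  a11 <- diff(xr) / w
  if (flip_y) {
    affine_transform(a11, 0, 0, -diff(yr) / h, xr[1], yr[2])
  } else {
    affine_transform(a11, 0, 0, diff(yr) / h, xr[1], yr[1])
  }
}

#' Transform every feature of an annotation set
#' @param ann An [annotation_set()].
#' @param T An [affine_transform()].
#' @return An [annotation_set()] in the target frame (image dimensions kept
#'   as provenance of the source frame).
#' @export
transform_annotations <- function(ann, T) {
  ann$features <- lapply(ann$features, function(f) {
    f$vertices <- apply_affine(T, f$vertices)
    f
  })
  ann
}

#' Invert an affine transform
#' @param T An [affine_transform()].
#' @export
affine_invert <- function(T) {
  det <- T$a11 * T$a22 - T$a12 * T$a21
  if (abs(det) < 1e-12) {
    stop_elemap("affine transform is numerically singular (|det| < 1e-12)",
                "elemap_degeneracy_error")
  }
  i11 <- T$a22 / det
  i12 <- -T$a12 / det
  i21 <- -T$a21 / det
  i22 <- T$a11 / det
  affine_transform(i11, i12, i21, i22,
                   -(i11 * T$tx + i12 * T$ty),
                   -(i21 * T$tx + i22 * T$ty))
}

#' Compose two affine transforms
#' @param A,B [affine_transform()]s; the result applies `B` first, then `A`.
#' @export
affine_compose <- function(A, B) {
  affine_transform(
    A$a11 * B$a11 + A$a12 * B$a21,
    A$a11 * B$a12 + A$a12 * B$a22,
    A$a21 * B$a11 + A$a22 * B$a21,
    A$a21 * B$a12 + A$a22 * B$a22,
    A$a11 * B$tx + A$a12 * B$ty + A$tx,
    A$a21 * B$tx + A$a22 * B$ty + A$ty
  )
}

#' Serialize / deserialize an affine transform as JSON
#' @param T An [affine_transform()].
#' @param path File path.
#' @export
write_transform_json <- function(T, path) {
  jsonlite::write_json(T[c("a11", "a12", "a21", "a22", "tx", "ty")], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  d <- jsonlite::read_json(path)
  affine_transform(d$a11, d$a12, d$a21, d$a22, d$tx, d$ty)
}

#' Read a landmarks CSV (columns u, v, x, y)
#' @param path CSV file.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("u", "v", "x", "y") %in% names(df))) {
    stop_elemap("landmarks file needs columns u, v, x, y",
                "elemap_format_error")
  }
  df[c("u", "v", "x", "y")]
}
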