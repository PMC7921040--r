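#' Construct a pixel grid of element intensities
#'
#' A `pixel_grid` is the in-memory form of one ablation image: an ordered set
#' of laser spots ("pixels") with stage coordinates in micrometres and one
#' intensity value (counts per second) per measured element.  Optional
#' per-pixel quantified amounts (ng) can ride along, either imported from
#' upstream software or produced by [quantify_pixels()].
#'
#' Baseline-corrected intensities may legitimately be negative; missing
#' values are carried as `NA` and are excluded pixel-wise downstream, never
#' imputed.
#'
#' @param x,y Numeric stage coordinates, micrometres. `(x, y)` pairs must be
#'   unique.
#' @param intensity Data frame or matrix, one column per element, one row per
#'   pixel. Column names are the element labels (e.g. `"12C"`, `"127I"`).
#' @param amount Optional data frame/matrix of per-pixel amounts (ng), columns
#'   named by element.
#' @param pitch Optional numeric of length 2 `c(x, y)`: the raster pitch in
#'   micrometres. Inferred from the coordinates when `NULL`.
#' @param source Provenance string (file path or generator id).
#' @return An object of class `pixel_grid` with fields `coords`, `intensity`,
#'   `amount`, `elements`, `pitch`, `source`.
#' @export
pixel_grid <- function(x, y, intensity, amount = NULL, pitch = NULL,
                       source = NA_character_) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  intensity <- as.data.frame(intensity, check.names = FALSE)
  n <- length(x)
  if (n < 1L) {
    stop_elemap("a pixel grid needs at least one pixel", "elemap_empty_input")
  }
  if (length(y) != n || nrow(intensity) != n) {
    stop_elemap("x, y and intensity must have one entry per pixel",
                "elemap_shape_error")
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop_elemap("stage coordinates must be finite", "elemap_validation_error")
  }
  if (anyDuplicated(paste(x, y, sep = "\r"))) {
    stop_elemap("(x, y) coordinate pairs must be unique",
                "elemap_validation_error")
  }
  if (is.null(colnames(intensity)) || anyDuplicated(colnames(intensity))) {
    stop_elemap("intensity columns must carry unique element labels",
                "elemap_validation_error")
  }
  for (el in colnames(intensity)) {
    v <- intensity[[el]]
    if (!is.numeric(v)) {
      stop_elemap(sprintf("intensity column '%s' is not numeric", el),
                  "elemap_parse_error")
    }
    if (any(is.infinite(v))) {
      stop_elemap(sprintf("intensity column '%s' contains non-finite values", el),
                  "elemap_validation_error")
    }
  }
  if (!is.null(amount)) {
    amount <- as.data.frame(amount, check.names = FALSE)
    if (nrow(amount) != n) {
      stop_elemap("amount table must have one row per pixel",
                  "elemap_shape_error")
    }
  }
  structure(
    list(
      coords = data.frame(x = x, y = y),
      intensity = intensity,
      amount = amount,
      elements = colnames(intensity),
      pitch = pitch %||% infer_pitch(x, y),
      source = source
    ),
    class = "pixel_grid"
  )
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid> %d pixels, %d elements (%s)\n",
              n_pixels(x), length(x$elements),
              paste(x$elements, collapse = ", ")))
  cat(sprintf("  x: [%g, %g] um   y: [%g, %g] um   pitch: %g x %g um\n",
              min(x$coords$x), max(x$coords$x),
              min(x$coords$y), max(x$coords$y),
              x$pitch[[1]], x$pitch[[2]]))
  if (!is.null(x$amount)) {
    cat(sprintf("  amounts: %s\n", paste(colnames(x$amount), collapse = ", ")))
  }
  invisible(x)
}

#' Number of pixels in a grid
#' @param grid A [pixel_grid()].
#' @export
n_pixels <- function(grid) nrow(grid$coords)

# Median positive step along each axis; falls back to 0 for degenerate axes.
infer_pitch <- function(x, y) {
  step <- function(v) {
    d <- diff(sort(unique(v)))
    d <- d[d > 0]
    if (length(d) == 0L) 0 else stats::median(d)
  }
  c(x = step(x), y = step(y))
}

#' Parser dialect for delimited intensity tables
#'
#' Describes how an exported LA-ICP-MS table is laid out. The canonical
#' layout is `element1, element2, ..., X coordinate, Y coordinate`; column
#' *names* vary between export tools, so the coordinate columns are found by
#' case-insensitive pattern among the trailing columns.
#'
#' @param delimiter Field separator; `NULL` auto-detects among tab, comma and
#'   semicolon on the header line (comma is not a candidate when it is the
#'   decimal mark).
#' @param decimal Decimal mark, `"."` or `","`.
#' @param coord_patterns Named character vector with regular expressions
#'   identifying the x and y coordinate columns (case-insensitive).
#' @param missing Strings read as missing values.
#' @param amount_suffix Columns named `<element><amount_suffix>` are read as
#'   per-pixel quantified amounts (ng) rather than intensities.
#' @export
intensity_dialect <- function(delimiter = NULL, decimal = ".",
                              coord_patterns = c(x = "^x", y = "^y"),
                              missing = c("", "NA", "NaN"),
                              amount_suffix = "_ng") {
  decimal <- match.arg(decimal, c(".", ","))
  list(delimiter = delimiter, decimal = decimal,
       coord_patterns = coord_patterns, missing = missing,
       amount_suffix = amount_suffix)
}

detect_delimiter <- function(header_line, decimal) {
  cands <- if (decimal == ",") c("\t", ";") else c("\t", ",", ";")
  counts <- vapply(cands, function(d) {
    length(gregexpr(d, header_line, fixed = TRUE)[[1]]) *
      (gregexpr(d, header_line, fixed = TRUE)[[1]][1] != -1)
  }, numeric(1))
  if (all(counts == 0)) {
    stop_elemap("could not detect a delimiter (tab, comma or semicolon) in the header",
                "elemap_format_error")
  }
  cands[which.max(counts)]
}

#' Read a delimited per-pixel intensity table
#'
#' Reads the text export of an LA-ICP-MS run: a header row naming the element
#' columns followed by the X and Y stage-coordinate columns, then one row per
#' ablation pixel.  All non-coordinate, non-amount columns become element
#' intensity channels; row order is preserved.
#'
#' @param path Path to the delimited text file.
#' @param dialect An [intensity_dialect()].
#' @return A [pixel_grid()].
#' @export
read_intensity_table <- function(path, dialect = intensity_dialect()) {
  if (!file.exists(path)) {
    stop_elemap(sprintf("file not found: %s", path), "elemap_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop_elemap("file is empty (no header row)", "elemap_format_error")
  }
  delim <- dialect$delimiter %||% detect_delimiter(lines[[1]], dialect$decimal)
  header <- trimws(strsplit(lines[[1]], delim, fixed = TRUE)[[1]])
  if (length(lines) == 1L) {
    stop_elemap("table has a header but no data rows", "elemap_empty_input")
  }
  rows <- strsplit(lines[-1], delim, fixed = TRUE)
  ncol <- length(header)
  bad <- which(lengths(rows) != ncol)
  if (length(bad)) {
    stop_elemap(sprintf("row %d has %d fields, expected %d",
                        bad[1] + 1L, lengths(rows)[bad[1]], ncol),
                "elemap_parse_error")
  }
  cells <- matrix(trimws(unlist(rows)), ncol = ncol, byrow = TRUE)

  find_coord <- function(axis) {
    pat <- dialect$coord_patterns[[axis]]
    hits <- grep(pat, header, ignore.case = TRUE)
    if (length(hits) == 0L) {
      stop_elemap(sprintf(
        "no %s-coordinate column: expected a trailing column matching /%s/ (case-insensitive)",
        axis, pat), "elemap_format_error")
    }
    max(hits)  # coordinate columns trail the element columns
  }
  xi <- find_coord("x")
  yi <- find_coord("y")
  if (xi == yi) {
    stop_elemap("x and y coordinate patterns matched the same column",
                "elemap_format_error")
  }

  to_num <- function(col_idx) {
    v <- cells[, col_idx]
    miss <- v %in% dialect$missing
    if (dialect$decimal == ",") v <- gsub(",", ".", v, fixed = TRUE)
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !miss)
    if (length(bad)) {
      stop_elemap(sprintf("non-numeric value '%s' at data row %d, column '%s'",
                          v[bad[1]], bad[1], header[col_idx]),
                  "elemap_parse_error")
    }
    out[miss] <- NA_real_
    out
  }

  xs <- to_num(xi)
  ys <- to_num(yi)
  if (anyNA(xs) || anyNA(ys)) {
    stop_elemap("coordinate columns contain missing values",
                "elemap_parse_error")
  }
  rest <- setdiff(seq_len(ncol), c(xi, yi))
  suf <- dialect$amount_suffix
  is_amount <- nzchar(suf) & endsWith(header[rest], suf)
  inten_idx <- rest[!is_amount]
  amt_idx <- rest[is_amount]
  if (length(inten_idx) == 0L) {
    stop_elemap("no element intensity columns found", "elemap_format_error")
  }
  intensity <- as.data.frame(lapply(inten_idx, to_num))
  names(intensity) <- header[inten_idx]
  amount <- NULL
  if (length(amt_idx)) {
    amount <- as.data.frame(lapply(amt_idx, to_num))
    names(amount) <- sub(paste0(suf, "$"), "", header[amt_idx])
  }
  pixel_grid(xs, ys, intensity, amount = amount, source = path)
}

#' Write a pixel grid as a delimited intensity table
#'
#' Inverse of [read_intensity_table()]: element columns, then amount columns
#' (suffixed), then `X`, `Y`. Values are written with 17 significant digits so
#' a round trip is bit-faithful.
#'
#' @param grid A [pixel_grid()].
#' @param path Output path.
#' @param delimiter Field separator (default tab).
#' @param amount_suffix Suffix for amount columns.
#' @export
write_intensity_table <- function(grid, path, delimiter = "\t",
                                  amount_suffix = "_ng") {
  fmt <- function(v) {
    out <- formatC(v, digits = 17, format = "g")
    out[is.na(v)] <- "NaN"
    trimws(out)
  }
  cols <- c(
    lapply(grid$elements, function(el) fmt(grid$intensity[[el]])),
    if (!is.null(grid$amount)) {
      lapply(colnames(grid$amount), function(el) fmt(grid$amount[[el]]))
    },
    list(fmt(grid$coords$x), fmt(grid$coords$y))
  )
  header <- c(grid$elements,
              if (!is.null(grid$amount)) paste0(colnames(grid$amount), amount_suffix),
              "X", "Y")
  mat <- do.call(cbind, cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = delimiter), con)
  writeLines(apply(mat, 1, paste, collapse = delimiter), con)
  invisible(path)
}

#' Read an ICP-ToF-MS HDF5 export (documented subset)
#'
#' Reads a minimal, documented HDF5 layout: a pixels-by-masses intensity
#' array, a vector of element labels, and x/y stage-coordinate vectors.  This
#' is deliberately not the full proprietary vendor schema; the four dataset
#' paths are configurable so exports can be mapped onto it.
#'
#' @param path HDF5 file.
#' @param layout Named list with dataset paths `intensity_path`,
#'   `labels_path`, `x_path`, `y_path`.
#' @return A [pixel_grid()] identical to what [read_intensity_table()] would
#'   return for the equivalent text table.
#' @export
read_tof_h5 <- function(path,
                        layout = list(intensity_path = "/data/intensity",
                                      labels_path = "/data/labels",
                                      x_path = "/data/x",
                                      y_path = "/data/y")) {
  if (!file.exists(path)) {
    stop_elemap(sprintf("file not found: %s", path), "elemap_io_error")
  }
  needed <- c("intensity_path", "labels_path", "x_path", "y_path")
  if (!all(needed %in% names(layout))) {
    stop_elemap(paste("layout must declare:", paste(needed, collapse = ", ")),
                "elemap_layout_error")
  }
  contents <- rhdf5::h5ls(path)
  available <- paste(sub("/$", "", contents$group), contents$name, sep = "/")
  available <- sub("^//", "/", available)
  for (key in needed) {
    p <- layout[[key]]
    if (!sub("^/", "", p) %in% sub("^/", "", available)) {
      stop_elemap(sprintf("dataset '%s' (%s) not in file; available: %s",
                          p, key, paste(available, collapse = ", ")),
                  "elemap_layout_error")
    }
  }
  inten <- rhdf5::h5read(path, layout$intensity_path)
  labels <- as.character(rhdf5::h5read(path, layout$labels_path))
  xs <- as.numeric(rhdf5::h5read(path, layout$x_path))
  ys <- as.numeric(rhdf5::h5read(path, layout$y_path))
  if (length(dim(inten)) != 2L) {
    stop_elemap("intensity dataset must be 2-D (pixels x masses)",
                "elemap_shape_error")
  }
  # Accept either orientation; rows must match the coordinate length.
  if (nrow(inten) != length(xs) && ncol(inten) == length(xs)) {
    inten <- t(inten)
  }
  if (nrow(inten) != length(xs) || length(xs) != length(ys)) {
    stop_elemap(sprintf(
      "intensity rows (%d) and coordinate lengths (x %d, y %d) disagree",
      nrow(inten), length(xs), length(ys)), "elemap_shape_error")
  }
  if (ncol(inten) != length(labels)) {
    stop_elemap(sprintf("intensity has %d mass columns but %d labels",
                        ncol(inten), length(labels)), "elemap_shape_error")
  }
  intensity <- as.data.frame(inten)
  names(intensity) <- labels
  pixel_grid(xs, ys, intensity, source = path)
}

#' Write the HDF5 subset layout (mainly for fixtures and interchange)
#' @param grid A [pixel_grid()].
#' @param path Output file (overwritten).
#' @param layout Dataset paths as in [read_tof_h5()].
#' @export
write_tof_h5 <- function(path, grid,
                         layout = list(intensity_path = "/data/intensity",
                                       labels_path = "/data/labels",
                                       x_path = "/data/x",
                                       y_path = "/data/y")) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  grp <- unique(dirname(unlist(layout)))
  for (g in setdiff(grp, "/")) rhdf5::h5createGroup(path, g)
  rhdf5::h5write(as.matrix(grid$intensity), path, layout$intensity_path)
  rhdf5::h5write(grid$elements, path, layout$labels_path)
  rhdf5::h5write(grid$coords$x, path, layout$x_path)
  rhdf5::h5write(grid$coords$y, path, layout$y_path)
  rhdf5::h5closeAll()
  invisible(path)
}
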