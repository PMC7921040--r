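#' Per-ROI descriptive statistics for one element
#'
#' For each ROI: pixel count, sum, mean, standard deviation, median,
#' variance, minimum and maximum of the element's per-pixel values.
#' Variance and standard deviation use the sample convention (n - 1); an
#' ROI with a single valid pixel reports them as `NA`, as does an empty
#' ROI for every statistic.  Pixels with a missing value are excluded per
#' ROI and counted in `n_missing`.
#'
#' @param grid A [pixel_grid()].
#' @param rois A [roi_mask_set()].
#' @param element Element label.
#' @param values Optional explicit per-pixel values (e.g. amounts) to
#'   summarize instead of the element's intensity column.
#' @return Data frame, one row per ROI, columns `roi, n_pixels, n_missing,
#'   sum, mean, sd, median, variance, min, max`.
#' @export
roi_summary <- function(grid, rois, element, values = NULL) {
  if (is.null(values)) {
    if (!element %in% grid$elements) {
      stop_elemap(sprintf("unknown element '%s'", element),
                  "elemap_config_error")
    }
    values <- grid$intensity[[element]]
  }
  if (length(values) != rois$n_pixels) {
    stop_elemap("values must have one entry per pixel", "elemap_shape_error")
  }
  rows <- lapply(rois$order, function(nm) {
    v <- values[rois$masks[[nm]]]
    n_missing <- sum(is.na(v))
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(
      roi = nm, element = element, n_pixels = n, n_missing = n_missing,
      sum = if (n) sum(v) else NA_real_,
      mean = if (n) mean(v) else NA_real_,
      sd = if (n > 1) stats::sd(v) else NA_real_,
      median = if (n) stats::median(v) else NA_real_,
      variance = if (n > 1) stats::var(v) else NA_real_,
      min = if (n) min(v) else NA_real_,
      max = if (n) max(v) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Read a calibration standard table
#'
#' CSV with columns `concentration` (analyte mass fraction or amount of the
#' spiked standards, e.g. agarose gels) and `intensity` (cps).
#'
#' @param path CSV file.
#' @param element Element label the calibration belongs to.
#' @param units Free-text units declaration for the concentration axis.
#' @return A `calibration_table`.
#' @export
read_calibration_table <- function(path, element, units = "ng") {
  df <- utils::read.csv(path)
  if (!all(c("concentration", "intensity") %in% names(df))) {
    stop_elemap("calibration table needs columns concentration, intensity",
                "elemap_format_error")
  }
  calibration_table(df$concentration, df$intensity, element, units)
}

#' @rdname read_calibration_table
#' @param concentration,intensity Numeric vectors of standards.
#' @export
calibration_table <- function(concentration, intensity, element,
                              units = "ng") {
  if (length(concentration) != length(intensity) || length(concentration) < 2L) {
    stop_elemap("need >= 2 (concentration, intensity) pairs of equal length",
                "elemap_validation_error")
  }
  if (any(concentration < 0)) {
    stop_elemap("concentrations must be non-negative", "elemap_validation_error")
  }
  if (length(unique(concentration)) < 2L) {
    stop_elemap("calibration needs at least two distinct concentrations",
                "elemap_degeneracy_error")
  }
  structure(list(concentration = as.numeric(concentration),
                 intensity = as.numeric(intensity),
                 element = element, units = units),
            class = "calibration_table")
}

#' Fit a linear calibration curve
#'
#' Ordinary least-squares line `intensity = slope * concentration +
#' intercept`.  The residual standard deviation is `sqrt(SSE / (n - 2))`
#' (`NA` for n = 2); detection and quantification limits follow the
#' 3.3-sigma / 10-sigma residual rule: `lod = 3.3 * residual_sd / |slope|`,
#' `loq = 10 * residual_sd / |slope|`.
#'
#' @param table A `calibration_table`.
#' @return A `calibration_curve` with `slope`, `intercept`, `r_squared`,
#'   `residual_sd`, `lod`, `loq`, `n_points`, `slope_se`, `usable`.
#' @export
fit_calibration <- function(table) {
  fit <- stats::lm(intensity ~ concentration, data = data.frame(
    concentration = table$concentration, intensity = table$intensity))
  smry <- suppressWarnings(summary(fit))  # exact lines trigger a precision note
  co <- stats::coef(fit)
  n <- length(table$concentration)
  sse <- sum(stats::residuals(fit)^2)
  residual_sd <- if (n >= 3) sqrt(sse / (n - 2)) else NA_real_
  slope <- unname(co[["concentration"]])
  usable <- slope != 0
  if (!usable) {
    warn_elemap("fitted slope is zero: curve flagged unusable",
                "elemap_unusable_curve_warning")
  }
  lod <- if (!is.na(residual_sd) && usable) 3.3 * residual_sd / abs(slope) else NA_real_
  loq <- if (!is.na(residual_sd) && usable) 10 * residual_sd / abs(slope) else NA_real_
  structure(list(element = table$element,
                 slope = slope,
                 intercept = unname(co[["(Intercept)"]]),
                 r_squared = smry$r.squared,
                 residual_sd = residual_sd,
                 slope_se = unname(smry$coefficients["concentration", "Std. Error"]),
                 lod = lod, loq = loq, n_points = n,
                 units = table$units, usable = usable),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: I = %.6g * c + %.6g  (r2 = %.4f, n = %d)\n",
              x$element, x$slope, x$intercept, x$r_squared, x$n_points))
  cat(sprintf("  residual sd %.4g, LOD %.4g, LOQ %.4g %s\n",
              x$residual_sd, x$lod, x$loq, x$units))
  invisible(x)
}

#' Serialize / read a calibration curve as JSON
#' @param curve A `calibration_curve`.
#' @param path File path.
#' @export
write_calibration_json <- function(curve, path) {
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert per-pixel intensity to amount via a calibration curve
#'
#' `amount_i = max(0, (I_i - intercept) / slope) * pixel_factor`. Negative
#' back-calculated amounts are floored at zero (a pixel cannot carry
#' negative mass); missing intensities give missing amounts.  Values whose
#' back-calculated concentration falls below the curve's detection limit
#' are kept but flagged in the `below_lod` attribute.
#'
#' @param grid A [pixel_grid()].
#' @param element Element label.
#' @param curve A `calibration_curve` from [fit_calibration()].
#' @param pixel_factor ng of analyte per concentration unit per pixel: the
#'   ablated mass/volume per pixel is instrument- and sample-specific and
#'   must be declared by the analyst.
#' @return Numeric vector of per-pixel amounts (ng) with attribute
#'   `below_lod` (logical).
#' @export
quantify_pixels <- function(grid, element, curve, pixel_factor) {
  if (!isTRUE(curve$usable)) {
    stop_elemap("calibration curve is unusable (zero slope)",
                "elemap_unusable_curve_error")
  }
  if (!is_scalar_number(pixel_factor) || pixel_factor <= 0) {
    stop_elemap("pixel_factor must be a positive number", "elemap_config_error")
  }
  if (!element %in% grid$elements) {
    stop_elemap(sprintf("unknown element '%s'", element), "elemap_config_error")
  }
  I <- grid$intensity[[element]]
  conc <- (I - curve$intercept) / curve$slope
  amount <- pmax(0, conc) * pixel_factor
  below <- if (is.na(curve$lod)) rep(FALSE, length(conc)) else conc < curve$lod
  below[is.na(conc)] <- NA
  attr(amount, "below_lod") <- below
  amount
}

#' Pass through per-pixel amounts quantified upstream
#'
#' Uses the amount column imported alongside the intensities (e.g. an
#' `"<element>_ng"` column quantified by the acquisition software).  Values
#' are passed through unchanged — negative upstream amounts are kept and
#' flagged, not clipped, to respect the upstream processing.
#'
#' @param grid A [pixel_grid()].
#' @param element Element label.
#' @return Numeric vector of per-pixel amounts with attribute `negative`
#'   (logical flags).
#' @export
import_amounts <- function(grid, element) {
  if (is.null(grid$amount) || !element %in% colnames(grid$amount)) {
    stop_elemap(sprintf(
      "grid carries no quantified amounts for '%s'; use quantify_pixels() with a calibration curve",
      element), "elemap_config_error")
  }
  v <- grid$amount[[element]]
  if (any(v < 0, na.rm = TRUE)) {
    warn_elemap(sprintf("%d negative upstream amount(s) for '%s' kept as-is",
                        sum(v < 0, na.rm = TRUE), element),
                "elemap_negative_amount_warning")
  }
  attr(v, "negative") <- !is.na(v) & v < 0
  v
}
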