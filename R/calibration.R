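# Linear calibration: OLS fit of peak area on concentration, intercept
# ignorability, external-standard inversion, and LOD/LOQ from an S/N model.

#' Fit a linear calibration curve
#'
#' Ordinary least squares of peak area (Y, mAU min) on concentration
#' (X, ug/mL). The validated range is set to the span of the fitted
#' concentrations.
#'
#' @param points A data.frame with columns `concentration` and `area`
#'   (at least 3 rows, at least 2 distinct concentrations).
#' @param analyte,wavelength Carried onto the returned curve.
#' @return A [calibration_curve()].
#' @export
fit_calibration <- function(points, analyte = "analyte", wavelength = NA) {
  if (!all(c("concentration", "area") %in% names(points)))
    stop("points needs columns 'concentration' and 'area'")
  x <- points$concentration
  y <- points$area
  if (length(x) < 3L) stop("at least 3 calibration points are required")
  if (any(x < 0)) stop("concentrations must be >= 0")
  if (length(unique(x)) < 2L)
    stop("degenerate design: all concentrations are equal")
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  calibration_curve(analyte, wavelength, slope = b[2], intercept = b[1],
                    r_squared = max(0, min(1, r2)),
                    range_low = min(x), range_high = max(x),
                    n_points = length(x))
}

#' Can the calibration intercept be ignored?
#'
#' The single-marker method drops the intercept and quantifies as X = Y / a.
#' That is justified when |a/b| exceeds 100, i.e. the intercept is small
#' relative to the slope and attributable to error.
#'
#' @param curve A [calibration_curve()].
#' @param threshold Ratio above which the intercept is ignorable (default 100).
#' @return A list with `ratio` (|a/b|, `Inf` when b = 0) and `ignorable`.
#' @export
intercept_ignorable <- function(curve, threshold = 100) {
  ratio <- if (curve$intercept == 0) Inf
  else abs(curve$slope / curve$intercept)
  list(ratio = ratio, ignorable = ratio > threshold)
}

#' Invert a calibration curve (external-standard quantitation)
#'
#' X = (Y - b) / a. A warning is raised when the result falls outside the
#' curve's validated range (diluted samples legitimately do), but the value is
#' still returned.
#'
#' @param curve A [calibration_curve()].
#' @param area Peak area Y (mAU min).
#' @return Concentration in ug/mL.
#' @export
invert_es <- function(curve, area) {
  conc <- (area - curve$intercept) / curve$slope
  if (!is.na(curve$range_low) && !is.na(curve$range_high) &&
      any(conc < curve$range_low | conc > curve$range_high))
    warning("concentration outside the validated range [",
            curve$range_low, ", ", curve$range_high, "] ug/mL for ",
            curve$analyte)
  conc
}

#' LOD and LOQ from a dilution series
#'
#' Fits peak height against concentration through the origin (S/N is a height
#' quantity) and converts the noise level: LOD = 3 sd / h and LOQ = 10 sd / h,
#' the concentrations at which S/N reaches 3 and 10.
#'
#' @param series A data.frame with columns `concentration` (ug/mL) and
#'   `height` (mAU), at least 3 points.
#' @param noise An [estimate_noise()] result with `sd > 0`.
#' @return An object of class `"lod_loq"` with fields `lod`, `loq` (ug/mL)
#'   and `height_slope` (mAU per ug/mL).
#' @export
lod_loq_from_series <- function(series, noise) {
  if (!all(c("concentration", "height") %in% names(series)))
    stop("series needs columns 'concentration' and 'height'")
  if (nrow(series) < 3L) stop("at least 3 dilution points are required")
  if (noise$sd <= 0) stop("noise standard deviation must be > 0")
  x <- series$concentration
  y <- series$height
  h <- sum(x * y) / sum(x * x)  # through-origin least squares
  if (h <= 0) stop("calibration error: non-positive height-response slope")
  structure(list(lod = 3 * noise$sd / h, loq = 10 * noise$sd / h,
                 height_slope = h),
            class = "lod_loq")
}

#' @export
print.lod_loq <- function(x, ...) {
  cat(sprintf("<lod_loq> LOD %.4g ug/mL, LOQ %.4g ug/mL (height slope %.4g)\n",
              x$lod, x$loq, x$height_slope))
  invisible(x)
}
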