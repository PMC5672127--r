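# The single-marker model (QAMS). One analyte - the internal reference - is
# calibrated against authentic standards; every other analyte is quantified
# through its relative correction factor f = a_K / a_S, the ratio of
# calibration slopes. Quantitation is then X = Y / (f * a_S), the
# intercept-free inversion justified when |a/b| > 100 for the curves involved.

#' Relative correction factor between two calibration curves
#'
#' f_K/S = a_K / a_S, the ratio of the analyte's calibration slope to the
#' reference's. Both curves should satisfy the intercept-ignorability rule
#' (|a/b| > 100); a warning is emitted otherwise since the intercept-free
#' quantitation then loses its justification.
#'
#' @param curve_k Analyte [calibration_curve()].
#' @param curve_s Reference [calibration_curve()].
#' @param check_intercepts Warn when either curve fails |a/b| > 100.
#' @return The unitless factor f.
#' @export
relative_correction_factor <- function(curve_k, curve_s,
                                       check_intercepts = TRUE) {
  if (curve_k$slope <= 0 || curve_s$slope <= 0)
    stop("calibration slopes must be > 0")
  if (check_intercepts) {
    for (cv in list(curve_k, curve_s))
      if (!intercept_ignorable(cv)$ignorable)
        warning("intercept of ", cv$analyte,
                " is not ignorable (|a/b| <= 100); the intercept-free",
                " single-marker form may be biased")
  }
  curve_k$slope / curve_s$slope
}

#' Fit a single-marker (QAMS) model
#'
#' Builds the table of relative correction factors from a set of per-analyte
#' calibration curves and a chosen internal reference. The returned object is
#' the package's central model: `coef()` gives the factors, `predict()`
#' quantifies peak areas, `summary()` reports slopes, intercept ratios and
#' factors per analyte.
#'
#' @param curves A named list of [calibration_curve()] objects, one per
#'   analyte (as from [read_calibration_table()] or [six_sterol_calibration()]).
#' @param reference Name of the internal-reference analyte.
#' @param check_intercepts Warn about curves violating |a/b| > 100.
#' @return An object of class `"qams"` with fields `reference`, `factors`
#'   (named, reference exactly 1), `wavelengths`, `reference_slope`, `curves`.
#' @examples
#' m <- qams(six_sterol_calibration(), reference = "cholesterol")
#' round(coef(m), 4)
#' @export
qams <- function(curves, reference, check_intercepts = TRUE) {
  if (length(curves) == 0L) stop("no calibration curves given")
  nm <- vapply(curves, function(cv) cv$analyte, character(1))
  if (anyDuplicated(nm)) stop("one calibration curve per analyte is required")
  names(curves) <- nm
  if (!reference %in% nm)
    stop("reference analyte '", reference, "' has no calibration curve")
  ref <- curves[[reference]]
  factors <- vapply(curves, function(cv)
    relative_correction_factor(cv, ref, check_intercepts = check_intercepts),
    numeric(1))
  factors[reference] <- 1  # exact by definition
  structure(
    list(reference = reference, factors = factors,
         wavelengths = vapply(curves, function(cv) cv$wavelength, numeric(1)),
         reference_slope = ref$slope, curves = curves),
    class = "qams"
  )
}

#' Build a relative-correction-factor table
#'
#' Alias of [qams()] kept for the pipeline vocabulary.
#' @inheritParams qams
#' @return A `"qams"` model object.
#' @export
build_rcf_table <- function(curves, reference, check_intercepts = TRUE) {
  qams(curves, reference, check_intercepts = check_intercepts)
}

#' @export
print.qams <- function(x, digits = 4, ...) {
  cat(sprintf("Single-marker (QAMS) model: reference %s (slope %g)\n",
              x$reference, x$reference_slope))
  cat("Relative correction factors:\n")
  print(round(x$factors, digits))
  invisible(x)
}

#' @export
coef.qams <- function(object, ...) object$factors

#' @export
summary.qams <- function(object, ...) {
  tab <- data.frame(
    analyte = names(object$factors),
    wavelength_nm = unname(object$wavelengths),
    slope = vapply(object$curves, function(cv) cv$slope, numeric(1)),
    intercept = vapply(object$curves, function(cv) cv$intercept, numeric(1)),
    a_over_b = vapply(object$curves, function(cv)
      intercept_ignorable(cv)$ratio, numeric(1)),
    intercept_ignorable = vapply(object$curves, function(cv)
      intercept_ignorable(cv)$ignorable, logical(1)),
    rcf = unname(object$factors),
    row.names = NULL
  )
  structure(list(reference = object$reference,
                 reference_slope = object$reference_slope, table = tab),
            class = "summary.qams")
}

#' @export
print.summary.qams <- function(x, ...) {
  cat(sprintf("Single-marker (QAMS) model - reference: %s\n\n", x$reference))
  print(x$table, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Quantify peak areas with a fitted QAMS model
#'
#' For method `"qams"` each area is converted with the intercept-free
#' single-marker form X = Y / (f * a_S); for `"es"` each analyte's own curve
#' is inverted, X = (Y - b) / a; `"both"` returns the two side by side with
#' their relative error (%, QAMS vs ES).
#'
#' @param object A `"qams"` model.
#' @param newdata A data.frame with columns `analyte` and `area`.
#' @param method `"qams"`, `"es"`, or `"both"`.
#' @param prep Optional [sample_prep()]; adds mass-fraction columns (ug/g).
#' @param ... Unused.
#' @return A data.frame with one row per input area.
#' @export
predict.qams <- function(object, newdata, method = c("qams", "es", "both"),
                         prep = NULL, ...) {
  method <- match.arg(method)
  if (!all(c("analyte", "area") %in% names(newdata)))
    stop("newdata needs columns 'analyte' and 'area'")
  unknown <- setdiff(newdata$analyte, names(object$factors))
  if (length(unknown))
    stop("analyte(s) not in the model: ", paste(unknown, collapse = ", "))
  out <- newdata[c("analyte", "area")]
  if (method %in% c("qams", "both"))
    out$conc_qams <- vapply(seq_len(nrow(out)), function(i)
      quantify_qams(out$area[i], object, out$analyte[i]), numeric(1))
  if (method %in% c("es", "both"))
    out$conc_es <- vapply(seq_len(nrow(out)), function(i)
      quantify_es(out$area[i], object$curves[[out$analyte[i]]]), numeric(1))
  if (method == "both")
    out$relative_error <- ifelse(out$conc_es != 0,
                                 100 * (out$conc_qams - out$conc_es) /
                                   out$conc_es, NA_real_)
  if (!is.null(prep)) {
    for (col in intersect(c("conc_qams", "conc_es"), names(out)))
      out[[sub("conc", "mass_fraction", col)]] <-
        to_mass_fraction(out[[col]], prep)
  }
  out
}

#' Single-marker quantitation of one area
#'
#' X = Y / (f * a_S): the area divided by the analyte's relative correction
#' factor times the reference slope.
#'
#' @param area Peak area Y (mAU min), >= 0.
#' @param rcf A `"qams"` model.
#' @param analyte Analyte name present in the model.
#' @return Concentration in ug/mL.
#' @export
quantify_qams <- function(area, rcf, analyte) {
  if (!analyte %in% names(rcf$factors))
    stop("analyte '", analyte, "' is not in the RCF table")
  if (any(area < 0)) stop("area must be >= 0")
  area / (rcf$factors[[analyte]] * rcf$reference_slope)
}

#' External-standard quantitation of one area
#'
#' Delegates to [invert_es()] on the analyte's own calibration curve.
#'
#' @param area Peak area (mAU min).
#' @param curve The analyte's [calibration_curve()].
#' @return Concentration in ug/mL.
#' @export
quantify_es <- function(area, curve) {
  invert_es(curve, area)
}

#' Relative retention time
#'
#' R = t_K / t_S, the ratio of the analyte's retention time to the internal
#' reference's. Invariant under uniform time rescaling (flow-rate changes),
#' which is why it locates peaks robustly across instruments.
#'
#' @param t_k Analyte retention time (min), > 0.
#' @param t_s Reference retention time (min), > 0.
#' @return Unitless ratio.
#' @export
relative_retention_time <- function(t_k, t_s) {
  if (any(t_k <= 0) || any(t_s <= 0))
    stop("retention times must be > 0")
  t_k / t_s
}

#' Assign detected peaks to panel analytes by relative retention time
#'
#' The reference peak is located first as the largest-area peak inside the
#' reference's absolute retention window; every peak's observed RTT is then
#' its apex time over the reference's. Each analyte takes the peak whose RTT
#' deviates least (as a fraction of the expected RTT) within `rtt_tolerance`;
#' assignment is greedy by smallest deviation, ties broken by larger area, and
#' no peak is assigned twice. Analytes with no candidate are reported absent.
#'
#' @param peaks List of [peak()] objects (one channel).
#' @param panel An [analyte_panel()]. Only its analytes are considered; use a
#'   subset for per-channel assignment.
#' @param rtt_tolerance Maximum fractional RTT deviation, in (0, 0.2].
#' @param reference_window Absolute retention window (min) in which the
#'   reference peak is sought; defaults to the panel's. Pass `NULL` to search
#'   the whole trace (the reference is then the largest-area peak overall).
#' @return A data.frame of class `"peak_assignment"`, one row per panel
#'   analyte: `analyte, assigned, apex_time, rtt_observed, rtt_expected,
#'   rtt_deviation, area, height, peak_index`.
#' @export
assign_peaks <- function(peaks, panel, rtt_tolerance = 0.05,
                         reference_window = panel$reference_window) {
  stopifnot(inherits(panel, "analyte_panel"))
  if (rtt_tolerance <= 0 || rtt_tolerance > 0.2)
    stop("rtt_tolerance must lie in (0, 0.2]")
  win <- reference_window
  apexes <- vapply(peaks, function(p) p$apex_time, numeric(1))
  areas <- vapply(peaks, function(p) p$area, numeric(1))
  cand_ref <- if (is.null(win)) seq_along(peaks)
  else which(apexes >= win[1] & apexes <= win[2])
  if (length(cand_ref) == 0L)
    stop("reference peak not found",
         if (!is.null(win)) paste0(" in window [", win[1], ", ", win[2], "]"))
  ref_idx <- cand_ref[which.max(areas[cand_ref])]
  t_s <- apexes[ref_idx]

  pan <- panel$analytes
  rtt_obs <- apexes / t_s
  # candidate (analyte, peak) pairs within tolerance
  cand <- do.call(rbind, lapply(seq_len(nrow(pan)), function(a) {
    dev <- (rtt_obs - pan$expected_rtt[a]) / pan$expected_rtt[a]
    ok <- which(abs(dev) <= rtt_tolerance)
    if (pan$name[a] == panel$reference) ok <- intersect(ok, ref_idx)
    if (length(ok) == 0L) return(NULL)
    data.frame(a = a, p = ok, dev = dev[ok], area = areas[ok])
  }))
  assigned <- data.frame(
    analyte = pan$name, assigned = FALSE, apex_time = NA_real_,
    rtt_observed = NA_real_, rtt_expected = pan$expected_rtt,
    rtt_deviation = NA_real_, area = NA_real_, height = NA_real_,
    peak_index = NA_integer_, stringsAsFactors = FALSE
  )
  if (!is.null(cand)) {
    cand <- cand[order(abs(cand$dev), -cand$area), , drop = FALSE]
    used_p <- integer(0)
    used_a <- integer(0)
    for (i in seq_len(nrow(cand))) {
      a <- cand$a[i]; p <- cand$p[i]
      if (a %in% used_a || p %in% used_p) next
      # ambiguity: another unused candidate for this analyte with identical
      # deviation magnitude and area
      twin <- cand$a == a & !(cand$p %in% used_p) & cand$p != p &
        abs(cand$dev) == abs(cand$dev[i]) & cand$area == cand$area[i]
      if (any(twin))
        stop("ambiguous assignment for ", pan$name[a],
             ": two candidate peaks with identical RTT deviation and area")
      assigned[a, c("assigned", "apex_time", "rtt_observed", "rtt_deviation",
                    "area", "height", "peak_index")] <-
        list(TRUE, apexes[p], rtt_obs[p], cand$dev[i], areas[p],
             peaks[[p]]$height, p)
      used_a <- c(used_a, a)
      used_p <- c(used_p, p)
    }
  }
  class(assigned) <- c("peak_assignment", "data.frame")
  attr(assigned, "reference_time") <- t_s
  assigned
}

#' Cosine similarity between two UV spectra
#'
#' Spectra are linearly resampled onto their common wavelength overlap,
#' mean-centred, and compared by cosine similarity; the score is scale
#' invariant, 1 for identical shapes and -1 for inverted ones.
#'
#' @param spectrum_a,spectrum_b data.frames with columns `wavelength` (nm)
#'   and `intensity`.
#' @param n_grid Number of resampling points (default 64).
#' @return Score in \[-1, 1\].
#' @export
spectral_similarity <- function(spectrum_a, spectrum_b, n_grid = 64) {
  for (s in list(spectrum_a, spectrum_b))
    if (!all(c("wavelength", "intensity") %in% names(s)))
      stop("spectra need columns 'wavelength' and 'intensity'")
  lo <- max(min(spectrum_a$wavelength), min(spectrum_b$wavelength))
  hi <- min(max(spectrum_a$wavelength), max(spectrum_b$wavelength))
  if (hi <= lo) stop("spectra have no common wavelength range")
  grid <- seq(lo, hi, length.out = n_grid)
  if (length(grid) < 5L) stop("at least 5 common wavelengths are required")
  a <- stats::approx(spectrum_a$wavelength, spectrum_a$intensity, grid)$y
  b <- stats::approx(spectrum_b$wavelength, spectrum_b$intensity, grid)$y
  a <- a - mean(a)
  b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("undefined score: zero-variance spectrum")
  sum(a * b) / (na * nb)
}

#' Convert extract concentration to mass fraction
#'
#' mass fraction (ug/g) = concentration (ug/mL) x extract volume (mL) /
#' sample mass (g).
#'
#' @param conc Concentration(s) in ug/mL.
#' @param prep A [sample_prep()].
#' @return Mass fraction(s) in ug/g.
#' @export
to_mass_fraction <- function(conc, prep) {
  stopifnot(inherits(prep, "sample_prep"))
  conc * prep$extract_volume / prep$sample_mass
}

#' Compare external-standard and single-marker results
#'
#' Per-analyte relative error RE% = 100 (QAMS - ES) / ES, plus the maximum
#' absolute RE and a flag when it exceeds the acceptance threshold.
#'
#' @param es Named numeric vector of external-standard values (> 0).
#' @param qams Named numeric vector of single-marker values, same analytes.
#' @param threshold Flagging threshold in percent (default 2).
#' @return A list with `relative_error` (named, %), `max_abs_re` and
#'   `flagged`.
#' @export
compare_methods <- function(es, qams, threshold = 2) {
  if (is.null(names(es)) || is.null(names(qams)))
    stop("es and qams must be named by analyte")
  if (!setequal(names(es), names(qams)))
    stop("es and qams cover different analytes")
  qams <- qams[names(es)]
  if (any(es <= 0)) stop("relative error undefined: ES value <= 0")
  re <- 100 * (qams - es) / es
  list(relative_error = re, max_abs_re = max(abs(re)),
       flagged = max(abs(re)) > threshold)
}
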