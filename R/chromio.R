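# Unit convention, fixed package-wide: times in minutes, intensities in mAU,
# concentrations in ug/mL, mass fractions in ug/g, wavelengths in nm.
# No unit inference is performed anywhere.

#' Construct a single-channel chromatogram
#'
#' A chromatogram is a detector trace sampled on a strictly increasing time
#' grid at one detection wavelength, with free-form acquisition metadata
#' (column, flow rate, temperature, instrument id, ...).
#'
#' @param times Numeric vector of sampling times in minutes, strictly
#'   increasing, length at least 8.
#' @param intensities Numeric vector of detector response in mAU, same length
#'   as `times`.
#' @param wavelength Detection wavelength in nm (positive scalar).
#' @param meta Named list of free-form metadata.
#' @return An object of class `"chromatogram"`.
#' @export
chromatogram <- function(times, intensities, wavelength, meta = list()) {
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities))
    stop("times and intensities must have equal length")
  if (length(times) < 8L)
    stop("insufficient data: a chromatogram needs at least 8 samples, got ",
         length(times))
  if (anyNA(times) || anyNA(intensities))
    stop("times and intensities must be finite")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  wavelength <- as.numeric(wavelength)
  if (length(wavelength) != 1L || is.na(wavelength) || wavelength <= 0)
    stop("wavelength must be a single positive number (nm)")
  structure(
    list(times = times, intensities = intensities,
         wavelength = wavelength, meta = meta),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %d points, %.3f-%.3f min, %g nm\n",
              length(x$times), min(x$times), max(x$times), x$wavelength))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.chromatogram <- function(x) length(x$times)

#' Construct a chromatographic peak
#'
#' @param apex_time Retention time of the apex (min).
#' @param start_time,end_time Integration bounds (min), bracketing the apex.
#' @param height Baseline-corrected apex height (mAU).
#' @param area Baseline-corrected peak area (mAU min).
#' @param width_half Full width at half of the baseline-corrected height (min).
#' @param analyte Optional analyte name once assigned.
#' @return An object of class `"chrom_peak"`.
#' @export
peak <- function(apex_time, start_time, end_time, height, area, width_half,
                 analyte = NA_character_) {
  if (!(start_time < apex_time && apex_time < end_time))
    stop("peak bounds must satisfy start_time < apex_time < end_time")
  if (height < 0 || area < 0) stop("peak height and area must be >= 0")
  if (width_half <= 0) stop("width_half must be > 0")
  structure(
    list(apex_time = apex_time, start_time = start_time, end_time = end_time,
         height = height, area = area, width_half = width_half,
         analyte = analyte),
    class = "chrom_peak"
  )
}

#' @export
print.chrom_peak <- function(x, ...) {
  cat(sprintf(
    "<peak%s> apex %.3f min [%.3f, %.3f], height %.3g mAU, area %.4g mAU.min\n",
    if (is.na(x$analyte)) "" else paste0(" ", x$analyte),
    x$apex_time, x$start_time, x$end_time, x$height, x$area))
  invisible(x)
}

#' Construct a linear calibration curve
#'
#' Linear response Y = a X + b with Y the peak area (mAU min) and X the
#' concentration (ug/mL), as fitted over a dilution series.
#'
#' @param analyte Analyte name.
#' @param wavelength Detection wavelength (nm).
#' @param slope Slope a (area per ug/mL); must be positive.
#' @param intercept Intercept b (area units).
#' @param r_squared Coefficient of determination in [0, 1] (NA if unknown).
#' @param range_low,range_high Validated concentration range (ug/mL).
#' @param n_points Number of calibration levels.
#' @return An object of class `"calibration_curve"`.
#' @export
calibration_curve <- function(analyte, wavelength, slope, intercept,
                              r_squared = NA_real_,
                              range_low = NA_real_, range_high = NA_real_,
                              n_points = NA_integer_) {
  if (!is.character(analyte) || length(analyte) != 1L || !nzchar(analyte))
    stop("analyte must be a non-empty name")
  if (slope <= 0) stop("calibration slope must be > 0 (analyte ", analyte, ")")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must lie in [0, 1]")
  if (!is.na(range_low) && !is.na(range_high) && range_low >= range_high)
    stop("range_low must be < range_high")
  structure(
    list(analyte = analyte, wavelength = as.numeric(wavelength),
         slope = as.numeric(slope), intercept = as.numeric(intercept),
         r_squared = as.numeric(r_squared),
         range_low = as.numeric(range_low), range_high = as.numeric(range_high),
         n_points = as.integer(n_points)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration> %s @ %g nm: Y = %g X %s %g (R2 = %s)\n",
              x$analyte, x$wavelength, x$slope,
              if (x$intercept < 0) "-" else "+", abs(x$intercept),
              format(x$r_squared)))
  invisible(x)
}

#' Construct an analyte panel
#'
#' The panel declares, per analyte, the detection wavelength, the expected
#' relative retention time (RTT) versus the internal reference, and the stock
#' concentration of the mixed standard. The reference analyte always carries
#' expected RTT 1.
#'
#' @param analytes A data.frame with columns `name`, `wavelength`,
#'   `expected_rtt`, `stock`.
#' @param reference Name of the internal-reference analyte (must be a row).
#' @param reference_window Optional numeric length-2: the absolute retention
#'   window (min) in which the reference peak is sought.
#' @return An object of class `"analyte_panel"`.
#' @export
analyte_panel <- function(analytes, reference, reference_window = NULL) {
  req <- c("name", "wavelength", "expected_rtt", "stock")
  if (!all(req %in% names(analytes)))
    stop("panel analytes need columns: ", paste(req, collapse = ", "))
  analytes <- as.data.frame(analytes, stringsAsFactors = FALSE)
  if (anyDuplicated(analytes$name))
    stop("duplicate analyte names in panel")
  if (!reference %in% analytes$name)
    stop("reference analyte '", reference, "' is not in the panel")
  if (any(analytes$stock <= 0))
    stop("stock concentrations must be > 0")
  analytes$expected_rtt[analytes$name == reference] <- 1.0
  if (anyNA(analytes$expected_rtt) || any(analytes$expected_rtt <= 0))
    stop("expected RTTs must be > 0")
  if (!is.null(reference_window)) {
    reference_window <- as.numeric(reference_window)
    if (length(reference_window) != 2L ||
        reference_window[1] >= reference_window[2])
      stop("reference_window must be c(low, high) with low < high")
  }
  structure(
    list(analytes = analytes, reference = reference,
         reference_window = reference_window),
    class = "analyte_panel"
  )
}

#' @export
print.analyte_panel <- function(x, ...) {
  cat(sprintf("<analyte_panel> %d analytes, reference: %s\n",
              nrow(x$analytes), x$reference))
  print(x$analytes, row.names = FALSE)
  invisible(x)
}

#' Sample preparation record
#'
#' Captures the mass of dried material extracted and the final extract volume,
#' used to convert extract concentrations (ug/mL) to mass fractions (ug/g).
#'
#' @param sample_mass Mass of powdered sample (g).
#' @param extract_volume Final extract volume (mL).
#' @return An object of class `"sample_prep"`.
#' @export
sample_prep <- function(sample_mass, extract_volume) {
  if (sample_mass <= 0 || extract_volume <= 0)
    stop("sample_mass and extract_volume must be > 0")
  structure(list(sample_mass = sample_mass, extract_volume = extract_volume),
            class = "sample_prep")
}

# ---- chromatogram I/O -------------------------------------------------------

#' Read a chromatogram from delimited text
#'
#' Reads a comma-separated trace with a mandatory header and an optional
#' `#`-prefixed metadata block (`# wavelength_nm: 205`, `# key: value`).
#' Single-channel files carry columns `time_min,intensity_mAU`; wide files may
#' carry one intensity column per channel (e.g. `intensity_205`), in which case
#' `wavelength` selects the channel.
#'
#' @param path Path to the file (or a connection).
#' @param wavelength Channel to extract (nm). Optional for single-channel
#'   files that record the wavelength in the metadata block.
#' @return A [chromatogram()].
#' @export
read_chromatogram <- function(path, wavelength = NULL) {
  lines <- readLines(path)
  is_meta <- grepl("^\\s*#", lines)
  meta <- parse_meta_block(lines[is_meta])
  body <- lines[!is_meta]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L)
    stop("insufficient data: no rows found in ", path)
  dat <- utils::read.csv(text = body, check.names = FALSE,
                         colClasses = NA, stringsAsFactors = FALSE)
  if (!"time_min" %in% names(dat))
    stop("chromatogram file must have a 'time_min' column")
  # map each malformed body row back to its file line for error reporting
  for (j in seq_along(dat)) {
    if (!is.numeric(dat[[j]])) {
      coerced <- suppressWarnings(as.numeric(dat[[j]]))
      row <- which(is.na(coerced) & !is.na(dat[[j]]))[1]
      if (!is.na(row)) {
        line_no <- which(!is_meta)[row + 1L]  # +1 for the header row
        stop("malformed value in column '", names(dat)[j], "' at line ",
             line_no, " of ", path)
      }
      dat[[j]] <- coerced
    }
  }
  int_cols <- setdiff(names(dat), "time_min")
  if (length(int_cols) == 0L) stop("no intensity column found")
  if (length(int_cols) == 1L && int_cols == "intensity_mAU") {
    col <- "intensity_mAU"
    if (is.null(wavelength)) {
      wavelength <- meta[["wavelength_nm"]]
      if (is.null(wavelength))
        stop("wavelength not given and not recorded in the file header")
      wavelength <- as.numeric(wavelength)
    }
  } else {
    if (is.null(wavelength))
      stop("multi-channel file: a wavelength must be requested")
    want <- as.character(as.numeric(wavelength))
    hits <- int_cols[sub("^intensity_?", "", int_cols) == want |
                       int_cols == want]
    if (length(hits) != 1L)
      stop("channel ", wavelength, " nm not found among: ",
           paste(int_cols, collapse = ", "))
    col <- hits
  }
  meta[["wavelength_nm"]] <- NULL
  chromatogram(dat$time_min, dat[[col]], wavelength = wavelength, meta = meta)
}

parse_meta_block <- function(lines) {
  meta <- list()
  for (ln in lines) {
    ln <- sub("^\\s*#\\s*", "", ln)
    if (!grepl(":", ln, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  meta
}

#' Write a chromatogram to delimited text
#'
#' Emits the `#`-prefixed metadata block (wavelength first), a header, and one
#' row per sample at full double precision, so that [read_chromatogram()]
#' inverts it exactly.
#'
#' @param chrom A [chromatogram()].
#' @param path Output path (or connection).
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  hdr <- c(sprintf("# wavelength_nm: %s", format(chrom$wavelength)),
           vapply(names(chrom$meta), function(k)
             sprintf("# %s: %s", k, format(chrom$meta[[k]])), character(1)))
  rows <- sprintf("%.17g,%.17g", chrom$times, chrom$intensities)
  writeLines(c(hdr, "time_min,intensity_mAU", rows), path)
  invisible(NULL)
}

# ---- calibration table I/O --------------------------------------------------

#' Read a calibration table
#'
#' Expects columns `analyte, wavelength_nm, slope, intercept, r_squared,
#' range_low, range_high` (optionally `n_points`), one row per analyte and
#' channel.
#'
#' @param path CSV path.
#' @return A named list of [calibration_curve()] objects (names = analytes).
#' @export
read_calibration_table <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(dat) == 0L) return(structure(list(), names = character(0)))
  req <- c("analyte", "wavelength_nm", "slope", "intercept", "r_squared",
           "range_low", "range_high")
  if (!all(req %in% names(dat)))
    stop("calibration table needs columns: ", paste(req, collapse = ", "))
  key <- paste(dat$analyte, dat$wavelength_nm)
  if (anyDuplicated(key))
    stop("duplicate (analyte, wavelength) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  curves <- lapply(seq_len(nrow(dat)), function(i)
    calibration_curve(dat$analyte[i], dat$wavelength_nm[i], dat$slope[i],
                      dat$intercept[i], dat$r_squared[i],
                      dat$range_low[i], dat$range_high[i],
                      if ("n_points" %in% names(dat)) dat$n_points[i]
                      else NA_integer_))
  names(curves) <- dat$analyte
  curves
}

#' Write a calibration table
#'
#' @param curves A list of [calibration_curve()] objects.
#' @param path Output CSV path.
#' @export
write_calibration_table <- function(curves, path) {
  dat <- do.call(rbind, lapply(curves, function(cv)
    data.frame(analyte = cv$analyte, wavelength_nm = cv$wavelength,
               slope = cv$slope, intercept = cv$intercept,
               r_squared = cv$r_squared, range_low = cv$range_low,
               range_high = cv$range_high, n_points = cv$n_points)))
  utils::write.csv(dat, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Published six-sterol calibration table
#'
#' Returns the six validated HPLC-DAD calibration lines for the Oviductus
#' Ranae sterol panel (cholesterol, stigmasterol, 7-hydroxycholesterol at
#' 205 nm; 7-ketocholesterol and 4-cholesten-3-one at 240 nm;
#' 7-dehydrocholesterol at 280 nm), shipped with the package as instrument
#' constants.
#'
#' @return A named list of [calibration_curve()] objects.
#' @export
six_sterol_calibration <- function() {
  read_calibration_table(system.file("extdata", "six_sterol_calibration.csv",
                                     package = "qamskit", mustWork = TRUE))
}

# ---- panel I/O --------------------------------------------------------------

#' Load an analyte panel from a YAML/JSON-style configuration
#'
#' @param source Path to a YAML document, or an already-parsed list with
#'   entries `reference`, `analytes` (each `name`, `wavelength`,
#'   `expected_rtt`, `stock`) and optionally `reference_window`.
#' @return An [analyte_panel()]. The reference's expected RTT is forced to 1.
#' @export
load_panel <- function(source) {
  cfg <- if (is.character(source)) yaml::read_yaml(source) else source
  if (is.null(cfg$reference))
    stop("panel configuration must name a reference analyte")
  if (is.null(cfg$analytes) || length(cfg$analytes) == 0L)
    stop("panel configuration lists no analytes")
  rows <- lapply(cfg$analytes, function(a) {
    if (is.null(a$name)) stop("every panel analyte needs a name")
    if (is.null(a$stock) || a$stock < 0)
      stop("analyte '", a$name, "': stock concentration must be positive")
    data.frame(name = a$name, wavelength = as.numeric(a$wavelength),
               expected_rtt = as.numeric(if (is.null(a$expected_rtt)) NA
                                         else a$expected_rtt),
               stock = as.numeric(a$stock), stringsAsFactors = FALSE)
  })
  analyte_panel(do.call(rbind, rows), reference = cfg$reference,
                reference_window = cfg$reference_window)
}

#' Built-in six-sterol panel
#'
#' The default panel: six sterols with their detection wavelengths, stock
#' concentrations of the mixed standard, and synthetic expected relative
#' retention times versus the cholesterol reference.
#'
#' @return An [analyte_panel()].
#' @export
six_sterol_panel <- function() {
  load_panel(system.file("extdata", "panel_six_sterols.yaml",
                         package = "qamskit", mustWork = TRUE))
}

# ---- peak table I/O ---------------------------------------------------------

#' Convert a list of peaks to a data.frame
#' @param peaks List of [peak()] objects.
#' @return data.frame with one row per peak.
#' @export
peaks_to_table <- function(peaks) {
  if (length(peaks) == 0L)
    return(data.frame(analyte = character(0), apex_time = numeric(0),
                      start = numeric(0), end = numeric(0),
                      height = numeric(0), area = numeric(0),
                      width_half = numeric(0)))
  do.call(rbind, lapply(peaks, function(p)
    data.frame(analyte = p$analyte, apex_time = p$apex_time,
               start = p$start_time, end = p$end_time, height = p$height,
               area = p$area, width_half = p$width_half,
               stringsAsFactors = FALSE)))
}

#' Write a peak table CSV
#' @param peaks List of [peak()] objects.
#' @param path Output path.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.csv(peaks_to_table(peaks), path, row.names = FALSE,
                   quote = FALSE)
  invisible(NULL)
}
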