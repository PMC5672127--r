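# End-to-end sample quantitation: baseline -> peaks -> RTT assignment ->
# external-standard and single-marker concentrations -> mass fractions.

#' Process one chromatogram channel
#'
#' Convenience wrapper: baseline estimation, noise estimation in a peak-free
#' leading region, and peak detection.
#'
#' @param chrom A [chromatogram()].
#' @param baseline_window Baseline window (min).
#' @param min_height Detection threshold (mAU above baseline).
#' @param min_width Minimum width at half height (min).
#' @param noise_region Length-2 numeric, the peak-free region for noise
#'   estimation (min); NULL skips it.
#' @return A list: `baseline`, `peaks`, `noise` (or NULL).
#' @export
process_chromatogram <- function(chrom, baseline_window = 1.0,
                                 min_height = 10, min_width = 0.02,
                                 noise_region = c(0.3, 2.0)) {
  bl <- estimate_baseline(chrom, baseline_window)
  pk <- detect_peaks(chrom, bl, min_height = min_height,
                     min_width = min_width)
  nz <- if (!is.null(noise_region))
    estimate_noise(chrom, noise_region[1], noise_region[2], peaks = pk)
  list(baseline = bl, peaks = pk, noise = nz)
}

#' Quantify a multi-channel sample acquisition
#'
#' Runs detection and relative-retention-time assignment on every channel,
#' then quantifies each analyte from the peak found on its own detection
#' wavelength, by both the external-standard and single-marker methods.
#'
#' @param chroms Named list of [chromatogram()] objects, names = wavelength
#'   (e.g. `"205"`), covering every channel the panel uses.
#' @param panel An [analyte_panel()].
#' @param model A fitted [qams()] model (provides both the factors and the
#'   per-analyte curves for the external standard).
#' @param prep Optional [sample_prep()] for mass fractions.
#' @param rtt_tolerance Fractional RTT matching tolerance.
#' @param ... Passed to [process_chromatogram()].
#' @return A data.frame, one row per panel analyte: assignment details,
#'   area, `conc_es`, `conc_qams`, `relative_error` (%), and mass fractions
#'   when `prep` is given.
#' @export
quantify_sample <- function(chroms, panel, model, prep = NULL,
                            rtt_tolerance = 0.05, ...) {
  stopifnot(inherits(panel, "analyte_panel"), inherits(model, "qams"))
  channels <- sort(unique(panel$analytes$wavelength))
  missing_ch <- setdiff(as.character(channels), names(chroms))
  if (length(missing_ch))
    stop("no chromatogram supplied for channel(s): ",
         paste(missing_ch, collapse = ", "))
  per_channel <- lapply(as.character(channels), function(ch) {
    proc <- process_chromatogram(chroms[[ch]], ...)
    assign_peaks(proc$peaks, panel, rtt_tolerance = rtt_tolerance)
  })
  names(per_channel) <- as.character(channels)

  pan <- panel$analytes
  rows <- lapply(seq_len(nrow(pan)), function(i) {
    ch <- as.character(pan$wavelength[i])
    asn <- per_channel[[ch]]
    row <- asn[asn$analyte == pan$name[i], , drop = FALSE]
    class(row) <- "data.frame"
    row
  })
  out <- do.call(rbind, rows)
  out$wavelength <- pan$wavelength
  out$conc_es <- NA_real_
  out$conc_qams <- NA_real_
  for (i in seq_len(nrow(out))) {
    if (!out$assigned[i]) next
    a <- out$analyte[i]
    out$conc_qams[i] <- quantify_qams(out$area[i], model, a)
    out$conc_es[i] <- quantify_es(out$area[i], model$curves[[a]])
  }
  out$relative_error <- ifelse(
    !is.na(out$conc_es) & out$conc_es != 0,
    100 * (out$conc_qams - out$conc_es) / out$conc_es, NA_real_)
  if (!is.null(prep)) {
    out$mass_fraction_es <- to_mass_fraction(out$conc_es, prep)
    out$mass_fraction_qams <- to_mass_fraction(out$conc_qams, prep)
  }
  rownames(out) <- NULL
  out
}
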