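# Synthetic HPLC-DAD acquisitions with known ground truth. Peaks are Gaussian
# with area = calibration slope x concentration on the analyte's own channel
# and a fixed fractional response on the other channels; the trace adds a
# linear drift and i.i.d. Gaussian detector noise. Retention times receive a
# shared multiplicative run factor (flow-rate variation: all peaks move
# together, so relative retention times are preserved) plus a small
# independent per-peak jitter. Everything is reproducible under a fixed seed.

#' Ground truth for a simulated acquisition
#'
#' @param concentrations Named numeric vector, ug/mL per analyte (>= 0).
#' @param apex_times Named numeric vector, nominal retention times (min).
#' @param sigmas Named numeric vector, Gaussian peak widths (min, > 0).
#' @param slopes Named numeric vector, on-channel response (area per ug/mL).
#' @param noise_sd Detector noise standard deviation (mAU).
#' @param drift Linear baseline drift (mAU per min).
#' @param baseline_level Constant baseline offset (mAU).
#' @param rt_jitter_sd Standard deviation of the shared multiplicative
#'   retention factor (fraction; emulates run-to-run flow variation).
#' @param rt_jitter_peak_sd Standard deviation of the per-peak multiplicative
#'   jitter (fraction).
#' @param off_channel_response Fractional response of each analyte on
#'   channels other than its own.
#' @return An object of class `"simulation_truth"`.
#' @export
simulation_truth <- function(concentrations, apex_times, sigmas, slopes,
                             noise_sd = 0.2, drift = 0.1,
                             baseline_level = 2.0,
                             rt_jitter_sd = 0.008,
                             rt_jitter_peak_sd = 0.002,
                             off_channel_response = 0.10) {
  nm <- names(concentrations)
  if (is.null(nm) || !setequal(nm, names(apex_times)) ||
      !setequal(nm, names(sigmas)) || !setequal(nm, names(slopes)))
    stop("concentrations, apex_times, sigmas and slopes must be named",
         " consistently by analyte")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (any(sigmas <= 0)) stop("peak sigmas must be > 0")
  if (any(slopes <= 0)) stop("response slopes must be > 0")
  structure(
    list(concentrations = concentrations, apex_times = apex_times[nm],
         sigmas = sigmas[nm], slopes = slopes[nm], noise_sd = noise_sd,
         drift = drift, baseline_level = baseline_level,
         rt_jitter_sd = rt_jitter_sd, rt_jitter_peak_sd = rt_jitter_peak_sd,
         off_channel_response = off_channel_response),
    class = "simulation_truth"
  )
}

#' Default simulation truth for the six-sterol panel
#'
#' Response slopes come from the published calibration table at each
#' analyte's own channel; retention times and peak widths are synthetic
#' (invented for simulation - the validated elution order is preserved but
#' no published retention times exist).
#'
#' @param panel An [analyte_panel()] (default [six_sterol_panel()]).
#' @param concentrations Optional named concentrations; defaults to
#'   mid-range sample-like extract concentrations (ug/mL).
#' @param ... Passed on to [simulation_truth()] (noise, drift, jitter, ...).
#' @return A `"simulation_truth"`.
#' @export
default_truth <- function(panel = six_sterol_panel(),
                          concentrations = NULL, ...) {
  curves <- six_sterol_calibration()
  nm <- panel$analytes$name
  if (!all(nm %in% names(curves)))
    stop("no published calibration slope for: ",
         paste(setdiff(nm, names(curves)), collapse = ", "))
  apex <- c("7-hydroxycholesterol" = 4.6, "7-ketocholesterol" = 6.1,
            "4-cholesten-3-one" = 7.9, "7-dehydrocholesterol" = 9.4,
            "cholesterol" = 11.2, "stigmasterol" = 13.6)
  sig <- c("7-hydroxycholesterol" = 0.060, "7-ketocholesterol" = 0.062,
           "4-cholesten-3-one" = 0.066, "7-dehydrocholesterol" = 0.070,
           "cholesterol" = 0.080, "stigmasterol" = 0.090)
  if (!all(nm %in% names(apex)))
    stop("no default retention time for: ",
         paste(setdiff(nm, names(apex)), collapse = ", "))
  if (is.null(concentrations)) {
    conc <- c("cholesterol" = 3000, "7-hydroxycholesterol" = 67,
              "7-ketocholesterol" = 16.8, "4-cholesten-3-one" = 7.5,
              "stigmasterol" = 13.4, "7-dehydrocholesterol" = 4.9)
    concentrations <- conc[nm]
  }
  simulation_truth(concentrations[nm], apex[nm], sig[nm],
                   vapply(curves[nm], function(cv) cv$slope, numeric(1)), ...)
}

#' Simulate one chromatogram channel
#'
#' @param truth A [simulation_truth()].
#' @param panel An [analyte_panel()] mapping analytes to their own channels.
#' @param wavelength Channel to render (nm).
#' @param duration Trace length (min); must cover every apex + 5 sigma.
#' @param dt Sampling interval (min); must be at most min(sigma) / 5.
#' @param seed Integer seed. The retention jitters are drawn from `seed`
#'   alone, so all channels of one run share identical retention times (as a
#'   diode-array detector records them); noise is channel specific.
#' @return A list: `chromatogram` (a [chromatogram()]) and `apex_times`
#'   (named numeric, the realised retention times).
#' @export
simulate_chromatogram <- function(truth, panel, wavelength,
                                  duration = 16, dt = 0.008, seed = 1) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(panel, "analyte_panel"))
  if (dt > min(truth$sigmas) / 5)
    stop("dt = ", dt, " min is too coarse: must be at most min(sigma)/5 = ",
         format(min(truth$sigmas) / 5))
  if (duration < max(truth$apex_times) + 5 * max(truth$sigmas))
    stop("duration does not cover all apexes + 5 sigma")
  nm <- names(truth$concentrations)
  set.seed(as.integer(seed))
  run_factor <- stats::rnorm(1, 1, truth$rt_jitter_sd)
  peak_factor <- stats::rnorm(length(nm), 1, truth$rt_jitter_peak_sd)
  apex <- truth$apex_times * run_factor * peak_factor
  names(apex) <- nm

  t <- seq(0, duration, by = dt)
  y <- truth$baseline_level + truth$drift * t
  own <- panel$analytes$wavelength[match(nm, panel$analytes$name)]
  for (i in seq_along(nm)) {
    conc <- truth$concentrations[[i]]
    if (conc == 0) next
    resp <- if (isTRUE(own[i] == wavelength)) truth$slopes[[i]]
    else truth$off_channel_response * truth$slopes[[i]]
    area <- resp * conc
    y <- y + area * stats::dnorm(t, apex[[i]], truth$sigmas[[i]])
  }
  set.seed((as.integer(seed) %% 1000003L) * 1009L + as.integer(wavelength))
  if (truth$noise_sd > 0)
    y <- y + stats::rnorm(length(t), 0, truth$noise_sd)
  list(
    chromatogram = chromatogram(t, y, wavelength,
                                meta = list(instrument = "synthetic",
                                            seed = seed)),
    apex_times = apex
  )
}

#' Simulate an injection-volume calibration series
#'
#' One acquisition per injection level; the effective on-column content of
#' each analyte is its stock concentration times the volume fraction (the
#' default fractions correspond to 5-60 uL injections relative to a 20 uL
#' reference).
#'
#' @param panel An [analyte_panel()] (stocks supply the level-1
#'   concentrations).
#' @param truth A [simulation_truth()]; its concentrations are overridden per
#'   level. Defaults to [default_truth()] for the panel.
#' @param volume_fractions Positive injection-volume fractions.
#' @param seed Integer seed (each level derives its own).
#' @param ... Passed to [simulate_chromatogram()] (duration, dt).
#' @return A list with one record per level: `fraction`, `concentrations`
#'   (named effective ug/mL), `chromatograms` (named list by channel),
#'   `apex_times`.
#' @export
simulate_calibration_series <- function(panel, truth = NULL,
                                        volume_fractions =
                                          c(0.25, 0.5, 0.75, 1,
                                            1.5, 2, 2.5, 3),
                                        seed = 1, ...) {
  if (length(volume_fractions) == 0L)
    stop("volume_fractions must be non-empty")
  if (any(volume_fractions <= 0)) stop("volume_fractions must be > 0")
  if (is.null(truth)) truth <- default_truth(panel)
  stock <- stats::setNames(panel$analytes$stock, panel$analytes$name)
  channels <- sort(unique(panel$analytes$wavelength))
  lapply(seq_along(volume_fractions), function(i) {
    fr <- volume_fractions[i]
    truth_i <- truth
    truth_i$concentrations <- stock[names(truth$concentrations)] * fr
    seed_i <- (as.integer(seed) %% 1000003L) * 131L + i
    runs <- lapply(channels, function(wl)
      simulate_chromatogram(truth_i, panel, wl, seed = seed_i, ...))
    names(runs) <- as.character(channels)
    list(fraction = fr,
         concentrations = truth_i$concentrations,
         chromatograms = lapply(runs, `[[`, "chromatogram"),
         apex_times = runs[[1]]$apex_times)
  })
}

#' Simulate a multi-batch sample study
#'
#' Each batch draws per-analyte extract concentrations uniformly within the
#' given ranges and renders the full multi-channel chromatogram set, paired
#' with its ground truth and the sample-preparation record.
#'
#' @param n_batches Number of batches (>= 1; the reference study used 14).
#' @param panel An [analyte_panel()].
#' @param concentration_ranges Named list/matrix: analyte -> c(low, high) in
#'   ug/mL. Defaults to sample-like extract ranges for the six-sterol panel.
#' @param truth Base [simulation_truth()] (concentrations overridden).
#' @param prep A [sample_prep()] shared by all batches (default 2 g / 2 mL).
#' @param seed Integer seed.
#' @param ... Passed to [simulate_chromatogram()].
#' @return A list with one record per batch: `batch`, `concentrations`,
#'   `chromatograms` (named by channel), `apex_times`, `prep`.
#' @export
simulate_batch_study <- function(n_batches = 14, panel = six_sterol_panel(),
                                 concentration_ranges = NULL, truth = NULL,
                                 prep = sample_prep(2.0, 2.0), seed = 1,
                                 ...) {
  if (n_batches < 1) stop("n_batches must be >= 1")
  if (is.null(truth)) truth <- default_truth(panel)
  if (is.null(concentration_ranges))
    concentration_ranges <- list(
      "cholesterol" = c(2100, 3900),
      "7-hydroxycholesterol" = c(53, 81),
      "7-ketocholesterol" = c(11.6, 22.1),
      "4-cholesten-3-one" = c(5.8, 9.2),
      "stigmasterol" = c(11.2, 15.6),
      "7-dehydrocholesterol" = c(3.7, 6.1)
    )
  nm <- names(truth$concentrations)
  if (!all(nm %in% names(concentration_ranges)))
    stop("concentration_ranges missing: ",
         paste(setdiff(nm, names(concentration_ranges)), collapse = ", "))
  for (a in nm)
    if (concentration_ranges[[a]][1] > concentration_ranges[[a]][2])
      stop("inverted concentration range for ", a)
  channels <- sort(unique(panel$analytes$wavelength))
  lapply(seq_len(n_batches), function(b) {
    seed_b <- (as.integer(seed) %% 1000003L) * 257L + b
    set.seed(seed_b)
    conc <- vapply(nm, function(a)
      stats::runif(1, concentration_ranges[[a]][1],
                   concentration_ranges[[a]][2]), numeric(1))
    truth_b <- truth
    truth_b$concentrations <- conc
    runs <- lapply(channels, function(wl)
      simulate_chromatogram(truth_b, panel, wl, seed = seed_b + 1L, ...))
    names(runs) <- as.character(channels)
    list(batch = b, concentrations = conc,
         chromatograms = lapply(runs, `[[`, "chromatogram"),
         apex_times = runs[[1]]$apex_times, prep = prep)
  })
}
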