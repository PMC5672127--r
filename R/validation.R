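# Method-validation statistics. Everything reduces to the relative standard
# deviation of replicate sets; the report functions organise replicates by
# analyte or acquisition condition and compare against acceptance thresholds.
# Thresholds default to the validated bounds of the reference study but are
# plain arguments: they are observations about a validated method, not
# specifications.

#' Relative standard deviation
#'
#' RSD% = 100 x sample standard deviation (n - 1 denominator) / mean.
#'
#' @param values Numeric vector of at least 2 finite replicate measurements
#'   with non-zero mean.
#' @return RSD in percent.
#' @export
rsd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("RSD needs at least 2 replicates")
  if (anyNA(values) || any(!is.finite(values)))
    stop("replicate values must be finite")
  m <- mean(values)
  if (m == 0) stop("RSD undefined: mean is zero")
  100 * stats::sd(values) / m
}

#' Spike recovery rate
#'
#' recovery% = 100 (measured_spiked - base_amount) / added_amount, for a
#' sample spiked with reference substance (typically at 1:1 of the native
#' content).
#'
#' @param base_amount Native analyte amount in the unspiked sample (ug).
#' @param added_amount Spiked amount (ug), > 0.
#' @param measured_spiked Amount measured in the spiked sample (ug).
#' @return Recovery in percent.
#' @export
recovery_rate <- function(base_amount, added_amount, measured_spiked) {
  if (any(added_amount <= 0)) stop("added_amount must be > 0")
  if (any(base_amount < 0) || any(measured_spiked < 0))
    stop("amounts must be >= 0")
  100 * (measured_spiked - base_amount) / added_amount
}

#' Stability report over a timepoint series
#'
#' RSD of peak areas across injection timepoints per analyte (e.g. 0-24 h
#' after preparation), with a pass flag at the stability threshold.
#'
#' @param timepoint_areas data.frame with columns `analyte`, `hours`, `area`;
#'   at least 3 timepoints per analyte.
#' @param threshold Pass threshold for RSD% (default 2.0).
#' @return data.frame: `analyte`, `n`, `rsd`, `pass`.
#' @export
stability_report <- function(timepoint_areas, threshold = 2.0) {
  req <- c("analyte", "hours", "area")
  if (!all(req %in% names(timepoint_areas)))
    stop("timepoint_areas needs columns: ", paste(req, collapse = ", "))
  split_by <- split(timepoint_areas, timepoint_areas$analyte)
  out <- do.call(rbind, lapply(split_by, function(d) {
    if (nrow(d) < 3L)
      stop("analyte ", d$analyte[1], ": at least 3 timepoints are required")
    data.frame(analyte = d$analyte[1], n = nrow(d), rsd = rsd(d$area))
  }))
  out$pass <- out$rsd <= threshold
  rownames(out) <- NULL
  out
}

#' Reproducibility of relative correction factors across conditions
#'
#' RSD of the factor within each acquisition condition (instrument, column,
#' flow, temperature, laboratory) plus the pooled RSD over all values, each
#' with a pass flag. The default thresholds are the within-laboratory and
#' cross-laboratory reproducibility bounds of the validated method.
#'
#' @param rcf_by_condition Named list: condition -> numeric vector of factor
#'   values (>= 2 each).
#' @param within_threshold RSD%% bound per condition (default 1.19).
#' @param overall_threshold RSD%% bound on the pooled values (default 2.0).
#' @return A list with `per_condition` (data.frame `condition, n, rsd, pass`)
#'   and `overall` (list `n, rsd, pass`).
#' @export
rcf_reproducibility <- function(rcf_by_condition,
                                within_threshold = 1.19,
                                overall_threshold = 2.0) {
  if (is.null(names(rcf_by_condition)))
    stop("rcf_by_condition must be a named list of conditions")
  per <- do.call(rbind, lapply(names(rcf_by_condition), function(cn) {
    v <- rcf_by_condition[[cn]]
    if (length(v) < 2L)
      stop("condition ", cn, ": at least 2 factor values are required")
    data.frame(condition = cn, n = length(v), rsd = rsd(v))
  }))
  per$pass <- per$rsd <= within_threshold
  pooled <- unlist(rcf_by_condition, use.names = FALSE)
  overall <- list(n = length(pooled), rsd = rsd(pooled))
  overall$pass <- overall$rsd <= overall_threshold
  list(per_condition = per, overall = overall)
}

#' Durability report across acquisition conditions
#'
#' RSD of each analyte's mass fraction across deliberately varied conditions
#' (instrument, column, flow rate, temperature), with a pass flag.
#'
#' @param mass_fractions_by_condition data.frame with columns `condition`,
#'   `analyte`, `value`; every condition must cover the same analyte set.
#' @param threshold Pass threshold for RSD% (default 3.1).
#' @return data.frame: `analyte`, `n_conditions`, `rsd`, `pass`.
#' @export
durability_report <- function(mass_fractions_by_condition, threshold = 3.1) {
  req <- c("condition", "analyte", "value")
  if (!all(req %in% names(mass_fractions_by_condition)))
    stop("needs columns: ", paste(req, collapse = ", "))
  d <- mass_fractions_by_condition
  sets <- lapply(split(d$analyte, d$condition), sort)
  if (length(unique(sets)) != 1L)
    stop("alignment error: conditions cover different analyte sets")
  out <- do.call(rbind, lapply(split(d, d$analyte), function(g)
    data.frame(analyte = g$analyte[1], n_conditions = nrow(g),
               rsd = rsd(g$value))))
  out$pass <- out$rsd <= threshold
  rownames(out) <- NULL
  out
}
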