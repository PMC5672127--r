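# Peak processing: baseline estimation, detection, integration, noise and
# system-suitability metrics. Heights and areas are always measured above the
# estimated baseline.

#' Estimate a chromatographic baseline
#'
#' Rolling-minimum filter followed by a same-window rolling mean. The rolling
#' minimum suppresses peaks (for windows wider than the peak base); the mean
#' smooths the staircase the minimum leaves behind. Windows are centred and
#' truncated at the trace edges.
#'
#' @param chrom A [chromatogram()].
#' @param window Full window width in minutes; must be at least 5 sampling
#'   intervals and no wider than the trace span.
#' @return An object of class `"baseline_model"` with fields `times`,
#'   `baseline` (same grid as `chrom`), `method` and `window`.
#' @export
estimate_baseline <- function(chrom, window) {
  stopifnot(inherits(chrom, "chromatogram"))
  dt <- stats::median(diff(chrom$times))
  span <- diff(range(chrom$times))
  if (window < 5 * dt)
    stop("baseline window must be at least 5 sampling intervals (",
         format(5 * dt), " min)")
  if (window > span)
    stop("baseline window (", window, " min) exceeds the trace span (",
         format(span), " min)")
  k <- max(1L, as.integer(round(window / (2 * dt))))
  lo <- roll_fun(chrom$intensities, k, min)
  bl <- roll_fun(lo, k, mean)
  structure(list(times = chrom$times, baseline = bl,
                 method = "rollmin_mean", window = window),
            class = "baseline_model")
}

# centred rolling statistic with edge truncation; k = half-window in points
roll_fun <- function(x, k, fun) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n))
    out[i] <- fun(x[max(1L, i - k):min(n, i + k)])
  out
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model> %s, window %g min, %d points\n",
              x$method, x$window, length(x$times)))
  invisible(x)
}

#' Detect peaks in a baseline-corrected trace
#'
#' Finds local maxima of (signal - baseline) above `min_height`; integration
#' bounds are set at the nearest valley between adjacent peaks (perpendicular
#' drop) or at the baseline crossing, whichever comes first. The width at half
#' height is obtained by linear interpolation of the half-height crossings.
#' Peaks narrower than `min_width` (at half height) are rejected as spikes,
#' and candidates whose prominence above their own bounds is below
#' `min_height` (noise ripples riding on the flank of a larger peak) are
#' rejected as well.
#'
#' @param chrom A [chromatogram()].
#' @param baseline A matching [estimate_baseline()] result.
#' @param min_height Minimum baseline-corrected apex height (mAU).
#' @param min_width Minimum width at half height (min).
#' @return A list of [peak()] objects ordered by apex time (possibly empty).
#' @export
detect_peaks <- function(chrom, baseline, min_height, min_width) {
  stopifnot(inherits(chrom, "chromatogram"),
            inherits(baseline, "baseline_model"))
  if (min_height <= 0 || min_width <= 0)
    stop("min_height and min_width must be > 0")
  if (length(baseline$baseline) != length(chrom$times))
    stop("baseline grid does not match the chromatogram")
  y <- chrom$intensities - baseline$baseline
  t <- chrom$times
  n <- length(y)
  # strict local maxima; plateaus keep their first point
  apex <- which(y > min_height &
                  y >= c(-Inf, y[-n]) & y > c(y[-1], -Inf))
  if (length(apex) == 0L) return(list())

  # valley (local minimum of y) or zero-crossing bounds around each apex
  out <- vector("list", length(apex))
  keep <- logical(length(apex))
  for (j in seq_along(apex)) {
    i <- apex[j]
    L <- i
    while (L > 1L && y[L - 1L] <= y[L] && y[L] > 0) L <- L - 1L
    R <- i
    while (R < n && y[R + 1L] <= y[R] && y[R] > 0) R <- R + 1L
    if (L == i || R == i) next  # apex on the edge: not a peak
    h <- y[i]
    if (h - max(y[L], y[R]) < min_height) next  # insufficient prominence
    wh <- half_width(t, y, i, L, R)
    if (is.na(wh) || wh < min_width) next
    area <- trapz_clipped(t[L:R], y[L:R])
    out[[j]] <- peak(apex_time = t[i], start_time = t[L], end_time = t[R],
                     height = h, area = area, width_half = wh)
    keep[j] <- TRUE
  }
  out[keep]
}

# width at half height by linear interpolation of the crossings; falls back to
# the peak bounds when a crossing is not bracketed inside them
half_width <- function(t, y, i, L, R) {
  hh <- y[i] / 2
  tl <- t[L]; tr <- t[R]
  if (any(y[L:i] <= hh)) {
    k <- max(which(y[L:i] <= hh)) + L - 1L
    if (y[k + 1L] != y[k])
      tl <- t[k] + (hh - y[k]) * (t[k + 1L] - t[k]) / (y[k + 1L] - y[k])
    else tl <- t[k]
  }
  if (any(y[i:R] <= hh)) {
    k <- min(which(y[i:R] <= hh)) + i - 1L
    if (y[k] != y[k - 1L])
      tr <- t[k - 1L] + (hh - y[k - 1L]) * (t[k] - t[k - 1L]) /
        (y[k] - y[k - 1L])
    else tr <- t[k]
  }
  w <- tr - tl
  if (w <= 0) NA_real_ else w
}

# trapezoid of max(y, 0) over the given nodes
trapz_clipped <- function(t, y) {
  y <- pmax(y, 0)
  sum(diff(t) * (y[-length(y)] + y[-1]) / 2)
}

#' Integrate a baseline-corrected region
#'
#' Trapezoidal integral of max(signal - baseline, 0) over \[start, end\].
#' The endpoint ordinates are obtained by linear interpolation, so integrating
#' \[a, b\] and \[b, c\] sums exactly to the integral over \[a, c\].
#'
#' @param chrom A [chromatogram()].
#' @param baseline A matching [estimate_baseline()] result.
#' @param start,end Integration bounds in minutes, inside the time grid.
#' @return Peak area in mAU min.
#' @export
integrate_peak <- function(chrom, baseline, start, end) {
  stopifnot(inherits(chrom, "chromatogram"))
  t <- chrom$times
  if (start >= end) stop("start must be < end")
  if (start < t[1] || end > t[length(t)])
    stop("integration bounds [", start, ", ", end,
         "] fall outside the time grid")
  y <- chrom$intensities - baseline$baseline
  inside <- t > start & t < end
  ys <- stats::approx(t, y, xout = start)$y
  ye <- stats::approx(t, y, xout = end)$y
  trapz_clipped(c(start, t[inside], end), c(ys, y[inside], ye))
}

#' Estimate detector noise in a peak-free region
#'
#' The noise standard deviation is that of the detrended signal (a straight
#' line is fitted and removed, so slow drift does not inflate the estimate).
#'
#' @param chrom A [chromatogram()].
#' @param region_start,region_end Bounds of the noise region (min).
#' @param peaks Optional list of detected peaks; the region must not overlap
#'   any of them.
#' @return An object of class `"noise_estimate"` with fields `sd`,
#'   `region_start`, `region_end`, `n_points`.
#' @export
estimate_noise <- function(chrom, region_start, region_end, peaks = NULL) {
  stopifnot(inherits(chrom, "chromatogram"))
  t <- chrom$times
  if (region_start < t[1] || region_end > t[length(t)] ||
      region_start >= region_end)
    stop("noise region must lie inside the chromatogram")
  for (p in peaks)
    if (p$start_time < region_end && p$end_time > region_start)
      stop("noise region overlaps a detected peak at ",
           format(p$apex_time), " min")
  idx <- which(t >= region_start & t <= region_end)
  if (length(idx) < 20L)
    stop("noise region must contain at least 20 points, has ", length(idx))
  fit <- stats::lm.fit(cbind(1, t[idx]), chrom$intensities[idx])
  structure(list(sd = stats::sd(fit$residuals),
                 region_start = region_start, region_end = region_end,
                 n_points = length(idx)),
            class = "noise_estimate")
}

#' Signal-to-noise ratio of a peak
#'
#' Defined here as the baseline-corrected peak height divided by the noise
#' standard deviation. The 3x and 10x multipliers for LOD/LOQ are applied on
#' this scale.
#'
#' @param peak A [peak()].
#' @param noise An [estimate_noise()] result with `sd > 0`.
#' @return Unitless S/N ratio.
#' @export
signal_to_noise <- function(peak, noise) {
  if (noise$sd <= 0)
    stop("S/N undefined: noise standard deviation is not positive")
  peak$height / noise$sd
}

#' Theoretical plate count
#'
#' Column efficiency from the half-height width: N = 5.54 (t_R / W_0.5)^2.
#'
#' @param peak A [peak()] with positive `width_half`.
#' @return Plate number (unitless).
#' @export
plate_count <- function(peak) {
  5.54 * (peak$apex_time / peak$width_half)^2
}

#' Resolution between two adjacent peaks
#'
#' Rs = 2 (t2 - t1) / (w1 + w2) with w the baseline widths (end - start).
#'
#' @param peak1,peak2 Two [peak()] objects with `peak1$apex_time <
#'   peak2$apex_time`.
#' @return Resolution (unitless).
#' @export
resolution <- function(peak1, peak2) {
  if (peak1$apex_time > peak2$apex_time)
    stop("peak1 must elute before peak2")
  w1 <- peak1$end_time - peak1$start_time
  w2 <- peak2$end_time - peak2$start_time
  2 * (peak2$apex_time - peak1$apex_time) / (w1 + w2)
}
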