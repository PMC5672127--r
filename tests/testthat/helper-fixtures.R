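# Shared fixtures and independent oracles, all built in code.

# a baseline model that is identically zero on the chromatogram's grid
zero_baseline <- function(chrom) {
  structure(list(times = chrom$times,
                 baseline = numeric(length(chrom$times)),
                 method = "zero", window = NA_real_),
            class = "baseline_model")
}

# Gaussian peak ordinates with a given total area
gaussian_trace <- function(times, apex, sigma, area) {
  area * stats::dnorm(times, apex, sigma)
}

# independent closed-form normal-equations fit (slope, intercept)
ne_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x * x)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx * sx)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# brute-force RSD straight from the definition
brute_rsd <- function(v) {
  m <- sum(v) / length(v)
  100 * sqrt(sum((v - m)^2) / (length(v) - 1)) / m
}

# manually constructed peak with sensible defaults
make_peak <- function(apex, start = apex - 0.2, end = apex + 0.2,
                      height = 100, area = 10, width_half = 0.1) {
  peak(apex_time = apex, start_time = start, end_time = end,
       height = height, area = area, width_half = width_half)
}

# published six-curve calibration list, loaded once per file
pub_curves <- function() six_sterol_calibration()
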