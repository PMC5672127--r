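---
title: "Single-marker quantitation of multi-component chromatograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker quantitation of multi-component chromatograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qamskit)
```

## The problem and the model

Quality control of multi-component natural materials by HPLC normally
requires an authentic standard for every analyte, which is expensive and for
some compounds (oxidised sterols, for instance) barely obtainable. The
single-marker approach (QAMS, *quantitative analysis of multicomponents by
single marker*) calibrates one cheap, abundant analyte — here cholesterol,
the internal reference of a six-sterol panel used to assess *Oviductus
Ranae* — and quantifies every other analyte through a **relative correction
factor**.

Each analyte obeys a linear detector response

$$Y = a X + b,$$

with $Y$ the peak area (mAU·min) and $X$ the concentration (µg/mL). When
$|a/b| > 100$ the intercept is within the noise of the fit and inversion
simplifies to $X = Y/a$. Under that condition the ratio of two analytes'
responses is captured entirely by their slopes, so the relative correction
factor of analyte $K$ against reference $S$ is

$$f_{K/S} = \frac{a_K}{a_S},$$

and single-marker quantitation of $K$ from its area $Y_K$ is

$$X_K = \frac{Y_K}{f_{K/S}\, a_S}.$$

Only $a_S$ requires a standard to be run; the $f_{K/S}$ are transferable
constants of the detection system. `qams()` is the package's fitting
function: it takes per-analyte calibration curves and a reference and
returns the factor table as a classed model object.

```{r}
model <- qams(six_sterol_calibration(), reference = "cholesterol")
round(coef(model), 4)
```

The five non-reference factors above are the package's reproduction of the
validated values for this panel; `summary(model)` additionally reports each
curve's $|a/b|$ ratio so violations of the intercept rule are visible rather
than silent (a warning, never a hidden correction).

## Locating peaks: relative retention time

Absolute retention times drift with flow rate, column and temperature; the
**relative retention time** $R_{tR} = t_{RK}/t_{RS}$ does not, because a
uniform change of flow rescales every retention time by a common factor that
cancels in the ratio. `assign_peaks()` therefore locates the reference peak
first — the largest-area peak inside the reference's absolute retention
window, since $t_{RS}$ must be known before any ratio can be formed — and
then matches each analyte to the detected peak minimising the fractional
RTT deviation, greedily, smallest deviation first, ties broken by larger
area, no peak used twice. Where chromatographic neighbours crowd an analyte,
`spectral_similarity()` (mean-centred cosine over a common wavelength grid)
supplies the DAD-spectral confirmation the method prescribes.

The default matching tolerance is 5% of the expected RTT. Observed RTT
variability for this panel is below 0.67% in routine use and below 4.91%
across deliberately varied instruments and columns, so 5% accepts all
legitimate drift while remaining far narrower than the spacing between
adjacent peaks (the closest pair sits about 18% apart in RTT).

## Peak processing

The detector trace is handled in three steps, each deliberately simple and
fully testable:

* **Baseline** — a centred rolling minimum followed by a same-window rolling
  mean. The minimum suppresses peaks for windows wider than the peak base
  (the default 1.0 min is roughly 12 times the widest peak sigma); the mean
  smooths the staircase. On a drifting baseline the rolling minimum sits low
  by about *slope × window/2*; with the default window and the drift levels
  simulated here that bias is a fraction of an mAU under peaks four to six
  orders of magnitude taller, which is why the simpler estimator was chosen
  over polynomial fitting.
* **Detection** — strict local maxima of the corrected signal above
  `min_height`, with bounds at the valley between fused peaks (perpendicular
  drop, the common workstation default) or at the baseline crossing. A
  candidate must also rise at least `min_height` above its own bounds; that
  prominence requirement rejects noise ripples riding on the flank of a
  large peak. Width at half height comes from linear interpolation of the
  half-height crossings; `min_width` rejects single-sample spikes.
* **Integration** — trapezoidal integral of the clipped corrected signal
  with interpolated endpoint ordinates, which makes integration exactly
  additive over adjacent intervals. Over a full Gaussian the trapezoid's
  endpoint-error terms cancel and accuracy is far better than second order;
  over a truncated window it degrades gracefully to $O(h^2)$.

System suitability uses the standard half-height plate count
$N = 5.54\,(t_R/W_{0.5})^2$ (floor 3500 for this method) and the
baseline-width resolution $R_s = 2(t_2-t_1)/(w_1+w_2)$ (floor 1.5). Both are
pure ratios, hence invariant to uniform time rescaling — the same property
that underpins RTT matching.

## Validation statistics

Everything reduces to the relative standard deviation,
$\mathrm{RSD\%} = 100\,s/\bar{x}$ with the sample ($n-1$) standard
deviation — the package fixes that convention since small replicate sets
(n = 6–8) are the norm and the population form would bias low. On top of it
sit precision/stability/repeatability reports, spike recovery
($100\,(\text{measured}-\text{base})/\text{added}$, 1:1 spiking design),
LOD/LOQ at 3× and 10× signal-to-noise, durability across deliberate
condition changes, and RCF reproducibility across instruments and
laboratories. S/N is defined as baseline-corrected height over the standard
deviation of the detrended signal in a peak-free region — one of several
conventions in use, stated here once and applied consistently; the 3×/10×
multipliers are untouched by that choice. Default pass thresholds (2.0%
stability, 2% method agreement, 3.1% durability, 1.19%/2.0% RCF
reproducibility) are the bounds the validated method achieved; they are
arguments, not constants, because they describe observations rather than
specifications.

## What the simulator emulates — and what it does not

`simulate_chromatogram()` renders each analyte as a Gaussian of area
*slope × concentration* on its own channel (205, 240 or 280 nm, per the
panel) and 10% of that on the other channels, over a linear drift plus
i.i.d. Gaussian noise. Retention times receive a shared multiplicative
run factor (sd 0.8% — flow-rate variation, moving all peaks together so
RTTs are preserved by construction) and a small independent per-peak jitter
(sd 0.2%, matching the sub-0.67% routine RTT variability). All channels of
one run share identical retention times, as a diode-array detector records
them. Everything is bit-reproducible under a fixed seed.

Choices a reader should know about:

* **Retention times are synthetic.** The validated elution order
  (7-hydroxycholesterol, 7-ketocholesterol, 4-cholesten-3-one,
  7-dehydrocholesterol, cholesterol, stigmasterol) is preserved, but the
  absolute times (4.6–13.6 min) and peak widths (σ 0.06–0.09 min) are
  invented; no published values exist.
* Response slopes are the published calibration slopes, so simulated areas
  live on the real response scale; the 10% off-channel response is likewise
  invented, present so that multi-channel peak location is genuinely
  exercised.
* The injection-volume calibration series uses fractions 0.25–3 of the
  20 µL reference injection, which reproduces the published linear ranges
  of five of the six analytes from their stock concentrations. (The
  reference analyte's published range is inconsistent with that series and
  is deliberately not reproduced.)
* Batch concentrations are drawn uniformly within sample-like extract
  ranges; with the standard 2 g / 2 mL preparation, µg/mL and µg/g
  coincide numerically.
* Not modelled: tailing/fronting (exponentially modified Gaussians),
  gradient elution, detector saturation, correlated (1/f) noise, matrix
  interferences. Passing end-to-end tests therefore demonstrates the
  *method logic* — detection, RTT assignment, calibration transfer,
  ES/QAMS agreement — under idealised peak shapes, not robustness to every
  real-world artefact.

## Numerical and design choices

* Factors are carried at full precision and rounded to 4 decimals only for
  display; mass fractions display at 1 decimal. Rounding at serialisation
  only, with `--full-precision` to disable, prevents accumulated rounding
  from contaminating downstream arithmetic.
* ES inversions outside a curve's validated range warn rather than fail:
  diluted samples legitimately fall outside, and a hard error would make
  honest reporting impossible.
* Ambiguous assignments (two candidate peaks with identical deviation and
  area) raise an error rather than picking arbitrarily.
* The end-to-end tests run at desk scale: 2001-point traces (16 min at
  0.008 min sampling), an 8-level calibration series, 14 synthetic batches
  and 50 assignment replicates, sizes chosen so the full suite completes in
  seconds while still exercising every pipeline stage at realistic peak
  geometry.

## Known limitations

The baseline estimator's drift bias (above) makes it unsuitable for steep
gradients; the valley convention splits strongly fused peaks approximately
(no deconvolution is attempted — out of scope by design); and the method
comparison reports relative errors only, with no inferential test, because
relative error is the quantity the validation protocol actually bounds.
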