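---
title: "Evaluating cameras for quantitative gel imaging: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating cameras for quantitative gel imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelimetry)
```

## The problem

A gel-document system photographs agarose gels after electrophoresis so that
DNA band intensities can be quantified. Quantification only works if the
camera is radiometrically linear: recorded counts must be proportional to
scene radiance. Consumer and open-platform board cameras are attractive
replacements for the expensive CCD/DSLR cameras in commercial systems, but
their response may carry gamma compression, offsets, or clipping that silently
distort band volumes.

`gelimetry` implements two complementary ways to score a camera's linearity
from photographs of a uniformly reflective test sheet under an LED whose
brightness is stepped through PWM duty cycles, plus a densitometry stage that
scores the resulting gel photographs through a dilution series. Because the
imaging rig itself is hardware, a seeded simulator with known ground truth
stands in for it, which makes every stage testable offline.

## Intensity profiles and the error metric

An image of the test sheet at duty $\omega$ is reduced to a profile
$y_\omega(t)$, $0 \le t \le 1$: the mean over rows of each column, with the
pixel position normalized so cameras with different pixel counts share one
domain. The profile is fitted with an order-$n$ polynomial by ordinary least
squares on the monomial basis,

$$p_\omega = \mathrm{polyfit}(t, y_\omega, n), \qquad
  \hat y_\omega(t) = \mathrm{polyval}(p_\omega, t),$$

and the fit is scored by the **population variance of the residuals**
(divisor $N$),

$$e_\omega = \operatorname{var}(y_\omega - \hat y_\omega).$$

Two properties of this metric matter and are preserved deliberately:

* it is blind to a constant residual offset (variance subtracts the mean), so
  it scores *shape* agreement, not absolute level;
* it is non-increasing in the fit order on the same profile (OLS nesting),
  which the order-selection rule exploits.

Fitting is done directly on $t \in [0,1]$ without basis orthogonalization;
at the orders used here (up to 6) the monomial basis is well conditioned on
that interval.

## Analysis 1: constancy, slope, and order selection

Three checks, all on the duty series $(100, 80, 60, 40, 20)$ with duty 100
(the brightest lighting) as reference:

1. **Reflectance constancy.** If the LED output is proportional to duty and
   the camera is linear, the profile at duty $\omega$ equals
   $(\omega/100)\,\hat y_{100}(t)$. Each level's own fit is compared against
   the scaled reference fit; the fit curves are tabulated on a 100-point grid
   and the scaled baseline on a 10-point grid (markers over curves, for
   plotting). We summarize the discrepancy by the maximum absolute deviation
   — a single bad region cannot be averaged away — and also report the
   deviation variance as the smoother companion summary.
2. **Slope vs duty.** The first-order fit slope should be proportional to
   duty; the $R^2$ of the straight-line regression of slope on duty is the
   summary. A flat scene (all slopes equal) makes this undefined and is
   reported as a degenerate flag rather than an error.
3. **Order selection.** $e_\omega[n]$ is computed for $n = 1..6$ and the
   recommended order is the smallest $n$ after which the relative improvement
   $(e[n]-e[n+1])/e[n]$ is below 5% at every level. The visual criterion
   "the error curves stop changing" needs a numeric rule; 5% relative
   improvement is that rule, and an error already at numerical zero
   ($\le 10^{-10}$ of the profile variance) counts as plateaued so exact
   low-order scenes recommend their true order. Under the default cubic
   illumination profile the recommendation is order 3, which is why the
   second analysis fixes its reference fit at order 3.

## Analysis 2: optimal scaling constants

For each non-reference duty, find the constant $d$ that best scales the
reference fit onto that duty's profile:

$$d_\omega = \arg\min_d \operatorname{var}\!\big(y_\omega - d\,\hat y_{100}(t)\big).$$

Scaling a polynomial's coefficients scales its values, so this is exactly the
best multiple of $p_{100}$. The objective is quadratic in $d$, giving the
closed form

$$d_\omega = \frac{\operatorname{cov}(y_\omega, \hat y_{100})}
                   {\operatorname{var}(\hat y_{100})},\qquad
  e_\omega^{\min} = \operatorname{var}(y_\omega)\,(1 - \rho^2),$$

with $\rho$ the correlation of $y_\omega$ and $\hat y_{100}$. A brute-force
grid search over $d$ is retained in the test suite as the independent oracle
for this closed form. A flat reference ($\operatorname{var}(\hat y_{100})=0$)
has no defined constant and is an error.

For a linear camera $d_\omega = \omega/100$, i.e. $(1, 0.8, 0.6, 0.4, 0.2)$
across the default series; for a pure-gamma camera
$d_\omega \approx (\omega/100)^\gamma$. We summarize a camera with the RMS
deviation of $d$ from the $\omega/100$ baseline over non-reference levels
("linearity RMSE") — the baseline comparison is classically judged by eye, so
the scalar score is this package's addition; per-level deviations and errors
are reported alongside. $d$ is never constrained: values outside $[0, 1.5]$
are flagged as suspicious rather than clipped. Ranking cameras by linearity
RMSE recovers, on synthetic cameras, the ordering by $|\gamma - 1|$.

```{r scaling-example}
cam  <- CameraModel("demo", gain = 220, gamma = 1.15, noiseSigma = 1)
imgs <- simulatePWMSeries(cam, IlluminationField(), seed = 1)
scalingAnalysis(profileSeries(imgs, "demo"))
```

## Gel densitometry and the sensitivity index

Gel photographs from different cameras have different pixel geometries, so
each is first rectified: the four gel corners are mapped to an upright
rectangle by the exact 4-point homography (eight unknowns from four point
pairs, solved as a dense linear system) with bilinear resampling.

**Band volume** is defined explicitly, since commercial analyzers do not
publish theirs: the background is the median of a border frame (default
3 px) around the band's rectangle, and the volume is
$\sum \max(\text{pixel} - \text{background}, 0)$ over the rectangle.
The median is robust to the band's own tails; clamping prevents noise in
empty corners from subtracting signal. ROI rectangles are 0-based and
half-open; they normally come from an annotation file, though a simple
column-profile peak finder (5-px smoothing, 5% prominence) is provided as a
convenience.

Volumes across a dilution series (default 1, 1/2, 1/5, 1/10, 1/20) are
regressed on concentration; the coefficient of determination $R^2$ measures
linearity and the sensitivity index is

$$\mathrm{SNR} = \frac{R^2}{1 - R^2}, \qquad R^2 = \frac{\mathrm{SNR}}{1 + \mathrm{SNR}},$$

a strictly monotone transform (so ranking by either is equivalent).
$R^2 = 1$ exactly is reported as infinite SNR with a degenerate flag and
treated as the maximum in rankings; identical volumes leave $R^2$ undefined
(degenerate flag, not an error).

**Alternating shots.** UV exposure fades the stain, so two cameras are
compared by photographing one gel in order A→B→A. Per experiment the package
ranks the three shots' $R^2$ (rank 1 = largest; ties are broken toward the
earlier shot, which faced less fading, and flagged) and compares the mean
$R^2$ of the flanking shots with the center shot, plus the ratio of
regression slopes after optional per-shot exposure normalization (default 1;
no normalization is imposed because none is canonically defined). The fading
itself is not corrected — it is exposed symmetrically by the design.

## What the simulator emulates — and what it does not

The simulator replaces the physical rig with:

* **Illumination**: relative radiance $(\omega/100) \cdot f(t)$ with $f$ a
  monotone cubic, default $0.6 + 0.5t - 0.35t^2 + 0.25t^3$ (non-negative and
  increasing on $[0,1]$). Real gel-doc lighting is smooth but not uniform; a
  cubic is the simplest profile that exercises order selection up to the
  order the analyses actually use. PWM-to-radiance is assumed exactly
  proportional, so the camera is the only distortion source; with real
  hardware any LED nonlinearity would be attributed to the camera.
* **Camera**: $\mathrm{clip}(g L^\gamma + o + \varepsilon,\, 0,\,
  \mathrm{saturation})$ with additive Gaussian read noise
  $\varepsilon \sim N(0, \sigma^2)$. Default 8-bit range (saturation 255);
  16-bit TIFF output is available. No Poisson shot noise, lens vignetting,
  PSF, Bayer mosaic, or auto-exposure/white-balance behavior is modeled —
  additive Gaussian noise is sufficient for a variance-based error metric,
  but it means passing tests say nothing about demosaicing artifacts or
  signal-dependent noise in real cameras.
* **Gels**: one 2-D Gaussian band per lane on a uniform background, peak
  amplitude proportional to concentration, so the ground-truth volume is the
  analytic integral $2\pi A \sigma_r \sigma_c$ and exactly proportional to
  concentration. Real bands have skewed migration profiles, smears, and
  spatially varying background; the uniform-background assumption is exactly
  what the border-median subtraction is good at, so synthetic results are a
  best case for the densitometry stage.
* **Seeding**: every stochastic stage takes an explicit seed; per-level and
  per-shot seeds are derived deterministically from the base seed, so series
  are reproducible level by level and images are bit-identical across runs.
  Simulation never disturbs the session RNG stream.

A constant camera offset deserves a note: it breaks proportional scaling and
the constancy check reports it as genuine non-constancy. That is the correct
behavior for these metrics — an offset camera *is* non-proportional — even
though the variance error metric within a single level cannot see it.

## Numerical choices

* Population variance (divisor $N$) everywhere, matching the metric
  definition; tests cross-check against independently written sums.
* Saturated pixels are kept, not excluded; if more than 1% of contributing
  pixels sit at saturation a warning is attached to the profile, because
  clipping biases every downstream fit.
* Coefficients are stored lowest-order-first internally;
  `coef(fit, highestFirst = TRUE)` converts for I/O with highest-first
  conventions, avoiding silent reversal bugs.
* The homography is solved with $H_{33} = 1$ fixed (valid for finite
  corner quads); degenerate or non-convex quads error out before any
  resampling. Bilinear interpolation is used for both warp and rectify;
  round-trip error on smooth synthetic gels is well under one count.
* Extrapolating a fit outside $[0,1]$ warns but proceeds.

## Problem sizes and the demonstration pipeline

The bundled demonstration (`demoConfig()`) simulates four cameras with
response exponents 1.0, 1.1, 1.3 and 1.6 on 48x192 test-sheet images, runs
both analyses, and quantifies simulated 100x300 gels in two alternating-shot
experiments. Those sizes keep a full run around a few seconds while leaving
per-profile noise after row averaging small enough that the gamma ordering
is recovered reliably; the same code scales to full-resolution images
unchanged. The test suite and the acceptance script use the same synthetic
conditions (gradient images 16x128 to 32x192, 20-seed replication where an
ordering is being verified).

## Known limitations

* The linearity score compares shapes, not absolute sensitivity; two cameras
  with identical linearity but different gain are indistinguishable here and
  must be separated by the gel-stage slope comparison.
* Scoring assumes the scene's reflectance is spatially constant; a stained
  or non-uniform test sheet would masquerade as camera nonlinearity.
* The rank comparison on three shots is coarse (3! = 6 outcomes); with a
  single gel per experiment it cannot distinguish fading from camera noise —
  repeating experiments and aggregating, as `compareExperiments()` does
  across a list, is the intended use.
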