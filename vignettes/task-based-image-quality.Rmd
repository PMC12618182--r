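---
title: "Task-based CT image quality: TTF, NPS and the NPW detectability index"
author: "ctiq"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Why a detectability index

Routine CT quality metrics — spatial resolution summarized by an MTF,
noise summarized by a standard deviation or a noise power spectrum — are
informative but do not directly predict whether a reader can detect a
specific low-contrast lesion. Task-based image quality closes that gap: a
*task* (a lesion of given size, contrast and profile) is combined with the
system's measured resolution (the task-transfer function, TTF) and noise
texture (the noise power spectrum, NPS) through a model observer, yielding
a single scalar, the detectability index d′. `ctiq` implements this chain
fully automatically for images of an ACR-464-style phantom, together with
a phantom simulator that provides exact ground truth for every estimator.

## The measurement chain

### Phantom and insert segmentation

A slice is thresholded at −200 HU; the largest connected component, with
interior holes filled (the air insert falls below the threshold and must
not punch through), is the phantom mask. Inside a lightly eroded mask
(3 px, so that thin HU-transition rings at the phantom boundary are not
picked up), each insert is the largest connected component inside a
material-specific HU window:

| material     | HU window      |
|--------------|----------------|
| bone         | (200, 1500)    |
| acrylic      | (90, 200)      |
| polyethylene | (−180, −60)    |
| air          | (−1100, −800)  |

The windows are configurable; the defaults are wide enough to be robust to
dose and kernel changes and narrow enough to be disjoint and to exclude
the water background. The insert centre is the *geometric* centroid of the
component (intensity-independent, hence unbiased under symmetric noise)
and its radius the equivalent-area radius `sqrt(area / pi)`.

### TTF estimation

Around each insert two circular ROIs are constructed: an inner ROI at 60 %
of the insert radius (the fraction is configurable; 60 % keeps the mean-HU
estimate clear of edge blur) and an outer ROI at the insert radius plus
30 px, which bounds the edge-spread-function (ESF) sampling region. Every
pixel inside the outer circle contributes a sample (radial distance in mm,
HU), tagged with a 10°-wide angular bin (36 bins).

The bins are then *phase-aligned*: each bin's 50 %-crossing radius is
estimated on a moving-median-smoothed profile and the bin's radii are
shifted so all crossings coincide with their mean. This compensates
sub-pixel centre mis-estimates (a 1 px centre error otherwise smears the
pooled edge by ±1 px, biasing the TTF low). Bins with no resolvable edge,
too few samples (< 10) or a monotonicity violation beyond 30 % of the edge
height are dropped and counted, so a streak artifact cannot corrupt the
pooled fit. The alignment statistic is a design choice: the 50 % crossing
of a smoothed profile is a robust, distribution-free phase estimate.

The pooled samples are fitted with a single logistic edge

```
ESF(x) = base + amplitude / (1 + exp(-(x - center) / width))
```

by Levenberg–Marquardt least squares (multi-start over four width
initializations; plateau medians initialize base/amplitude). All 36 bins
are pooled into one fit rather than fitted per bin and averaged: the
pooled fit uses every sample's exact fractional radius and is the natural
reading of a *single* logistic fit. The logistic enforces a strictly
monotone edge, which is precisely its noise-filtering purpose: the line
spread function (LSF) is then the *analytic* derivative of the fitted
model, `amplitude/(4 width) * sech^2((x-center)/(2 width))`, evaluated on
a uniform grid with spacing `pixel_mm / 4` (4× oversampled — justified by
the fractional-radius samples), so no grid noise is re-introduced by
finite differences. The TTF is the DFT magnitude of the LSF normalized to
1 at zero frequency, reported up to the image Nyquist `1/(2 pixel_mm)`;
f50 and f10 are first downward crossings by linear interpolation (the band
edge is reported when the curve never crosses — an "at least" value for an
ideal edge). For a logistic of width `w` the transfer has the closed form
`(2 pi^2 w f) / sinh(2 pi^2 w f)`, which the tests use as an exact oracle.

One modelling caveat is documented rather than hidden: a Gaussian system
PSF produces an erf-shaped ESF, and the best logistic fit to an erf edge
differs from the exact Gaussian MTF by about 3 % RMS over the band (the
pipeline adds < 0.01 % on top). This is the price of the strictly monotone
noise-rejecting model; f50 is still recovered to well within 2 %.

CNR is measured alongside: `|mean(inner ROI) − mean(background annulus)| /
sd(annulus)`, with the annulus between the insert radius + 5 px and the
outer circle. TTF measurements are averaged over five consecutive slices
by default (pointwise mean, renormalized; CNR averaged).

An edge-based MTF is available for phantoms without inserts: the same
chain applied to the phantom's outer boundary (circle fitted to the mask
by centroid and equivalent-area radius, samples restricted to a ±30 px
annulus), using the ~1000 HU solid-water-to-air contrast.

### NPS estimation

Five 64×64-px ROIs (counts 1–6 and 9 supported) are placed around an
anchor displaced from the mask centroid by a quarter of the phantom radius
— to the left by default, so the homogeneous module's two point objects
(right half) never enter the ROIs. The displacement magnitude and the
layout are design choices the measurement exposes: the default layout is a
non-overlapping cross (pairwise-disjoint ROIs keep the realizations
independent, which the χ²-scaling test relies on); a half-overlapping
quincunx is available as `layout = "quincunx"`. All ROIs must fall inside
the mask eroded by 10 px.

Per ROI and slice the estimator computes

```
NPS2D(u, v) = (dx dy) / (Lx Ly) * |DFT2(ROI - trend)|^2,
```

averaged over all ROI × slice realizations, with `Lx = Ly = 64`
interpreted as the ROI side *in samples* — the only reading under which
the discrete Parseval identity `integral(NPS) = mean detrended-ROI
variance` holds exactly (and it is tested at 1e-9). Detrending is mean
subtraction by default; first- and second-order polynomial surfaces are
available for non-uniformity studies. No taper is applied.

The 1D NPS is obtained by dense radial sampling: 360 rays at 1° spacing,
bilinear interpolation, averaged per radial step (step = the 2D bin
width, starting at 0). Three summaries are attached: the noise magnitude
`sqrt(integral of the 2D NPS)` (in HU, computed from the 2D spectrum so
polynomial smoothing of the 1D curve cannot change it), the peak frequency
(argmax of the 1D curve, DC bin excluded — "maximum frequency" is read as
the argmax location), and the NPS-weighted mean frequency. Optional
polynomial smoothing of any order below the point count is provided,
clipped at zero.

### Task functions

A task is a circular object of diameter `d` (mm), contrast `c` (HU) and
profile *flat* (homogeneous nodule) or *Gaussian* (hepatic-nodule-like),
rendered on a fine grid (300 px of 0.05 mm by default). The Gaussian's
width–diameter relation is a convention the literature leaves open; here
FWHM = nominal diameter, which makes the two profiles comparable at equal
`d` (`sigma = d/4` is one configuration away). The flat disk uses
pixel-centre rasterization; at a 0.05 mm pitch the pixelation error is
negligible for diameters ≥ 1 mm.

The frequency representation uses the continuous-FT scale
`W(u,v) = dp^2 * DFT2(spatial)`, i.e. `|W|^2 = dp^4 |DFT2|^2`. Written
with a single `dp^2` outside the squared transform the expression would
carry the wrong units; the `(dp^2 * FFT)^2` reading is the only one that
makes d′ dimensionless, and it satisfies
`sum(|W|^2) du dv = dp^2 sum(spatial^2)` exactly (tested).

When a swept diameter approaches the grid extent the grid is enlarged at
fixed pixel size (to at least 1.5× the diameter), so a 15 mm object is
never rendered touching the field edge.

### Resampling and the NPW observer

The measured TTF (and a 1D NPS, when used) is expanded to the task grid by
rotation — the inserts are cylinders, so radial symmetry is the physically
correct assumption — with linear interpolation at radius
`sqrt(u^2 + v^2)` and a fill value of 0 beyond the measured band; a 2D NPS
is interpolated bilinearly with the same fill rule. The NPW detectability
index is

```
d'^2 = [ ∫∫ |W|^2 TTF^2 du dv ]^2 / ∫∫ |W|^2 TTF^2 NPS du dv
```

evaluated as midpoint Riemann sums on the DC-centred task grid
(`du = dv = 1/(matrix * pixel_mm)`; no quadrature refinement — at 300²
the grid error is negligible, and an explicit double-loop oracle agrees to
1e-12). Degenerate inputs follow fixed conventions: zero contrast gives
d′ = 0 (0/0 → 0); a zero NPS under a nonzero signal is an error, not
infinity. Exact homogeneities — d′ linear in contrast, d′ scaling as
`k^(-1/2)` when the NPS is scaled by `k` — follow from this form and are
asserted as identities in the tests.

Two human-vision variants are provided as configurable options. NPWE
weights the integrands with an eye filter `E(f) = f_deg^n exp(-c
f_deg^2)` (numerator `E^2`, denominator `E^4`); the constants are not
standardized, so they are exposed with literature-style defaults
(`n = 1.3`, peak at 4 cycles/degree, 500 mm viewing distance, unit zoom)
and are *not* validated against human readings here. NPWi adds internal
noise as `NPS + fraction * mean(NPS over the measured band)` in the
denominator — an additive-fraction parameterization chosen for its two
guaranteed properties: fraction 0 reduces exactly to NPW, and d′ decreases
strictly monotonically in the fraction.

### Synthetic nodule images

For visual checks the task map is blurred by the resampled TTF in the
frequency domain, and stationary noise is added in the spatial domain: a
white Gaussian field's spectrum is shaped by `sqrt(NPS)` (DC forced to 0;
the shaped spectrum inherits Hermitian symmetry from the real white field,
so the image is real), scaled analytically so the spatial variance equals
the NPS integral. Images are bit-reproducible for a fixed seed.

## The phantom simulator

The simulator is the package's ground-truth generator, standing in for
scanner acquisitions. It emulates a 200 mm water-equivalent disk in air
with four 25 mm inserts (bone +955, acrylic +120, polyethylene −95, air
−1000 HU) at 45°/135°/225°/315°, 60 mm off-centre, on a 512² grid of
0.459 mm pixels — nominal accreditation-phantom geometry, since the
source material gives no numbers. Two ideas keep it honest:

* **Blur is exact by construction.** Edges are rendered analytically as
  Gaussian-blurred steps (`pnorm((R − r)/sigma)`) evaluated at pixel
  centres, rather than rasterized and filtered; the curvature correction
  is negligible for 12.5 mm inserts blurred at ≤ 0.65 mm. The system MTF
  is therefore exactly `exp(-2 pi^2 sigma^2 f^2)`, an analytic target for
  the TTF chain. With `blur_sigma = 0` the image is piecewise constant at
  the exact configured HU values.
* **Noise is post-reconstruction.** Stationary correlated noise is added
  after the geometry is rendered, shaped in the frequency domain by a
  radial filter: `white` (flat), `ramp` (`NPS ∝ f exp(-(f/cutoff)^2)`,
  the filtered-back-projection shape, the default) or `band` (a Gaussian
  bump). The amplitude is normalized analytically so the in-phantom SD
  equals `noise_sd` in expectation. Slices draw independent noise from a
  single per-stack seed.

A tube current of `mA` is emulated by scaling the reference noise SD
(4 HU at 140 mA, matching the ~4 HU NPS integral of a typical 140 mA
head-protocol acquisition) by `sqrt(140 / mA)` — quantum-noise scaling,
which also reproduces the mid-30s-percent noise drop from 80 to 200 mA
seen on real scanners. Kernel presets order resolution as Lung > Edge >
Standard > Soft via `blur_sigma` (0.25 / 0.35 / 0.45 / 0.65 mm) and move
the ramp cutoff with sharpness (0.70 / 0.50 / 0.35 / 0.25 mm⁻¹). The noise
multiplier combines the ideal ramp-bandwidth scaling `(cutoff/0.35)^1.5`
— under which, for pure quantum noise, the low-frequency NPS density would
be kernel-independent — with an excess factor (1.8 / 1.3 / 1.0 / 1.05):
sharp kernels overshoot the ramp (enhancement), very soft kernels sit on
an electronic-noise floor. The consequence, emergent rather than asserted,
is that the Standard kernel maximizes and the Lung kernel minimizes d′ for
a 5 mm / 15 HU task, as observed on real scanners.

What the simulator does **not** model — and what passing tests therefore
do not demonstrate about real data: projection/reconstruction physics (no
Radon transform or FBP), beam hardening and other HU nonuniformity,
noise non-stationarity across the field of view, phantom tilt, and the
nonlinear behaviour of iterative or deep-learning reconstruction. The TTF
of real iterative reconstructions is contrast- and dose-dependent; here
the simulator's transfer is a single Gaussian, so contrast-dependence
tests are limited to polarity invariance.

## Conventions, sizes, limitations

* Pixel indices are 1-based `(row, col)` as in R throughout; physical
  coordinates are mm with the origin at the image centre, and all
  frequency grids are DC-centred with axes in mm⁻¹.
* DICOM support is deliberately minimal: single-frame CT, explicit VR
  little endian, uncompressed; slices are sorted by scan-axis position
  with instance-number fallback, and HU conversion happens eagerly at
  read time. Rescale slope/intercept for writing are chosen from the HU
  range so the round-trip error is at most `slope/2`.
* Default problem sizes, chosen as the package's standard operating
  points: 512² slices, 5 slices per measurement, 2048-point LSF DFT,
  64² NPS ROIs, 300² task grid. The test suite and the trend scripts run
  these same sizes.
* The d′ obtained this way is an approximation by design: the TTF comes
  from high-contrast inserts while the tasks of interest sit at 1–29 HU,
  so linear-systems transfer is assumed across contrast. The comparison
  of absolute d′ between scanners, kernels or reconstruction families
  should always be read with that assumption in mind.

## A minimal session

```{r example}
library(ctiq)

base <- scan_config(seed = 1)            # 200 mm phantom, Standard kernel
meas <- measure_condition(base)          # simulate + measure TTF and NPS
meas$ttf                                 # f50 / f10 / CNR
meas$nps                                 # noise magnitude, peak, mean

d <- dprime_for_task(meas$ttf, meas$nps, "flat", diameter = 5, contrast = 15)
d

sw <- run_sweep("contrast", measurement = meas)
attr(sw, "fit_flat")$r_squared           # 1 to float precision
```
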