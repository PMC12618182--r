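# ctiq — automated task-based CT image quality

`ctiq` measures task-based image quality from CT phantom image stacks,
fully automatically, and condenses it into the model-observer
detectability index d′. It is aimed at medical physicists doing protocol
optimization or scanner QA who want a one-command path from a phantom
scan (or a simulated one) to a defensible scalar figure of merit — without
hand-placing a single ROI.

## What it computes

For an ACR-464-style phantom (a module with four cylindrical inserts and
a homogeneous module), the package:

1. **Segments** the phantom (global −200 HU threshold, largest component,
   holes filled) and the bone / acrylic / polyethylene / air inserts
   (material-specific HU windows, geometric centroids).
2. **Measures the task-transfer function (TTF)** per insert: edge-spread
   function sampled radially in 10° bins, statistically phase-aligned,
   fitted with a single strictly-monotone logistic; the LSF is the fit's
   analytic derivative and

   `TTF(f) = |DFT(LSF)| / |DFT(LSF)|(0)`,

   summarized by f50, f10 and CNR. An edge-based MTF from the phantom
   boundary is available for phantoms without inserts.
3. **Measures the noise power spectrum (NPS)** in the homogeneous module
   from five 64×64 ROIs over five slices:

   `NPS2D(u,v) = (Δx Δy / (Lx Ly)) · mean |DFT2(ROI − mean)|²`,

   radially averaged along 360 rays at 1° spacing, with noise magnitude
   `√∬NPS`, peak and mean frequency.
4. **Builds a circular task function** (flat or Gaussian profile; e.g.
   5 mm, 15 HU on a 300 px / 0.05 mm grid), `|W|² = Δp⁴ |DFT2(task)|²`.
5. **Computes d′** with the non-pre-whitening (NPW) observer after
   resampling TTF and NPS onto the task grid:

   `d′² = [∬ |W|² TTF² du dv]² / ∬ |W|² TTF² NPS du dv`,

   with NPWE (eye filter) and NPWi (internal noise) variants, and renders
   synthetic nodule images (task blurred by TTF, NPS-shaped noise).
6. **Simulates** ACR-style phantom stacks with exactly known Gaussian
   blur, noise magnitude and noise colour (tube-current and
   reconstruction-kernel surrogates), so every estimator can be validated
   against ground truth; stacks can be written/read as DICOM.

## Worked example

```r
library(ctiq)

base <- scan_config(seed = 1)   # 200 mm phantom, Standard-kernel blur/noise
meas <- measure_condition(base) # simulate both modules, measure TTF + NPS
meas$ttf
#> <ttf_result> material: bone
#>   f50 = 0.416 mm^-1, f10 = 0.860 mm^-1, CNR = 239.0
#>   257 frequencies up to 1.089 mm^-1
meas$nps
#> <nps1d> 32 radial frequencies up to 1.055 mm^-1
#>   noise magnitude 4.021 HU, peak 0.204 mm^-1, mean 0.310 mm^-1

dprime_for_task(meas$ttf, meas$nps, "flat", diameter = 5, contrast = 15)
#> <detectability_result> d' = 16.9841 (NPW observer)
#>   task: flat, 5 mm, 15 HU on 300 px / 0.05 mm grid
#>   inputs: TTF = bone, NPS = nps2d[64x64]

sw <- run_sweep("contrast", measurement = meas)  # d' vs 1..29 HU
attr(sw, "fit_flat")$r_squared
#> [1] 1
```

Reading the numbers: f50 = 0.416 mm⁻¹ is the frequency where the bone
insert's transfer drops to 50 % (the simulated 0.45 mm Gaussian PSF
predicts 0.416 analytically); the noise magnitude 4.02 HU recovers the
configured 4 HU; d′ ≈ 17 says a 5 mm, 15 HU flat nodule is easily
detectable at these settings, and d′ is exactly linear in contrast
(R² = 1), so halving the contrast halves d′.

A thin CLI wraps the same functions
(`inst/cli/ctiq.R simulate | ttf | nps | dprime | sweep | report`), and
`run_pipeline()` drives the whole chain from a YAML config
(`inst/extdata/config-default.yaml`), exporting curves as CSV and the
report as JSON.

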