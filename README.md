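# sliderasl

Slice-direction super-resolution reconstruction, simulation and evaluation
for SLIDER-SMS arterial spin labeling (ASL) perfusion MRI.

## What this is for

ASL measures cerebral blood flow (CBF) from the tiny difference between
magnetically labeled and control images, so its SNR is chronically low.
Acquiring thicker slices buys SNR (signal scales with voxel volume, thermal
noise per readout does not) but costs through-slice resolution.  A
slice-dithered (SLIDER) protocol recovers it: `N_set` thick-slice stacks are
acquired, each shifted along the slice axis by one thin-slice width, and the
thin-slice volume is estimated by solving the resulting linear inverse
problem.  This package is for MR physicists and methods researchers who want
to prototype, reason about, or teach such protocols without scanner time: it
implements the acquisition geometry, the forward operator, the regularized
reconstruction, the SNR-efficiency theory, the standard evaluation metrics,
CBF quantification, and a digital-phantom simulator that exercises all of it.

## The model

Per in-plane voxel, the acquisition obeys

    A · I_hr = I_lr

where `I_hr` is the thin-slice column, `I_lr` stacks the thick-slice
measurements of all shifted sets, and `A` is a banded boxcar-averaging
(Toeplitz-with-shifts) matrix assuming a perfect slice profile: each thick
slice is the mean of the `N_set` thin slices it covers.  The reconstruction
is the Tikhonov-regularized pseudo-inverse computed through the SVD,

    I_hr = (AᵀA + λI)⁻¹ Aᵀ I_lr ,   filter factors  σᵢ/(σᵢ² + λ),

with λ typically 0.1–0.5 (larger λ: less noise, more slice blur).  The
accompanying SNR-efficiency model for `N`-measurement averages,

    var = g² · var_thermal / N + var_physio / N′ ,
    SNR_SLIDER / SNR_ref = √N_set · √(var_ref / var_SLIDER) ,

separates thermal noise (averages as `1/N`, amplified by the parallel-imaging
g-factor) from temporally correlated physiological noise (averages only as
`1/N′`, with `N′ ≤ N` the effective measurement count; an AR(1) helper
computes it).  Evaluation uses the even/odd sum–difference spatial SNR, the
temporal SNR, and a slice-shift Pearson correlation as the blur measure, with
Gaussian FWHM blur matching between conditions.  CBF comes from the standard
single-compartment pCASL model with slice-dependent post-labeling delay
correction.  See the methods vignette
(`vignettes/slider-asl-methods.Rmd`) for assumptions and limitations.

## Worked example

Simulate a two-shift (4-mm) acquisition of a digital phantom, reconstruct
2-mm slices, and evaluate:

```r
library(sliderasl)

geom <- slider_preset("slider2")
geom
#> SLIDER-SMS acquisition geometry (preset 'slider2')
#>   sets: 2, thin 2 mm -> thick 4 mm
#>   MB 4 x 6 groups = 24 thick slices/TR (band spacing 20 mm)
#>   HR grid: 48 slices of 2 mm, coverage 96 mm
#>   timing: TR 5000 ms, label 1500 ms, PLD 1800 ms, readout 6 x 45 ms

phantom <- make_phantom(c(32, 32, hr_grid(geom)$n_slices), seed = 42)
noise   <- noise_model(var_thermal = 16, var_physio = 4, rho = 0.5)
sim     <- simulate_acquisition(phantom, geom, noise, n_meas = 20, seed = 42)

inv  <- tikhonov_inverse(sim$operator, lambda = 0.1)
perf <- reconstruct_series(lapply(sim$sets, perfusion_frames), inv)
m0   <- reconstruct_volume(lapply(sim$m0, function(s) s$data[, , , 1]), inv)

mask <- gm_mask(phantom$gm_probability, threshold = 0.9)
snr_report(perf, mask, condition = "slider2", lambda = 0.1)
#>   condition lambda     ssnr    tsnr blur_corr n_mask degenerate
#> 1   slider2    0.1 7.871423 1.33772 0.7644611  11144      FALSE

cbf <- quantify_cbf(mean_volume(perf), m0, sim$cbf_params,
                    slice_offsets_ms = hr_pld_offsets(geom))
roi_means(cbf, phantom$labels, roi_names = list(`1` = "gm", `2` = "wm"))
#>   roi   mean_cbf n_voxels n_na empty
#> 1  gm 59.7298511    11144    0 FALSE
#> 2  wm 20.2455072     9608    0 FALSE
#> 3   3 -0.5382735      294    0 FALSE
```

The report row says: spatial SNR 7.9 and temporal SNR 1.34 in the 11 144
gray-matter voxels, with a slice-blur correlation of 0.76 at λ = 0.1.  The
quantified ROI means recover the phantom's ground-truth perfusion (GM
60, WM 20 ml/100 g/min) to well under 2%, despite noise and regularization;
the tiny CSF region (label 3) is perfusion-free, so its mean is noise around
zero.

The analytic efficiency calculator works standalone — e.g. four shifted sets
of 20 measurements versus a 40-measurement reference, with strongly
correlated physiological noise (ρ = 0.8) as strong as thermal noise:

```r
b <- noise_budget(n_set = 4, n_meas = 20, n_full = 40,
                  var_thermal = 1, var_physio = 1,
                  n_meas_eff = ar1_effective_n(20, 0.8),
                  n_full_eff = ar1_effective_n(40, 0.8))
snr_efficiency_ratio(b)
#> [1] 1.497854
```

A command-line wrapper for the pipeline stages (simulate, reconstruct,
metrics, snr-theory, quantify, run) lives at `inst/cli/sliderasl.R`:

```sh
Rscript inst/cli/sliderasl.R run \
  --config inst/extdata/slider2_demo.yaml --out-dir out/
```

Volumes are NIfTI-1 (slice axis third, spacing in the header; frame labels
in a JSON sidecar); configs are YAML/JSON; every run writes a
`manifest.json` with seeds and outputs, and re-running a manifest's config
reproduces the outputs exactly.

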