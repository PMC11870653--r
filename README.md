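# fibretensor

Structure tensor microstructure analysis and tractography for 3D white
matter microscopy.

High-resolution phase-contrast tomography of stained brain tissue resolves
myelinated axons as dark tubes on a brighter background. `fibretensor` turns
such volumes into quantitative descriptions of fibre organisation:

- **Scale-space 3D structure tensors.** Per-voxel tensors
  `S = K_rho * (grad f_sigma grad f_sigma^T)` from separable
  derivative-of-Gaussian filtering; per-voxel selection among a suite of
  `(sigma, rho)` scales by maximal scale-normalised fractional anisotropy,
  so fibres of different calibre are each measured at their own scale.
- **Diffusion-like conversion.** Raw eigenvalues are mapped through
  `lambda_i = exp(-lambda_i*/gamma)` and renormalised, reversing the
  ordering so the principal eigenvector is the fibre direction, and FA
  `= sqrt(3/2 * sum((lambda_i - mean)^2) / sum(lambda_i^2))` reads as for a
  diffusion tensor.
- **Orientation statistics.** Area-normalised spherical histograms (FODs)
  of the axial principal directions; Bingham fits with the Orientation
  Dispersion Index `ODI = (2/pi) atan(1/sqrt(k1 k2))` and Dispersion
  Anisotropy `DA = (2/pi) atan((k1 - k2)/k2)`; FA kernel-density summaries
  under inclusion/exclusion ROIs.
- **Tractography and fasciculus metrics.** Deterministic FACT tracking on
  the principal-direction field, QuickBundles clustering (minimum average
  direct-flip distance, running centroids), tortuosity `tau = L/d` and
  maximum deviation `d_max` per centroid, and Kolmogorov–Smirnov / Wilcoxon
  / Brown–Forsythe group comparisons at alpha = 0.05.
- **Synthetic phantoms with exact ground truth.** Parallel, laminar and
  crossing fibre populations, bright cell/vessel obstacles that deflect
  fibres, focal demyelination, and seeded imaging noise — so the whole
  pipeline is testable without multi-gigabyte scan data.

Volumes are read and written as NIfTI (voxel size in the header) or
multi-page TIFF with a JSON sidecar; streamlines as TCK. Voxel sizes are
carried in nm, streamline and kernel geometry in µm.

## A worked example

Build a 90° crossing phantom, estimate structure tensors, and read off the
fibre orientation distribution:

```r
library(fibretensor)

spec <- phantom_spec(grid_shape = c(64, 64, 64), voxel_size_nm = 1000,
                     lamina_thickness_um = 16, crossing_angle_deg = 90)
ph  <- build_crossing_volume(spec)
ef  <- structure_tensor_analysis(ph$volume, sigma = 1, rho = 4, gamma = 0.3)
dirs <- extract_principal_directions(ef)

fod <- build_fod(dirs, pole_axis = "auto", bin_width_deg = 5)
fod
#> <spherical_histogram> 110592 directions, pole y, 5 deg bins, 1225 bins
#>   sum(p * domega) = 1.000000
round(fod_modes(fod, k = 2), 3)
#>       [,1]  [,2]  [,3]
#> [1,] 0.044 0.044 0.998
#> [2,] 0.998 0.044 0.044
fit_bingham(dirs)
#> <bingham_fit> n = 110592, kappa = (1e+04, 0.334), ODI = 0.011, DA = 1.000
fa_density(dirs$fa)
#> <distribution_summary> n = 110592, mean 0.701 +/- 0.101, median/IQR: 0.75/0.13
```

The two FOD modes sit on the true crossing axes (x and z, within one 5°
bin); the near-zero ODI says each population is tightly aligned, and the
saturated DA reflects the two-axis spread. `plot_fod(fod)` and
`plot_fa_density(fa_density(dirs$fa))` draw the corresponding figures.

The full chain — phantom → tensors → statistics → tracking → bundles →
metrics — runs from one declarative config and writes `summary.json`,
`metrics.csv`, `fod.csv` and `tracks.tck` plus a complete parameter log:

```r
cfg <- pipeline_config(preset = "parallel",
                       phantom = phantom_spec(grid_shape = c(128, 128, 128),
                                              voxel_size_nm = 1000),
                       scales = scale_params(sigma = 1, rho = 4),
                       rng_seed = 5)
run <- run_pipeline(cfg)
attr(run, "summary")$metrics$median_tortuosity
#> [1] 1
```

Re-running an identical config reproduces every numeric output.

## Documentation

The methods vignette (`vignettes/fibre-orientation-pipeline.Rmd`) describes
the model and its assumptions, every tunable parameter with units and
defaults, what the phantoms do and do not emulate, and the numerical design
choices. Function-level documentation lives in the roxygen comments in `R/`.
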