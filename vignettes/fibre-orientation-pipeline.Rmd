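---
title: "Quantifying white matter fibre organisation with structure tensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying white matter fibre organisation with structure tensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-resolution 3D microscopy of white matter — for instance x-ray
phase-contrast tomography of osmium-stained tissue at voxel sizes of
75–550 nm — resolves individual myelinated axons and small fasciculi as dark
tubular structures on a brighter background, with cell bodies and blood
vessels appearing bright. At these resolutions the anatomical questions are
quantitative: in which direction do the fibres run in each voxel, how
dispersed are those directions, how do fasciculi bend around obstacles, and
how do these quantities differ between regions (a homogeneous tract versus a
crossing region) or conditions (healthy versus demyelinated tissue)?

`fibretensor` implements that analysis chain end to end: per-voxel 3D
structure tensors with scale-space selection, conversion to diffusion-like
tensors with fractional anisotropy (FA), fibre orientation distributions
(FOD) with Bingham dispersion indices, deterministic FACT tractography on the
principal-direction field, QuickBundles clustering, and streamline shape
metrics with non-parametric group tests. Because the real volumes of interest
are tens of gigabytes, the package also ships a synthetic phantom generator
with exact ground truth; every stage is validated against it.

## The structure tensor model

For a scalar volume $f$, the structure tensor at voxel $j$ is

$$ S_j(\sigma, \rho) = K_\rho * \left( \nabla f_\sigma \, \nabla f_\sigma^\top \right), $$

computed in three steps: (1) gradients by separable filtering with
derivative-of-Gaussian kernels of standard deviation $\sigma$ voxels, (2) the
per-voxel outer product of the gradient with itself, and (3) aggregation over
a Gaussian neighbourhood of standard deviation $\rho$ voxels (the "patch
size"). All filtering is separable and uses mirror-reflection boundaries;
voxels within one $\rho$-kernel radius of the border are flagged and excluded
from statistics by default.

The eigen-decomposition gives $\lambda_1^* \ge \lambda_2^* \ge \lambda_3^*$
(normalised to unit sum) with orthonormal eigenvectors. Gradients of a
tubular fibre are perpendicular to its axis, so the *smallest* eigenvalue's
eigenvector is the fibre direction. To reuse the familiar diffusion-tensor
vocabulary, eigenvalues are converted through the single-parameter model

$$ \lambda_i = e^{-\lambda_i^*/\gamma}, $$

then renormalised to unit sum. The exponential is decreasing, so the
conversion reverses the ordering: after conversion the *principal*
eigenvector is the fibre direction, and FA,

$$ \mathrm{FA} = \sqrt{\tfrac{3}{2}\,
   \frac{\sum_i (\lambda_i - \bar\lambda)^2}{\sum_i \lambda_i^2}}, $$

reads as for a diffusion tensor (0 isotropic, 1 stick-like). We always
normalise $\lambda^*$ before conversion so that $\gamma$ is dimensionless and
transferable across volumes; $\gamma$ values around 0.25–0.35 give a usable
FA dynamic range, and the package default is 0.30.

### Scale-space selection

A single $(\sigma, \rho)$ pair cannot be right for axons whose diameters span
an order of magnitude. The scale-space variant computes the tensor for a
suite of scales and keeps, per voxel, the scale with the largest
*scale-normalised* FA: each scale's FA map is divided by that scale's maximum
FA over the volume, and the dominant scale index is the argmax of the
normalised value (ties go to the lowest index, i.e. the largest patch). The
default suite pairs $\rho$ = 5.50, 4.50, 3.50, 3.50, 2.50, 2.50, 1.50, 1.00
with $\sigma$ = 3.00, 2.75, 2.50, 1.50, 1.50, 1.00, 1.00, 0.50 voxels.
Tensors are recomputed per scale from the same (optionally downsampled)
volume; there is no pyramid resampling between scales.

### Kernel truncation and reported kernel sizes

Gaussian kernels are truncated at radius $\lceil 2\rho \rceil$ voxels
(derivative kernels at $\lceil 4\sigma \rceil$), and the physical "kernel
size" reported for an analysis is the full truncated width converted to
micrometres:

$$ \text{kernel size} = (2\lceil 2\rho \rceil + 1) \times
   \text{voxel size} \times \text{downsampling factor}. $$

`kernel_size_um(2.5, 550, 2)` is 12.1 µm, `kernel_size_um(4, 550, 2)` is
18.7 µm, and `kernel_size_um(5.5, 100, 4)` through `kernel_size_um(1, 100, 4)`
span 9.2–2 µm — the integration scales appropriate for these acquisition
settings. Large volumes are prepared by block-mean downsampling
(`downsample_volume()`), which multiplies the voxel size by the factor.

## Orientation statistics

Principal directions are axial (a fibre pointing along $v$ and $-v$ is the
same fibre), so all angular comparisons use the acute angle. Directions and
FA values are collected under inclusion/exclusion ROI masks
(`extract_principal_directions()`), excluding zero-tensor voxels and filter
borders.

The **FOD** is a spherical histogram parameterised by azimuth and elevation
around a pole axis chosen where the least directional contribution is
expected (`auto_pole_axis()` minimises the mean $|v \cdot \text{axis}|$).
Directions are first mapped to one hemisphere; because lat-long bins subtend
unequal solid angles, each bin's count is divided by $n\,\Delta\omega$ so the
histogram is a true density with $\sum_b p_b \Delta\omega_b = 1$. The band
touching the pole is a single cap bin (azimuth is degenerate there), and
directions exactly on the equator are canonicalised by their in-plane sign so
antipodal inputs always bin identically. The default bin width of 5° resolves
a 35° laminar separation with ample margin.

The FOD's dispersion is summarised by fitting an antipodally symmetric
**Bingham distribution**
$f(x) \propto \exp(-\kappa_1 (a_1 \cdot x)^2 - \kappa_2 (a_2 \cdot x)^2)$:
axes come from the eigenvectors of the orientation scatter matrix
$\tfrac1n \sum v v^\top$ (the mean axis $a_3$ is its principal eigenvector),
and the concentrations $\kappa_1 \ge \kappa_2 \ge 0$ by maximum likelihood.
The normalising constant reduces, via the closed-form Dawson-function
integral over the polar angle, to a smooth periodic 1D integral evaluated by
the trapezoid rule (1024 azimuth nodes, accurate to ~1e-10 and verified
against brute-force spherical quadrature in the tests). Concentrations are
capped at $10^4$; a sample that is numerically uniform returns
$\kappa_1 = \kappa_2 = 0$ with a degeneracy flag. Two indices follow:

* **ODI** $= \tfrac{2}{\pi}\arctan\!\big(1/\sqrt{\kappa_1 \kappa_2}\big)$ —
  overall angular spread, 0 for perfectly aligned fibres, 1 for uniform;
* **DA** $= \tfrac{2}{\pi}\arctan\!\big((\kappa_1 - \kappa_2)/\kappa_2\big)$ —
  anisotropy of that spread, 0 for circular dispersion, 1 when the spread is
  confined to a girdle.

The exact algebra behind these indices varies between published toolboxes;
the forms above were chosen because they satisfy all the qualitative
requirements (both in $[0,1]$; DA $=0$ iff $\kappa_1 = \kappa_2$; ODI $\to$ 0
as $\kappa \to \infty$) while staying simple and invertible. They may differ
numerically from other implementations, which matters only when comparing
absolute index values across software. Note the indices are meaningful for a
single-pathway FOD; for a 90° crossing the fit is still returned (and
flagged non-degenerate) but DA saturates by construction.

FA distributions are summarised by a Gaussian KDE with Scott's-rule bandwidth
($\hat\sigma n^{-1/5}$) and boundary reflection at 0 and 1, reported in
`median/IQR` style.

## Tractography and streamline metrics

Tracking uses the classic **FACT** rule: from each seed, travel along the
current voxel's axial direction — sign-aligned with the previous step — to
the voxel's exit face, voxel by voxel, bidirectionally from the seed.
Termination: leaving the tracking mask, turning by more than the angle
threshold (default 60°; measured between successive sign-aligned voxel
directions), exceeding the maximum length, or hitting a zero-direction voxel.
The step rule is parameter-free (no step size, no interpolation variant); the
angle threshold and seed density are exposed in `tracking_config()` because
no canonical values exist for microscopy data. Seeds are placed at voxel
centres (density 1) or uniformly jittered inside their voxel, reproducibly
from the seed. Exact corner hits advance across the corner deterministically.
Streamline points are voxel-face crossings in physical µm with 0-based voxel
indexing; masks built by thresholding (Otsu or fixed) are cleaned by binary
opening then closing with ball structuring elements.

Streamlines are clustered with **QuickBundles**: a single pass in input
order, assigning each streamline (resampled to 18 points) to the first
bundle whose running flip-aligned centroid is within the MDF threshold
(minimum of direct and flipped mean pointwise distance), else founding a new
bundle. The threshold is data-dependent and deliberately a per-run parameter.
Shape metrics are computed on bundle centroids by default, treating a
centroid as the trajectory of one fasciculus:

* **tortuosity** $\tau = L/d \ge 1$, trajectory length over endpoint
  distance (undefined at $d = 0$: excluded with a warning);
* **maximum deviation** $d_{max}$, the largest orthogonal distance of the
  interior points ($i = 2..N-1$; 0 by convention for $N \le 2$) from the
  endpoint chord, in µm. The metric is the maximum of the distance values,
  per its "maximum amplitude" interpretation.

Metric distributions are compared with two-sample Kolmogorov–Smirnov,
two-sided Wilcoxon rank-sum, and Brown–Forsythe tests at $\alpha = 0.05$; the
Brown–Forsythe statistic is the one-way ANOVA F on absolute deviations from
the group medians (cross-checked against `car::leveneTest(center = median)`).

## The phantom generator

The generator emulates the features of the real volumes that drive each
analysis stage — and nothing more. Myelinated fibres are dark anti-aliased
tubes (voxel intensity interpolates the tube coverage over one voxel width,
so the tensor sees smooth sub-voxel gradients) on a brighter background;
cells and vessels are bright spheres/cylinders; demyelination multiplies the
fibre/background intensity gap by a contrast factor and adds extra cells.
Defaults mirror reported tissue geometry: fibre radii ~2 µm, laminae up to
40–45 µm thick with inclinations up to ~35°, near-orthogonal crossings,
cell radii 2.5–7 µm, vessel radii 5–15 µm.

* `build_parallel_fibre_volume()` — one direction, square (optionally
  jittered) lattice; with two radii, the two grid halves get different
  calibres for scale-space tests.
* `build_laminar_volume()` — alternating slabs whose directions differ by
  the inclination angle, both in the plane containing the fibre axis; slab
  lattices are aligned so tubes never straddle a slab boundary.
* `build_crossing_volume()` — two interleaved laminar populations separated
  by the crossing angle.
* `insert_obstacles()` — fibre centrelines within a halo $h$ of an obstacle
  of radius $R$ are displaced radially away from its surface, in the plane
  perpendicular to the fibre axis, by $d(r) = R\,(R + h - r)/h$ (extended
  continuously inside $r < R$, clamped to the grid), then the image is
  re-rendered from the deflected centrelines. The rule is a deliberately
  simple stand-in — no quantitative deformation model exists for real
  tissue — but its amplitude is anchored to observation: with $h = R$ the
  maximum deviation is $2R$, matching vessel-scale obstacles producing
  deviations up to ~12 µm.
* `apply_demyelination()`, `add_imaging_noise()` — contrast reduction plus
  added cells, and seeded i.i.d. Gaussian noise.

Everything is reproducible bit-for-bit from (spec, seed), and re-rendering
from the stored ground truth reproduces the image exactly — a property the
tests rely on. What the phantoms do *not* model: imaging physics
(phase-retrieval artefacts, detector blur, anisotropic PSF), vacuoles,
curvature of whole pathways, or realistic packing disorder. Passing phantom
tests therefore demonstrates the correctness of the algorithms under
controlled geometry, not robustness to every acquisition artefact of real
scans.

## Numerical choices

* **Eigensolver** — closed-form trigonometric eigenvalues of the symmetric
  3×3 tensors, fully vectorised over voxels; eigenvectors from the
  best-conditioned cross product of rows of $A - \lambda I$, computing the
  best-separated eigenvalue's vector first and completing the frame by
  orthogonalisation, so near-degenerate pairs still return an orthonormal
  frame deterministically. Validated to 1e-10 against `eigen()` on random
  PSD tensors.
* **Zero-tensor mask** — trace below $10^{-12} \times$ the field maximum, or
  below the squared round-off gradient scale of the volume (so constant
  volumes are fully masked). Masked voxels get isotropic eigenvalues, a
  canonical frame and FA 0.
* **Axial sign convention** — first eigenvector component larger than 1e-9
  in magnitude is made positive; ties in the dominant-scale argmax go to the
  lowest scale index.
* **Separable filtering** — implemented as banded-matrix products so BLAS
  does the work; equal to brute-force 3D convolution to 1e-6 relative (tested
  at 16³).
* **Problem sizes** — validation runs use phantoms of 48³–128³ voxels at
  0.5–1 µm: large enough for >10⁵ fibre-interior voxels and hundreds of
  streamlines, small enough that the full suite and the acceptance script
  each complete in a couple of minutes on one CPU.

## Known limitations

Anisotropic voxels are unsupported (resample first). Volumes must fit in
memory; chunked filtering is future work. The FOD weights voxels equally
rather than by anisotropy — with no stated convention, equal weighting is the
least-surprising default. ODI/DA absolute values are comparable within this
package but not necessarily across Bingham toolboxes. Tracking uses one
direction per voxel (no trilinear interpolation, no probabilistic variant),
and no multi-peak FOD decomposition is attempted: in voxels containing
genuine crossings the structure tensor returns a single compromise
direction.

## A worked example

```{r, eval = FALSE}
library(fibretensor)

spec <- phantom_spec(grid_shape = c(64, 64, 64), voxel_size_nm = 1000,
                     lamina_thickness_um = 16, crossing_angle_deg = 90)
ph <- build_crossing_volume(spec)

ef <- structure_tensor_analysis(ph$volume, sigma = 1, rho = 4, gamma = 0.3)
dirs <- extract_principal_directions(ef)
fod <- build_fod(dirs, pole_axis = "auto", bin_width_deg = 5)
fod_modes(fod, k = 2)              # the two crossing axes, within one bin
fit_bingham(dirs)                  # kappa, ODI, DA
plot_fod(fod)

cfg <- pipeline_config(preset = "parallel",
                       phantom = phantom_spec(grid_shape = c(128, 128, 128),
                                              voxel_size_nm = 1000),
                       scales = scale_params(sigma = 1, rho = 4),
                       rng_seed = 5)
run <- run_pipeline(cfg)           # writes summary.json, metrics.csv, tracks.tck
attr(run, "summary")$metrics
```
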