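Package: fibretensor
Title: Structure Tensor Microstructure Analysis and Tractography for 3D
    White Matter Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies white matter fibre organisation in 3D microscopy
    volumes such as x-ray phase-contrast tomography reconstructions.
    Implements scale-space 3D structure tensor estimation with conversion
    to diffusion-like tensors and fractional anisotropy, fibre orientation
    distributions on the sphere with Bingham dispersion indices (ODI, DA),
    deterministic FACT tractography on the principal-direction field,
    QuickBundles streamline clustering, and streamline shape metrics
    (tortuosity, maximum deviation) with non-parametric group comparisons.
    Ships a synthetic phantom generator (parallel, laminar and crossing
    fibre populations, obstacles, demyelination, imaging noise) with exact
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    tiff,
    jsonlite,
    yaml,
    pracma,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
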