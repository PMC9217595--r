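Package: DWIdenoise
Title: Weighted Nuclear Norm Minimization Denoising and ADC Evaluation for
    Diffusion-Weighted MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Patch-based low-rank denoising of diffusion-weighted MR images by
    weighted nuclear norm minimization (WNNM): nonlocal block matching groups
    similar patches into low-rank matrices whose singular values are shrunk by
    noise-adaptive weights. Ships Perona-Malik anisotropic diffusion and total
    variation (ROF) comparators, PSNR/SSIM/MSE image-quality metrics, synthetic
    piecewise-smooth phantoms with additive Gaussian noise, apparent diffusion
    coefficient (ADC) mapping from multi-b DWI signal stacks with ROC analysis
    of chemotherapy-response discrimination, and group-comparison statistics
    (chi-square on contingency tables, t tests from summary data) applied to
    bundled clinical outcome tables from a two-arm comfort-care trial.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    RNifti,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
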