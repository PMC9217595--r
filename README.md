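# DWIdenoise

Patch-based low-rank denoising of diffusion-weighted MR images (DWI) by
**weighted nuclear norm minimisation (WNNM)**, with the evaluation
machinery around it: Perona–Malik and total-variation comparator
denoisers, PSNR/SSIM/MSE quality metrics, apparent diffusion coefficient
(ADC) mapping with ROC analysis of chemotherapy-response discrimination,
and the group-comparison statistics for the bundled clinical outcome
tables of a two-arm comfort-care trial (59 patients per arm).

Intended users: medical-image-analysis researchers who need a
deterministic, fully inspectable WNNM reference implementation in R, and
anyone reproducing the denoiser-comparison / ADC-evaluation protocol it
implements.

## The method

A noisy image is modelled as `n = m + q` with i.i.d. zero-mean Gaussian
`q` of variance σ². For each reference patch, the `p` most similar patches
in a local search window are stacked as columns of a matrix `N_r`, which
would be low-rank without noise. The group is denoised by weighted
singular value thresholding,

    M̂_r = U G_ω(Σ) Vᵀ,   G_ω(Σ)_tt = max(Σ_tt − ω_t, 0),

with noise-adaptive weights

    ω_t = s √p σ² / (σ̂_t + γ),   σ̂_t = sqrt(max(σ_t²(N_r) − p σ², 0)),

so structure-bearing singular values are barely touched while
noise-dominated ones are suppressed. Denoised patches are aggregated by
rank-weighted averaging, and the whole sweep is iterated K times with a
relaxation step that feeds a fraction δ of the residual back in. Every
step is deterministic (ties broken by fixed rules), so repeated runs are
bitwise identical.

## Worked example

```r
library(DWIdenoise)

clean <- generatePhantom(128, 128, blobs = NULL, seed = 11)
noisy <- addGaussianNoise(clean, sigmaFraction = 0.25, seed = 1011)

den <- wnnmDenoise(noisy, sigma = 0.25)          # ~1.5 min on one core
imageMetrics(clean, noisy)
imageMetrics(clean, den)
```

```
MetricReport: PSNR 12.05 dB, SSIM 0.0505, MSE 0.0624 (max 1)
MetricReport: PSNR 31.61 dB, SSIM 0.9646, MSE 0.00069 (max 1)
```

The denoiser recovers ~20 dB: the noisy input sits at 12 dB PSNR with
essentially no structural similarity to the clean phantom (SSIM 0.05), the
WNNM output at 32 dB with SSIM 0.96. The full three-way comparison against
the TV and Perona–Malik baselines at both 25% and 50% noise is one call:

```r
res <- runBenchmark(benchmarkConfig())   # 3 noise seeds x 2 noise levels
```

ADC mapping and response-cohort ROC:

```r
coh <- simulateResponseCohort(59, 59, seed = 7)
rocAnalysis(coh$adc_800, coh$responder)
```

```
ROCResult: AUC 0.949; optimal threshold 0.001124 (sens 0.864, spec 0.932)
```

Clinical table statistics from the bundled fixtures:

```r
vom <- loadClinicalFixture("vomiting")
proportionPercent(vom["experiment", "0"], 59)   # 45.76
chiSquareTest(vom)$pValue                       # << 0.05
```

A thin command-line front end over these functions ships as
`inst/scripts/dwibench.R` (subcommands `phantom`, `noise`, `denoise`,
`metrics`, `benchmark`).

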