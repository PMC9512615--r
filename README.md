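# ctdenoise

Denoising toolkit for single-channel CT images, built around a hybrid
wavelet–bilateral method and the simulation/evaluation machinery needed to
benchmark it: the analytic Shepp–Logan head phantom, seeded noise injectors,
baseline denoisers, full-reference quality metrics and a tidy benchmark
runner.

## The problem and the method

CT rasters are corrupted by a mix of additive (approximately Gaussian) image-
domain noise, impulse ("salt-and-pepper") noise and signal-dependent
multiplicative speckle, `g = x(1 + n)`. Plain smoothing removes noise and
anatomy alike; the hybrid method here splits the image by frequency and
treats each part with the tool suited to it:

1. **Analysis.** A multilevel separable 2D discrete wavelet transform
   (orthogonal filter banks: Haar, db2, db4, sym4) decomposes the image into
   an approximation band `cA` and per-level horizontal/vertical/diagonal
   detail bands `cH, cV, cD`.
2. **Low-frequency branch.** The approximation band is filtered with an
   edge-preserving bilateral filter,

   `g(i,j) = Σ f(k,l) w(i,j,k,l) / Σ w(i,j,k,l)`,
   `w = exp(−((i−k)² + (j−l)²) / 2σ_d²) · exp(−(f(i,j) − f(k,l))² / 2σ_r²)`,

   which averages within flat regions but not across intensity steps.
3. **High-frequency branch.** Detail coefficients are shrunk with a
   threshold family containing the classical hard and soft rules, a
   compromise rule `sign(ω)(|ω| − aλ)` and an improved rule that attenuates
   (rather than kills) sub-threshold coefficients, `a·ω` for `|ω| < λ`. The
   per-subband threshold is selected by BayesShrink, `λ = σ²/σ_x`, with the
   noise level `σ` estimated robustly from the finest diagonal band as
   `median(|cD₁|)/0.674`. Donoho's universal threshold `σ√(2 log N)` and
   manual thresholds are available as alternatives.
4. **Synthesis.** Inverse transform and clipping to `[0, 1]`.

Quality is reported as MSE, PSNR (`10·log10(peak²/MSE)`, peak 1.0) and SSIM
(canonical 11×11 Gaussian window, σ = 1.5).

## Worked example

```r
library(ctdenoise)

phantom <- shepp_logan(512)                                   # clean reference
noisy   <- add_noise(phantom, noise_spec("gaussian", variance = 0.04, seed = 101))
clean   <- denoise(noisy, "q5")                               # hybrid method

quality_report(phantom, noisy)
#> # A tibble: 1 × 3
#>      mse  psnr   ssim
#>    <dbl> <dbl>  <dbl>
#> 1 0.0241  16.2 0.0757
quality_report(phantom, clean)
#> # A tibble: 1 × 3
#>       mse  psnr  ssim
#>     <dbl> <dbl> <dbl>
#> 1 0.00611  22.1 0.229
```

The noisy image carries MSE 0.024 (16.2 dB); the hybrid output cuts the
error fourfold to 0.006 (22.1 dB) and roughly triples the structural
similarity. `run_benchmark()` repeats this over grids of noise levels,
methods (`q1` wavelet-only, `q2` bilateral-only, `q4` non-local means, `q5`
hybrid) and seeds, returns a tibble via `tidy()`, plots via `autoplot()` and
exports a stable CSV via `export_grid()`. A thin command-line wrapper with
subcommands `phantom`, `addnoise`, `denoise`, `evaluate` and `benchmark`
lives at `inst/exec/ctdenoise`.

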