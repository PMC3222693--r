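# rltv

Richardson–Lucy deconvolution with total-variation (TV) regularization
for 3D fluorescence microscopy stacks recorded in photon-counting mode —
with an automatic, per-iteration estimate of the TV regularization
parameter and a stopping criterion derived from its trace.

## Who this is for

Microscopists and image-analysis developers who want to deconvolve
confocal z-stacks without hand-tuning the regularization weight, and who
need a reproducible synthetic benchmark for deconvolution parameters.

## The method

Photon-counting acquisition makes the image formation model
`i = Poisson(o ⊗ h)` exact.  Maximum-likelihood inversion with a TV
penalty gives the multiplicative update

    o[s+1] = ( (i / (o[s] ⊗ h)) ⊗ h* ) · o[s]  /  ( 1 − λ · div(∇o[s]/|∇o[s]|) )

starting from `o[0] = i`.  The package contributes:

* **λ estimation** — the least-squares minimizer
  `λ_lsq = C · Σ r·d / Σ d²` of the Euler–Lagrange residual `r − λ·d`,
  with `C` calibrated once so that the first-iteration value equals
  `50/SNR` (the empirically near-optimal setting);
* **stopping rule** — iterate until five steps past the running maximum
  of the `λ_lsq` trace;
* **peak SNR estimation** — `√(max of the 3×3×3-averaged stack)`, the
  Poisson mean/σ at the brightest region;
* **PSF estimation** from fluorescent-microsphere stacks (detection,
  subvoxel alignment, background subtraction, √M noise gain from summing
  M profiles, grid resampling);
* **a synthetic benchmark** (blocky / honeycomb / bead-cluster phantoms,
  Poisson degradation to a target peak SNR, λ grid searches, the
  `λ_opt ≈ 50/SNR` inverse-relation fit, τ₂/τ₁ oscillation diagnostics).

## Worked example

```r
library(rltv)

# a known object, blurred and Poisson-degraded to peak SNR 22.7
truth <- generatePhantom("blocky", shape = c(32, 64, 64), seed = 1)
psf   <- syntheticPSF(voxelDims(truth), c(5, 9, 9),
                      sigma_xy = 0.15, sigma_z = 0.45)
ds    <- degradeStack(truth, psf, target_snr = 22.7, seed = 1)

estimatePeakSNR(degradedStack(ds))
#> Peak SNR estimate: 22.78 (peak mean 518.963 counts, sqrt-of-mean)

res <- deconvolve(degradedStack(ds), psf, lambda = "auto",
                  pad_mode = "none",
                  truth = ImageStack(stackValues(truth) * ds@scale,
                                     voxelDims(truth),
                                     "arbitrary-intensity"))
res
#> DeconvolutionResult: 9 iterations, stop reason 'converged-window'
#>   recommended estimate: iteration 9
#>   lambda_lsq calibration C: 6.90095
#>   last step: lambda 4.601, tau1 0.04655

head(diagTrace(res), 3)
#>   iteration   lambda       tau1      tau2         mse
#> 1         1 2.194835 0.09044162        NA 0.002082656
#> 2         2 2.728379 0.04620277 0.1333740 0.001827606
#> 3         3 3.902623 0.04255548 0.0752889 0.001673877
```

The first-iteration `lambda` is exactly `50/22.7 = 2.195`; the trace
rises to its maximum and the run stops five steps later.  The `mse`
column (normalized mean squared error against the known truth) falls
from 0.0021 to 0.0012 at the stopping point — compared with 0.0015 for
the degraded input itself.

A λ grid search on the same dataset finds the MSE-optimal fixed value:

```r
gr <- lambdaGridSearch(ds, seq(0, 5, by = 0.5), max_iter = 60)
lambdaOpt(gr)
#> [1] 2
```

close to the `50/SNR = 2.2` rule.

## Command line

A thin wrapper over the same functions is installed as `exec/rltv`:

```sh
rltv snr stack.tif
rltv deconvolve image.tif --psf psf.tif --lambda auto --out restored.tif
rltv estimate-psf beads.tif --threshold 50 --window 5,6,6 --out psf.tif
rltv simulate --texture blocky --snr 22.7 --seed 1 --out-prefix run1
rltv benchmark --snr 5,10,22.7,50,100 --seeds 1,2,3 --out report.csv
```

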