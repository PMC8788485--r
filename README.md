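# medreg

Penalized-likelihood PET image reconstruction with similarity-driven
median regularization, for imaging scientists who want a compact,
fully-simulated testbed for median-prior and super-resolution
reconstruction methods.

## The method

Emission data are Poisson counts with means `ḡ = H f + r`, where `H` is a
parallel-beam strip-integral system matrix and `f` the activity image.
The package solves the penalized-likelihood problem

    f̂ = argmin_f [ −L(g|f) + β R(f, m) ],
    R(f, m) = Σ_j Σ_{j'∈N_j} w_jj' ψ(f_j − m_j'),   ψ(ξ) = √(ξ² + ε),

where `m` is an auxiliary *median image* in register with `f` and the
weights `w` are either uniform (the non-weighted median regularizer,
NWMR) or driven by non-local-means patch similarities
`w̃_jj' = exp(−‖ρ(N_j) − ρ(N_j')‖² / δ²)` (the similarity-driven median
regularizer, SDMR), so that fine structure occupying less than half the
median window survives the median vote. The optimizer alternates
complete-data ordered-subsets EM (COSEM) likelihood updates — each pixel
a closed-form root of a scalar quadratic, via half-quadratic optimization
transfer — with iteratively reweighted sweeps that drive `m` to the
weighted median of its neighborhood. Reconstructing on a twice-finer grid
from the same sinogram gives single-frame super-resolution (SR). Local
quadratic (LQR), local non-quadratic (LNQR) and non-local quadratic (NLR)
comparator penalties, parametric circle/brain phantoms with ROI masks, a
Poisson sinogram simulator, and the evaluation suite (MPE, CRC/MCRC,
MSSIM, PSNR, RMSE, MAE, VIF, line profiles, background-noise-based β
matching) are included. See the methods vignette
(`vignettes/median-regularized-pet.Rmd`) for the full model and the
design choices.

## Worked example

Super-resolution SDMR reconstruction of the built-in circle phantom, with
the smoothing parameter chosen by background-noise matching (target: 10%
of the true background activity), 200 iterations x 4 subsets, 500,000
counts, and K = 10 noise trials:

```r
library(medreg)
res <- run_method_comparison(methods = "hr_sdmr", K = 10,
                             master_seed = 1, verbose = TRUE)
res$summary[, c("beta", "noise", "mpe", "MSSIM", "PSNR", "RMSE")]
res$mcrc
```

prints (seed 1):

```
hr_sdmr: beta = 0.0649 (noise 0.0256, target 0.02555)
     beta  noise   mpe  MSSIM  PSNR   RMSE
   0.0649 0.0263 16.33 0.8666 24.70 0.0582
  roi hr_sdmr
   R1  0.9457
   R2  0.8919
   R3  0.8198
   R4  0.9464
   R5  0.9537
   R6  0.9671
```

Read: the matched smoothing parameter is β ≈ 0.065; over 10 Poisson
trials the mean percentage L2 error of the HR reconstruction against the
HR phantom is 16.3%; the anecdotal reconstruction scores PSNR 24.7 dB
against the phantom (both normalized by the phantom maximum); and the
mean contrast recovery coefficient rises with ROI size from 0.82 (4-pixel
radius) to 0.97 (14-pixel radius) — small hot structures lose the most
contrast, the expected partial-volume behavior. `run_method_comparison()`
with the default seven-method list reproduces the full LR/HR x
{LQR, LNQR, NWMR, SDMR, NLR} comparison; `run_beta_sweep()` traces MPE
and MCRC over β on the brain phantom.

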