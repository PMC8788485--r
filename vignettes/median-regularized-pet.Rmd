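---
title: "Penalized-likelihood PET reconstruction with similarity-driven median regularization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized-likelihood PET reconstruction with similarity-driven median regularization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 6)
library(medreg)
```

## The estimation problem

Emission tomography measures projection counts $g_i$ whose means follow the
linear model $\bar g_i = \sum_j H_{ij} f_j + r_i$, where $f_j \ge 0$ is the
activity in pixel $j$, $H_{ij} \ge 0$ is the probability-weighted
contribution of pixel $j$ to detector pair $i$, and $r_i$ is a constant mean
background (zero by default here). Counts are independent Poisson, so
maximum-likelihood estimation minimizes
$-L(g \mid f) = \sum_i \left(\bar g_i - g_i \log \bar g_i\right)$ (constant
$\log g_i!$ terms dropped). Unregularized ML amplifies noise badly at
clinical count levels, so the package solves the penalized-likelihood (PL)
problem

$$\hat f = \arg\min_f \left[-L(g \mid f) + \beta\, R(f)\right].$$

### The weighted median regularizer

The regularizer couples the image to an auxiliary *median image* $m$ on the
same grid,

$$R(f, m) = \sum_j \sum_{j' \in N_j} w_{jj'}\, \psi(f_j - m_{j'}),
\qquad \psi(\xi) = \sqrt{\xi^2 + \varepsilon},$$

with $N_j$ a $3\times 3$ window including $j$ itself and $\psi$ a
differentiable stand-in for $|\xi|$. Minimizing $R$ over $m$ with $f$ fixed
drives each $m_j$ to the (smoothed) weighted median of the image values
around it; minimizing over $f$ with $m$ fixed attracts each pixel toward
the median-image values in its window. Because the attractor is a median
rather than a mean, isolated impulsive deviations do not drag their
neighbors, and locally monotonic regions and straight edges are preserved.

With uniform weights $w_{jj'} = 1/|N_j|$ this is the non-weighted median
regularizer (NWMR). Its known weakness is that any structure occupying
less than half the window elements is voted away by the majority. The
similarity-driven variant (SDMR) replaces the uniform weights with
non-local-means style patch weights,

$$w_{jj'} = \frac{\tilde w_{jj'}}{\sum_{j' \in N_j} \tilde w_{jj'}},
\qquad \tilde w_{jj'} =
\exp\!\left(-\Delta\rho_{jj'} / \delta^2\right),$$

where $\Delta\rho_{jj'}$ is the squared L2 difference between the
$3\times3$ patches centered at $j$ and $j'$ (reflect padding at borders).
Neighbors whose patch resembles the center patch get large median weights;
neighbors across an edge get weights near zero, so fine structure survives
the median vote. In homogeneous regions all patches look alike and SDMR
reduces to NWMR.

### Optimization

The likelihood is handled by complete-data ordered subsets (COSEM): the
latent counts $C_{ij} = g_i H_{ij} f_j / \bar g_i$ are accumulated per
angle-interleaved subset, which keeps a global objective while giving
OSEM-like acceleration. The penalty is handled by optimization transfer:
$\psi$ is majorized at the current iterate by the half-quadratic parabola
with curvature $\omega(\xi) = \dot\psi(\xi)/\xi = 1/\sqrt{\xi^2 +
\varepsilon}$, which makes each pixel update the positive root of a scalar
quadratic $a f^2 + b f + c = 0$ — closed form, nonnegativity guaranteed.
The median image is refreshed after each iteration by `Q` sweeps of the
iteratively reweighted mean
$m_j \leftarrow \sum_{j'} w_{j'j}\,\omega(f_{j'} - m_j) f_{j'} /
\sum_{j'} w_{j'j}\,\omega(f_{j'} - m_j)$ (transposed weights, as the
gradient of $R$ in $m$ dictates), each sweep a monotone surrogate step.
With one subset and frozen weights every step provably decreases the joint
objective; the test suite asserts this numerically for all regularizers.

Super-resolution (SR) reconstruction needs no extra machinery: the same
sinogram is reconstructed with a system matrix built on a twice-finer
grid. The area-weighted strip projector guarantees every fine pixel is
covered by every view, which is what makes the SR inverse problem
well-posed enough to attempt.

### Comparator regularizers

The package also implements the standard comparators, all through the same
surrogate machinery: the local quadratic penalty (LQR,
$\psi(\xi)=\xi^2/2$ on neighbor differences of $f$), the local
non-quadratic penalty (LNQR, $\psi$ as above on neighbor differences), and
the patch-weighted non-local quadratic penalty (NLR). For these pairwise
penalties the per-pixel surrogate comes from convexity-based pair
splitting — each unordered pair contributes to the pixel from both
directions of the sum, giving quadrupled curvature and midpoint targets —
so LQR and LNQR share the monotone-descent guarantee; NLR's patch weights are not symmetric, so it
runs the same update without that formal guarantee. Two NLR defaults
differ from the median methods, both because its mechanism differs: its
search window is $5\times5$ (a $3\times3$ window would leave a "non-local"
method with no non-local reach), and its similarity bandwidth sits at the
*noise* scale rather than the structure scale — for a quadratic penalty
the weights are the only thing standing between an edge and the
smoothing, so they must discriminate structure from noise, whereas the
median vote preserves edges even under near-uniform weights. That noise
scale must reflect the data, not the current (smoothed, or warm-started)
iterate, so it is measured once per run: a short unregularized burn-in
(10 COSEM iterations from the count-matched uniform start) produces a
data-driven image, the bandwidth is set to the square root of three times the median
squared patch difference of that image, and stays frozen thereafter.
Re-estimating it from the evolving iterate is unstable — as the image
smooths, the measured difference scale collapses and the weights start
protecting residual noise.

## Parameters that matter

- `beta` — the smoothing weight. It is expressed in *sensitivity-normalized
  units*: the penalty enters the objective multiplied by `beta *
  mean(sensitivity)`, where sensitivity is the per-pixel column sum of the
  system matrix. With the strip projector the mean sensitivity is roughly
  the number of views, so a raw multiplier would make useful `beta` values
  depend on the projector normalization, the count level and the grid;
  normalizing by it makes `beta` dimensionless, with the interesting range
  roughly 0.02–1 for the median methods (the quadratic LQR, whose
  restoring force grows linearly, needs 10–100x more).
- `epsilon` — the $\psi$ smoothing constant (activity$^2$). Default:
  $\sqrt{\varepsilon}$ equal to 1% of the dynamic range, proxied by
  $4\times$ the mean of the count-matched uniform initializer. Much
  smaller values make $\psi$ a sharper $|\cdot|$ but the surrogate
  curvature $1/\sqrt{\varepsilon}$ then damps updates so strongly wherever
  $f \approx m$ that the optimizer stalls between the initializer and the
  solution (classic IRLS starvation); 1% is small enough that the penalty
  still acts as a median attractor at the image's contrast scale.
- `delta` — the patch-similarity bandwidth (activity units). For the
  median weights the default is `sqrt(P) * 0.3 * range`, i.e. a
  per-patch-pixel RMS difference of 30% of the dynamic range counts as
  structure, fixed once per run (`default_delta()`). Two alternatives
  were rejected for this role. Bandwidths at the *noise* difference scale
  make the median weights respond to Poisson noise — and because Poisson
  variance grows with activity, the hottest regions get the most
  selective weights and their noise is preserved as if it were structure.
  Bandwidths re-measured from the *current iterate* are unstable for a
  median prior: a regularized iterate has strongly correlated neighboring
  patches, the measured difference scale collapses, and the weights start
  tracking the method's own staircase texture. The data-scale default
  keeps the median weights near-uniform in every homogeneous region at
  study count levels while suppressing genuine contrast edges. (The NLR
  comparator is the exception — see below.)
- `n_iterations`, `n_subsets` — 200 and 4 in the study protocol; the
  brain-phantom sweep ships with a 100-iteration default, which is close
  to converged on the native grid.
- `n_sub_iterations` (`Q`) — median-image sweeps per iteration, default 2:
  the sweep is a fast fixed point and is refreshed every iteration anyway.
- `weight_refresh` — adaptive weights recomputed `per_subset` (the literal
  schedule), `per_iteration` (default in the experiment drivers; visually
  and numerically indistinguishable at a quarter of the weight cost), or
  `fixed` (frozen; used by the monotonicity tests).

## The simulator and what it does (not) emulate

Phantoms are piecewise-constant, rasterized by pixel-center test so ROI
means and the LR/HR block-sum relation stay exact. The circle phantom (a
base disk with six hot disks of graded radii at 4:1 contrast) and the
brain-like slice (gray/white 4:1, ventricles, a warm disk outside the head
for noise measurement) are frozen, versioned stand-ins drawn in code —
approximations to the figures of the study they emulate, not replicas, so
regional numbers are regression-stable but not literature-exact. The
projector is an area-weighted parallel-beam strip model (128 bins x 128
views over 180°); data are Poisson draws scaled to 500,000 expected
counts. Not modeled: attenuation, scatter and randoms structure (only a
constant mean background term), detector blur, positron range, dead time,
3D effects. Passing tests therefore demonstrate the statistical behavior
of the regularizers under ideal system modeling, not clinical performance.

The study protocol chooses each method's `beta` by background-noise
matching: the standard deviation over a flat background region is brought
to a common target, here fixed a priori at 10% of the true background
activity, a mid-range operating point for count-limited emission images.
`match_beta()` scans a log grid from the smooth end downward (cold start
at the strongest smoothing, warm continuation toward weaker smoothing —
the stable direction for a median prior, whose solution at strong
smoothing holds a flat start flat) and refines the bracketing pair by
log-log interpolation. The background standard deviation is not monotone
in `beta` for the diffusive LQR (over-smoothing bleeds structure into the
background), so the scan targets the noise-dominated crossing.

## Numerical choices

- Pixel updates solve $a f^2 + b f - c = 0$ ($c \ge 0$) in the
  cancellation-free form, with an EM fallback ($f = c/b$) when
  $a < 10^{-12}\max(|b|,1)$; both branches agree in the overlap.
- $\bar g$ is floored at $10^{-15}$ before division where $g_i = 0$;
  observed counts on a vanishing mean projection raise a model-mismatch
  error.
- Pixels with zero sensitivity are frozen at zero; with this projector
  every pixel has positive sensitivity, so the guard is latent.
- The likelihood passes run over a cached row-major copy of the system
  matrix; `precision = "single"` stores that copy (and the gather
  buffers) in single precision with double accumulation — the
  conventional storage for PET system matrices — and is what the
  experiment drivers use. The default `"double"` path is kept as the
  reference and is what the oracle tests (MLEM equivalence at $10^{-10}$)
  run against.
- Initialization: uniform image matched to the observed counts
  ($f^0 = \sum_i g_i / \sum_j s_j$), $m^0 = f^0$.
- The smoothed weighted median has a unique fixed point for
  $\varepsilon > 0$ (strictly convex objective), so no tie-breaking is
  needed.

## Scale of the shipped studies

`run_method_comparison()` reproduces the seven-method circle-phantom
protocol (200 iterations, 4 subsets, 500k counts) with K = 10 noise trials
by default; `run_beta_sweep()` runs the brain phantom over
$\beta \in \{0.05, \dots, 0.7\}$ at K = 10 trials and 100 iterations.
These desk-scale defaults keep a full run in minutes; raising `K` to 50
and `n_iterations` to 200 reproduces the full-scale protocol unchanged.

## Worked example

```{r example, eval = FALSE}
geom <- pet_geometry(128, 128, pi, 128)
sm_lr <- system_matrix(geom, 128)     # native grid
sm_hr <- system_matrix(geom, 256)     # super-resolution grid
truth <- rasterize(circles_phantom(), 128)
sim <- simulate_sinogram(truth, sm_lr, target_counts = 5e5, seed = 1)

rec <- reconstruct(sim$sino, sm_hr,
                   recon_config("sdmr", beta = 0.1, sr_factor = 2,
                                precision = "single"))
plot(rec)
mpe(rec$f, rasterize(circles_phantom(), 256) * sum(sim$truth) / sum(truth))
```

## Known limitations

- The median window, patch size (both $3\times3$) and the `delta` /
  `epsilon` defaults are choices; the study source does not specify them.
- The comparator penalties (LQR, LNQR, NLR) are standard minimal readings
  of their one-line descriptions, not replications of unpublished code.
- Printed accuracy numbers from the emulated study depend on phantom
  geometry that is depicted but not numerically specified; the frozen
  stand-ins reproduce orderings and magnitudes, not digits.
- NLR's asymmetric weights void the formal monotonicity guarantee (in
  practice its objective decreases as well).
- 2D only; no attenuation/scatter modeling beyond a constant background
  term.
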