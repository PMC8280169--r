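# swdmorph

Landmark-free volumetric morphometrics for 3D image volumes (micro-CT,
MRI), for comparative biologists, paleontologists and neuroimagers who
want to characterize, segment and compare whole shapes rather than
hand-picked landmark sets.

The package implements two complementary constructs:

* **Spherical wave decomposition (SWD).** A volume $s(\mathbf x)$ is
  expanded about its centroid in products of spherical harmonics and
  spherical Bessel functions,

  $$s(r,\theta,\phi) \;\approx\; \sum_{n=1}^{N}\sum_{l=0}^{L}\sum_{m=-l}^{l}
    c_{nlm}\, \mathcal N_{nl}\, j_l(k_{l,n} r)\, Y_{lm}(\theta,\phi),
    \qquad k_{l,n} = z_{l,n}/R,$$

  with Dirichlet wavenumbers ($z_{l,n}$ the $n$-th root of $j_l$) on the
  support sphere of radius $R$. The coefficients `c[n, l, m]` are the
  shape descriptor; least-squares model-order selection over the angular
  degree $L$ yields a *shape complexity*; analytic derivatives of the
  basis drive boundary detection and a segmentation pipeline whose
  connected-component filter excludes isolated isointense grains that
  defeat histogram thresholds.

* **Symplectomorphic registration.** Non-linear warps are computed by
  evolving grid positions and momenta $(q, p)$ under a demons-style
  image force smoothed by a Gaussian coupling kernel
  $Q(x,x') \sim N(x', S^{-1})$, integrated with a symplectic
  (semi-implicit Euler) scheme whose undamped step preserves phase-space
  volume exactly. On top of it sit groupwise template construction with
  the unbiased shape update, posture-factored morphological distances
  (rigid pose removed before the non-rigid comparison), and minimum
  spanning trees over distance matrices.

Everything runs on synthetic phantoms generated in code — rippled dunes,
nested shells, corrugated balls, articulated limbs, deformed pairs with
known ground-truth fields — so the full test suite needs no external
data.

## Worked example

A 48³ phantom — a ball corrugated at pure angular degree 6 — is
decomposed, its complexity estimated, and compared against a plain ball:

```r
library(swdmorph)
skull <- make_corrugated_ball(48, radius = 16, l = 6, amp = 0.15)
shape_complexity(skull, orders = 0:8)
#> <model_order_curve (swd_angular): selected order 6, noise floor 0.1576>
#>  order      rms
#>      0 0.206420
#>      1 0.205961
#>      2 0.205490
#>      3 0.205415
#>      4 0.204437
#>      5 0.204228
#>      6 0.159271
#>      7 0.158970
#>      8 0.157617
#> complexity: 6   coefficients: 196
```

The RMS misfit barely moves over degrees 0–5, drops sharply once the
basis can represent the $l = 6$ corrugation, and plateaus again — so the
plateau rule reports complexity 6, with $N(L+1)^2 = 196$ coefficients at
the selected bandwidth. The residual floor (~0.16) is the radial
truncation error of fitting a hard-edged indicator, not angular misfit.

```r
fit <- swd_forward(skull, L = 6, N = 8, samples = "grid")
fit
#> <swd_coefficients L=6 N=8 (392 terms)  R=18.63  fit=least_squares  rms=0.07902>

ball <- make_ball(48, radius = 16)
ref  <- swd_forward(ball, 6, 8, center = fit$center, R = fit$R, samples = "grid")
dissimilarity_map(ref, fit, 2, ball)$fraction   # compare at coarse bandwidth
#> [1] 0.0140
dissimilarity_map(ref, fit, 6, ball)$fraction   # corrugation now resolved
#> [1] 0.0720
```

At bandwidth $L' = 2$ both shapes reconstruct as nearly the same ball and
1.4% of voxels differ; at $L' = 6$ the corrugation is resolved and the
dissimilar fraction rises to 7.2% — the bandwidth-resolved comparison
that localizes *where* and at *what scale* two specimens differ.

A shell entry point wraps the same functions
(`inst/cli/swdmorph phantom|fit|reconstruct|order|segment|register|compare`),
writing a JSON manifest of the effective configuration next to every
output.

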