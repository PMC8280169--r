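---
title: "Volumetric morphometrics with spherical waves and symplectomorphic registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric morphometrics with spherical waves and symplectomorphic registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdmorph)
```

Landmark-free geometric morphometrics asks two questions of a 3D image
volume (a micro-CT scan of a skull, an anatomical MRI of a brain): *what
shape is in here* (characterization and segmentation), and *how does it
differ from another specimen* (registration and comparison). `swdmorph`
answers the first with a spherical wave decomposition (SWD) and the second
with a symplectic phase-space registration regularized by a Gaussian
coupling kernel. This vignette explains the models, the parameters that
matter, the synthetic phantoms the test suite runs on, and the numerical
choices behind the implementation.

## The spherical wave decomposition

A volume is a scalar field $s(\mathbf{x})$ sampled on a voxel grid. Just
as a rippled dune is parsimoniously described by a handful of plane
waves, a compact biological shape is parsimoniously described in a basis
adapted to its geometry: spherical coordinates $(r, \theta, \phi)$ about
the object's centroid. The basis functions are products of spherical
harmonics (angular structure) and spherical Bessel functions (radial
structure),

$$\Psi_{nlm}(r,\theta,\phi) \;=\; \mathcal{N}_{nl}\,
  j_l(k_{l,n}\, r)\; Y_{lm}(\theta,\phi),
  \qquad 0 \le l \le L,\; |m| \le l,\; 1 \le n \le N,$$

and the expansion $s \approx \sum_{nlm} c_{nlm} \Psi_{nlm}$ turns the
shape into a complex coefficient array `c[n, l, m]` — the quantitative
descriptor everything else builds on.

Choices a user should know about:

* **Radial boundary condition.** The wavenumbers are
  $k_{l,n} = z_{l,n}/R$ with $z_{l,n}$ the $n$-th positive root of
  $j_l$, i.e. a Dirichlet condition $j_l(kR) = 0$ on the support sphere
  of radius $R$. This gives a discrete family orthogonal on $[0, R]$
  with weight $r^2$. (Neumann or free-space families would serve too;
  Dirichlet is this package's documented choice, and it has one visible
  consequence — every fitted function is pinned to zero at $r = R$ —
  which the segmentation module works around, below.)
* **Harmonic convention.** Complex orthonormal harmonics with the
  Condon–Shortley phase; real inputs therefore satisfy
  $c_{n,l,-m} = (-1)^m \overline{c_{n,l,m}}$, which the suite checks on
  every fitted volume.
* **Support sphere.** By default the center is the intensity centroid
  and $R$ is 1.05 times the maximum distance to a voxel above 10% of
  the peak intensity. Both are recorded in the coefficient container.
* **Quadrature.** Product Gauss–Legendre in $\cos\theta$ (exact for
  harmonic products up to degree $2L$), uniform in $\phi$
  ($\ge 2L+1$ nodes), Gauss–Legendre in $r$ with enough nodes for the
  $\sim N + L/2$ radial oscillations. Basis functions are normalized to
  unit norm under this quadrature, so the Gram matrix is the identity to
  $10^{-6}$ or better (the suite verifies $L=4, N=4$ at $1.3\times
  10^{-14}$).

**Estimating the coefficients.** The naive route — applying the adjoint
(conjugate-transpose) of the basis — is only exact when the basis is
orthonormal over the actual sample set. `swd_forward` therefore offers
two estimators: `projection` (quadrature inner products on the spherical
grid; fast, and convergent to the true coefficients as the grid refines)
and `least_squares` (QR solution of the overdetermined linear system;
the reconstruction route). By default least squares fits **all voxels
inside the support sphere**, which makes the fit exact for any volume
that is band-limited in the basis — the property the round-trip tests
exercise at machine precision. For high bandwidths (segmentation uses
$L=6, N=16$, i.e. 784 functions) the system is instead solved on the
quadrature nodes (`samples = "grid"`), trading a little interpolation
error for tractability.

**Derivatives are analytic.** Because the basis is known in closed form,
the gradient of a reconstruction is computed termwise from
$j_l'(x) = j_{l-1}(x) - \tfrac{l+1}{x} j_l(x)$ and the ladder identity
$\partial_\theta Y_{lm} = \tfrac12\sqrt{(l-m)(l+m+1)}\,Y_{l,m+1}e^{-i\phi}
- \tfrac12\sqrt{(l+m)(l-m+1)}\,Y_{l,m-1}e^{i\phi}$ — no finite
differences. The azimuthal term $imY_{lm}/(r\sin\theta)$ is regular
because $Y_{lm} \sim \sin^{|m|}\theta$ near the poles; the implementation
clamps $\sin\theta$ and $r$ at $10^{-9}$, which affects only voxels lying
exactly on the polar axis or at the center. A finite-difference
cross-check in the suite confirms the gradients to $10^{-5}$.

## Model order as shape complexity

How many basis functions does a shape need? Fitting nested models of
increasing order by least squares gives a non-increasing RMS curve; the
optimal order is where the curve stops improving. The classic 1-D
illustration is a cubic polynomial: 101 noiseless samples of
$y = 1 + 2x - x^2 + 0.5x^3$ fitted with polynomials of order 0–10 give
an RMS that collapses to numerical zero exactly at order 3 and stays
there. With noise at twice the data's mean absolute deviation the curve
keeps creeping downward past the true order as the fit starts absorbing
noise — the selection is then genuinely ambiguous, and the package
reports whatever the rule yields rather than pretending otherwise.

**The plateau rule.** An improvement from one order to the next counts
as significant when it exceeds
$\max(\texttt{noise\_floor\_fraction}\cdot\mathrm{rms},\ \texttt{abs\_tol})$
with defaults $0.01$ and $10^{-9}$. The selected order is the one reached
by the **last** significant improvement — equivalently, the smallest
order beyond which the curve is flat to within the noise. The
"first insignificant improvement" variant is not used because it fails
on shapes whose spectrum has gaps: a ball corrugated purely at degree
$l=6$ shows no improvement at $L = 1..5$ and a large drop at $L = 6$; a
first-crossing rule would stop at 0, the last-improvement rule correctly
reports 6. `shape_complexity` applies this rule over the angular degree
$L$ with the radial order held fixed (a joint $(L, N)$ search is out of
scope), so a plain ball has complexity 0 and an $l$-corrugated ball has
complexity $l$.

**Spectral smoothing.** `weighted_smoothing` damps coefficients by the
heat kernel in both indices,
$c_{nlm} \leftarrow c_{nlm}\exp\{-\sigma[l(l+1) + (k_{l,n}R)^2]\}$, with
$\sigma$ dimensionless. This is this package's concrete instantiation of
weighted spectral smoothing (the literature describes the idea without
fixing weights); reconstruction energy is non-increasing in $\sigma$ and
the $\sigma \to \infty$ limit retains only the $(n{=}1, l{=}0)$ mode.

## Segmentation with grain exclusion

Histogram thresholding classifies voxels by intensity alone, so any
isolated grain that happens to be isointense with bone — ubiquitous sand
grains in fossil CT — lands in the bone class. The SWD pipeline uses
spatial structure twice to avoid this:

1. intensities are clustered into $K$ classes (1-D k-means, deterministic
   quantile initialization);
2. each non-background class's binary indicator is fitted by SWD and
   reconstructed — a spatially coherent, band-limited "response" per
   class. The background (lowest-intensity) class is represented as the
   complement $1 - \sum_{k \ge 2}$ responses, which stays exact at and
   beyond the support radius where the Dirichlet family pins every
   *fitted* indicator to zero;
3. each voxel takes the class of maximal response (ties to the lower
   class index);
4. connected components smaller than `min_component` voxels (default 27,
   a $3^3$ grain; 26-connectivity) are absorbed into their surrounding
   label — the explicit grain-exclusion knob.

On a 64³ nested-shells phantom (air core, bone shell at 100, rock matrix
at 40) with 50 isointense 1–2-voxel speckles scattered in the matrix, the
pipeline reaches Dice ≥ 0.95 per class with zero speckle voxels in the
bone label, while the histogram threshold keeps all of them. The radial
order $N$ is the parameter that matters here: concentric interfaces are
radial step edges, and the assignment boundary lands within a fraction of
a voxel of the true interface once $N \gtrsim 12$ for shells a few voxels
thick.

## Symplectomorphic registration

Registration warps one volume onto another. Each grid point gets a
position $q$ *and* a momentum $p$; the algorithm evolves the pair
$(q, p)$ under an image-matching force, and with undamped updates the
one-step map is a symplectomorphism — it preserves phase-space volume
exactly (unit Jacobian), which the suite verifies to $10^{-10}$ against
finite differences of the actual step map.

The pieces, each with its documented choice:

* **Matching force.** The phase-space framing does not by itself fix a
  force law; this package uses the demons force for the SSD potential,
  $F = (f - m_w)\nabla f / (\|\nabla f\|^2 + (f - m_w)^2 + \epsilon)$
  with $\epsilon = 10^{-3}\,(\text{intensity range})^2$, oriented so it
  points toward alignment under the pull-back convention (the warped
  image samples the moving image at $x + w(x)$). Its direction is
  invariant to a common intensity rescaling.
* **Coupling kernel.** Forces are smoothed by a normalized Gaussian of
  covariance $S^{-1}$ — the simplest spatial coupling density
  $Q(x, x') \sim N(x', S^{-1})$; richer non-local couplings are out of
  scope. Isotropic $\sigma = 2$ voxels per level by default. The kernel
  sums to one, so constant fields pass through unchanged; a delta
  impulse reproduces the requested second moments to better than 2% on
  a 33³ grid.
* **Integrator.** Semi-implicit (symplectic) Euler: kick then drift,
  with optional momentum damping $\gamma$ (default 0.2) for convergence;
  $\gamma > 0$ deliberately trades exact phase-space volume preservation
  for robustness, and the symplecticity tests pin $\gamma = 0$. The
  adjoint drift-kick variant is exposed so a momentum-flipped step pair
  retraces a trajectory exactly.
* **Step control.** If a step would increase the MSD, the momentum is
  first restarted (heavy-ball overshoot is the usual culprit — without
  the restart, coarse levels stall within a few iterations), then the
  step size is halved, at most 5 times per level. The similarity trace
  is therefore non-increasing within each level.
* **Multi-resolution.** 3 levels (×4, ×2, ×1), 50 iterations each by
  default. The warp is checked by its central-difference Jacobian
  determinant; a non-positive minimum raises a warning and a
  non-diffeomorphic flag, never a silent pass.

**What recovery experiments can show.** A displacement component
tangential to the image's level sets produces no intensity change — the
aperture problem — so *no* intensity-driven method can recover arbitrary
fields on featureless phantoms. The recovery experiment in the suite
therefore uses a ball carrying smooth multiplicative texture
(correlation length 3 voxels, amplitude 0.5), making the field observable
throughout the interior, and measures the mean endpoint error inside the
half-maximum support. A smooth random field of 4-voxel peak amplitude on
a 64³ grid is recovered to a mean error below 0.5 voxel (typically
0.37–0.42 across seeds) with the final MSD under 1% of the initial; the
force-smoothing scale is raised to $\sigma = 4$ for this experiment to
match the field's correlation length. None of this says anything about
multi-modal matching or intensity nonstationarity in real scanners —
the SSD force assumes comparable intensity profiles.

**Templates.** `build_template` registers every (rigidly pre-aligned)
subject to the current template and averages the warped volumes. The
initial template is the *first volume*, not the voxelwise mean: matching
subjects onto a blurred mean merely reproduces its blur, whereas
averaging subjects warped onto one sharp reference stays sharp. The
reference bias is removed by the standard unbiased shape update —
after each averaging step the mean of the subject warps is subtracted —
so the template drifts to the population mean shape (two translated
copies of one phantom yield a template centered midway to 0.02 voxel)
while remaining sharper than the naive mean (gradient energy 33.9 vs
29.5 on six jittered corrugated balls at 48³).

## Posture-factored comparison

Two scans of the *same* limb in flexed and extended postures should be
closer than scans of *different* limbs in matching postures. The
comparison pipeline factors pose in two stages: a rigid pre-alignment
(intensity centroid + second-moment principal axes, axis signs fixed by
third moments) absorbs whole-body pose and is reported separately; the
non-rigid registration absorbs what remains. The distance is

$$d(a, b) \;=\; \frac{\mathrm{RMS\ residual}}{s}
  \;+\; \lambda\,\frac{\overline{|w|}}{R},$$

residual intensity mismatch normalized by the joint 99th-percentile
intensity scale $s$, plus mean non-rigid displacement normalized by the
object's support radius $R$ in voxels, $\lambda = 1$. The design point:
once registration converges the residual is near zero for *both* kinds
of pairs, and the morphological signal lives in how much deformation the
warp needed — thickening a limb costs more deformation than re-bending
it after rigid alignment. (A batch-relative z-score weighting was
considered and rejected: it makes the distance depend on which
comparisons happen to be in the batch, and it cancels exactly the
deformation-vs-residual contrast the comparison relies on.) On two limb
phantoms (capsule radii 4 vs 6.5 voxels) in two postures (120° vs 175°),
all same-limb distances (0.025–0.028) fall below all different-limb
distances (0.039–0.040), in both directions of comparison
(asymmetry < 2%).

Distance matrices feed `distance_matrix_mst` (Prim with lexicographic
tie-breaks, verified against exhaustive enumeration of all spanning
trees at $n = 6$), with Newick export for tree viewers.

## Phantoms: what they emulate and what they do not

Every input in the test suite is generated by the phantom module from a
specification and a seed — bitwise reproducible, no downloads.

* `make_dune` — the plane-wave worked example: one low-frequency
  high-amplitude wave along $y$ plus two high-frequency low-amplitude
  ripples at ±45° to the $y$ axis. The ripple wavevector components are
  snapped to the integer frequency lattice
  ($\mathrm{round}(24/\sqrt2) = 17$ cycles), so the discrete spectrum is
  leak-free and peak counting is exact; with non-integer components,
  scalloping loss would drop the ripple peaks from 20% to ~6% of the
  dune peak and make the "peaks above 10%" criterion an artifact of FFT
  leakage rather than of the shape. The default amplitude ratio is 5:1
  (a 10:1 ratio would park the ripple peaks exactly *at* the 10%
  detection threshold).
* `make_polynomial_series` — the fixed cubic `c(1, 2, -1, 0.5)` (the
  literature shows the curve, not its coefficients; these are this
  package's fixed demo values).
* `make_ball` / `make_nested_shells` / `make_corrugated_ball` — hard
  voxelized edges by default so voxel-count oracles are exact; an
  optional logistic `smooth_edge` exists for registration work, where
  image gradients carry the information.
* `make_articulated_limb` — two capsules meeting at a joint; angle
  changes posture, thickness changes "species"; volume is invariant to
  angle within 4%.
* `make_deformed_pair` — smooth random fields via *periodic* FFT
  Gaussian smoothing of white noise (a clamped-edge kernel inflates
  border variance, and normalizing by the field maximum would then
  crush the interior amplitude), rescaled to a requested peak amplitude
  and rejected if not diffeomorphic.
* `add_speckle` — exactly `count` well-separated 1–2 voxel grains, in
  material chosen by value, for the grain-exclusion contrast.

What phantoms do not emulate: beam hardening, ring artifacts, partial
volume at real detector resolutions, intensity inhomogeneity, or
anatomy whose shape is far from star-convex about its centroid (deep
folds can make the single-center spherical parameterization inefficient
— per-structure fits after segmentation mitigate this). Passing tests
demonstrate correctness of the machinery under these controlled
conditions, not scanner-grade robustness.

## Numerical notes and limitations

* Bessel roots are bracketed by interlacing ($z_{l-1,n} < z_{l,n} <
  z_{l-1,n+1}$) and refined by `uniroot` to $10^{-14}$; failures raise
  errors rather than returning silently. $j_l$ switches to its series
  below $x = 10^{-4}$.
* The least-squares solver is QR (LAPACK) with condition logging;
  normal equations are never formed. Ill-conditioning (a grid too coarse
  for the requested bandwidth) is an error.
* Trilinear interpolation tolerates $10^{-9}$ voxel rounding at grid
  boundaries; out-of-grid queries fill with 0 and spherical sampling
  logs the clipped-node count.
* Coefficient containers are JSON (layout: `c_real`/`c_imag` arrays of
  shape $[N, L{+}1, 2L{+}1]$ with $m$ packed as $m + l$, plus center,
  $R$, $L$, $N$, spacing, fit method and the wavenumber/normalization
  tables). Volumes travel as NIfTI-1 (lossless float64), raw +
  JSON sidecar (lossless), or TIFF stacks (32-bit samples rescaled to
  $[0,1]$ with scale/offset in the sidecar — exact to about $2^{-32}$
  of the range). Anisotropic volumes are resampled isotropically before
  any spherical fit, since the basis assumes an isotropic metric.
* Problem sizes in the suite — 48³–64³ volumes, $L \le 8$, 50–60
  registration iterations — were chosen as the smallest at which each
  phenomenon is cleanly measurable; all scale up linearly in voxels and
  as $N(L+1)^2$ in basis size.
* Degenerate inputs: empty volumes cannot be oriented
  (`rigid_align` errors); fewer distinct intensities than classes is a
  degeneracy error; labels smaller than the minimal fit support are
  skipped with a warning; a constant volume with `K = 2` classes is
  rejected rather than split arbitrarily.
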