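---
title: "Nonrigid-geometry tomography: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonrigid-geometry tomography: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A tomographic scan assumes the sample does not change while projections are
collected.  Radiation-sensitive specimens — biological tissue under an
intense X-ray nanoprobe being the motivating case — violate this: deposited
dose drives a continuous, spatially smooth deformation over the scan, and a
static reconstruction blurs and distorts wherever material has moved by more
than the resolution element.

`nctomo` reconstructs such data by changing the geometry instead of the
sample model.  Each measurement remains a line integral, but the straight
line of sight is replaced by a virtual curved path through a single
reference volume `g`: the path of projection `j`, acquired at normalized
time `t_j`, visits `l + Gamma(l, t_j)` for each point `l` on the straight
ray, where `Gamma(x, t)` is a time-evolving deformation vector field (DVF)
mapping the sample state at time `t` back to the reference state at
`t = 0`.  Formally the data model keeps the linear form `p = A_N g`, so any
algebraic solver (here: FBP and SIRT) can be reused with the curved
operator pair.  Density changes under deformation are neglected.

The DVF is not measured; it is estimated from the data itself using an
interleaved acquisition: the scan is split into `N` temporally contiguous
sub-tomograms, each containing every `N`-th angle, so each sub-tomogram
covers the full half turn at coarser angular sampling and sees the sample
in a narrower time window.  Differences between the sub-tomogram
reconstructions carry the deformation signal.

## Discretization of the curved operators

Volumes live on a regular grid with the world origin at the volume centre
and voxel centres at integer coordinates; the rotation axis is z, angles
sweep the x-y plane, and the detector axes are `u` (in-plane, perpendicular
to the ray) and `v = z`.  The straight projector samples each ray at a
fixed step of 0.5 voxel with trilinear (in-plane bilinear, since rays stay
in a z-plane) interpolation, scaled by the step; the backprojector scatters
with the same weights, making the straight pair an exact adjoint — a
property the test suite checks to 1e-6 and that FBP/SIRT correctness rests
on.

For the curved pair we use the warp-composed form:

* forward: pull-back warp the reference volume by `Gamma(., t_j)`
  (`W g (x) = g(x + Gamma(x, t_j))`), then project along straight rays —
  this evaluates exactly the virtual-path sum, with the displacement read
  at grid points rather than at ray samples;
* transpose: backproject along straight rays, then warp-gather through the
  *inverse* displacement, `out(x) += B(x + Gamma^{-1}(x, t_j))`.

The voxel-driven inverse-warp form is the faithful reading of the
"contribution of pixel j to voxel i" transpose: a reference-frame point
`x` is seen by the detector at the straight-ray position
`x + Gamma^{-1}(x)`, so gathering the straight backprojection there smears
each measurement along the same curve the forward operator integrates.
Two properties follow and are enforced by tests: with a zero field both
operators are bit-identical to the straight ones (the warp with zero
displacement is an exact copy), and for rigid (constant) fields the pair
is exactly adjoint, because the adjoint of a translation-by-interpolation
matrix is the translation by the opposite vector.  For general smooth
fields the pair is an approximate adjoint — the discrepancy is of the
order of the displacement Jacobian — which we accept and monitor (the
dot-product mismatch stays below 5% for fields in the regime of the
simulation study) rather than correct; SIRT tolerates a slightly
inexact transpose.

`Gamma^{-1}` is computed by the fixed-point iteration
`v <- -Gamma(x + v)` (5 iterations by default; exact for rigid fields,
residuals of order 1e-4 voxels for the smooth fields used here).  Inside
the iteration the field is extended by its edge values rather than by
zero: with zero extension the inverse of even a rigid field would be
corrupted near the grid boundary.  Everywhere else — evaluation, warping,
projection — fields evaluate to zero outside their grid, since the sample
is surrounded by empty space.

## The DVF model and its estimation

`Gamma(x, t)` is stored at `N + 1` interpolation nodes in time (the
beginning and end of each sub-tomogram) and interpolated linearly between
them; displacements are pull-back vectors in full-resolution voxel units.
The node at `t = 0` is pinned to zero.  This boundary condition is what
removes the gauge freedom of the joint problem — without it, a rigid shift
or scaling could migrate freely between the volume and the DVF — and it
makes the reconstruction an estimate of the sample *before* deformation.

Each outer iteration of `joint_optimize()` performs three steps:

1. **Reconstruct.**  Nonrigid FBP (Ram-Lak by default) of the full data
   set and of each sub-tomogram, all through the current DVF and shifts,
   so every volume lives in the reference frame and differences between
   them reflect only the unmodelled deformation.
2. **Update the DVF.**  A 3-D optical-flow solve between the full
   reconstruction and each sub-tomogram reconstruction: per axis, a pass
   adds `lambda * smooth(residual * grad) / (smooth(grad^2) + alpha)`,
   with an isotropic Gaussian smoothing kernel (sigma 30 full-resolution
   voxels by default, truncated at 3 sigma) and
   `alpha = 0.01 * max(smooth(grad^2))` guarding smooth regions; the
   gradient and the denominator are taken on the sharper full
   reconstruction.  Each solve runs several incremental-warping passes
   (12 by default): after every pass the sub-tomogram volume is re-warped
   by the current estimate and the update re-linearized, which extends
   the capture range beyond sub-voxel displacements and roughly doubles
   the convergence rate of the outer loop; a single pass is the classic
   one-step update.  The residual is oriented so that the increment
   estimates the displacement of the sub-tomogram volume *relative to*
   the full reconstruction in the pull-back sense — with the operators
   above, this is the direction that contracts toward the true field
   (the test suite checks the contraction on known translations and
   smooth warps).  `lambda` must stay in (0, 2); the default 1.7 is
   measurably faster than 1 through a wide kernel and still clear of the
   instability we observe near 1.9.  The per-block estimates are then
   deconvolved in time.  Each block value is modelled as the midpoint
   average `(node_i + node_{i+1}) / 2` of the piecewise-linear DVF, and
   the node values solve a small regularized least-squares system with a
   squared second-difference penalty across nodes (`reg_weight` 0.1) and
   the `t = 0` node eliminated; this undoes the systematic
   underestimation that block averaging causes for a growing deformation
   (for a saturating amplitude the end node correctly overshoots the last
   block average).  Inside the joint loop one more piece of estimator
   algebra matters: the full reconstruction is itself contaminated by the
   *mean* of the uncompensated residual deformation, so each flow
   measurement equals `delta_i - mean_j(delta_j)` to first order.  The
   loop therefore solves the node *increments* against the column-centred
   averaging matrix `S - 1 s̄`, which models that contamination exactly;
   the second-difference penalty (applied to the increments, so the
   accumulated field is not biased against genuine temporal curvature)
   keeps the solve well posed across the one direction the centring
   renders unobservable.  Without the centring the mean deformation mode
   is invisible to each individual update and converges only through slow
   self-consistency feedback — in our experiments this correction roughly
   halves the DVF error at a fixed iteration budget.
   [temporal_deconvolve()] keeps the plain (uncentred, full-block) form
   for standalone use.
3. **Align.**  Projection matching: each measured image is compared with
   the reprojection of the current volume through the current DVF, and a
   single (du, dv) per projection is estimated by 2-D optical flow
   averaged over a support mask (reprojection above 5% of its maximum).
   Two stabilizers matter in the self-consistent setting: the
   rigid-translation component of the shifts (du ~ a sin + b cos, constant
   dv) is projected out, because it is exactly degenerate with moving the
   reconstruction; and the update is damped (factor 0.5), so persistent
   true shift errors are integrated over the iterations while transient
   deformation residuals — which masquerade as apparent shifts early in
   the loop — are left for the DVF to claim.

DVF estimation runs on a grid binned by a configurable factor (2 for the
bundled study; the flow kernel sigma is divided by the binning), which is
both faster and better conditioned when the field is smooth.  After the
loop the DVF is upscaled trilinearly to full resolution — the projectors
interpolate a coarse field identically, so this is a representation
change, not an approximation — and the final volume is refined by
nonrigid SIRT (inverse row/column-sum preconditioning, relaxation 1,
nonnegativity off by default since phase-contrast values can be signed),
initialized from the nonrigid FBP.

Convergence is defined operationally as completing the configured
iteration budget (50 + 50 for the study); a guard aborts and returns the
best iterate if the reprojection misfit doubles from its running minimum.

## The simulation study

`simulation_study()` regenerates the package's reference experiment
end to end:

* **Phantom**: a porous pillar — Gaussian-smoothed white noise (sigma
  2 px, i.e. a smoothing length of ~4 px FWHM, giving pores a few voxels
  across) thresholded at the quantile giving 50% void fraction, masked by
  a vertical cylinder.  The cylinder radius is kept `max_disp + 2` px clear
  of the lateral field of view so the deformed sample never leaves the
  detector; a real pillar is prepared to stay in view for the same reason.
* **DVF model**: per component, white noise convolved with a Gaussian of
  sigma `spatial_period / 2` (period 20 px), jointly rescaled so the peak
  vector magnitude is `max_disp` (5 px at the bundled 100 x 100 x 50
  scale); temporal amplitude `(1 - exp(-3 t)) / (1 - exp(-3))`, a
  saturating dose-response-like growth that vanishes at `t = 0`.
* **Acquisition**: 160 equidistant angles over 180 degrees in 4
  interleaved sub-tomograms, acquisition time `t_j = j / (n - 1)`.  The
  phantom is warped with the *densely* time-evaluated model before each
  straight projection, so the ground truth contains intra-sub-tomogram
  evolution that the node-sampled estimate can only average — data are
  generated by warp-then-project with the continuous field, while
  reconstruction uses node-interpolated fields, deliberately avoiding a
  trivial inverse crime.  Detector noise is off by default (the reference
  experiment is noiseless) but parameterized.
* **Comparison**: the same data reconstructed by conventional
  static-geometry SIRT with the identical budget and FBP initialization.
* Shift refinement is disabled in the study configuration: the virtual
  acquisition has no detector shift errors, and a free per-projection
  nuisance search can only trade deformation against shifts in the DVF
  error metric.

Reported metrics: the support-masked RMS vector difference between the
recovered and true DVF at the node times (the support is the pillar
cylinder minus `ceiling(max_disp)` slices at the top and bottom faces,
where material exchanges with unmeasured space and the DVF is not
constrained by data); Fourier shell correlation of each reconstruction
against the phantom with the 1/2-bit information threshold
`T = (0.2071 + 1.9102 / sqrt(n_eff)) / (1.2071 + 0.9102 / sqrt(n_eff))`,
`n_eff` the half shell population, behind a 10% Tukey mask; gray-level
histograms inside the pillar with a valley-to-peak bimodality score (the
two modes located by 2-means with quantile initialization — a binary
volume scores 0, blur raises the score); and an uncentred PCA of the DVF
nodes (no mean removal: the zero node is the natural origin), whose first
mode and per-node weights summarize the deformation's spatial pattern and
time course.

What passing this study shows — and what it does not.  The simulation
exercises the full estimation loop under a smooth, saturating, spatially
random deformation with realistic interleaving, and verifies sub-pixel DVF
recovery plus resolution and histogram improvements over the static
reconstruction.  It does not emulate ptychographic phase noise, phase
wrapping, residual alignment errors of a real instrument, dose-dependent
contrast change, or deformation faster than a sub-tomogram; conclusions
about real data are correspondingly limited.

## Numerical choices and edge cases

* Ray sampling 0.5 voxel; rays are clipped to the circumscribed circle of
  the x-y extent plus one voxel.
* Ramp filtering uses the DFT of the band-limited real-space Ram-Lak
  kernel (not |f| sampled on the DFT grid, whose DC defect biases
  interiors several percent low) on projections zero-padded to the next
  power of two at least twice the detector width; the backprojection is
  scaled by `pi / n_angles`, which the uniform-cylinder test pins to
  within 3%.
* SIRT row/column weights come from the straight operator also in the
  curved case; weights below 1e-6 of their maximum are zeroed.
* Sub-voxel detector shifts are applied by bilinear resampling with zero
  fill; binning block-averages images (and divides by the factor, keeping
  line integrals consistent in binned units) and rescales shifts.
* Degenerate inputs fail loudly: empty sub-tomograms, all-zero volumes in
  FSC, empty support masks, times outside [0, 1], non-divisible binning.
* All randomness (phantom, DVF model, noise, injected shifts) derives from
  the single seed in `sim_config()`; equal configurations reproduce
  bit-identical inputs and deterministic results.

Problem sizes: the bundled study runs the 100 x 100 x 50 phantom with 160
projections and the full 50 + 50 iteration budget; the operator and
estimator tests use 32-64 voxel grids, where every property they check is
already sharply resolved.

## Known limitations

* The temporal model is piecewise linear with one node per sub-tomogram
  boundary; deformation varying faster than a sub-tomogram aliases into
  the block averages (per-projection shift refinement recovers only its
  rigid component).
* On perfectly static data the flow reads the systematic streak-artifact
  differences between sub-tomogram FBPs as a small spurious deformation
  (~0.02-0.06 px at the scales studied), and the centred deconvolution's
  unobservable temporal direction accumulates estimation noise very
  slowly; both effects stay an order of magnitude below the study's
  deformation signal over the configured iteration budgets, but very long
  runs on featureless data would drift.
* The optical flow is a one-step, single-scale scheme; spatial DVF
  structure much finer than the smoothing kernel converges slowly and may
  be partially unrecoverable within a fixed iteration budget.  The
  study's kernel (sigma 30 px) against a 20 px spatial period is the
  stress case inherited from the reference experiment.
* The curved transpose is an approximate adjoint for non-rigid fields;
  gradient solvers relying on exact adjointness (e.g. CGLS) would need
  the mismatch bounded or corrected.
* Parallel-beam geometry only; no cone/fan beam, no density change under
  deformation, no total-variation or other image regularization.
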