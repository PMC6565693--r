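# nctomo — nonrigid-geometry computed tomography

Tomography assumes a static sample; radiation-sensitive specimens imaged at
the nanoscale are not.  Under an intense X-ray probe a biological sample
deforms continuously while its projections are collected, and a
conventional reconstruction blurs every feature that moved by more than a
resolution element.  `nctomo` implements nonrigid-geometry computed
tomography (NCT) for parallel-beam data: the straight line of sight of each
projection is replaced by a virtual curved path through a single reference
volume, and the curvature — a time-evolving deformation vector field (DVF)
`Γ(x, t)` — is estimated *from the data itself*, jointly with the
reconstruction.

The package is aimed at users of time-resolved / dose-limited tomography
(PXCT and similar nanotomography, in-vivo phase tomography) and at method
developers who want a complete, tested, self-contained reference
implementation with a built-in simulation study.

## The model

With measurements `p_j` and reference volume `g`, the data model stays
linear, `p = A_N(Γ) g`, but each ray integrates `g` along the displaced
path `l + Γ(l, t_j)`, where `t_j` is the projection's normalized
acquisition time and `Γ(·, t)` maps the sample state at time `t` back to
the reference state at `t = 0` (`Γ(x, 0) = 0` anchors the gauge).  The DVF
is represented at `N + 1` temporal nodes — the boundaries of `N`
interleaved sub-tomograms, each holding every `N`-th projection angle — and
interpolated linearly in time.

Estimation alternates three steps for a fixed iteration budget:

1. nonrigid FBP of the full data set and of every sub-tomogram through the
   current `Γ` (all volumes live in the reference frame);
2. a 3-D optical-flow solve per sub-tomogram
   (`Δ = λ · smooth((g⁽ⁱ⁾ − g⁽F⁾) ∇g⁽F⁾) / (smooth(|∇g⁽F⁾|²) + α)`, with
   incremental warping passes and a wide Gaussian smoothing kernel),
   followed by a Tikhonov deconvolution of the per-block averages onto the
   temporal nodes;
3. optional projection-matching refinement of per-projection detector
   shifts.

The final volume is refined by nonrigid SIRT.  Quality metrics include
Fourier shell correlation with the 1/2-bit information threshold, DVF RMS
error and principal components, and gray-level histogram bimodality.  See
the methods vignette (`vignettes/nonrigid-tomography.Rmd`) for the
discretization of the curved operator pair, estimator internals, and known
limitations.

## Worked example

The built-in study reproduces the numerical experiment end to end: a porous
pillar phantom (100 × 100 × 50 voxels) deformed by a smooth random field
(peak displacement 5 px, spatial period 20 px, amplitude `1 − exp(−3t)`),
160 projections in 4 interleaved sub-tomograms, 50 joint iterations plus 50
nonrigid-SIRT iterations, compared against a conventional static-geometry
SIRT of the same data:

```r
library(nctomo)
res <- simulation_study(cfg = sim_config(seed = 42))

round(res$dvf_rms, 4)
#> [1] 0.7734
round(res$resolution_conv, 4) # 1/2-bit crossing of conventional SIRT
#> [1] 0.4399
res$resolution_nct            # NA: FSC stays above the threshold to Nyquist
#> [1] NA
res$fsc_improved_frac         # shells below 0.35 cyc/px with NCT >= conventional
#> [1] 1
round(res$bimodality, 3)
#>      phantom          nct conventional
#>        0.000        0.378        0.524
plot(res$fsc_nct)
```

Reading the numbers: the recovered 4-D DVF differs from the ground-truth
model by 0.77 px RMS over the sample support (the deformation itself
reaches 5 px, 2.3 px RMS at its peak); the nonrigid reconstruction's FSC
against the phantom is at or above the conventional one on every shell
below 0.35 cycles/px and never crosses the 1/2-bit threshold (the
conventional reconstruction loses the threshold at 0.44 cycles/px); and
the nonrigid volume's gray-level histogram is markedly more binary
(valley-to-peak 0.38 versus 0.52; the binary phantom scores 0).

A configurable end-to-end driver with file outputs is available as
`run_pipeline()`, and a thin command-line front end in `inst/cli/nct`
(subcommands `simulate`, `reconstruct`, `metrics`, `run`).

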