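---
title: "Quantifying branch mechanics in organoid time-lapse imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying branch mechanics in organoid time-lapse imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(branchmech)
library(dplyr)
```

## The measurement problem

Epithelial organoids growing in floating collagen I gels elongate their
branches by pulling on the surrounding matrix. Live confocal imaging of such
cultures produces multi-channel time-lapse stacks — tracer beads embedded in
the gel, nuclei inside the branches, and the collagen fiber network — from
which four families of quantities are extracted:

1. **ECM deformation** around a branch tip, from bead tracks: how strong,
   how anisotropic, how far-reaching, and how irreversible the matrix
   displacement is;
2. **collagen fiber alignment**, from the fiber channel: an orientation
   histogram, its Gaussian-fit width, and a normalized degree of alignment;
3. **intra-branch cell dynamics**, from dense optical flow of the nuclei
   channel: velocities decomposed along the branch axis and segmented into
   collective and uncoordinated phases;
4. **cell–ECM coupling**: the lagged correlation between collective cell
   velocity and matrix deformation.

`branchmech` implements this chain as composable functions operating on
tibbles, plus a seeded synthetic-scene generator with exact ground truth, so
that every stage is verifiable by parameter recovery rather than by eye.

## Conventions

Positions are in µm; the centre of voxel `(i, j, k)` (0-based, z/y/x) is at
`(i, j, k) * voxel_size`. Time is in minutes; the default frame interval is
10 min, a typical confocal acquisition rate for these cultures. Angles
`theta` are measured between the tip-to-bead vector and the outward branch
axis, so `theta = 0` is the matrix directly in front of the tip. The central
sign convention, used everywhere: **`s` is the component of a bead step
toward the tip; positive `s` is contraction toward the branch, negative `s`
is relaxation away from it.** Fiber orientations are axial (mod 180°),
reported in `[-90, 90)` degrees.

## The reference displacement field

The generator advects tracer beads with a tip-centred field

$$u(x, t) \;=\; A \,\cos^{k}\!\theta(x)\,[\theta \le 90^\circ]\;
  e^{-r(x)/\lambda}\; g(t)\;\hat e(x \to \mathrm{tip}),$$

$$g(t) \;=\; \rho\,\frac{t}{P} \;+\;
  (1-\rho)\,\tfrac12\!\left(1 - \cos\frac{2\pi t}{P}\right).$$

This functional form is the package's own construction. It is the simplest
field with independently tunable versions of the three signatures of
tip-driven matrix remodeling: deformation decreasing with angle to the
branch axis (exponent `k`), decaying with distance (length `lambda`),
and alternating contraction/relaxation cycles (period `P`) that leave a net
plastic gain of `rho * A` per cycle. With `rho = 0` the matrix springs back
fully each period; with `rho = 1` deformation accumulates linearly. Beads
are advected frame-to-frame by field *increments*, so each bead accumulates
history at its own moving position like a real tracer.

Defaults used across the test scenes: `A` of a few µm per period,
`lambda` 80–150 µm, `k = 2`, `P = 60` min, `rho = 0.5`. These are chosen to
sit in the regime the imaging data shows qualitatively — hour-scale cycles,
deformations of a few µm per cycle reaching hundreds of µm from the tip —
without reproducing any measured value.

```{r field}
fp <- field_params(amplitude = 3, decay_length = 80, anisotropy = 2,
                   period = 60, plastic_fraction = 0.5,
                   tip = c(0, 64), axis = c(1, 0))
u <- make_displacement_field(fp)
u(c(50, 64), t = 30)   # on-axis point, mid-period: pulled toward the tip
```

### What the generator emulates — and what it does not

The generator prescribes *kinematics only*: beads follow the field, fibers
are straight segments with wrapped-normal orientations, nuclei translate in
scheduled phases, and noise is additive Gaussian. There is no fiber
mechanics, no force balance, no strain stiffening, no Poisson shot noise,
no bleaching, no z-drift of focus, and bead density/SNR are free knobs
because the source imaging reports none of them. Passing parameter-recovery
tests therefore demonstrates that the *analysis chain* is correct and
well-calibrated at realistic noise levels; it does not validate the
analysis against optical artifacts (spherical aberration, scattering deep
in the gel) or against mechanically coupled fiber motion. Bead defaults —
PSF width 1.5 voxels, peak SNR 5–10, spacing at least twice the PSF — are
documented assumptions, not measurements.

Fiber textures default to long fibers (100 px on a 640² field) at a
coverage where single fibers remain resolvable. Both choices matter for the
orientation statistics: short segments contaminate the per-pixel angle
distribution with end-cap pixels (biasing the fitted width up), while heavy
overlap averages neighbouring orientations inside the tensor window
(biasing it down). Real collagen fibers at this magnification are long
relative to the field of view, so the default sits in the realistic regime.

## Drift correction

`estimate_drift()` maximizes the normalized cross-correlation between
consecutive frames over an exhaustive integer-shift window (`max_shift`,
default 10 voxels), then chains the per-pair shifts into cumulative shifts
relative to frame 1. Design points:

* **Normalized** correlation (on the overlap region) rather than raw
  products, for robustness to intensity drift, with the correlation score
  of every accepted shift reported.
* **Consecutive-pair chaining** mirrors how stage drift arises; its known
  drawback — random-walk accumulation of estimation error over long movies
  — is negligible while per-pair recovery is exact, which the tests verify
  on constructed translations.
* **Ties** are broken toward the smaller-magnitude shift, so featureless
  pairs do not jump.
* Flat frames are an error (`"uninformative frame"`); a peak on the window
  edge warns that `max_shift` is too small.
* Optional subvoxel refinement (quadratic interpolation around the peak) is
  off by default — stepwise integer search is the reference behaviour.

`apply_drift()` translates frames by minus the cumulative shift and fills
out-of-field voxels with `NA`. The sentinel choice is load-bearing: filled
voxels excluded as missing leave re-estimated residual drift at zero, while
any numeric fill would act as a bright or dark feature anchored to the
frame and bias every downstream correlation.

## Bead tracking

Detection follows mask → label → filter → localize:

* **Threshold**: default `median + 3·MAD` of the frame. Otsu's method is
  available (`threshold = "otsu"`) but is not the default: tracer frames
  are almost entirely background, and a bimodality-based threshold placed
  inside the noise distribution floods the mask at realistic SNR.
* **Components** are 26-connected (8-connected in single-slice mode);
  components of fewer than 3 voxels are discarded as chance noise
  excursions.
* **Boundary filter before pair filter**, in that order: beads touching
  the image margin are removed first, then *both* members of every pair
  closer than `min_distance` (default 5 µm) are removed. The order is a
  correctness property — a bead should never be eliminated by a neighbour
  that was itself invalid — and is pinned by a constructed
  counterexample test.
* **Localization**: intensity-weighted centroid on a trilinearly
  interpolated grid (`upsample = 4`), refined by an iterated Gaussian mask
  of width `mask_sigma` (set to the spot width). The refinement suppresses
  the noise contribution of the support boundary and roughly halves the
  localization error at SNR 5, bringing it below a quarter voxel.

Linking is mutual nearest-neighbour matching between consecutive frames
within `link_radius` (default 10 µm per 10-min frame), keeping only chains
of at least three consecutive frames; there is no gap closing, and no
detection is ever shared between tracks. Mutual NN is the most conservative
reading of coordinate matching — ambiguous candidates produce no link
rather than a wrong one — and the tests compare it against brute-force
optimal assignment on scenes where the truth is unambiguous.

## ECM deformation statistics

`project_samples()` attaches `(r, theta, s)` to every track step, computed
at the step's starting position. From there:

* `cumulative_displacement()` — per bead, the running sum of `s`; the
  series is the mean over beads in the near field (default 300 µm, forward
  half-space). Beads leaving the region are **frozen at exit**: their
  accumulated deformation keeps contributing, no further motion is
  attributed to them, and the count is logged. The alternative
  (re-weighting survivors) was rejected as assuming more than the data
  states. On a plastic field the series increases between period starts by
  `rho * A` times the angular/radial attenuation — the property the
  acceptance tests check against the closed form.
* `stripe_profile()` — mean `s` in 100-µm distance stripes in front of the
  tip. Empty stripes are reported `NA` with `n = 0`: missing, never zero.
* `angular_profile()` — mean `s` in angular bins (default 15°, a
  resolution the bead counts support).
* `label_phases_ecm()` — contraction / relaxation / neutral per frame by
  the sign of the mean `s`, with a noise floor; the recommended floor is
  twice the median per-frame `|s|` of a matched zero-field scene, i.e. a
  calibration of localization noise, configurable.
* `relaxation_delta()` — the signed series change after a perturbation
  event (drug, ablation): `value(end) - value(event)`.

Whether published distance profiles used the raw step magnitude or the
signed toward-tip component is not stated in the source material; the
signed component is used throughout, as it is the quantity whose sign
distinguishes contraction from relaxation.

## Fiber alignment

`extract_angles()` uses the structure tensor: Gaussian pre-smoothing
(`gradient_sigma = 1` px) before central-difference gradients, tensor
smoothing (`smoothing_sigma = 1` px), per-pixel orientation from the minor
eigenvector, pixels kept when their coherence exceeds 0.2 and their
gradient energy is above 2% of the region maximum. The pre-smoothing
sharpens the estimator's angular response on pixel-discretized fibers to
about one degree; the modest tensor window limits orientation mixing
between neighbouring fibers. Alternatives (FFT anisotropy, ridge tracing)
were rejected for complexity; the extraction method is unstated in the
source and is a documented package choice.

`fit_fwhm()` re-centres the histogram mode to 0° (wrapping modulo 180°) and
fits a **wrapped** Gaussian — the ±180° replicas included — by
Levenberg–Marquardt. Two numerical choices matter for wide distributions:
the replicas replace a free constant baseline (with which they are
degenerate; a baseline remains available via `offset = TRUE`), and
Sheppard's correction removes the bin-width broadening of the 5° default
bins. A fitted width wider than the domain is clipped to 180° and flagged.
`FWHM = 2*sqrt(2*ln 2)*sigma`.

`degree_of_alignment()` is `d = (FWHM_max - FWHM) / FWHM_max`, with
`FWHM_max` always the maximum over the supplied set of regions or
conditions — an input-set property, never a constant. A single supplied
region yields `d = 0` with a warning.

```{r fibers}
tx <- simulate_fiber_texture(mean_angle_deg = 20, sigma_deg = 10,
                             n_fibers = 300, image_dim = c(320, 320),
                             fiber_length = 80, seed = 1)
fit <- fit_fwhm(orientation_histogram(extract_angles(tx$image)))
generics::glance(fit)
```

## Cell dynamics

`compute_flow()` is a dense polynomial-expansion optical flow of the
Farnebäck family, implemented in the package (no installed R package
provides one): each frame is approximated locally by a quadratic form over
a Gaussian applicability window (`poly_n = 7`, `poly_sigma = 1.5`), and the
displacement solving the relation between the two expansions is aggregated
over a Gaussian integration window (`winsize = 15`), iterated with warping
(3 iterations) over an image pyramid (3 levels, each level required to
accommodate the kernels). Flow is 2D on the z-maximum-projection, matching
how intra-branch velocity maps are usually presented; velocities are
returned in µm/min via the pixel size and frame interval, a unit chain the
tests audit against hand-computed values.

`decompose_velocity()` projects onto the branch axis (`v_par`, outward
positive) and its 90° rotation (`v_orth`); the decomposition reconstructs
the vector exactly. `segment_phases()` summarizes each frame by the
direction-consensus order parameter `Phi = |mean(sign(v_par))|` and labels
frames collective (outward/inward) above `phi_threshold = 0.5`, else
uncoordinated. Both the order parameter and its threshold are package
inventions — the source describes the phases qualitatively — and are
config-exposed. Tip-cell exchange counting is deliberately not automated:
no algorithm is specified for it anywhere, so the package only exports
trajectories for manual annotation.

`couple_cell_ecm()` correlates `v_par(t)` with `-s(t + lag)` over a lag
scan: the sign pairing encodes that outward collective motion accompanies
matrix relaxation and inward motion accompanies contraction, so synchrony
appears as a *positive* peak. Pearson is the default (the series are
signed, roughly symmetric); Spearman is available. Constant series are
flagged as undefined rather than returning a number.

## Pipeline, determinism, degenerate inputs

`run_pipeline()` chains drift → tracking → deformation → fibers → cells →
coupling from a single nested config (R list or YAML), writes per-stage
CSVs, a provenance log (seed, config hash, versions) and a markdown
summary, and aborts naming the failing stage while keeping completed
outputs. All randomness flows from one seed; two runs with one config are
bit-identical, which the tests assert.

Degenerate inputs have defined behaviour throughout: empty masks give
empty detection tables (not errors), empty stripes are `NA`, zero-length
movies give empty trajectories, flat images and constant series are
errors or flagged warnings, and over-dense bead scenes (mean spacing below
twice the PSF) are rejected by the generator as undetectable by
construction.

## Problem sizes

The test-suite and acceptance scenes are sized for a workstation run:
single-slice 128–256 px fields with 40–500 beads over 2–19 frames, 16–56 px
3D drift volumes, 640–896 px fiber textures with 500 fibers (replicate
textures averaged where a single 500-fiber draw realizes the population
width only to a few percent), and 12-frame nuclei schedules with 40–60
cells. These sizes keep every property the package claims measurable with
comfortable statistical power while the full suite runs in about a minute.

## Known limitations

* Drift correction is rigid translation only; no rotation, no non-rigid
  registration, no all-to-reference scheme.
* Tracking has no motion model and no gap closing; a missed detection ends
  a track. This is faithful to the three-consecutive-frames rule but
  shortens tracks at low SNR.
* The flow implementation targets the displacement scales of nuclei
  imaging (a few px/frame via the pyramid); it is not a general-purpose
  optical-flow benchmark implementation.
* Fiber statistics are per-pixel, coherence-weighted; they quantify
  orientational order, not single-fiber geometry (length, curvature,
  pore size).
* The synthetic truth is kinematic; agreement with it cannot detect errors
  that only mechanically coupled deformations would reveal.
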