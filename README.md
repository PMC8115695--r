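# branchmech

Quantification of branch mechanics in organoid time-lapse imaging.

Epithelial organoids growing in floating collagen gels elongate their
branches by pulling on the matrix: tracer beads embedded in the gel reveal
an anisotropic, periodically contracting and partially irreversible
deformation field in front of each branch tip; the collagen network aligns
along the pulling direction; and the cells inside the branch move in
alternating collective and uncoordinated phases whose direction is coupled
to the matrix motion. `branchmech` turns multi-channel time-lapse stacks of
such cultures (beads / nuclei / collagen channels) into those quantities,
for researchers doing mechanobiology of branching morphogenesis who want
the full measurement chain scripted, seeded, and testable.

## What it computes

**ECM deformation.** Global stage drift is removed by maximizing the
normalized cross-correlation between consecutive frames over an integer
shift window. Beads are detected by intensity masking and localized as
intensity-weighted centroids on an interpolated grid (with an iterated
Gaussian-mask refinement), filtered at boundaries and below a minimum
pairwise distance, and linked by mutual nearest neighbours over at least
three consecutive frames. Each track step is projected into the branch
frame as *(r, θ, s)* — distance to the tip, angle to the branch axis, and
the signed component *s* toward the tip (positive = contraction). From
these: cumulative near-field displacement over time, mean *s̄(θ)* angular
profiles, 100-µm distance-stripe profiles, contraction/relaxation phase
labels, and the signed change after a perturbation event.

**Fiber alignment.** Per-pixel orientations from the structure tensor
(coherence-filtered) feed an orientation histogram over [−90°, 90°); a
wrapped Gaussian is fitted and its full width at half maximum recovered as
`FWHM = 2√(2 ln 2) σ`. Across a set of regions or conditions the degree of
alignment is

```
d = (FWHM_max − FWHM) / FWHM_max,
```

where `FWHM_max` is the maximal width measured in the set, so the least
aligned condition has `d = 0`.

**Cell dynamics and coupling.** A dense polynomial-expansion optical flow
(Farnebäck family, pyramidal with warping) of the nuclei channel yields
per-pixel velocities in µm/min, decomposed into branch-parallel and
orthogonal components. Per frame, the order parameter
`Φ = |mean(sign(v_par))|` segments collective (outward/inward) from
uncoordinated phases, and the lag-scanned correlation of `v_par(t)` with
`−s̄(t+lag)` quantifies cell–ECM coupling (outward motion ↔ matrix
relaxation).

**Synthetic scenes.** Every stage is testable without microscope data: a
seeded generator renders bead stacks advected by a reference field

```
u(x,t) = A · cos^k θ(x) [θ ≤ 90°] · exp(−r(x)/λ) · g(t) · ê(x → tip),
g(t)   = ρ·t/P + (1−ρ)·(1 − cos(2πt/P))/2,
```

plus fiber textures with controlled orientational spread and nuclei moving
in scheduled phases — all with exact ground truth recorded before
rendering.

## Worked example

Simulate a branch scene (known field), run the bead chain, and look at the
deformation statistics:

```r
library(branchmech)
library(dplyr)

fp <- field_params(amplitude = 3, decay_length = 80, anisotropy = 2,
                   period = 60, plastic_fraction = 0.5,
                   tip = c(0, 64), axis = c(1, 0))
scene <- simulate_bead_scene(fp, n_frames = 13, image_dim = c(1, 128, 128),
                             n_beads = 40, noise_sigma = 0.1,
                             min_spacing = 6.5, seed = 1)
scene$stack
#> <timelapse_stack: 13 frame(s), 1 x 128 x 128 voxels (z,y,x), voxel 1 x 1 x 1 um, dt 10 min, channel 'beads'>

geometry <- branch_geometry(tip = c(0, 64), axis = c(1, 0),
                            near_field_um = 120)
samples <- detect_beads_stack(scene$stack, min_distance = 5) |>
  link_tracks(link_radius = 6) |>
  track_displacements() |>
  project_samples(geometry)

tail(cumulative_displacement(samples, geometry), 3)
#> # A tibble: 3 × 4
#>   frame time_min cum_um n_active
#>   <int>    <dbl>  <dbl>    <int>
#> 1    11      100  0.859       39
#> 2    12      110  0.747       39
#> 3    13      120  0.722       39

angular_profile(samples, bin_width = 30)
#> # A tibble: 3 × 6
#>   theta_lo theta_hi theta_mid s_mean  s_sd     n
#>      <dbl>    <dbl>     <dbl>  <dbl> <dbl> <int>
#> 1        0       30        15 0.0826 0.236   262
#> 2       30       60        45 0.0520 0.199   134
#> 3       60       90        75 0.0167 0.137    48
```

The cumulative series ends at 0.72 µm after two full periods: the two
contraction/relaxation cycles cancel and what remains is the plastic part
of the imposed field (`ρ = 0.5`), scaled down by its angular and radial
attenuation over the tracked beads. The angular profile falls from
0.083 µm/step head-on to 0.017 µm/step at 60–90°, recovering the imposed
`cos²θ` anisotropy. Phase labels follow the sign of the per-frame mean:

```r
fm <- frame_mean_displacement(samples, geometry)
label_phases_ecm(fm, noise_floor = 0.02)
#> # A tibble: 12 × 5
#>   frame time_min  s_mean     n phase
#>   <int>    <dbl>   <dbl> <int> <chr>
#> 1     2       10  0.149     35 contraction
#> 2     3       20  0.273     36 contraction
#> 3     4       30  0.223     35 contraction
#> 4     5       40 -0.0863    35 relaxation
#> # ℹ 8 more rows
```

`run_pipeline()` chains all stages (drift → tracking → deformation →
fibers → cells → coupling) from one config list or YAML file and writes
per-stage CSVs plus a provenance log; see the vignette
(`vignettes/branch-mechanics.Rmd`) for the full model description and
every tunable parameter.

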