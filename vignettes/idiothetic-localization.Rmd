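---
title: "Idiothetic localization: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Idiothetic localization: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idioloc)
```

## The problem

An agent moving in a familiar 2D arena receives only error-prone self-motion
estimates (idiothetic cues: per-step heading change and step length) and
holds a remembered map of the arena boundary. It senses nothing of the
outside world — no vision, no boundary contact. Can it determine its pose
(position plus heading), even when it starts fully disoriented?

The answer implemented here: yes, provided the arena has 1-fold rotational
symmetry (no rotation short of 360° maps it onto itself). The mechanism is
Bayesian fusion, approximated by a particle filter. Each particle is a pose
hypothesis that dead-reckons the reported displacements with its own process
noise; any hypothesis whose implied path crosses a remembered boundary is
impossible and is culled, and survivors are cloned back to the fixed
population size. Uncertainty grows by path-integration noise (a diffusing
particle cloud) and shrinks by culling; in a rotationally asymmetric arena
the balance settles well above chance.

## The generative model

**Trajectories.** Movement is simulated at `dt = 0.5` s. The random policy
is a correlated random walk: per-step turning `N(0, turn_sd^2)` with
`turn_sd = 30°`, per-step speed `N(15, 4^2)` cm/s truncated at zero
(rodent-like open-field locomotion; the mean is the only value the problem
statement fixes, the rest are package choices). A step that would cross a
boundary is truncated just short of the wall and the next step's heading is
redrawn uniformly from inward directions. The redraw is deferred to the next
step on purpose: each step's displacement then stays collinear with its
end-of-step heading, so dead reckoning on a noise-free stream reproduces the
trajectory exactly — a property the test suite asserts. The thigmotactic
policy steers along the outer wall at `wall_offset = 5` cm, measured from
the body surface; for an elongated body the centre target adds the lateral
half-width plus a `0.15 a` curvature allowance, without which a 7.5 × 3.5 cm
body jams against a curved wall.

**Self-motion errors.** Heading error accumulates as a Wiener process:
in iPI mode each reported heading change carries an independent
`N(0, sigma_theta^2 dt)` increment, so heading-error variance grows linearly
at rate `sigma_theta^2`. In aPI mode a compass resets orientation error
every step: the reported absolute heading is exact and only step lengths are
noisy, `reported = true * (1 + N(0, sigma_step^2))`. Optional intermittent
observations are a Poisson-timed noisy compass (default one reading per
30 s, SD 15°) and a boundary-contact flag (body within `contact_tol` of a
wall).

**Calibration.** The rodent-recorded noise magnitudes are not available to
this implementation, but their behavioural consequence is: with path
integration alone, initially oriented at the kite centre, the median place
stability index must fall below chance within about 3 minutes using iPI and
about 6 minutes using aPI. `calibrate_noise()` selects the smallest grid
values meeting those anchors — `sigma_theta = 0.05` rad s^-1/2 (crossing
≈ 2:10) and `sigma_step = 0.15` (crossing ≈ 4:15), packaged as
`default_error_model()` and reproducible with `scripts/calibrate.R`. These
defaults were fixed by that calibration and not adjusted afterward.

## The filter

`run_filter()` advances N pose hypotheses per reported step (heading update
first, then translation — the same order the generator uses, so zero-noise
tracking is exact). Three boundary modes expose what the map constraint
actually does:

* `crossing` — cull a particle if its step segment (for a finite body: the
  swept paths of perimeter sample points) intersects the outer boundary, a
  barrier or a void. This is the full model.
* `discrete_endpoint` — only require the step endpoint to lie in
  traversable space. Zero-width barriers are invisible to this test, which
  is exactly why localization fails with it in the barrier arena.
* `none` — pure path integration.

Culled weight is redistributed by systematic resampling (cloning), which
preserves every equal-weight survivor when the population is at least the
survivor count — that makes small enumeration examples exactly reproducible
— and has lower variance than multinomial cloning. If every particle dies
(possible with a misleading map or harsh observations) the ensemble is
reinitialized from the disoriented prior over the map and the event is
counted in the result; the alternative of keeping a dead ensemble would
break the fixed-N invariant.

Each particle records the index of its ancestral initial pose. That gives
two retrospective estimators: `reverse_replay()` re-runs the filter backward
over the stored stream from the final ensemble (move back along the current
heading, then un-apply the heading change, with identical culling), and
`backward_inference_online()` reads the time-0 posterior directly off the
surviving lineages at any moment, with no stored stream at all. Lineages
lost to a total-cull reinitialization are dropped from that posterior.

## Metrics

The place stability index is defined as

\[ I_p = 1 - \frac{\bar D_{post}}{2 \bar D_{unif}}, \]

where \(\bar D_{post}\) is the weighted mean distance from the particles to
the true position and \(\bar D_{unif}\) the mean distance from a uniformly
distributed point in the traversable region to the true position (a 10^5
point quadrature, cached per arena; metric time series use a 2 cm bilinear
interpolation table of the same quadrature). The exact functional form used
in the source work is not published in its main text; this distance-ratio
form is adopted because it provably pins the two stated anchors — 0.5 for a
uniform ensemble and 1 for a perfect one — and admits values below zero for
worse-than-chance estimates. All quantitative claims in this package use
only those anchors and crossing/convergence times, never formula-specific
values.

For an arena with n-fold rotational symmetry the adjusted index
`adjusted_place_stability()` replaces the distance to the truth with the
minimum distance over the n rotational images of the truth about the
centroid (normalizer recomputed the same way): within each of the n
geometrically equivalent sectors localization is possible, and the adjusted
index credits it.

Heading quality is the circular variance `V = 1 - R` of the across-trial
ensemble-mean heading errors: 0 means no error, values near 1 uniformly
random headings. (The source text states this convention in its results;
its methods section inverts it in one sentence, treated here as a
typographical slip.) Convergence speed is `t90`: the plateau is the median
of the last 10% of the median-I_p series and t90 is the first time the
series completes 90% of its change from the starting value.

## Arenas and geometry

Arenas are polygons (outer boundary, optional zero-width barrier polylines,
optional void holes), coordinates in cm, centred on the traversable
centroid. The canonical kite has interior angles 60/90/120/90° and an 80 cm
long diagonal (area ≈ 2771 cm²); egg, T-maze, square and regular polygons
are matched to that area so that cross-arena comparisons are not confounded
by size. The circle keeps its 76 cm diameter. Curves are discretized to
polygons whose sagitta stays below 0.1 mm (137 edges for the 76 cm circle,
capped at 360) so one segment-intersection code path serves all geometry.

Rotational asymmetry `A(phi)` is the area of the symmetric difference
between the traversable region and its rotation by `phi` about the centroid,
divided by twice the area — 0 exactly when the rotation is a symmetry, and
identically 0 for a circle. It is computed on a rasterized membership mask
(0.25 cm grid; the rotated copy is evaluated by nearest-grid lookup), which
matches a 1 mm direct point-in-polygon oracle to better than 0.2% relative
in the tests; no polygon-clipping library is required. The pivot is the
traversable centroid, a package choice (the source leaves it unstated).
Note that zero-width barriers contribute no area: the barrier arena is
rotationally symmetric *in traversable space*, which is precisely the
regime where only the crossing model localizes.

Numerical edge cases worth knowing: containment uses an even-odd ray cast
(points exactly on an edge are resolved arbitrarily but consistently);
segment intersection counts touching as crossing (conservative for
culling); the elliptic body is sampled at 72 perimeter points for
containment queries and 8 for the filter's swept-path tests (the coarser
sampling changes cull decisions only for near-tangent grazes and halves the
hot-loop cost).

## Grid-cell readout

`simulate_spikes()` draws per-step Poisson spike counts with rate
`lambda_max * exp(-d^2 / (2 sigma_f^2))`, where `d` is the distance of the
*estimated* position from the nearest node of a hexagonal lattice
(default spacing 30 cm, `sigma_f = 6` cm, `lambda_max = 20` Hz, phase and
orientation randomized per cell). Spikes are georeferenced to the *true*
position: spatial structure appears in the firing field only insofar as the
estimate tracks the truth, making the rate map a time-averaged display of
localization quality. Rate maps are occupancy-normalized on 2 cm pixels
with 1-pixel Gaussian smoothing; `gridness()` is the standard rotational
autocorrelogram score (annulus from the central peak's first zero crossing
to 1.25× the modal peak distance; min of 60°/120° correlations minus max of
30°/90°/150°), `spatial_information()` the usual bits-per-spike measure, and
`optimal_rescaling()` grid-searches the stretch that best aligns a test
firing field with a reference (reporting the stretch embodied in the test
map, e.g. ≈1.1 after a 10% arena expansion).

## What the simulations do and do not show

The generator emulates: rodent-scale arenas and speeds, Wiener heading
drift, multiplicative step noise, wall-bounded correlated-random-walk and
wall-following exploration, finite body geometry, and intermittent
allothetic observations. It does not emulate speed-dependent noise,
biomechanics, continuous-time kinematics, moving boundaries, map
acquisition (the map is given), or any neural circuit dynamics — grid
spikes are a readout of the filter's estimate, not a model of entorhinal
computation. Passing tests therefore demonstrate properties of the
information-fusion problem, not of any specific animal.

Problem sizes in the tests and acceptance script are scaled down from the
full protocols (10^3 trials, up to 192 simulated minutes) to 100–200 trials,
2000 particles and 8–48 simulated minutes; medians and orderings are stable
at that scale, and every scale knob (`trials`, `duration`, `N`) accepts the
full values.

## Worked example

```{r example, eval = FALSE}
library(idioloc)
kite <- make_standard_arena("kite")
cfg <- preset_config("fig2", trials = 20, duration = 2880, N = 2000,
                     master_seed = 3)
res <- run_experiment(cfg)
res
#> <experiment_result 'fig2'> 20 trials, 48:00 simulated
#>   final Ip_median = 0.849, V(theta) = 0.160, t90 = 0:50
```

Starting from complete disorientation, the median place stability index
rises from chance (0.5) to about 0.85 within the first minute and holds
there for 48 simulated minutes, while the circular variance of the heading
error falls from 1 toward 0.1–0.2 — localization from idiothetic cues and a
remembered boundary alone.

## Known limitations

* Heading convergence in n-RS arenas is reported per trial by the ensemble
  circular mean; while an ensemble still carries several symmetric modes
  that mean is not meaningful (the resultant-length flag in
  `estimate_pose()` marks this).
* The uniform-prior reinitialization after a total cull discards lineage
  information, so online backward inference degrades in conditions with
  frequent total culls (severely mismatched maps).
* `I_p` compares against a uniform prior over the *full* traversable space
  even for finite bodies, whose centres cannot reach the wall zone; the
  disoriented anchor is therefore slightly above 0.5 for large bodies.
* The asymmetry raster (0.25 cm) limits `A(phi)` resolution to ~10^-3;
  symmetry detection uses a 0.02 tolerance accordingly.
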