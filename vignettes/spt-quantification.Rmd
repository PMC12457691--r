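---
title: "Quantifying membrane-protein dynamics in rod-shaped bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-protein dynamics in rod-shaped bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodtrack)
```

## The problem

Peptidoglycan-synthesizing enzymes of rod-shaped bacteria such as *Bacillus
subtilis* live in the plasma membrane and are visible by TIRF microscopy as
diffraction-limited foci. A single protein species typically shows several
coexisting behaviors: a minority subpopulation moves processively and
circumferentially (perpendicular to the cell long axis) at tens of nm/s,
reporting on active cell-wall synthesis by the Rod complex, while the
majority diffuses in the membrane, often as a mixture of a slow and a fast
diffusive state. `rodtrack` implements the full quantification chain for
such data — spot detection, trajectory linking, motion classification,
per-trajectory diffusion-coefficient estimation and mixture decomposition —
together with morphometric descriptors of cell curvature, and synthetic-data
generators so that every stage can be validated against known ground truth.

## The analysis pipeline

The single-particle pipeline runs in five stages.

**1. Preprocessing** (`preprocess_stack()`). The minimum projection over the
whole stack is subtracted from every frame (removing static background and
camera offset), then frames are averaged pairwise with a sliding window of
two consecutive frames at stride 1. The output has one frame fewer than the
input and is non-negative by construction. A stride of 1 (overlapping
windows) was chosen over stride 2 (tiling): it preserves the acquisition
rate, which the downstream time base assumes.

**2. Spot detection** (`detect_spots()`). Frames are convolved with a
scale-normalized Laplacian-of-Gaussian kernel. The filter scale is tied to
the nominal spot radius as sigma = radius / sqrt(2), the scale at which the
LoG response of a matched Gaussian blob peaks; the default radius of
0.25 µm matches a diffraction-limited spot imaged at high NA. Local maxima
above a threshold are kept, refined to subpixel position by a quadratic fit
to the 3×3 response neighborhood, and pruned so no two detections sit
closer than one radius. The response is linear in spot amplitude, so the
threshold is expressed in image intensity units and must be set relative to
the camera scaling of the data at hand — there is no universal default that
is meaningful across instruments, which is why synthetic tests set it
relative to the simulated amplitude.

**3. Linking** (`link_detections()`). Frame-to-frame association is a
linear assignment problem: candidate links cost their squared displacement,
capped at `max_dist_um^2` (default 0.4 µm); ending a track or starting a
new one costs the cap. The augmented square problem is solved exactly with
a shortest-augmenting-path assignment solver, so a pair is linked precisely
when that improves on the birth/death alternative and the total squared
displacement is minimal. No gap closing is performed (`max_gap = 0`): a
trajectory ends as soon as no admissible match exists in the next frame.

**4. Motion classification** (`classify_tracks()`). For each trajectory of
at least `min_frames` points (default 10) the overlapping-estimator MSD is
computed and fitted over a short window to two models:

* ballistic, MSD(t) = (v t)^2 — fitted as sqrt(MSD) = v t, which is linear
  in the speed and numerically stable;
* free diffusion, MSD(t) = 4 D t, with zero intercept by default (a free
  intercept absorbing localization noise is available via
  `noise_intercept = TRUE`).

A track is *directed* when the ballistic R² reaches `r2_dir` (default 0.9),
otherwise *diffusive* when the linear R² reaches `r2_diff` (default 0.8),
otherwise *unclassified*. Directed is tested first because a ballistic
track also fits a line well; the converse is rare. The fit window is the
first `max(3, min(floor(n/4), 10))` lags: long lags of the overlapping
estimator are dominated by noise, and fewer than three points would make R²
degenerate (any two points fit both one-parameter models exactly, so
without the floor every minimum-length track would classify as directed).
The directed subpopulation is summarized by its mean and SD of fitted
speeds and its fraction of classifiable tracks (`summarize_directed()`),
and by its surface density: directed foci counted per frame inside the cell
mask, divided by the mask area (`compute_density()`). The density
denominator is the *cell* area, not the imaged field — the quantity of
interest is machinery per unit of membrane.

**5. Diffusion quantification** (`estimate_dc_table()`,
`fit_lognormal_mixture()`). Directed tracks are excluded — a processive
track looks like very slow diffusion at a fixed lag and would contaminate
the slow component. For each remaining trajectory, displacement magnitudes
at a fixed lag of 4 frames (observation period Δt = 4 t_lag) are compared
with the free-diffusion displacement model

$$\mathrm{CDF}(r, \Delta t) = 1 - \exp\!\left(-\frac{r^2}{4 D \Delta t}\right)$$

and D is estimated per trajectory by least squares between this model and
the empirical CDF at the Hazen plotting positions (i − 0.5)/n, which avoid
placing probability exactly at 0 or 1 and behave well in the small
per-trajectory samples (a 20-frame track yields 16 overlapping
displacements). Overlapping displacements are used deliberately: they are
correlated, but discarding them would halve the information per track, and
the estimator is validated against the closed-form exponential maximum
likelihood estimate mean(r²)/(4Δt) — the two agree within 5% at 10³ model
displacements and converge as n grows.

The per-cohort distribution of log D is then decomposed into two Gaussian
components (equivalently, D into two log-normals) by maximum likelihood
via EM, with k-means initialization plus seeded random restarts, a
log-likelihood tolerance of 1e-8, and components ordered so that d1 < d2.
The reported `w1` is the weight of the *slow* component. Coefficients that
are zero (perfectly stationary tracks) are excluded with their count
reported, since the log-normal has positive support. When the two fitted
log-means are closer than 0.5 log units the fit is flagged as effectively
unimodal rather than reporting two spurious components. Replicate fits are
aggregated per strain as medians (`aggregate_replicates()`), and
between-strain changes as ratios of medians (`fold_change()`).

## The synthetic-data generators

`simulate_trajectories()` draws a cohort that mirrors the statistical
structure the analysis assumes: a fraction `frac_directed` of tracks moving
ballistically at constant speed along a fixed random orientation, the rest
Brownian with per-axis step variance 2 D t_lag, split between a slow and a
fast population (`frac_slow` of the non-directed tracks, i.e. the mixture
weight w1). Defaults are the wild-type study conditions: D = 0.0024 and
0.0147 µm²/s with the slow population at 23%, directed speed 56.5 nm/s
(0.0565 µm/s), frame interval 0.1 s. Track lengths follow a geometric
distribution truncated to [20, 40] frames by default, so the
minimum-duration filter is actually exercised; the mean of ~30 frames is
realistic for fluorophore survival in SPT at these rates. Localization
noise is i.i.d. Gaussian per coordinate (default SD 20 nm, typical for a
bright organic dye at 100 ms exposure); motion blur within the exposure is
not modeled, being secondary to the pipeline logic being tested.

Directed motion is modeled as a straight line in the TIRF plane rather
than as a projected circumferential arc: at ~56 nm/s a 10–30 frame track
traverses well under half a micron, a small arc of the cell circumference
that is close to linear in projection.

One modeling decision deserves emphasis: **the diffusion coefficients used
as simulation ground truth are *apparent* coefficients.** The printed
values any study reports are themselves outputs of a CDF fit applied to
noisy positions, so localization error is already folded into them.
Simulating "true D = printed value" *and* adding localization noise on top
would double-count the error — 20 nm noise at Δt = 0.4 s alone adds
σ²/Δt = 0.001 µm²/s, inflating a 0.0024 µm²/s component by over 40%. The
mixture-recovery validations therefore simulate the diffusive cohorts
noise-free, making the configured D the apparent D. Speed recovery, by
contrast, is validated with 20 nm noise, since the ballistic MSD fit is
robust to it.

`simulate_movie()` renders foci as pixel-integrated 2D Gaussians (PSF SD
0.1 µm by default) at their true subpixel positions inside rod-shaped cell
footprints, on a constant background with Poisson shot noise and Gaussian
read noise, at 0.065 µm/px (a 16 µm EMCCD pixel behind 100× with an
additional magnification lens). `constant_density_tracks()` builds
schedules of back-to-back directed tracks so that an exact, known number
of directed foci is present in every frame — giving a movie whose true
directional-foci density is known exactly for density-recovery tests.

`simulate_bent_rod_contour()` produces cell outlines as a circular-arc
centerline dilated by half the cell width, with semicircular poles and an
optional smooth width-noise profile (spline through Gaussian knots,
rescaled so the realized profile SD equals the requested one). The `length`
parameter is the full pole-to-pole extent. Configurations whose inner wall
would fold onto itself, or that would bend past a half circle, are
rejected.

What the generators do *not* emulate: photophysics (blinking, bleaching
kinetics) beyond truncated track lengths, 3D motion and defocus, motion
blur, anomalous or confined diffusion, cell-to-cell variability in D, and
non-uniform (asymmetric) cell bending. Passing recovery tests therefore
demonstrates the correctness of the estimators under the stated model, not
robustness to every artifact of real acquisitions.

## Cell-shape descriptors

`extract_medial_axis()` recovers the cell centerline by an iterative chord
method: chords are drawn perpendicular to the current centerline estimate
(initially the principal axis), and their smoothed midpoints become the
next estimate. Smoothing is local-linear (lowess), chosen over a moving
average because it does not drag the endpoints inward — an effect that
would systematically truncate the measured cell and bias width statistics.
Widths are chord lengths; poles are the contour points extremal along the
end tangents.

`solidity()` is polygon area over convex-hull area. `width_stats()`
resamples widths at a fixed spacing along the centerline (one pixel, by
analogy with measuring width at every axis position of a digitized cell)
and excludes samples within half a mean width of either pole, because
chords through the hemispherical caps understate the cylinder diameter;
width variation is the SD of the remainder.

`asymmetry()` reports the intersection-over-union of the cell with its
mirror image — IoU because it is symmetric in the two halves and equals 1
exactly at perfect symmetry. The reflection axis required care. Reflecting
point-wise across the *curved* medial axis is, in straightened coordinates,
the map d → −d, which is a set-bijection of any tube-shaped cell onto
itself: every uniformly bent rod would score exactly 1, and the descriptor
would carry no curvature information at all. The implementation therefore
reflects across the straight line fitted (total least squares) to the
medial-axis polyline — identical to the medial axis for straight cells, and
yielding an overlap that decreases strictly with curvature. The
longitudinal axis is the perpendicular to that line at the centerline
arclength midpoint. Note that a uniform circular arc is genuinely
mirror-symmetric about its midpoint perpendicular, so on arc-generated
cells the longitudinal descriptor stays near 1 regardless of curvature; it
responds to asymmetric bending, which the generator deliberately does not
produce. Cross-strain *differences* in these descriptors, not their
absolute values, are the comparable quantity, since the exact
normalization conventions differ between morphometry tools.

Label masks are converted to contours with a marching-squares object
tracer, smoothed by a short moving average, and pushed half a pixel
outward along the local normal (the trace runs through boundary-pixel
centers, half a pixel inside the object support).

## Numerical choices and degenerate inputs

* CDF fit: optimized over log D bracketed at a factor of 50 around the
  closed-form moment estimate, which seeds the search; all-zero
  displacement sets return D = 0 with a degeneracy flag.
* EM: component SDs floored at 1e-6 log units; a die-off of one component
  terminates that start; the best of all starts is returned with its
  log-likelihood trace, so monotonicity is checkable.
* Stationary tracks (MSD identically zero) classify as diffusive with
  D = 0 and a perfect zero-model fit.
* R² is 1 − SS_res/SS_tot on the fit window; an SS_tot of 0 with zero
  residuals counts as a perfect fit.
* Asymmetry grids are offset half a cell from the bounding box so that no
  grid point sits exactly on a polygon edge, where inside/outside ties
  would bias the overlap.
* Mixture fits require at least 20 positive coefficients; fewer is an
  error, not a silent fit.

## Validation problem sizes

The bundled validations run at the scale the method is meant for while
staying quick: speed recovery uses 200 directed tracks of 30 frames;
mixture recovery uses cohorts of 4000 trajectories (the scale of a typical
per-strain SPT dataset) of 20–40 frames; density recovery uses a 200-frame
movie of one ~15.6 µm² cell with two concurrent directed foci; morphometry
uses a five-point curvature sweep from 0 to 0.3 µm⁻¹ at 0.8 µm width.
`scripts/acceptance.R` re-runs all of these from scratch from a single
seed.

## Known limitations

* No gap closing, track splitting or merging; detections lost for one
  frame start a new trajectory.
* The two-component mixture is fixed at two components; model selection
  over one vs. two is reported only via the unimodality flag, and three or
  more states are out of scope.
* No pause/reversal segmentation within directed tracks.
* The per-trajectory CDF estimator assumes free diffusion within each
  track; state switching within a trajectory blurs the mixture.
* Shape descriptors assume a single, simple, elongated contour per cell;
  dividing cells with pronounced septa may fail medial-axis extraction and
  are reported as failures rather than guessed at.
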