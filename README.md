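# rodtrack

Single-particle tracking (SPT) quantification and cell morphometrics for
membrane proteins of rod-shaped bacteria imaged by TIRF microscopy.

Cell-wall synthesis machinery (e.g. the SEDS glycosyltransferase of the Rod
complex in *Bacillus subtilis*) appears in TIRF movies as diffraction-limited
foci with mixed dynamics: a directed subpopulation moving circumferentially
at tens of nm/s, and a diffusing majority that itself splits into a slow and
a fast state. `rodtrack` implements the full quantification chain for such
data and ships synthetic-data generators with exact ground truth so every
stage is testable.

The pipeline:

1. **Preprocess** — subtract the stack minimum projection, average over a
   2-frame sliding window (`preprocess_stack()`).
2. **Detect** — scale-normalized Laplacian-of-Gaussian spot detection with
   subpixel refinement (`detect_spots()`, radius 0.25 µm by default).
3. **Link** — frame-to-frame linear-assignment matching, squared-displacement
   cost capped at 0.4 µm, no gap closing (`link_detections()`).
4. **Classify** — per-trajectory MSD fits to a ballistic model
   MSD = (v·t)² and a diffusive model MSD = 4·D·t; a track is *directed*
   when the ballistic R² ≥ 0.9, else *diffusive* when the linear R² ≥ 0.8;
   tracks under 10 frames are dropped (`classify_tracks()`). Speed, the
   directional fraction and the surface density of directed foci per µm² of
   cell area follow (`summarize_directed()`, `compute_density()`).
5. **Quantify diffusion** — directed tracks are excluded; for each remaining
   trajectory the displacement magnitudes at lag 4 (Δt = 4·t_lag) are fitted
   to the free-diffusion model

   CDF(r, Δt) = 1 − exp(−r² / (4·D·Δt))

   giving one diffusion coefficient per trajectory
   (`estimate_dc_table()`). The cohort's log-D distribution is decomposed
   into two log-normal components (D₁ < D₂, slow weight w₁) by EM maximum
   likelihood (`fit_lognormal_mixture()`); replicates aggregate as
   strain-wise medians (`aggregate_replicates()`, `fold_change()`).

A separate morphometrics module computes curvature descriptors from cell
contours or label masks: solidity (area / convex-hull area), lateral and
longitudinal asymmetry (overlap of the cell with its reflection across axes
derived from the medial axis; 1 = perfectly symmetric), width variation,
mean width and length (`extract_medial_axis()`, `shape_descriptors()`,
`run_shape_pipeline()`).

Synthetic generators cover all inputs: trajectory cohorts
(`simulate_trajectories()`), TIRF-like movies of Gaussian spots with
Poisson–Gaussian noise inside rod-cell footprints (`simulate_movie()`,
`constant_density_tracks()`), and bent-rod contours of known curvature
(`simulate_bent_rod_contour()`). Real data enters as multi-page TIFF
(`read_stack_tiff()`), plain track CSV (`read_track_csv()`) or TrackMate
exports (`read_trackmate_csv()`).

## Worked example

Simulate a wild-type-like strain (12% directed foci at 56.5 nm/s; slow/fast
diffusion at 0.0024 / 0.0147 µm²/s with the slow state at 23%) in two
replicates, and run the whole pipeline:

```r
library(rodtrack)

sim <- trajectory_sim_config(n_traj = 1500, frac_directed = 0.12,
                             frac_slow = 0.23, d_slow = 0.0024,
                             d_fast = 0.0147, speed = 0.0565,
                             t_lag = 1, loc_noise_sd = 0.02)
cfg <- spt_run_config(
  replicates = list(list(strain = "wt", replicate = 1, sim = sim),
                    list(strain = "wt", replicate = 2, sim = sim)),
  seed = 42)
report <- run_spt_pipeline(cfg)
print(report)
#> SPT pipeline report
#> -- per-strain mixture medians --
#>  strain n_replicates w1_median  d1_median  d2_median
#>      wt            2 0.2405279 0.00244976 0.01447318
#> -- directed subpopulation --
#>  strain replicate mean_speed_um_s sd_speed_um_s directional_fraction n_directed
#>      wt         1      0.07005733    0.03139487            0.1366667        205
#>      wt         2      0.06823827    0.02967764            0.1433333        215
```

Reading the numbers: the mixture decomposition recovers the simulated
ground truth almost exactly — slow fraction w₁ = 0.241 (truth 0.23) and
coefficients 0.00245 / 0.0145 µm²/s (truth 0.0024 / 0.0147). The
directional fraction (~0.14) slightly exceeds the simulated 0.12 because a
few percent of fast-diffusing tracks pass the ballistic R² test by chance;
those false positives carry meaningless fitted speeds, which is also why
the cohort speed mean (0.068–0.070 µm/s) sits above the simulated
0.0565 µm/s. On pure directed cohorts the recovered mean speed is within
2% of truth (see the acceptance script); on mixed cohorts the directed
*fraction* is the reliable summary and per-track speeds should be read from
the directed subpopulation after visual vetting, as in any SPT study.

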