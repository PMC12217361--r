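# punctatrack

Single-particle localization, tracking, mobility, activity and spatial
analysis of membrane ion-channel puncta — built around the kind of imaging
experiment in which endogenous PIEZO1 channels, tagged with HaloTag and
labelled with fluorescent or Ca²⁺-sensitive HaloTag ligands, appear as
diffraction-limited puncta in TIRF or lightsheet movies.

The package is aimed at microscopists and quantitative biologists who need
the full analysis chain behind such experiments as reusable, tested R
functions, together with a synthetic-movie generator that produces
ground-truth-annotated data so every stage can be validated without any raw
microscopy data.

## What it computes

**Localization.** Each frame is band-pass filtered (difference of Gaussians),
candidate spots above a robust `k·MAD` threshold are fit with an integrated
symmetric 2-D Gaussian, giving sub-pixel positions, PSF width σ, integrated
intensity and local background. Detections with σ > 280 nm (autofluorescent
blobs; bead-calibrated puncta have σ ≈ 189 nm) are removed.

**Tracking.** Nearest-neighbour linking within a 3-pixel radius between
adjacent frames, with gap closing (one frame by default; 90 ms worth of
frames for the flickering Ca²⁺ probe) and linear interpolation of gap-frame
positions. Tracks need at least 4 links; a persistence filter removes objects
not detected in ≥ 4 frames.

**Mobility.** Single lag displacements (SLD) and exponential-mixture fits to
the CDF of SLD²; per-track path length over a 5 s window with the 3 µm
mobile/immobile cutoff; time-averaged MSD per track and the apparent
diffusion coefficient from a linear fit at lags ≤ 2 s,

    MSD(t) = 4 D t + b,   D = slope / 4,

with the intercept absorbing the localization-error offset. Also:
localization error from fixed samples, photobleaching time constants from
`A·exp(−t/τ) + C` fits, and signal-to-background from 3×3-pixel ROIs.

**Activity.** Background-subtracted 3×3-ROI intensity traces per tracked
punctum, all-points amplitude histograms (pooled or averaged with equal
punctum weight), flicker event detection with dwell-time statistics, puncta
densities, and condition comparisons (Shapiro normality → t or Mann-Whitney,
Cohen's d with pooled SD, two-sample KS on amplitude distributions).

**Organoid spatial statistics.** For radial organoids with a central lumen:
filtering to bona fide puncta (σ filter + persistence for static labels;
σ filter + 261 c.u. intensity threshold for the Ca²⁺-sensitive label),
Euclidean-distance-transform distances from puncta to lumen and outer-edge
masks (rounded up to whole pixels), kernel-density distance scatter
(bandwidths 2.503 / 3.661 µm), area-normalized 2-µm distance histograms,
ECDFs and near-mask fractions.

**Simulation.** Ground-truth generators for all of the above: immobile and
(fractional) Brownian puncta rendered as integrated Gaussians with
photobleaching, Poisson shot noise and camera gain/black level; two-state
Markov flicker traces for channel clusters; organoid scenes with lumen/outer
masks, lumen enrichment, autofluorescent blobs and single-frame spurious
spots.

## Worked example

Simulate a two-population field, run the full pipeline, and estimate the
diffusion coefficients per mobility class:

```r
library(punctatrack)

spec  <- simulation_spec(n_immobile = 10, n_mobile = 10, D_um2_s = 0.029,
                         n_frames = 60, fps = 10, image_size_px = 128, seed = 42)
truth <- simulate_trajectories(spec)
movie <- render_movie(truth, spec)

locs  <- sigma_filter(detect_and_localize(movie), 280)
trajs <- link_trajectories(locs, link_params(radius_px = 3, gap_frames = 1,
                                             min_links = 4),
                           pixel_size_um = movie$pixel_size_um)

paths <- path_lengths(trajs, window_s = 5,
                      frame_interval_s = movie$frame_interval_s)
paths$class <- classify_mobility(paths$path_um, cutoff_um = 3)
table(paths$class)
#> immobile   mobile
#>        7        8

mobile_ids <- paths$track_id[paths$class %in% "mobile"]
msd <- compute_msd(trajs[trajs$track_id %in% mobile_ids, ],
                   movie$frame_interval_s)
fit_diffusion(mean_msd(msd), fit_max_lag_s = 2)$D_um2_s
#> [1] 0.03597317
```

The mobile-population estimate (0.036 µm²/s from 8 tracks) scatters around
the simulated 0.029 µm²/s; the immobile class on the same run fits to
D = 0 µm²/s with a mean localization error of 14 nm. Tracks shorter than the
5 s window are excluded from classification (NA class).

A thin CLI over the same functions lives at `inst/cli/punctatrack.R` with
subcommands `simulate`, `detect`, `track`, `mobility`, `activity` and
`organoid`, each accepting `--config` (YAML) and `--seed`.

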