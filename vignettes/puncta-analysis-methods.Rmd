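---
title: "Methods: puncta localization, tracking, activity and organoid spatial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: puncta localization, tracking, activity and organoid spatial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctatrack)
```

punctatrack analyses movies of diffraction-limited fluorescent puncta of
membrane ion channels — the archetype being endogenous PIEZO1 tagged with
HaloTag and labelled with bright or Ca²⁺-sensitive ligands. This vignette
documents the models and procedures each stage implements, the parameters
that matter, the numerical choices made where the design was genuinely open,
and what the synthetic-data generator does and does not emulate.

## Data model and conventions

A movie is a `frame × row × col` array of raw camera units (c.u.) with four
pieces of metadata: pixel size (µm), frame interval (s), camera gain
(photoelectrons per camera unit, 0.229 for the TIRF camera modelled here) and
black level (c.u.). Coordinates are 0-based; the centre of pixel (0,0) is
position (0 nm, 0 nm) and x runs along columns. Localization tables store
positions in nm (the ThunderSTORM CSV convention); analysis functions convert
to µm at a single point (`compute_sld`), so units cannot drift. Missing pixel
size or frame interval is a configuration error, never a silent default.

All fixed analysis constants live in `pipeline_config()`: 3 px linking
radius, 4 links minimum, 90 ms gap time (Ca²⁺ probe), 5 s path window, 3 µm
mobility cutoff, 2 s MSD fit range, 280 nm σ filter, 261 c.u. intensity
threshold, KDE bandwidths (2.503, 3.661) µm, 2 µm histogram bins, 5 µm
near-mask radius. Every value can be overridden from a YAML file.

## Spot detection and localization

Detection is a difference-of-Gaussians band-pass (default SDs 1 and 2 px)
followed by 8-neighbourhood local maxima above
`median + k · MAD` of the band-pass response (default `k = 5`). MAD rather
than SD makes the threshold robust against the bright puncta themselves.
Each candidate is fit by least squares with an *integrated* symmetric 2-D
Gaussian — the erf-difference flux over each pixel, not a point-sampled
Gaussian — with free amplitude, sub-pixel centre, σ and offset, inside a
9-px window. Point-sampling would bias both σ and the recovered photon count;
with the integrated model the noise-free recovery tests pass at 0.02 px and
5 % of σ. Fits that fail to converge are dropped and counted in the log.

This detector is deliberately a single-emitter fitter. Simulated densities
are kept below the overlap regime; fields dense enough to need multi-emitter
fitting are a documented limitation (the density-recovery test therefore
plants puncta on a jittered grid at 0.34 µm⁻², below overlap).

The σ filter removes fits with σ strictly greater than 280 nm, keeping the
boundary value, since the stated rule removes puncta *higher than* the
threshold. Diffraction-limited puncta fit at ≈ 189 nm; autofluorescent blobs
(simulated at 450 nm) fail the filter.

## Linking and gap closing

Linking is greedy nearest-neighbour, frame-sequential: candidate pairs
between open tracks and new localizations within the 3-px radius are ranked
by distance and assigned one-to-one, ties broken by localization order so
results are deterministic. A global assignment (Hungarian) linker was
deliberately not used: the described behaviour is "nearest punctum", and
greedy matching reproduces it exactly. When a track misses a frame the next
`gap_frames` frames are searched (`round(gap_time × fps)`, floor 1: 9 frames
at 100 fps for the 90 ms Ca²⁺-probe allowance, 1 frame otherwise); recovered
gaps are filled by linear interpolation and flagged. Interpolated entries
contribute to path lengths and SLDs (the flicker analysis depends on them)
but never count toward persistence minima, and mean track positions in the
organoid path use detected entries only.

"Minimum of 4 links" is ambiguous between 4 segments (5 points) and 4 frames
(3 segments); both readings are exposed (`min_links` in `link_params`,
`min_frames` in `persistence_filter`) with defaults of 4 links for the TIRF
diffusion path and 4 detected frames for the organoid persistence filter, as
printed for each context.

## Mobility

*SLD mixtures.* The empirical CDF of squared single-lag displacements is fit
to `1 − Σ aᵢ exp(−x/λᵢ)` at the sorted sample points. For one Brownian
population with per-axis localization noise σ_loc, SLD² is exactly
exponential with mean `4DΔt + 4σ_loc²` (each axis displacement is Gaussian
with variance `2DΔt + 2σ_loc²`); the test suite verifies this against the
analytic CDF by KS at α = 0.01 on 10⁴ simulated displacements. The
two-component fit is initialized from the sample mean split by {0.3×, 3×},
with three fallback splits because component collapse (λ₁ ≈ λ₂) makes the
Jacobian singular on one-population data. On such data the second component
can still soak up empirical-CDF noise, so "exp2 is not materially better" is
a statement about typical behaviour — the tests compare the median residual
ratio over replicate draws.

*Path-length classification.* The path length is the sum of SLDs over the
first `round(window/Δt)` frames of a track (50 frames at 10 fps for the 5 s
window, i.e. 49 segments); shorter tracks are excluded, not extrapolated.
Paths above 3 µm (strict) are mobile. For pure Brownian motion the expected
path is `(n−1)·√(πDΔt)`: 1.50 µm at D = 0.003 µm²/s and 4.68 µm at
0.029 µm²/s, so the two canonical populations classify correctly ≥ 90 % of
the time. A static punctum with 29 nm per-axis localization error walks an
apparent 2.5 µm in 5 s — still immobile. Note an intrinsic tension: *adding*
29 nm noise to a true D = 0.003 µm²/s walk pushes the expected path to
≈ 2.9 µm, right at the cutoff; published fixed-cell path distributions
(peak ≈ 1.2 µm over 50 frames) imply a smaller effective per-frame error
than the printed per-localization 29 nm, presumably from correlations
introduced by fitting and averaging. The classification tests therefore
separate the two effects (motion-only populations, and noise-only statics)
rather than forcing agreement.

*MSD and D.* Per track, the time-averaged MSD uses all ordered frame pairs
per lag — standard for short single-particle tracks and verified exactly
against a brute-force oracle. Per-video curves average tracks with equal
weight. The diffusion coefficient comes from a straight-line fit at lags
≤ 2 s with a *free intercept*; the intercept absorbs the `4σ_loc²`
localization-error offset so that D is read from the slope alone
(`D = slope/4`). Negative slopes clamp to D = 0 with a warning. On 500
simulated tracks the estimator recovers D within 10 %, and static emitters
with 29 nm noise stay below the 0.003 µm²/s immobile ceiling.

*Bleaching and photometry.* `bleach_time_constant()` fits `A·exp(−t/τ) + C`
by Levenberg-Marquardt, initialized from a log-linear fit; non-decaying
traces return `NA` with a warning rather than an error. At the canonical
τ = 38.1 s with Poisson noise on ~900 photoelectrons per point, the
estimator is unbiased to < 2 %. Signal-to-background and intensity traces
use 3×3-pixel ROIs, black-level subtracted; the background ROI is
user-specified and must not overlap any detection.

## Activity

Intensity traces subtract the per-frame background-ROI 3×3 sum, so the black
level cancels. All-points amplitude histograms default to 1 c.u. bins (no
published bin width; exposed in the API). Averaged histograms give each
punctum unit mass (equal punctum weight) rather than pooling frames — the
published averaging convention is not stated, and equal weighting keeps a
bright, long-lived punctum from dominating. Pooled histogram counts conserve
the total frame count exactly.

Flicker detection thresholds at `baseline + k·σ` (default `k = 4`) with the
baseline the trace median and σ a MAD-type scale from the dim portion; this
rule is the package's own (visual inspection is not reproducible). Event
durations recover the mean bright dwell `1/k_close` within 10 % across a
decade of closing rates at 500 fps sampling; the residual positive bias,
`1/(1−exp(−k_c Δt)) · Δt` versus `1/k_c`, is the discrete-sampling geometric
correction (≈ 2 % at `k_c Δt = 0.04`) and is left uncorrected since it is
well inside the Monte-Carlo error at practical rates.

Condition comparisons follow the published convention: Shapiro normality per
group, then a two-sided two-sample t test or Mann-Whitney, plus Cohen's d in
the classic pooled-SD form without small-sample correction — that form
reproduces the published patch-clamp effect size (−1.31) exactly from its
summary statistics (mean, SEM, n with `s = SEM·√n`).

## Organoid spatial analysis

Static-label filtering chains the σ filter, 3-px/one-gap linking, the
4-detected-frame persistence rule, and reduction of each track to its mean
detected position. The Ca²⁺-probe path cannot use persistence (flickering
puncta vanish between events), so it keeps single-frame detections at or
above 261 c.u.; the threshold stays in camera units because its printed
photon equivalent presumes the acquiring instrument's own gain.

Distances use the Euclidean distance transform of each mask's complement
(EBImage), sampled at the punctum's pixel and rounded *up* to the next whole
pixel before conversion to µm — "rounded up" is read as ceiling, and
positions on mask pixels get 0. The EDT agrees exactly with brute-force
nearest-mask-pixel search in the tests. The distance density scatter is a
product-Gaussian KDE with per-axis kernel SDs (2.503, 3.661) µm, normalized
to integrate to one — "scaled to the total number of puncta" is read as
probability normalization (the count-scaled alternative only rescales the
colour map). Distance histograms use 2 µm bins normalized to unit area;
near-mask fractions default to a 5 µm radius with SEM across videos.

## The synthetic generator

`simulate_trajectories` places puncta uniformly (inside a 6σ margin) and
moves the mobile population by fractional Brownian motion with per-axis
covariance `D(s^α + t^α − |t−s|^α)` — α = 1 (exact Gaussian increments) is
Brownian; sub-Brownian behaviour is a free knob because only its existence,
not a value, is established. Reported positions add independent per-axis
Gaussian noise (default 29 nm, the printed localization error of the
best-behaved ligand). `render_movie` integrates the 189 nm PSF over pixels,
scales amplitude by `exp(−t/τ)` (bleaching acts on emission, not on gating),
adds Poisson shot noise to photons and converts to integer camera units via
gain and black level. Defaults (~950 photoelectrons per punctum per frame,
10 photons/pixel background, black level 100 c.u.) give a signal-to-
background ratio around 5, matching the bright-ligand regime.

Flicker traces make each of the `cluster_size` channels an independent
two-state Markov chain sampled with exact discrete-time transition
probabilities, initialized at stationarity; punctum brightness is
`(n_open + dim_fraction · n_closed) × unitary`. The dim state defaults to 0
(a closed punctum is indistinguishable from background). No kinetic rates
are established for PIEZO1 flickers, so the rate defaults are illustrative
placeholders, not fits.

Organoid scenes are desk-scale: an annulus (defaults 4–9 µm; tests use
3–12 µm in a 256-px field) rather than a hundred-µm rosette, with a filled
lumen-disk mask and an outer ring mask, optional exponential lumen
enrichment, persistent wide blobs (σ = 450 nm) and single-frame spurious
spots. What the generator does *not* emulate: evanescent-field depth decay
(only per-punctum brightness scaling), sCMOS read-noise structure, emitter
overlap, drift (measured < 10 nm / 5 s in fixed samples and therefore
ignored), and 3-D optics — the package operates on 2-D frames or maximum-
intensity projections only. Passing tests therefore demonstrate estimator
correctness under the stated forward model, not performance on arbitrary
real data.

## Problem sizes and reproducibility

All generators run from explicit seeds via a private RNG stream (the
caller's `.Random.seed` is restored), and seeded runs are bit-reproducible.
The validation suite uses desk-scale sizes chosen to keep Monte-Carlo error
well inside each tolerance: 500 tracks × 50 frames for diffusion recovery,
10⁴ displacements for the exponentiality test, 25 × 10⁴-frame traces per
rate for dwell times, 256-px organoid scenes with 10 true puncta, 5 blobs
and 8 spurious spots for the filter-chain counts.

## Known limitations

Single-emitter fitting only; greedy (not globally optimal) linking with no
merge/split handling; no motion-model prediction; path lengths include
interpolated segments (choice logged); the published 29 nm localization
error and the published fixed-cell path-length peak are mutually
inconsistent under naive error summation, and the package documents rather
than resolves this; the two printed camera gains (0.229 pe/c.u. TIRF; the
organoid instrument's 77 photons ≈ 261 c.u.) are exposed per movie and not
reconciled.
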