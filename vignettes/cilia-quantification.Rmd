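---
title: "Quantifying cilia dynamics, basal-body polarity and ciliary flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cilia dynamics, basal-body polarity and ciliary flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliadyn)
```

`ciliadyn` turns three kinds of raw observation — two-channel 3D
fluorescence stacks, traced orientation vectors, and particle trajectories
— into the quantitative readouts used in ciliogenesis and planar cell
polarity studies. This vignette describes the models and procedures, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical choices behind edge cases.

## 1. Cilia detection and length measurement

The detection engine (`quantify_field()`) consumes a two-channel stack —
a centrosome marker (e.g. pericentrin or γ-tubulin) and acetylated
α-tubulin marking the axoneme — and processes it in six steps:

1. **Maximum-intensity projection** of each channel along z
   (`project_max()`). Acquisitions of 10–12 z-planes are collapsed to 2D;
   the procedure is deliberately two-dimensional and reports the projected
   length of each axoneme.
2. **Centrosome detection** (`detect_centrosomes()`): a
   difference-of-Gaussians band-pass at the spot scale
   (`spot_sigma_px`, default 2 px), local 8-neighbourhood maxima, and an
   intensity gate at the image background median plus `min_peak_snr`
   robust (MAD-based) standard deviations. Spots closer than
   `min_separation_px` resolve to the brighter one.
3. **Peri-centrosomal crop** (`crop_pericentrosomal()`): an 11 µm square
   around each spot, cut from the projected axoneme channel. The pixel
   side is forced odd so the centrosome is the exact centre pixel;
   off-image area is padded with the background median and flagged.
4. **Seed segmentation** (`segment_proximal_cluster()`): the crop is
   thresholded at its `seed_quantile` (default 0.99) intensity quantile
   and the qualifying connected component nearest the crop centre becomes
   the seed — the bright proximal part of the axoneme.
5. **Region growing** (`grow_axoneme()`): border pixels are admitted while
   their intensity is at least `contrast_stop_ratio` (default 1.5) times
   the local background, re-estimated each iteration as the median of
   crop pixels outside the current mask dilated by 2 px. A stop rule
   phrased as "grow *until* contrast is *above* a threshold" would never
   start; it is implemented as *grow while the contrast criterion holds*.
6. **Length measurement** (`measure_axoneme_length()`): the mask is
   thinned to a 1-px skeleton and the length is the longest geodesic path
   through it (step cost 1 axial, √2 diagonal, × pixel size).

A centrosome is *ciliated* when its measured length reaches
`min_cilium_length_um` (default 1 µm); non-ciliated records carry an empty
mask and zero length by contract. Percent-ciliated summaries feed
`summarize_timecourse()`, which reports mean ± s.e.m. per condition and
timepoint and a two-sided Welch (unequal-variance) t-test against a named
control — the plain "t-test" of common figure legends, made explicit.

### Parameter defaults and calibration

The original high-content implementations of such pipelines rarely publish
their script parameters, so every threshold here is a config value
(`default_config()`), calibrated once against the synthetic stated world
(below) by parameter recovery, and not tuned thereafter:

| parameter | default | role |
|---|---|---|
| `spot_sigma_px` | 2 px | DoG band-pass scale for centrosome spots |
| `min_peak_snr` | 8 | spot gate, robust sds above background |
| `min_separation_px` | 5 px | duplicate-spot suppression |
| `crop_side_um` | 11 µm | peri-centrosomal crop side |
| `seed_quantile` | 0.99 | seed threshold quantile |
| `min_seed_px` | 3 px | minimum seed area |
| `contrast_stop_ratio` | 1.5 | region-growing admission ratio |
| `min_cilium_length_um` | 1 µm | ciliated call |

Two defaults deserve comment. `min_peak_snr = 8`: on a max-projected
Poisson stack the MAD underestimates the upper tail of the noise-maximum
distribution, and a gate of 5 sds admits spurious spots sitting just above
threshold while true spots are ~3× brighter; 8 sds sits in the middle of
that wide gap. `min_seed_px = 3`: a diffraction-limited proximal cluster
spans only ~2×2 px, and demanding 5 px made the seed fail entirely on long
axonemes whose own ridge pixels dominate the 0.99 quantile; 3 px does not
admit false positives because a noise seed cannot grow to the 1 µm
minimum length.

`pixel_size_um` has *no* default: the acquisition pixel size must come
from image metadata or the caller, never from an assumption.

### Numerical choices

* Skeletonization uses the Lam–Lee–Suen G123 two-subcycle parallel
  thinning. Naive parallel Zhang–Suen deletes both pixels of a 2×2 block
  simultaneously and therefore annihilates 2-px-wide diagonal bands —
  exactly the geometry of a thresholded thin filament — fragmenting
  skeletons and destroying length estimates.
* The longest geodesic is the weighted graph diameter of the skeleton
  (igraph shortest paths over all pixel pairs); skeletons are small enough
  that the exact computation is cheap.
* Thinning erodes roughly one pixel from each filament end while the
  thresholded mask extends slightly beyond the true tip; these biases
  largely cancel (residual bias ≈ +0.1 µm on the stated world).
* Crops at image borders are padded with the image median rather than
  zeros so the local-background estimate of step 5 is not dragged down.

## 2. Circular statistics and polarity

Orientation angles are directional (full 360°, the vectors have a defined
head), measured counterclockwise from +x in a y-up frame; image-storage
(y-down) coordinates are flipped exactly once, at `vector_angle()`. All
downstream statistics are base-independent.

The dispersion statistic is the circular standard deviation
$\mathrm{CSD} = \sqrt{-2\ln R}$ (in degrees), where
$R = \lVert \tfrac1n \sum_k (\cos\theta_k, \sin\theta_k)\rVert$ is the mean
resultant length. The angular-deviation variant $\sqrt{2(1-R)}$ is *not*
used. For a von Mises distribution with concentration $\kappa$ the
population value is $\sqrt{-2\ln(I_1(\kappa)/I_0(\kappa))}$
(`von_mises_csd()`), which the tests use as a closed-form oracle.

**Rotational polarity** (`rotational_polarity_summary()`) scores the
alignment of basal-rootlet orientation vectors *within* each cell: CSD per
cell, then mean ± s.d. of CSDs per condition. **Translational polarity**
(`translational_polarity_summary()`) scores tissue-level coordination of
basal-body patch displacement: the BBOV points from the cell outline's
uniform-area (shoelace) centroid to the unweighted pixel centroid of the
adaptively thresholded basal-body patch (`segment_basal_bodies()`,
`bbov()`); the CSD is taken across all BBOVs in a field of view and
conditions are characterised by mean ± s.d. of field CSDs.

Before pooling angles across cells or fields for a rose plot, each group
is re-centred: every angle has the group *circular* mean subtracted and
90° added, modulo 360 (`normalize_angles()`), so the pooled display shows
within-group dispersion only. The arithmetic mean would be ill-defined for
groups straddling 0°/360°; the circular mean is the only interpretation
that survives wraparound (groups with resultant length numerically zero
have no defined mean and are rejected).

Condition comparisons use a two-sided Mann–Whitney U test
(`mann_whitney()`): exact, by full enumeration of rank assignments, for
tie-free data with min(n) ≤ 8; otherwise the normal approximation with tie
and continuity corrections. Two-sidedness is defined symmetrically,
$p = P(|U - \mu_U| \ge |u_{obs} - \mu_U|)$.

Interpretation choices that the underlying protocols leave open, decided
here once: the normalization "average" is the circular mean (above); the
basal-body patch centroid is intensity-unweighted; when adaptive
thresholding yields several patches the largest connected component is
taken; the adaptive window is 51 px with offset 0 by default.

## 3. Bead flow

`link_tracks()` builds trajectories from per-frame detections by greedy
mutual-nearest-neighbour linking within `max_disp_um`, consecutive frames
only — a bead that disappears ends its track; reappearances start new
ones. Per track, **velocity** is total path length over elapsed time and
**tortuosity** is path length over the first-to-last chord (≥ 1 by the
triangle inequality). Velocity is deliberately path-based — speed and
straightness stay independent readouts; note that positional jitter
inflates path-based velocity, so the two must be read together. Tracks
with net displacement below `min_net_disp_um` (default 0.1 µm) are
excluded as non-motile; the motility filter of the emulated experiments is
unstated, so the floor is explicit and configurable. The default frame
interval is 1/37 s (the acquisition rate of the emulated movies, stated in
the protocol; a figure legend implies 30 fps — the interval is therefore
always an explicit argument, never inferred).

## 4. The synthetic stated world

`generate_cilia_field()` renders fields whose statistical structure
matches what the detector assumes, with ground truth for recovery tests:

* 600×600 px at 0.32 µm/px (~192 µm, around 100 cells per field, as in
  acquisitions designed "to capture at least 100 cells"), 10 z-planes.
* Centrosomes placed by dart-throwing with a minimum pairwise distance of
  the crop width (a `crowded` flag disables this for stress tests);
  Gaussian spots of σ 1.5 px, amplitude 200 counts.
* Exactly `round(fraction × n)` centrosomes carry an axoneme: a constant-
  width polyline of exact arc length (uniform 2–6 µm) with bounded
  per-step curvature (≤ 0.3 rad/µm), rendered 1 px wide, blurred by a
  σ 0.7 px kernel, amplitude 120 counts.
* Signal spreads across z with a Gaussian focal profile; the camera model
  is Poisson on signal + background (20 counts) plus Gaussian read noise
  (sd 5), clamped at zero.

This "moderate SNR" world is a choice, not a measurement — the emulated
studies never characterise their imaging noise — and it is what a green
recovery test does and does not establish: the pipeline recovers ciliation
fractions within ±5 points and lengths within 0.5 µm MAE *under this noise
model*. The generators do not emulate out-of-focal-plane axoneme
geometry, PSF physics, photobleaching, uneven illumination, or
cell-to-cell intensity variation; absolute performance on real microscopes
must be established against manual annotation.

The other generators are direct: `generate_polarity_cells()` draws von
Mises angles (Best–Fisher rejection sampler; κ = 0 degenerates to uniform)
around per-cell means with Gaussian between-cell spread;
`generate_bead_tracks()` produces drift-plus-diffusion trajectories;
`generate_lumier_table()` plants a known number of preys with both
replicate LIRs at or above 3. All generators are pure functions of
(parameters, seed).

## 5. File formats

Stacks travel as plain little-endian multi-page grayscale TIFF, channels
as consecutive page blocks, pixel size in the X/Y-resolution tags as
pixels-per-µm (no R TIFF package is required; the dialect round-trips
exactly at 64-bit and is readable by standard tools). Tables are CSV with
documented headers (`cell_id, base_x, base_y, tip_x, tip_y`;
`track_id, frame, x, y`; `prey, lir_rep1, lir_rep2`), ground truth is
JSON, and `write_results()` emits deterministic, sorted, 6-significant-
digit CSV so identical analyses yield byte-identical files. Configuration
is a flat `key: value` file mirroring `default_config()`, with unknown
keys rejected. A thin command-line launcher (`inst/scripts/ciliadyn`)
exposes `simulate`, `detect`, `timecourse`, `rotational`,
`translational`, `flow` and `lumier` subcommands over these formats.

## 6. Known limitations

* Lengths are 2D projections; a cilium tilted out of plane is
  foreshortened. The 11 µm crop bounds measurable length at ~5.5 µm from
  the centrosome.
* One cilium per centrosome; overlapping crops are processed
  independently, so two adjacent cilia can in principle contaminate each
  other's crops (visible as rare ±1 µm outliers at high density).
* The region-growing contrast rule is ratio-based; it is exactly invariant
  to intensity *scaling* but only approximately to large additive offsets
  (ciliated/non-ciliated calls are robust; raw lengths can shift
  slightly).
* The Mann–Whitney exact path requires tie-free data; tied small samples
  fall back to the corrected normal approximation.
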