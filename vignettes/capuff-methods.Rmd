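---
title: "Ca2+ puff detection and quantification: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ca2+ puff detection and quantification: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capuff)
```

## The measurement problem

IP₃ receptors (IP₃Rs) are intracellular Ca²⁺ channels that assemble into
small clusters anchored near the plasma membrane. When IP₃ is released
uniformly in a cell (by photolysis of a caged analogue), these clusters
produce Ca²⁺ *puffs*: localized fluorescence transients, a few hundred
milliseconds or less, visible in TIRF recordings of a Ca²⁺ indicator. Three
quantitative questions drive the analysis:

* **Where and when** do puffs occur, and at how many fixed *release sites*?
* **How many channels** open in each puff? The closure of a single channel
  during a puff's falling phase produces a quantal drop in fluorescence
  (the *unitary step*, ≈ 0.101 ΔF/F₀ under these recording conditions), so
  the peak amplitude divided by the unitary step estimates the number of
  active channels, N = ΔF/0.101.
* **Has the recording found all the sites?** Later puffs are ever less
  likely to reveal a previously unseen site; the per-interval count of new
  sites declines mono-exponentially, and its half-time converts a finite
  recording into an expected *coverage*, 1 − 2^(−window/t₁/₂).

`capuff` implements this chain end to end and pairs it with a synthetic
movie generator whose ground truth makes every stage testable.

## Normalization model

Each pixel's baseline is estimated from the last `n_baseline_frames`
(default 500, ≈ 2.7 s at 188 Hz) before the flash: the mean F₀ and the
population standard deviation. The analysed stack is

$$z = \frac{(F/F_0) - 1}{\sigma},$$

with σ the baseline s.d. *expressed in F/F₀ units* (`sd_map / f0_map`).
This makes z a dimensionless, scale-free quantity — a z-score of the
relative fluorescence change — so the 0.8 critical value means the same
thing whatever the camera gain. Expressing σ in camera units instead would
tie the threshold to the absolute intensity; the F/F₀ reading was chosen
for that reason. Two guards keep z finite and honest:

* `sd_floor` (default 10⁻³ F/F₀ units) bounds σ from below so dead or
  saturated pixels cannot produce infinite z; on noise-free synthetic
  input this floor is what carries the signal into z.
* Pixels with F₀ ≤ 0 are masked (z = 0) and counted in a reported mask
  total.

The z stack is then Gaussian-filtered spatially (σ = 1 px by default,
`gaussian_sigma_px`), one frame at a time — no temporal filtering, so event
timing is not smeared. With `gaussian_sigma_px = 0` the arithmetic is
returned exactly, which the tests use as an oracle.

## Detection

Supra-threshold voxels (z > `critical_value`, default 0.8) in the
post-flash frames are grouped into 26-connected components in (x, y, t).
Two events at one location separated by fully sub-threshold frames are
therefore distinct — which is what per-cell puff frequencies count.
Components are kept only if their largest single-frame footprint is at
least `min_px` (2) pixels and their extent at least `min_frames` (2)
frames. The brightest voxel (ties: earliest frame, then smallest row,
column) fixes the measurement ROI — 1.76 µm square, 11 px at 160 nm/px,
clipped and flagged at field edges — and the event trace is the per-frame
ROI mean of the *raw* F/F₀, not the filtered z. The window keeps
`pad_frames` (100) frames of context on each side.

The 0.8 threshold is deliberately permissive: on the normalized scale the
pixel noise itself is of order 1 before filtering, so noisy recordings
yield many small noise components alongside the true puffs, and
`min_px`/`min_frames` only reject the smallest of them. The package leaves
this trade-off exposed (`run_benchmark()` sweeps it; detection recall and
localization are insensitive to thresholds anywhere in 0.8–2 on synthetic
data because rendered puffs reach z far above either value). Event counts
at the default threshold on noisy data should be read accordingly, or the
threshold raised.

Sub-pixel localization fits an isotropic 2-D Gaussian plus offset to the
ROI of the peak z frame (`minpack.lm::nlsLM`). A fit that fails, has
non-positive amplitude, or lands outside the ROI falls back to the
brightest-pixel centre with a flag — degenerate inputs (flat ROIs) take
this path rather than erroring.

A *global rise* — the signal invading the whole cell — is declared at the
first frame where ≥ 50% of unmasked pixels exceed z = 0.8 and stay there
for ≥ 0.5 s. Events starting at or after this frame are dropped and the
effective recording is truncated there, because discrete puffs cannot be
scored on top of a global elevation.

## Per-puff metrics

* **Reference.** F_pre pools the ROI trace over the 10 frames immediately
  before the event onset and the 10 after its end (one-sided, flagged, when
  the window clips a side). ΔF = F_peak − F_pre, with F_peak the trace
  maximum within the supra-threshold extent.
* **Kinetics.** Rise = time from the last upward crossing of
  F_pre + 0.2 ΔF to the peak; decay = peak to the first downward crossing
  of the same level; duration = the span between the 50%-level crossings
  bracketing the peak. Crossings are linearly interpolated between frames;
  the peak itself is a sample, not a crossing, so there is no interpolation
  at the top (sub-frame values are therefore possible and valid). Traces
  that never return below a level inside the window are flagged censored
  and report the available extent. With several peaks in a window the
  highest is measured and the event flagged.
* **Unitary steps.** The falling phase is segmented into plateaus by
  binary segmentation: a segment splits where the within-plateau sum of
  squares drops by more than a penalty of 3σ̂² log n, with σ̂ the MAD of
  the first differences divided by √2. The MAD-based σ̂ is zero on a
  noise-free staircase, so the penalty collapses to a tiny floor and the
  segmentation returns exactly the true steps; under noise the BIC-like
  scaling suppresses spurious splits. Plateaus shorter than 2 frames merge
  into the neighbour with the closer mean, and non-decreasing neighbours
  merge, so the result is a strictly descending staircase. The per-puff
  unitary step is the median of the consecutive drops; pooling across
  puffs (mean ± s.e.m.) reproduces the 0.101 calibration on synthetic
  staircases. Any consistent estimator would do here — steps in real data
  have historically been read off by eye — and the changepoint route was
  chosen for reproducibility.
* **Channel count.** N = ΔF/`unitary_dF` (default 0.101), reported both
  continuous and rounded (`max(1, round(N))`; zero amplitude reports 0,
  flagged) for histograms.

## Sites and discovery saturation

Puffs are assigned to sites greedily in chronological order: join the
nearest existing site if its running-mean centroid is within `sep_um`
(0.96 µm), else found a new site. The separation rule is the field's
operational definition of "different sites"; the *algorithm* around it is
a design choice, since chains of events 0.9 µm apart have no unambiguous
partition. Greedy-with-running-centroid was chosen because it is
order-stable for well-separated sites, never lets a site's centroid drift
more than the localization noise, and matches single-linkage clustering
exactly in the two provable regimes (all events pairwise farther than
`sep_um`: one site per event; all events within `sep_um`/2 of a point: one
site). On chain configurations greedy splits where single linkage would
merge; the tests exercise both regimes exhaustively rather than pretending
the chain case has a ground truth.

New-site counts per `bin_s` interval are fitted with
c(t) = A·2^(−t/t₁/₂) by least squares at the bin centres (zero trailing
bins included; Poisson weighting is available but not the default, because
counts are small and the unweighted fit reproduces exact geometric
sequences exactly). Non-decaying counts are flagged and reported with an
infinite half-time rather than a spurious finite one. Coverage follows as
100·(1 − 2^(−w/t₁/₂)): 93.75% at four half-lives, 99.3% for a 40-s window
at t₁/₂ = 5.53 s, 96.8% for a 10-s window at t₁/₂ = 2.01 s.

## The synthetic movie generator

The generator emulates the acquisition geometry the analysis was built
for: 120 × 120 px at 160 nm/px, 5.32 ms frames, 42.7 s with the flash at
2.7 s. Its event model:

* Sites are placed uniformly, pairwise ≥ `site_min_sep_um` apart and
  ≥ `edge_margin_um` (1 µm) from the field edge — the margin keeps every
  site's 11 × 11 px measurement ROI inside the field, without which the
  quantal calibration below would be violated at edges.
* Per site, puff onsets are a homogeneous Poisson process at
  `puff_rate_hz`, starting an exponential latency (`latency_scale_s`)
  after the flash. Channel counts are drawn from a Poisson truncated to
  1..10 with its rate solved so the truncated mean is 2.8, matching the
  observation that most puffs involve fewer than seven channels with a
  mean near 2.8.
* All channels are open at the peak; the summed signal ramps linearly over
  `rise_ms` (25 ms, so the measured 20→100% rise is ≈ 20 ms). After the
  peak, channels close independently after exponential dwells
  (`open_dwell_ms`, 15 ms), producing the descending staircase the step
  estimator consumes. The dwell clock starts at the *first sampled frame*
  at or after the end of the ramp, not at the continuous peak instant:
  this guarantees the sampled trace contains at least one full-amplitude
  frame, so a noise-free rendering is exactly quantal. Without this
  anchoring, a channel closing within a fraction of a frame of the peak
  would make the true channel count unrecoverable from any sampled trace.
* Each open channel adds an isotropic 2-D Gaussian (`psf_sigma_um`,
  0.15 µm) scaled so that its **mean over the 11 × 11 px ROI at the site
  equals `unitary_step_dF` × `baseline_f0`**. The quantal amplitude is
  thus defined in exactly the units the analysis measures (ROI-averaged
  ΔF/F₀), which is what makes N = ΔF/0.101 recover the simulated channel
  count identically. Parameterizing the *peak* pixel instead would leave
  the ROI average dependent on the PSF width and break that
  correspondence.
* Noise is additive Gaussian with s.d. 2% of the baseline by default; a
  Poisson shot-noise model (`gain`) is available. An optional global rise
  is a circular plateau wave from a random pixel; only its onset time is
  part of the ground truth.
* `simulate_movie()` seeds R's RNG from the config, so a config is a
  complete, bit-reproducible description of a dataset.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: Ca²⁺ and indicator diffusion (real puffs
spread over a micron or more, not an optical PSF), indicator binding
kinetics and saturation, EGTA buffering chemistry, baseline drift and
bleaching, axial PSF structure, and cell boundaries (there is no
extracellular region, so background subtraction is exercised on
constructed fixtures instead). Recovery rates on synthetic movies are
best-case figures for the algorithmic chain, not for microscopy.

## Numerical choices and scales

* Frame i is sampled at (i − 1)·dt; physical coordinates are pixel
  centres, x = (col − 0.5)·pixel size; reported times are relative to the
  flash. Frame counts follow round(duration/dt) — e.g. 42.7 s at 5.32 ms
  is 8026 frames.
* Peak ties break to the earliest frame, then smallest (row, column);
  event IDs are chronological by onset.
* The discovery fit seeds `nlsLM` from a log-linear regression on the
  positive counts; a non-negative log-slope short-circuits to the
  non-decaying flag.
* Tests and the validation suite run on reduced problem sizes chosen to
  exercise every code path at full fidelity: movies of 1 000–3 000 frames
  (4–15 s) with 140–150 baseline frames instead of 40 s/500, 10–30 sites,
  and batches of 200+ rendered puffs for the quantal-counting checks.
  These sizes are the package's choice of test scale; nothing in the
  algorithms depends on them.

## Known limitations

* At the default 0.8 critical value, noisy recordings produce abundant
  small false events; raw event counts need either a stricter threshold or
  downstream filtering (amplitude, size) before biological interpretation.
* Overlapping puffs at one site within a window are not deconvolved (the
  merged component is reported as one event, flagged if multi-peaked).
* Amplitudes are not corrected for indicator kinetics; channel counts
  inherit the unitary-step calibration and its ±0.002 uncertainty.
* The greedy site assignment is order-dependent on chain configurations,
  as any single-pass rule must be; the single-linkage cross-check is the
  guard against silent pathologies.
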