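# capuff

Detection and quantal analysis of Ca²⁺ puffs in TIRF microscopy image
stacks.

Ca²⁺ puffs are brief, localized Ca²⁺ release events produced by the
near-simultaneous opening of a few clustered IP₃ receptors (IP₃Rs) on the
endoplasmic reticulum. In a typical experiment, cells loaded with a
fluorescent Ca²⁺ indicator and a caged IP₃ analogue are imaged by total
internal reflection fluorescence (TIRF) microscopy at high frame rates
(e.g. 120 × 120 px at 160 nm/px, 188 Hz); a UV flash photo-releases IP₃ and
puffs appear at fixed subcellular release sites until the signal propagates
into a global Ca²⁺ rise. `capuff` turns such recordings into per-puff,
per-site and per-cell statistics, and ships a synthetic-movie generator
with ground truth so that every stage of the analysis can be validated.

## What the pipeline computes

1. **Normalization.** Background-corrected frames are converted to
   per-pixel z-like units: the last 500 pre-flash frames give each pixel a
   baseline mean F₀ and standard deviation, and the stack becomes
   [(F/F₀) − 1]/s.d. (s.d. in F/F₀ units), spatially Gaussian-filtered.
2. **Detection.** Voxels exceeding a critical value (0.8) are clustered
   into 26-connected components in (x, y, t); each component is one puff.
   The event window is the component extent ± 100 frames, and the event
   trace is the mean F/F₀ over a 1.76 × 1.76 µm ROI centred on the
   brightest pixel. A 2-D Gaussian fit refines the centroid to sub-pixel
   precision.
3. **Per-puff metrics.** Amplitude ΔF = F_peak − F_pre (F_pre averaged
   over the 10 frames before and after the event); 20→100% rise time,
   100→20% decay time and duration at half-maximal amplitude, with
   linearly interpolated crossings; changepoint segmentation of the falling
   phase into the stepwise closures of individual channels; and the active
   channel count **N = ΔF / 0.101**, where 0.101 is the unitary ΔF/F₀ step
   of a single IP₃R in these recording conditions.
4. **Sites and saturation.** Puffs whose centroids lie within 0.96 µm are
   assigned to the same fixed release site (greedy, chronological, running
   centroids). New-site discovery declines mono-exponentially as a
   recording proceeds; fitting the half-time t₁/₂ of that decline gives the
   expected fraction of all sites seen in a window of length w:
   coverage = 1 − 2^(−w/t₁/₂).

## Worked example

Simulate a 6-s recording with 10 release sites and analyse it:

```r
library(capuff)

cfg <- sim_config(n_sites = 10, duration_s = 6, flash_time_s = 1,
                  site_min_sep_um = 2, puff_rate_hz = 0.4,
                  latency_scale_s = 0.2, seed = 42)
sim <- simulate_movie(cfg)
sim$movie
#> ca_movie: 120 x 120 px, 1128 frames (6.00 s at 187.97 Hz), 160 nm/px, flash at frame 189

res <- analyze_movie(sim$movie, analysis_params(critical_value = 2,
                                                n_baseline_frames = 150))
res
#> puff_analysis: 20 puffs at 8 sites; latency 0.16 s, frequency 4.00 Hz over 5.0 s

head(events_table(res$events)[, c("event_id", "site_id", "t_peak_s",
                                  "amplitude_dF", "rise_ms", "decay_ms",
                                  "n_channels_round")])
#>   event_id site_id t_peak_s amplitude_dF rise_ms decay_ms n_channels_round
#> 1        1       1    0.192        0.301   24.7      9.05                3
#> 2        2       2    0.340        0.204   24.5     24.46                2
#> 3        3       3    0.809        0.404   19.8     24.55                4
#> 4        4       4    0.990        0.605   23.1     20.75                6
#> 5        5       5    1.692        0.199   21.3     29.84                2
#> 6        6       3    1.910        0.305   23.0      9.04                3
```

Each row is one puff: when it peaked (seconds after the flash), its
ROI-averaged amplitude in ΔF/F₀ units, its kinetics in ms, and the number
of active channels implied by the 0.101 unitary step — e.g. event 4, with
ΔF = 0.605, was produced by about six open IP₃Rs. Comparing against the
simulator's ground truth with `match_events(sim$truth, res$events)` shows
every simulated puff recovered with the correct channel count here.

The default `critical_value = 0.8` is deliberately permissive and, on noisy
recordings, also picks up small noise clusters (they are cheap to discard
downstream but inflate raw event counts); the example tightens it to 2.
`run_benchmark()` quantifies the trade-off, and recall stays at 100 % here
for thresholds anywhere in 0.8–2.

How saturated is a recording? With the slowest plausible discovery
half-time:

```r
coverage_fraction(5.53, 40)
#> $n_half_lives
#> [1] 7.233273
#> $coverage_percent
#> [1] 99.33539
```

i.e. a 40-s recording spans 7.2 half-lives of site discovery and is
expected to reveal 99.3 % of all release sites.

A command-line front end for `simulate` / `analyze` / `benchmark` lives at
`inst/cli/capuff.R`, driven by a single YAML config
(see `?pipeline_config`).

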