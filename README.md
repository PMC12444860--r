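# phagopulse

Quantification of pulsatile reporter recruitment on neutrophil phagosomes in
3D time-lapse fluorescence movies.

## The problem

When a neutrophil engulfs a bacterium, Class I PI3-kinases deposit
PIP3/PI(3,4)P2 on the nascent phagosome membrane; a fluorescent
pleckstrin-homology reporter (e.g. PHAkt-eGFP) therefore surges onto the
membrane at cup closure, fades as the lipid is turned over, and — on a
subset of phagosomes — re-surges in discrete *pulses*. Pulses mark
phagosomes that transiently re-open and re-close, i.e. phagosomes that never
fully sealed, with consequences for acidification, ROS exposure, and
exchange with the extracellular space (fluid-phase dyes such as Lucifer
Yellow enter these "leaky" phagosomes).

phagopulse turns that observation into a tested, reusable pipeline for
anyone analysing two-channel (membrane reporter + stained prey) confocal
z-stack time lapses of phagocytosis:

* **Segmentation** — 3×3×3 box smoothing, two-level (cell / phagosome)
  thresholding of the reporter channel and single-level thresholding of the
  prey channel, 3D connected components on the anisotropic voxel grid,
  inside/outside bacterial volume ratios.
* **Tracking** — TrackMate XML import, or a built-in frame-to-frame linker
  (exact Hungarian assignment on Euclidean distance in µm, gap closing).
* **Ring fluorescence** — for each tracked phagosome, the intensities of all
  pixels within a ring around the centroid are extracted on the nearest
  z-plane and binned into 21 angular directions, giving a frames × 21
  kymograph plus the ring mean per frame; traces are low-pass filtered,
  min–max normalised per track to [0, 1], aligned at time zero
  (engulfment), and averaged as mean ± s.d. across tracks.
* **Pulse calling** — a deterministic detector on the normalised ring-mean
  trace: the closure surge (until the trace first falls below a fade
  threshold, default 0.4) is excluded, then local maxima with topographic
  prominence ≥ 0.2 and separation ≥ 3 frames are called as pulses; per
  phagosome it reports the pulsing flag, pulse count, and first-pulse
  latency in minutes.
* **Cohort statistics** — per-neutrophil pulsing fractions (mean ± s.d. over
  neutrophils), fraction of neutrophils with ≥ 1 pulsing phagosome,
  latency summaries, Spearman burden correlations, relative pHrodo/CellROX
  change versus baseline, dye-accumulation classification
  (background + 3·s.d. threshold), peri-bacterial 0.5 µm shell ratios, and
  exact binomial confidence intervals for event tallies.
* **Synthetic ground truth** — a 4D movie generator that renders neutrophils
  with 1–25 bacteria-bearing phagosomes (spherical membrane shells with a
  Gaussian cross-section, solid prey spheres, pH-dependent prey brightness,
  azimuthal pore sectors during open intervals, camera noise) against a
  complete event log, so every stage is testable without external data.

Tracks, profiles, calls and summaries are tibbles throughout; results plug
into dplyr/ggplot2 directly, and `tidy()` / `glance()` methods are provided.

## Worked example

Simulate a 12-neutrophil cohort at the packaged reference conditions
(per-phagosome pulse probability 12.4 %, first-pulse latency
10.5 ± 12.49 min, dye-leak probability 20.1 %, SNR 8) and run the full
pipeline:

```r
library(phagopulse)

cfg <- cohort_defaults(n_neutrophils = 12, seed = 42)
cfg$out_dir <- "phagopulse_out"
res <- run_pipeline(cfg)
print(res)
#> <pp_pipeline_result> 32 track(s) across 12 FOV(s); outputs in phagopulse_out
#> <pp_pulsing_summary> 12 neutrophils, 32 phagosomes
#>   pulsing phagosomes per neutrophil: 18.3 +/- 38.6 %
#>   neutrophils with >=1 pulsing phagosome: 25.0 %
#>   first-pulse latency: 6.5 +/- 1.5 min
```

The 32 tracked phagosomes across 12 neutrophils give a mean per-neutrophil
pulsing fraction of 18.3 % (each neutrophil weighted equally; at this small
cohort size the binomial noise around the generative 12.4 % is large), a
quarter of neutrophils carry at least one pulsing phagosome, and the first
pulses in this draw started 6.5 ± 1.5 min after engulfment. `phagopulse_out/`
now holds `tracks.csv`, per-track kymographs, `calls.csv`/`pulses.csv`,
`aligned_mean_sd.csv`, `summary.json` and a run manifest; re-running with the
same config and seed reproduces them bit-identically.

Event tallies (categorical outcomes scored on time-lapses) get exact
binomial confidence intervals:

```r
tally_statistics(read_event_tally())
#> # A tibble: 6 x 6
#>   name                        numerator denominator   pct ci_lo_pct ci_hi_pct
#> 1 reopening_during_pulse             27         138  19.6   13.3         27.2
#> 2 full_release_during_pulse           7         138   5.1    2.06        10.2
#> 3 recaptured_same_neutrophil         29          31  94     78.6         99.2
#> 4 tubule_neck_during_pulse            3          31   9.7    2.04        25.8
#> ...
```

Plotting: `plot_kymograph(series)` (frames × 21 angular sectors),
`plot_trace(series)` (normalised ring mean with detected pulses),
`plot_aligned(align_and_average(series_list))` (cohort mean ± s.d.), and
`autoplot()` on summaries.

A thin command-line wrapper lives at `inst/cli/phagopulse.R`
(`simulate`, `run`, `report` subcommands over the same functions).

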