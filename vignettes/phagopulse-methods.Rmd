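---
title: "phagopulse: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phagopulse: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(phagopulse)
```

This vignette is the package's own account of the science it implements:
the quantification model, the synthetic ground-truth generator, the
numerical conventions, and the places where the design was genuinely open
and a choice had to be made.

## 1. The quantification model

The object of study is the recruitment of a lipid-binding fluorescent
reporter (a PH-domain fusion that binds PIP3/PI(3,4)P2, read out as Class I
PI3K activity) to the membrane of a phagosome inside a neutrophil, imaged as
two-channel confocal z-stacks over 30 min to 3 h. The canonical trace is:
minimal signal during cup formation, a strong *closure surge* over the whole
phagosome membrane when the cup seals, an exponential-looking fade, and — on
a subset of phagosomes — repeated transient re-surges (*pulses*) that
coincide with the phagosome transiently re-opening and re-closing.

The pipeline measures this as **ring fluorescence**: for each tracked
phagosome and frame, the z-slice nearest the centroid is selected and all
pixels within a ring around the (sub-pixel) centroid are extracted. Pixel
membership uses the exact Euclidean distance from the unrounded centre.
Pixels are binned into 21 equal angular sectors (angle measured with the
image y-axis pointing down, sector k covering [2*pi*(k-1)/21,
2*pi*k/21)), yielding a frames-by-21 kymograph; the *ring mean* is the mean
over all ring pixels (not the mean of sector means, which would weight
sparse sectors up). Per track the values are then low-pass filtered along
time, min-max normalised to [0, 1], shifted so every track starts at time
zero (engulfment), and averaged across tracks as mean +/- s.d. per frame,
with ragged track ends handled by counting only contributing tracks.

"All pixels within a ring of radius r" admits two readings, and the
original description does not disambiguate them, so both are implemented:
the default is an **annulus** of half-width 1.5 px centred on the ring
radius (it captures the membrane the reporter decorates and excludes the
dark lumen); a filled **disc** mode is retained for parity checks. Likewise
the low-pass filter is unspecified upstream; it is realised here as a
centred moving average (default window 5 frames) with mirrored ends, the
least-committal linear smoother, and is config-exposed rather than asserted
as unique truth.

The default ring radius is 6 px, the field's convention at typical
40x/EM-CCD pixel sizes. The *packaged reference configuration* uses 3 px
instead, because there the xy pixel is 0.33 um and the rendered membrane
radius is 1 um: the ring must sit on the membrane in pixels, and 6 px at
0.33 um/px would miss a 1 um shell entirely. Users analysing real data
should set the radius to their membrane radius in pixels.

## 2. Pulse detection

Upstream, a pulse is defined only verbally (a brief, high-amplitude
re-surge of recruitment); the detector makes it operational and
deterministic:

1. The trace is the per-track ring mean rescaled to its own [0, 1] span.
   (The joint sector/ring-mean normalisation keeps the kymograph and the
   trace on one scale, but it leaves the ring-mean trace compressed — its
   maximum is below the brightest sector's maximum — so thresholds defined
   on the trace must use the trace's own span; the rescale is idempotent.)
2. The closure surge is excluded: everything before the trace first falls
   below `fade_threshold` (default 0.4) is out of bounds, so the surge is
   never counted as a pulse.
3. Strict local maxima are suppressed to a minimum peak-to-peak separation
   (default 3 frames), keeping the higher peak and breaking ties toward the
   earlier one. Suppression runs **before** the prominence filter: this
   ordering makes the pulse count provably monotone non-increasing in
   `prominence_min` (filtering first can open slots for two smaller nearby
   peaks and break monotonicity).
4. Remaining maxima with topographic prominence >= `prominence_min`
   (default 0.2) are the pulses. Onset and end are the frames where the
   trace last/first crosses half the prominence below the peak — the rise
   and fall flanks — rather than the minima of the flat valley between
   pulses, whose exact position is set by noise; first-pulse latency is
   onset minus engulfment, converted to minutes via the frame interval.

The defaults (0.4 / 0.2 / 3) were fixed with the operating-point sweep
harness (`sweep_operating_point()`) on the noise-free and SNR 8 reference
cohorts, where they achieve F1 = 1 and F1 >= 0.9 respectively (the
acceptance suite recomputes both), and are recorded in the packaged
configuration. Tracks with fewer than 10 frames after the fade are flagged
low-confidence rather than dropped.

## 3. Segmentation and tracking

All channels are smoothed with a 3x3x3 voxel box kernel (three separable
running-mean passes; borders by symmetric reflection, so a constant volume
is a fixed point). The reporter channel is thresholded at two levels — low
for the whole neutrophil, high for the phagosome — and the prey channel at
one level; connected components use 26-connectivity by default
(6-connectivity by config) on the native anisotropic voxel grid, with no
resampling; all reported volumes convert voxel counts through the physical
voxel size. Components smaller than 5 voxels are discarded as noise specks.
Because the two reporter masks are nested thresholds of one volume, every
phagosome voxel lies inside a cell component by construction. The
inside/outside bacterial volume ratio partitions each prey component by the
cell mask; inside + outside equals the total exactly, and a fully-internal
component is flagged with an infinite ratio rather than silently divided.

Level selection, when not fixed in the config, is automatic. The plain
default is 3-class multi-level Otsu for the reporter and single Otsu for the
prey, which is what `auto_levels()` does on histograms whose classes have
comparable mass. Full fields of view are different: >90 % of voxels are
background, and a global (multi-)Otsu then splits the background mode
instead of separating signal. The pipeline therefore uses a hierarchical
variant (`robust = TRUE`): low = Otsu of the volume, high = Otsu of the
supra-low intensities, and for spot-like prey a noise floor (median +
4 * MAD) followed by Otsu of the supra-floor voxels
(`detection_level()`). For the same reason levels are picked on the *last*
frame of each movie rather than the first: the generator's movies (and any
acquisition started before engulfment) contain no phagosome signal in frame
1, so a first-frame histogram is meaningless. Because prey brightness is
pH-modulated and dips mid-movie, the tracking threshold is the minimum of
the detection levels found at 1/3, 2/3 and the end of the movie. Per-frame
level recomputation remains available via the config.

Tracking runs on the **prey** channel, not the reporter: bacteria stay
bright (the pH reporter dims but never vanishes) while the membrane
reporter fades to its plateau between pulses, so prey-based detections keep
phagosome identity alive for the whole movie. Frame-to-frame association is
a true optimal one-to-one assignment (an O(n^3) Hungarian solver in
compiled code) on Euclidean distance in micrometres, honouring the
anisotropy; links beyond `max_displacement` (default 2 um/frame — phagosome
motion at these frame rates is slow) are forbidden, unmatched detections
start new tracks, tracks unseen for more than `max_gap` (default 2) frames
terminate, and closed gaps are linearly interpolated and flagged. TrackMate
XML import is provided as the drop-in alternative, preserving track IDs and
requiring the file's own calibration. Phagosome fusion is out of scope: a
fusion appears as one track ending and another continuing, not as a merge.

## 4. The synthetic-data generator

The generator exists so that every downstream stage can be validated
against known truth; its defaults *are* the reference study conditions:

| parameter | default | unit | basis |
|---|---|---|---|
| per-phagosome pulse probability | 0.124 | — | in vivo estimate |
| neutrophils with >=1 pulsing phagosome | emergent | — | checked, not set |
| pulses per pulsing phagosome | 1 + Pois(3), trunc. [1, 18] | — | mode near 4, max 18 observed |
| first-pulse latency | lognormal, mean 10.5, s.d. 12.49, floor 5 | min | in vivo estimate; floor: a pulse is re-recruitment *after* the fade |
| dye-leak probability | 0.201 | — | human-neutrophil estimate |
| phagosomes per neutrophil | 1 + Geom, trunc. [1, 25] | — | range observed; mean 3 chosen as typical burden |
| z step | 1.5 | um | acquisition convention |
| xy pixel | 0.33 | um | documented convention (unstated upstream), overridable |
| frame interval | 30 | s | typical acquisition |
| movie length | 120 frames (60 min) | — | phagosomes followed for ~72 min on average |
| SNR (surge amplitude / read noise s.d.) | 8 | — | reference noise level |

Each field of view holds one neutrophil (a cytoplasmic sphere on the
reporter channel, radius grown adaptively to fit the drawn phagosome
count). Phagosomes are membrane shells of radius 1 um with a Gaussian
cross-section (sigma 0.25 um) and a solid 0.5 um prey sphere inside.
Objects are rendered with a mild axial elongation (z PSF scale 0.5 um):
point-sampling a 0.5 um object onto 1.5 um z-planes would make it vanish
whenever it sits between planes, whereas a real camera integrates the axial
PSF and slab. Reporter amplitude follows a linear 2-frame rise to the surge,
exponential fade (tau 90 s) to a 25 % plateau, and per pulse a 2-frame rise
of amplitude 0.8 and 90 s decay. No pulse waveform is reported upstream;
these are conventions chosen for detectability control, with successive
pulse onsets at least 10 frames (5 min) apart so that events remain
resolvable under the default 5-frame low-pass at 30 s frames. Open
intervals (probability 0.196 per pulse, 3 frames) cut a 60 degree azimuthal
sector of the shell to background, enabling angular-asymmetry tests; leaky
phagosomes (unsealed) carry an open interval over their whole lifetime.
Prey brightness follows a pH map: bright at tissue pH, dimming toward 0.6
while a sealed phagosome is alkaline, staying near 0.95 on
pulsing/leaky phagosomes, 1.0 during open intervals — which is what makes
the relative-change contrast between pulsing and non-pulsing classes, and
the dye experiment, reproducible in silico. Noise is additive Gaussian read
noise (s.d. = surge amplitude / SNR) plus a signal-proportional
(Poisson-like) variance term. Release/recapture outcomes are sampled at the
observed 29:1:1 proportions but are log-level annotations only: prey voxels
are not animated out of the cell, so the rendered-object conservation
invariant holds at every frame.

Placement enforces a minimum *in-plane* (xy) centre separation of 2.5 um
rather than a full 3D separation: with 1.5 um z-steps and 3x3x3 smoothing,
two objects separated only in z merge unless they are ~6 um apart, which
would make 25-phagosome neutrophils unplaceable; in-plane separation is
what actually guarantees segmentability at the reference SNR. Seeds are
derived per field of view from the config seed, so cohorts can be generated
FOV-by-FOV (streamed by the pipeline, which never holds more than one movie
in memory) while remaining bit-identical to `simulate_cohort()`.

**What the generator does not emulate:** photobleaching, chromatic shift,
cell deformation and chemotaxis, phagosome fusion, prey expulsion
trajectories, depth-dependent scattering, and any negative dependence of
pulsing on bacterial burden (the observed negative burden correlation is
*not* built in; `burden_correlation()` is validated against oracles, not
against an emulated effect). Passing the synthetic suites therefore
demonstrates correctness of the measurement pipeline, not robustness to
every property of real tissue movies.

## 5. Numerical conventions and degenerate inputs

* Axis convention: arrays are stored (y, x, z, channel, time); voxel indices
  are 1-based in R, physical coordinates in um with the origin at the first
  voxel's centre; time zero of an aligned track is its first frame.
* Movies are written as multi-page 32-bit-float TIFF in TCZYX page order
  with an OME-style XML sidecar holding axes, channel names, physical voxel
  sizes, frame interval and the affine intensity scale (float TIFF storage
  here requires [0, 1] data); reading restores intensities to float32
  precision. A TIFF without a sidecar is refused unless calibration is
  supplied explicitly — pixel units are never assumed silently.
* Min-max normalisation of a constant track maps to zero and sets a flag
  instead of dividing by zero; empty angular sectors (possible only for
  very small rings) are filled by circular linear interpolation and
  flagged; rings clipped by the image border are flagged; a ring with no
  pixels is a degenerate-geometry error.
* The Spearman correlation uses midranks and a two-sided t approximation;
  |rho| = 1 reports p = 0; a constant column warns and returns NA.
* Dunn post-hoc z tests use the joint-rank variance with tie correction and
  Holm adjustment (the upstream analysis names only "multiple
  comparisons"); t-tests on groups of n < 2 are flagged, not computed.
* Per-neutrophil versus pooled weighting is genuinely ambiguous upstream;
  both are emitted (`mean_pct_pulsing` weights neutrophils equally — the
  primary figure convention — `pooled_pct_pulsing` pools phagosomes).
* The dye classifier threshold is background mean + 3 s.d. of the pre-dye
  mask intensities (the instrument-software rule is unstated); `k` and a
  fixed threshold are config overrides. Dye is measured within prey masks
  clipped to the cell interior, mirroring the "bacteria inside neutrophils"
  protocol and keeping the mask off the extracellular dye pool.
* All file writes are atomic (temp file + rename); the run manifest records
  the config hash, seed and package version, and contains no timestamps so
  that reruns are bit-identical.

## 6. Validation scales

The test suite validates against brute-force oracles (pixel-scan ring
statistics at 1e-9 relative tolerance, triple-loop convolution, exhaustive
assignment enumeration, rank-then-Pearson, flood fill, distance-transform
shells) and against generator ground truth. Cohort-level checks run at desk
scale, chosen to keep the default suite fast while leaving the binomial
error bars meaningful: 60 neutrophils for the full-pipeline pulsing-fraction
recovery, 100 tracks of 2 h movies for latency, 800 (3 x 2000 in the
dedicated invariant test) phagosomes for the dye classifier, and ~200
phagosomes at SNR 8 for the detector operating point. The acceptance script
scales these to 100 neutrophils / 200 tracks / 2000 phagosomes. All
recoveries are asserted within three standard errors of the generative
values; none of the numbers quoted anywhere in the documentation are stated
without being recomputed by the tests or the acceptance script.

## 7. Known limitations

* Ring profiling is 2D on one z-plane (optionally a 3-slice maximum
  projection); no 3D spherical profiling.
* Touching phagosomes are not split (no watershed); the generator's
  separation constraint sidesteps this, real data may not.
* The pulse detector's thresholds are conventions validated against
  synthetic ground truth; the original human-in-the-loop criterion for
  "intense" is unrecoverable.
* TrackMate ingestion covers Spots/Tracks/ImageData; exotic TrackMate
  features (splitting, merging) are out of scope, as is full LAP tracking.
* Proprietary microscope formats are not read; convert to TIFF first.
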