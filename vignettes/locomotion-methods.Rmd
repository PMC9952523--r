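---
title: "Measuring broiler locomotion on a gait-scoring platform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring broiler locomotion on a gait-scoring platform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`broilergait` turns raw platform recordings — a top-view keypoint track
of a bird's back, optionally a depth stream — into per-bird locomotion
metrics and gait-score group comparisons. This vignette describes the
measurement model, the parameters that matter, the choices made where
the procedure was genuinely open, and what the synthetic validation
does and does not establish about real recordings.

## The assay and its coordinate frames

A bird walks (or refuses to walk) along a 1.8 m x 0.46 m platform with
a 1.5 m walking space, recorded from ~2.39 m above by a 30 Hz video
camera and a 10 Hz depth camera. Analysis happens in a Cartesian frame
on the platform plane: `x` along the long (forward) axis in mm, `y`
lateral, `z` height above the platform. Image pixel coordinates are
0-based with the origin at the top-left corner and `v` increasing
downwards, so the conversion is `x = (u - u0)/s`, `y = (v0 - v)/s` with
`s` the pixel-to-distance factor (0.62 px/mm by default, assumed
isotropic because nothing in the acquisition geometry suggests
direction-dependent scale) and `(u0, v0)` the start-line corner of the
rectified crop. Pixel windows are half-open; these conventions are
fixed so geometric tests can be bit-exact.

## Rectification

The platform rarely lies axis-aligned in the frame, so each image is
rotated until bird movement runs horizontally:

1. **Canny edge detection** (Gaussian blur `sigma = 2` px, hysteresis
   thresholds 0.1 and 0.3 of the peak gradient magnitude). The
   thresholds are fractions of the observed dynamic range, making them
   exposure-invariant; all three are configurable.
2. **Hough transform** over `rho = x cos(theta) + y sin(theta)` with a
   1 px x 1 degree accumulator grid, `theta` in `[0, 180)`. The default
   grid matches the 1-degree recovery tolerance the package promises;
   ties are broken toward smaller `theta`, then smaller `rho`, so
   results are deterministic.
3. The top-ranked line is taken as the platform's long side. Lines
   implying a rotation of 45 degrees or more are treated as the short
   side and skipped, since the long side is near-horizontal in any
   sensible camera mounting.
4. **Rotation** by `alpha = 90 - theta` degrees about the image
   centroid, output dimensions preserved, uncovered pixels black,
   bilinear interpolation. The rotation is defined so that a line at
   Hough angle `theta` moves to `theta + alpha`; that is the only
   direction convention under which `alpha = 90 - theta` actually
   rectifies, so it is fixed throughout (the synthetic image renderer
   uses the same map, and a round-trip test pins it down).
5. **Crop** to the platform: either a fixed user box, or the bounding
   box of above-threshold pixels in the rotated image with the
   threshold chosen by Otsu's method. Otsu is computed on a 256-bin
   histogram; when the intensity histogram has an empty valley the
   maximizer is a plateau and any threshold in it yields the same crop.

Edge detection runs on the original frame, and the rotation is then
applied to that same frame, following the visual order of the
preprocessing workflow. An auxiliary construction angle sometimes drawn
in such workflow figures plays no computational role and is not
represented.

## Track cleaning and 3D assembly

Pose-estimation exports carry a per-frame confidence. Samples below
`conf_min` (default 0.6) are dropped; gaps of at most `max_gap`
(default 5) frames are filled by linear interpolation of `(u, v)` —
interpolated points never leave the segment between their anchors —
and longer gaps split the track into segments that are analyzed
independently, so no speed or event ever spans a tracking loss. No
temporal smoothing is applied: the metric definitions operate on raw
adjacent-frame differences, and smoothing would bias them.

Depth is read as the median of a 5 x 5 px window centred on the
keypoint position nearest in time (pairing tolerance: half the depth
frame interval, i.e. nearest-in-time association between the 30 Hz and
10 Hz clocks — the two streams share a spatial calibration but not a
shutter). Zero-valued pixels are sensor holes and are excluded; the
median makes the read-out robust to them. Height is
`z = camera_height - depth` (camera height 2390 mm by default) and
stays on its native 10 Hz grid: the vertical speed definition
multiplies by the depth frame rate, so resampling `z` to 30 Hz would
silently corrupt that arithmetic.

## The sixteen metrics

For each axis, speed is the absolute adjacent-sample displacement times
the axis frame rate (30 Hz for X/Y, 10 Hz for Z); acceleration is the
absolute difference of *signed* speeds over the sampling interval.
Signed speeds matter: an oscillating bird whose absolute speed is
constant still accelerates, and taking `|d|dx||` instead of `|d(dx)|`
would hide that.

Two event families are detected on the planar series:

- **Forward-moving bouts.** A frame interval is "moving" when the
  forward (+X) displacement exceeds `d_min = 5` mm; maximal runs of at
  least `n_min = 3` such intervals (about 0.1 s at 30 fps) become
  bouts. The persistence requirement filters single-frame jumps from
  electronic noise. Backward movement never counts: the assay is about
  progress along the platform.
- **Half-cycles of lateral oscillation.** Broilers waddle: the back
  keypoint sways periodically in Y. Maximal same-sign runs of
  supra-threshold lateral displacements ("sweeps") qualify with the
  same `d_min`/`n_min` rules; each pair of consecutive opposite-sign
  sweeps is one half-cycle. Its duration is the time between the
  onsets of the two sweeps, which equals half the oscillation period
  for a sinusoidal sway — the quantity a "half-cycle" names. Measuring
  instead to the end of the second sweep would return the full period
  plus a threshold-dependent offset, and no sinusoid would ever score
  its nominal half-period. Two further details are forced by the
  geometry of thresholded sinusoids: (i) displacements near the sway
  extremes are sub-threshold, so a pause of up to `max_pause` (default
  0.5 s) is allowed between the paired sweeps — with a hard `n_min - 1`
  frame tolerance, no realistic sway would ever pair; (ii) a sweep
  already underway at the first observed frame has an unobserved onset
  and never anchors a half-cycle, which removes edge-truncated
  durations instead of reporting them short.

The average and maximum of the eight base quantities (3 speeds, 3
accelerations, 2 event durations) give 16 metrics per bird. Speed and
acceleration summaries include stationary frames by default (a
`moving_only` switch restricts them to supra-threshold frames). Birds
with no depth data get `NA` Z metrics, and birds with no events get
`NA` durations — absence, never zero, since a zero duration would be a
fabricated observation. Vertical movement durations are not computed;
vertical excursions of sitting birds are irregular, and only their
speed and acceleration are summarized.

## Group comparison

Each metric is compared across gait scores with a fixed-effects one-way
ANOVA (the bird is the experimental unit; a mixed-model formulation
with a single fixed effect and no random terms reduces to exactly
this), reported as mean ± pooled SE with `SE = sqrt(MS_within / n)`.
Pairwise comparisons use unprotected Fisher LSD — letters are computed
whether or not the omnibus test is significant, matching the convention
of means tables that print letters beside non-significant rows — with
two-sided t-tests on the residual `N - k` degrees of freedom and no
further multiplicity correction. The compact letter display uses the
insert-and-absorb algorithm, so two groups share a letter exactly when
their pairwise `p > alpha`. Birds lacking a metric are excluded from
that metric's ANOVA and counted in `n_excluded`. Degenerate inputs are
flagged rather than fatal: all-identical data give `p = 1` by
convention, perfectly separated groups with zero within-group variance
give `F = Inf`, `p = 0`.

## The synthetic generator

No public recordings accompany platform assays of this kind, so the
package ships a seeded generator whose outputs carry exact ground
truth. The latent path is a gated walk: exponential-length move/pause
alternation (mean move bout 2 s, pause length set by the profile's
`move_fraction`); constant forward speed while moving, direction
reversing at the walking-space ends so an episode is not exhausted in
the first few seconds; a sinusoidal lateral sway whose phase advances
only while moving; and a 10 Hz vertical series with standing height,
walking bob, and stand-attempt excursions for sitting birds. Observed
positions add i.i.d. Gaussian jitter (`noise_sd`, default 1 mm) to the
latent path. Truth bout and half-cycle lists are derived from the
noise-free latent path with the same threshold rules the detectors use.

The three default profiles encode the walking styles the three scores
describe — a continuous zigzag walker, an intermittent walker, a
near-immobile sitter with occasional stand attempts:

| score | speed while walking | sway amplitude/period | move fraction |
|------:|--------------------:|----------------------:|--------------:|
| 0 | 300 mm/s | 40 mm / 1.2 s | 0.75 |
| 1 | 180 mm/s | 35 mm / 1.2 s | 0.30 |
| 2 |  40 mm/s |  6 mm / 1.6 s | 0.06 |

Magnitudes were chosen once, inside physically plausible ranges for
5-7-week broilers (episode-average forward speeds then span roughly
35-230 mm/s across scores; half-cycle durations sit near 0.6 s, the
scale reported for broiler waddling). A score-0 walking speed of
300 mm/s (10 mm/frame) also keeps the per-frame displacement well clear
of the 5 mm threshold relative to the jitter, which is what makes
noise-free and noisy bout counts agree; a sitter's 6 mm sway is
sub-threshold by construction. These are generator parameters, not
estimates of any real flock.

What the generator does *not* emulate: pose-estimation failure modes
other than confidence dips (identity swaps, systematic drift),
correlated or heavy-tailed tracking noise, bird-shape deformation, and
occlusion. One visible consequence: with 1 mm i.i.d. jitter at 30 fps,
mean absolute accelerations land near 1800 mm/s², dominated by noise
rather than locomotion — real tracking pipelines have strongly
correlated frame-to-frame error and report far smaller values. Passing
the synthetic suite therefore demonstrates that the *computations* are
correct and that the pipeline separates the programmed walking styles;
it does not certify performance on any particular tracking system's
output.

Depth frames place a Gaussian depression (sigma 25 px) of depth
`camera_height - z` at the keypoint; any bump shape with a stable
extremum would do, since only the windowed median at the keypoint is
read. Synthetic depth uses its own scale (0.2 px/mm by default) so the
platform fits the depth sensor's frame.

## Numerical choices and degenerate inputs

- Event pairing compares time gaps with a 1e-9 s slack so that a gap of
  exactly `max_pause` is accepted regardless of floating-point path.
- Hough ties (identical votes) resolve to smaller `theta`, then smaller
  `rho`; Otsu plateaus resolve to the lowest maximizing bin.
- Speed needs 2 samples, acceleration 3; shorter inputs are errors, as
  is a track whose every sample fails the confidence filter.
- Bout durations are integer multiples of the frame interval by
  construction and at least `n_min` frames.
- Per-bird failures inside a cohort run are warnings (the bird is
  skipped and listed); only an entirely failed cohort is an error.

## Validation sizes

The test suite and `scripts/acceptance.R` validate against independent
brute-force oracles and R's reference linear-model fits: 20 platform
images with rotations drawn in [-30, 30] degrees (19/20 must recover
within 1 degree), 50 random edge maps for exact Hough agreement, 100
random displacement sequences of length 1000 for exact detector
agreement, 50 random balanced ANOVA fixtures (agreement to 1e-8), and
100 replicate cohorts (4 birds/score, 60 s) for effect recovery on
average X speed (p <= 0.05 in at least 90, group ordering 0 > 1 > 2 in
at least 95). These sizes give stable Monte-Carlo rates while keeping a
full run in a few minutes on one CPU.

## Known limitations

- One keypoint per bird: no step frequency, step length, or posture
  metrics; no identity re-association across birds.
- The pixel-to-distance factor is assumed isotropic and constant over
  the platform (no lens-distortion model).
- Depth and video clocks are associated by nearest time, not hardware
  sync.
- Fisher LSD without multiplicity correction is the field's reporting
  convention for such tables, not a family-wise error guarantee.
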