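---
title: "Tracking and kinematics in animtrack: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and kinematics in animtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The detection model

animtrack assumes one animal (or one colour tag) per video whose colour is
separable from the background in HSV space. Per frame the pipeline is:

1. optional crop to a rectangle (all downstream coordinates are then in
   cropped-frame space; the offset is recorded in the settings log);
2. HSV thresholding with inclusive bounds — a pixel is kept iff hue,
   saturation and value all lie inside the user's window;
3. 8-connected component labelling of the mask, discarding components
   smaller than `min_area`;
4. the largest remaining component becomes the frame's detection: its
   filled pixel count (area), its pixel-centroid, and its minimum rotated
   rectangle.

The coordinate convention is origin top-left, x rightward, y downward,
0-based pixel indices; centroids are floating-point in the same frame.
This matches every raster format the package touches.

**Hue wraparound.** Hue is an angle, and red — the most practical marker
colour on fur and against agar — straddles 0°. The hue interval is
therefore a first-class wrapped interval: `h_low > h_high` means the
window passes through 0°, so `hsv_range(350, 10, …)` selects red. The
other two channels are ordinary closed intervals. Preset files written in
the 8-bit convention (hue 0–179, S/V 0–255) are converted only when the
caller says so (`dialect = "opencv"`); the dialect is never guessed from
the values, because small integer thresholds are valid in both dialects.

**Connectivity and the rectangle.** Components are 8-connected, the
connectivity contour-following detectors use; the package labels with
`EBImage::bwlabel` (4-connected) and then merges diagonally adjacent
labels with union-find. The minimum rotated rectangle is computed by
rotating calipers over the convex hull of the component's boundary-pixel
*corners* (each boundary pixel contributes its four half-integer corners),
so a 10 × 10 pixel square measures exactly 10 × 10 rather than 9 × 9.
Sides are normalised so `rect_l ≥ rect_w`, because the larva analysis
defines body length as the largest dimension; the angle is the long side's
orientation in degrees [0, 180). Only outermost extent matters: holes
inside the thresholded blob do not affect the component's area (filled
pixel count) or its rectangle.

**Ties and degenerate inputs.** Equal-area components are resolved by the
smallest bounding-box origin, top-most then left-most — deterministic and
arbitrary, and documented as such. An empty mask, or one whose components
are all below `min_area`, is a *not-found* value, not an error.
Single-channel frames are rejected rather than auto-promoted: the method
is defined on colour.

# From detections to paths

`track()` emits one record per frame, found or not. Distances are sums of
Euclidean steps between successive detected centroids, scaled by the
pixels-per-mm calibration (`calibrate_scale()`; without one, distances are
in pixels and the summary flags the run as uncalibrated). The centroid,
not the rectangle centre, is the position used for distances: it is the
moment-based location and is insensitive to the angle jitter a tight
rectangle shows on nearly isotropic shapes. Both are kept in the CSV.

**Gap policy.** When detection fails mid-video there are two defensible
totals: bridge the gap with one straight-line step (a lower bound on the
true distance) or drop gap-crossing steps entirely. The default is
`bridge`; `skip` is available, and `n_detected` is always reported next
to `n_frames` so users can judge how much the policy matters. The choice
is recorded in the settings file, which contains every parameter needed
to reproduce a run byte-for-byte.

There is no randomness anywhere in the tracking pipeline.

# Kinematic analytics

**Instantaneous velocity** is the distance travelled over a window of
`window_frames` consecutive inter-frame steps divided by the window
duration `window_frames / fps`. A *step* interpretation (rather than a
*position* one) is used deliberately: a constant 2 px/frame trajectory at
30 fps then reads exactly 60 px/s, and the default 10-step window spans
333 ms at 30 fps. Windows tile the recording without overlap and any
window touching a not-found frame is omitted — zero-filling would bias
velocities downward. Because the window is defined in frames over the
video's own fps, 29 fps and 15 fps recordings are handled correctly
rather than assuming a hard-coded 333 ms.

**Distance binning** histograms the per-step distances over half-open
bins `[k·w, (k+1)·w)` and also reports per-bin distance totals;
conservation (binned distances sum to the total distance under the same
gap policy) is an invariant the tests enforce to 1e-9 relative.

**Region occupancy** is the fraction of *detected* frames whose centroid
lies in an axis-aligned rectangle, boundary inclusive — half-open
membership would make the whole-frame region fail to contain centroids on
the far edges. A path with zero detections returns `NA` with a warning,
deliberately distinct from an occupancy of 0. Occupancy is monotone under
region inclusion.

**Segment CV** splits the recording into consecutive non-overlapping
segments of a requested duration and reports the coefficient of variation
(sd/mean, in %, sample sd) of the per-segment distances. This is the
statistic used to pick a minimal reliable recording length: variation
across short segments of one long video estimates how unrepresentative a
short recording would be. Scaling all segment distances by the
whole-video mean rate cancels in the CV, so raw segment distances are
used. Durations that do not fit at least twice are skipped with a
warning; a zero-mean segment set (animal never moved) yields `NA`.

# The stride/turn classifier

For a crawling larva, body length per frame is `rect_l`. The classifier:

1. flags **turn frames**: aspect ratio `rect_l / rect_w` below
   `ratio_turn_threshold` × median aspect ratio over the video (default
   factor 0.6). The median-relative form adapts to each animal's
   elongation instead of hard-coding a ratio; the factor itself is an
   exposed parameter, since no principled universal cutoff exists —
   a curled larva at aspect ≈ 1.5 against a typical elongation of ≈ 4 is
   flagged with a wide margin at 0.6.
2. smooths the length trace with a centred moving average
   (`smooth_window`, default 5 frames, odd). Turn frames are *not*
   removed before smoothing; their extrema are discarded afterwards, so
   the smoother never sees artificial discontinuities.
3. extracts alternating local maxima/minima of the smoothed trace
   (plateau-aware), iteratively removes adjacent extremum pairs whose
   amplitude is below `min_prominence_px` (default 2 px — above the
   sub-pixel wiggle that rasterisation puts on the length of a moving
   shape, far below a real stride), drops extrema on turn frames, and
   pairs each peak with the following trough.

Each pair is one **stride event** with amplitude peak − trough in pixels
(converted to mm when calibrated); events whose peak→trough span contains
a turn frame are excluded. Amplitude is defined peak-to-trough — twice
the half-amplitude of a sinusoidal length oscillation; deviation-from-mean
is the natural alternative and is half this value, so either convention is
recoverable from the reported events. The mean amplitude over events is
the summary statistic.

A centred moving average of window $k$ attenuates a sinusoid of period
$T$ by $\sin(k\pi/T) / (k \sin(\pi/T))$ — about 0.90 for the default
$k = 5$ at $T = 20$ frames — which is why recovered amplitudes sit a few
percent below the generator's nominal peak-to-trough value; the tests
budget 10% for the combination of attenuation and rasterisation.

# The synthetic-video generator

The generator renders what the detector assumes: a single uniformly
coloured shape (disc, rotatable ellipse, rectangle) over a uniform
background, with exact per-frame ground truth (centre, length, width,
turn flags, Euclidean path length). Shapes are rasterised without
anti-aliasing — a pixel is inside iff its centre satisfies the shape
inequality — so mask geometry is exact, and videos are written as
uncompressed RGB24 AVI so no codec can perturb sub-pixel geometry.
Seeded salt noise (isolated single pixels of the target colour, never
touching the shape or each other, density ≤ 10⁻³) stress-tests the
`min_area` rejection; rendering is deterministic given the spec, and the
generator's RNG use is local, never disturbing the session's RNG state.

The pulsating-larva fixture oscillates an ellipse's major axis as
`base_length + stride_amp · sin(2πt/period)` with a fixed width chosen
from a baseline aspect ratio of 4, dropping to 1.5 during declared turn
windows. Defaults (base length 40 px, amplitude 6 px — i.e. 12 px
peak-to-trough, period 20 frames, 200 frames at 15 fps) give a fixture in
the proportions of a larva filmed at 640 × 480 and the frame rate used
for larval recordings.

What the generator does *not* emulate: fur texture, shadows, specular
highlights, cage clutter, anti-aliased or compressed video, partial
occlusion, and multiple same-coloured animals. Passing tests therefore
demonstrate the correctness of the geometry and the analytics, not
robustness to difficult real footage — threshold quality on real video
remains the user's responsibility, as it is with any colour-threshold
tracker.

Test problem sizes — 60-frame 320 × 240 disc videos, 200-frame larva
fixtures, twenty random paths per conservation property, fifty
random-walk replicates for the CV trend — are the package's chosen
balance of statistical cover against a test suite that runs in well under
a minute.

# Video I/O

The decoding backend reads and writes uncompressed RGB24 (BI_RGB) AVI
containers: intra-only, lossless, universally decodable. Compressed
streams raise an explicit error naming the codec rather than being
mis-decoded. Container metadata is the source of truth for fps, with a
user override (`open_video(path, fps = …)`) because phone recordings
commonly misreport it; stored as a rational, integer rates round-trip
exactly. Frame indices are 0-based everywhere, including the CSV.

# Known limitations

- One target per threshold: multiple same-coloured animals are not
  disambiguated (use `track_multi()` with distinct colour tags instead).
- No trajectory smoothing or motion model: the path is the raw centroid
  sequence, and the bridged-gap total is a lower bound on true distance.
- The turn threshold is relative to the video's own median elongation; a
  larva that turns more than half the time would shift its own baseline.
- Statistical comparison across animals or conditions (t-tests, ANOVA) is
  out of scope; the outputs are tidy tables intended for standard tools.
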