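---
title: "Closed-loop virtual-reality tracking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop virtual-reality tracking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vrtracker)
```

## The closed-loop model

A closed-loop virtual-reality assay binds an animal's behavior to its
sensory input through position. The animal moves freely in a 2D arena; a
camera records it at a fixed frame rate; a tracker localizes a body point
`p(t)` in each frame; and a homogeneous stimulus (in practice, the
intensity of an optogenetic activation backlight) is commanded at

```
I(t) = L(p(t - lag)),
```

where `L` is a predefined intensity landscape over the arena and `lag` is
the whole-frame latency between image capture and the stimulus update.
`vrtracker` reproduces this loop in software on recorded or synthetic image
sequences. The hardware latency (milliseconds between exposure, processing,
and LED actuation) is abstracted into the single integer `lag_frames`,
default 1: the command computed from frame `t` takes effect at frame
`t + 1`, matching a device whose update lands within the next frame
interval. Commands are strictly causal — `I(t)` depends only on frames at
or before `t - lag_frames` — so truncating the input video never changes
the stimulus already emitted, a property the test suite asserts exactly.

Intensities are abstract landscape units with ceiling `I_max = 1` by
default; physical calibration (uW/mm^2) is a reporting-side scale factor
and is out of scope.

## Detection and background reconstruction

The tracker must find the animal with no prior. Every frame is first
smoothed with a Gaussian kernel (`gaussian_sigma_px`, scaled to the
animal; the kernel is truncated at three sigma and renormalized, with
replicate boundaries). Detection then proceeds in three stages:

1. **Motion.** A running mean of the frames so far is maintained; the
   difference `current - mean` is thresholded at `mean(difference) - 4`
   gray levels. The animal, darker than the background it moves onto,
   appears below threshold. When exactly one 8-connected component with
   area inside `[min_area_px, max_area_px]` is present, its bounding box
   expanded by `roi_padding_px` becomes the region of interest. Absence of
   a detection is a normal outcome and simply accumulates the next frame.
2. **Local threshold.** Inside the ROI of the *first* frame, a gray-value
   cutoff is calibrated: starting from `mean(roi) - 4`, the threshold is
   lowered by one gray level while more than one animal-sized component
   passes, raised while none does, and fails if the 0–255 range is
   exhausted. The accepted component is the animal's initial silhouette.
3. **Background.** Each subsequent frame is binarized with that threshold;
   when the silhouette is re-found among the pixels the animal has *left*
   (centroid within 2 px and area within 20% of the initial blob — the
   tolerances absorb noise), the animal is deemed to have vacated its
   footprint. The footprint, dilated by 2 px plus the Gaussian kernel
   radius so that the filter's soft halo is covered, is patched with the
   corresponding pixels of the current frame. Where the animal's current
   silhouette still grazes the patch, that sliver is filled with the
   median of the cleanly pasted pixels rather than with animal pixels, and
   is re-pasted from a pristine frame once the animal has cleared the
   patch by a full kernel radius (a one-time refinement during tracking).
   On a uniform backlight the reconstruction is exact at zero noise; with
   camera noise the residual is the blurred noise itself (a fraction of a
   gray level in the frame interior — the outermost frame band carries
   somewhat higher variance because replicate-padded convolution
   concentrates weight there, but that band lies outside the dish).

Two details here are implementation-defined because no published account
pins them down: the direction/step of the threshold adjustment (a monotone
one-gray-level sweep, which guarantees termination) and the blob-identity
metric (the 2 px / 20% tolerances above). The running mean weights all
frames equally, including the current one.

## Per-frame tracking

Tracking is local background subtraction: inside the current ROI,
`D = frame - background` is thresholded at `mean(D) - 3 * sd(D)`; among
below-threshold components with animal-like area the largest is the
animal (ties broken toward the previous centroid), and its bounding box
expanded by `roi_padding_px` is the next search box. Restricting work to
the ROI is what makes the original device fast, and it is preserved here:
the Gaussian filter is evaluated only on the padded crop, which equals
whole-frame filtering exactly away from (and, by construction of the
padding, at) the frame border.

A frame with no valid component is a *lost* frame: the record is marked
invalid (positions are never interpolated), the search box is grown by one
padding step, and after three consecutive losses the whole frame is
searched. The padding (default 25 px) exceeds the largest per-frame
displacement of the supported organisms, so on clean video the next box
provably contains the animal.

## Head and tail

The silhouette is thinned to a one-pixel, 8-connected morphological
skeleton by a two-subiteration parallel thinning scheme (Guo–Hall
conditions) — chosen because the classic two-pass scheme retracts the
skeleton inside wide rounded body ends, displacing the endpoints.
Skeleton pixels with exactly one neighbor are the candidate endpoints; if
spurs leave more than two, the pair farthest apart along the skeleton
(geodesic distance by breadth-first search) is kept. The tail is the
endpoint nearer the previous tail — with two candidates and one reference
the optimal assignment reduces to this nearest-distance rule; an optional
`"assignment"` mode solves the full 2x2 correspondence against both
previous head and tail by minimized summed distance. A skeleton shorter
than 4 px (a disk-like blob, or a loop with no endpoints) is a degenerate
posture: head and tail are recorded as missing, the centroid still logged.

Two orientation safeguards sit in the orchestrator. On the first tracked
frame there is no previous tail and a straight body makes the centroid
fallback ambiguous; since the animal has necessarily travelled about a
body length for the background to exist, the head is taken as the endpoint
leading the net displacement since first detection. Thereafter continuity
rules; a one-time audit swaps all labels if the head systematically trails
the direction of motion. Only the trajectory is relabelled — the stimulus
log is an online record and is never rewritten.

## Virtual landscapes

Parametric landscapes are evaluated in closed form at sub-pixel positions:

* Gaussian: `I(p) = I_max * exp(-|p - c|^2 / (2 sigma^2))`;
* exponential: `I(p) = I_max * exp(-|p - c| / lambda)` (the alternative
  point-source profile; both are provided, Gaussian being the default);
* volcano: `I(p) = I_max * exp(-(|p - c| - R)^2 / (2 w^2))` — maximal on
  the rim circle of radius `R`, depressed at the center;
* checkerboard: `I_on` where `floor(x/s) + floor(y/s) + phase` is odd;
* raster grids, sampled nearest-neighbor.

Positions outside the arena (a rectangle, or a circular dish) command
intensity 0. `intensity_at()` is pure, and the stimulus log of a
closed-loop run equals the landscape evaluated at the logged tracked point
bit-for-bit.

Which body point drives the stimulus is experiment-specific: the head for
larval chemotaxis (the head carries the sensors and casts laterally), the
centroid for adult flies and fish. It is a parameter (`tracked_point`),
with the centroid used as a fallback on frames with degenerate posture.

## Trajectory analysis

**Smoothing.** Coordinates are smoothed with a centered triangular rolling
filter whose window spans the time the animal needs to traverse one pixel
at its speed bound: `round(frame_rate / (speed_bound * px_per_mm))`
frames, at least 1 — at 30 Hz typically ~0.3 s for a larva (1 mm/s bound)
and 0.06–0.09 s for a walking fly (~5 mm/s). Fish coordinates use a
*causal* half-triangular (ramp) window of 1 s: linearly increasing weights
ending at the current frame, so that the sluggish filter does not leak
future bout displacement backwards in time. Edge windows are truncated and
renormalized; missing frames stay missing but do not poison their
neighbors (weights renormalize over available samples).

**Speed** is the per-frame Euclidean displacement of the smoothed
coordinates, converted to mm/s, then smoothed again (1 s triangular for
larva and fly; 0.3 s for fish).

**Sensory experience** is `(1/I) dI/dt` after a 1 s boxcar on the
intensity series, by central differences; it is undefined (missing) where
`I = 0`.

**Distance to source** supports a hand-marked source (real gradients), the
landscape maximum (point-source virtual gradients), the nearest point of
the volcano rim (`| |p - c| - R |`, analytically), and unstimulated
controls, for which the landscape is placed relative to the animal's
starting position via a stated start-to-source offset vector.

**Preference index.** On a checkerboard, each valid frame is ON when the
centroid's landscape intensity is positive; `PI = (T_on - T_off) /
(T_on + T_off)`.

**Bouts.** Fish trajectories are discretized at local maxima of the speed
series with height at least 2.5 mm/s and at least 5 frames between
retained peaks (the higher peak wins a conflict; plateaus resolve to their
middle sample). For each pair of consecutive peaks, the bout displacement
vector connects the positions 0.66 s before and after the peak; theta is
the unsigned angle between consecutive displacement vectors; bouts with
theta of 135 degrees or more are discarded (in the original assay these
are wall-reflection misdetections — the synthetic agents hit the same
filter when they bounce off the dish wall). `delta_I` is the intensity
change experienced *during the previous bout* (post-window minus
pre-window sample of the previous peak). Sampling it across the previous
bout, rather than between the two peaks, matters: peak-to-peak sampling
includes half of the current bout's own displacement, so a large turn that
reverses direction would classify itself as "up-gradient" and bias the
turn-angle contrast. The bearing error alpha is the angle between the
current bout's displacement and the bearing to the source at the bout's
start; the turn index `beta = (#toward - #away) / N` uses 90 degrees as
the toward/away boundary, with bouts exactly on the boundary counted in
the denominator only (unbiased).

**Inclusion.** A trial enters analysis only if the animal moved at least
20 mm in total — with per-frame movements of 1 mm or less suppressed as
detection noise by position anchoring — and was tracked for at least 3/5
of the trial.

Hypothesis tests on binned turn angles are delegated to `stats::t.test` /
`stats::wilcox.test` with Bonferroni correction via `stats::p.adjust`;
the package never re-implements standard tests.

## The synthetic arena

The generator exists so that every stage above is testable without any
recorded data. Its defaults emulate the published experimental scale: a
100 mm petri dish imaged at 640 x 480 px (4.8 px/mm) and 30 Hz, a bright
uniform infrared backlight (gray 200), an animal silhouette 80 gray levels
darker, optional Gaussian camera noise, and 8-bit quantization. All
stochastic draws flow from one seeded stream per simulation (the caller's
RNG state is untouched), and per-frame noise is keyed by `(seed, frame)`,
so any access order — and any truncation — reproduces identical pixels.

* **Larva**: runs at 0.7 mm/s mean with a sinusoidal peristaltic
  modulation (peaks below the 1.6 mm/s reported magnitude), interrupted by
  stochastic stop-and-cast events in which the body pauses and the head
  sweeps laterally. With positive chemotaxis gain, stops are promoted when
  the sensed `(1/I) dI/dt` turns negative and the cast resolves toward the
  side with higher sampled intensity. The rendered body is a constant-width
  curved capsule through tail, spine midpoint and head; the recorded
  ground-truth centroid is the capsule's shape centroid (which shifts into
  the bend during casts), so tracker-versus-truth comparisons are
  geometrically fair.
* **Fly**: a heading-persistent walker (speeds up to ~14 mm/s, about ten
  times the larva). With the avoidance phenotype enabled, its mean speed
  rises on lit checkerboard squares and it frequently stops on a
  lit-to-dark transition, so occupancy drifts into the dark squares and PI
  turns negative.
* **Fish**: discrete swim bouts — 2.0 mm mean displacement over 0.2 s
  (peak burst ~20 mm/s) at 1.5 s mean intervals. The bout amplitude is
  chosen so that, after the 1 s causal coordinate filter, peak filtered
  speeds sit well above the 2.5 mm/s detection threshold (smaller bouts
  would be invisible to the published analysis settings), and the interval
  so that the 0.66 s turn windows of adjacent bouts do not overlap. Each
  bout is preceded by a reorientation drawn from a forward-scoot /
  routine-turn mixture (heavy-tailed, as larval swims are); with gain `g`,
  the drawn magnitude is scaled by `1 + g` when the previous bout went
  down-gradient *and* the current intensity is below 35% of `I_max`. Turn
  *direction* is left/right symmetric at every gain, so the agent carries
  no constructed bias toward the source. The canonical amplified condition
  uses `g = 0.75`, i.e. a 1.75x magnitude scaling, matching the modest
  effect size real cohorts show rather than a caricature.
* Walls are specular: the heading reflects off the dish tangent, so wall
  encounters do not steer the agents toward the dish center (which would
  masquerade as taxis toward a centered source).

What the generators do *not* emulate: body deformation beyond the bent
capsule, reflections and shadows near the dish wall, illumination
inhomogeneity, multi-animal scenes, or learned behavior. Passing tests
therefore certify the pipeline's correctness on its stated imaging model,
not performance on arbitrary real footage.

## Numerical choices and degenerate inputs

* Coordinates are 0-based pixel centers, x rightward, y downward; boxes
  are inclusive; connectivity is 8-connected throughout.
* Gray conversion of color input is the unweighted channel mean (the
  reference camera is monochrome; the rule is stated for reproducibility).
* The difference-image conventions keep the animal *below* threshold
  (`current - reference`), matching silhouettes darker than the backlight.
* A uniform ROI (zero variance) yields an empty binarization and a lost
  frame, not an error; a never-moving animal exhausts the background
  budget with a diagnostic.
* Ties — equal-area blobs, equidistant endpoints — break deterministically
  (previous-centroid proximity; previous-axis orientation, then smaller
  `(y, x)`).
* Trajectory and stimulus tables are plain one-header-line CSV with empty
  fields for missing values; calibration metadata travels as constant
  columns so a file is self-describing and the round trip is lossless.

## Validation scope and problem sizes

The test suite validates each operation against independent oracles
(direct convolution, brute-force connected components and local-maxima
scans, closed forms, 10,000-point rim sampling) and the whole loop against
generator ground truth: sub-pixel centroid recovery and correct head/tail
assignment on a 300-frame zero-noise larva video, 2 px RMSE under sd-3
camera noise, exact background reconstruction at zero noise (within 2 gray
levels under noise), bit-exact closed-loop stimulus logs, and end-to-end
recovery of the fish turn-amplification rule (50 amplified plus 50 control
trials of 30 s at 30 Hz, tracked from rendered video; one-sided Welch test
on low-intensity down- versus up-gradient turn angles, with per-intensity-
bin Bonferroni-corrected comparisons of the recovered turn index against
controls). Trial lengths and cohort sizes were chosen to give these
contrasts comfortable statistical power at interactive run times; the
methods scale unchanged to longer recordings.

## Known limitations

* No video-container input: frame sources are numbered PNG/TIFF image
  directories, in-memory matrices, or the synthetic renderer.
* The background is reconstructed once (with one refinement pass) and then
  held fixed; slow illumination drift over long recordings is not
  compensated.
* Single-animal scenes only, matching the closed-loop contract.
* The stimulus is spatially homogeneous by design; patterned or panoramic
  displays are out of scope.
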