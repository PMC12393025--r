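---
title: "NemaTrack methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NemaTrack methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NemaTrack)
```

NemaTrack quantifies *C. elegans* behavior from three kinds of raw data:
grayscale frame sequences of a single crawling worm (with motorized-stage
logs), centroid time series from long sleep recordings, and current-clamp
voltage traces. This vignette describes the models and procedures behind
each analysis, the parameters that matter, and the choices made where the
design was genuinely open. It states no empirical result beyond what the
package's own test suite and acceptance script compute.

## Worm segmentation and the 13-marker midline

A frame is binarized at a user-selected brightness threshold; with
transmitted illumination the worm is dark, so the foreground is every pixel
strictly below the threshold (`polarity = "worm-dark"`; the complement is
available for dark-field recordings). Connected components smaller than
3,000 pixels are removed as debris. Components use 8-connectivity — the
choice matters only for masks within a few pixels of the area cutoff, and
it is the more permissive convention for thin diagonal body sections.

The outline of the remaining component is traced, smoothed with a circular
moving average (window 5 vertices; the window is exposed as configuration
because any small value works and the tracing noise it suppresses is about
one pixel), and scored for corner sharpness: at each vertex, the angle
subtended by the vertices 15 steps away on either side. The tail is the
sharpest corner and the head the second sharpest; this works because the
animal's tail tapers to a finer point than its head. On the first frame the
assignment is reported unconfirmed (a head seed can be supplied); on later
frames the candidate nearer the previous head keeps the label, so the head
identity propagates through the recording.

The midline is built by splitting the outline at head and tail into two
flanks and pairing each point of one flank with its nearest point on the
other. Nearest-point pairing (rather than pairing by matched arc-length
fraction) is robust to the systematic length mismatch between the inner and
outer flank of a bent body. The midpoint polyline is smoothed, interpolated
with a cubic spline, and resampled; 13 markers are placed at equal
arc-length intervals, marker 1 at the head. Two details matter for
accuracy:

* boundary smoothing erodes sharp tips, so the midline endpoints are
  re-anchored to the unsmoothed contour positions of the head and tail
  corners;
* the worm length is the arc length of the dense midline, not the chord
  sum of the 13 markers.

A failed fit — degenerate mask, no component above the debris cutoff, an
ambiguous silhouette, or an omega posture — triggers automatic threshold
retry: alternating offsets (+s, −s, +2s, −2s, ...) of step s = 5 intensity
levels around the user threshold, up to 10 retries (11 thresholds in all).
Omega postures are flagged in two independent ways: a hole enclosed by the
body mask (detected by hull filling), and a self-intersecting recovered
midline. Fitting runs at full image resolution.

## Locomotion

World coordinates merge the pixel positions with the stage log: world =
stage position at the latest log entry at or before the frame time, plus
pixel position × µm/px. A stage move that exactly recenters the animal
therefore produces zero apparent displacement — this identity is exact and
is asserted in the tests.

Metrics are computed on the actual frames for 1, 3 and 5 FPS recordings
and at 3 FPS (frames 1, 6, 11, ...) for 15 FPS recordings. Direction per
step compares the velocity vector (previous → current centroid) with the
head vector (centroid → head tip): forward if their dot product is
positive, otherwise backward, with a zero dot product classified backward
(the strict complement) and zero velocity excluded as stationary.
Amplitude is the width of the smallest rectangle parallel to the velocity
vector enclosing all 13 markers; the velocity used for frame *t* is the
step ending at *t* (window configurable). Elapsed time always comes from
the time log rather than frame count divided by nominal rate, so timing
jitter does not bias speeds. Per-frame amplitude is reported both as the
recording mean and the maximum, since a single global value hides
amplitude changes across a recording.

## Bending

The bend angle at marker *i* (1–11) is the angle between the vector from
marker *i*+1 to marker *i* and the direction of the line through markers
*i*+1 and *i*+2; the sign is positive ventrally once the `R_`/`L_`
orientation of the recording is known, and follows a fixed cross-product
convention (flagged undifferentiated) otherwise. RMS bend is
√(Σxᵢ²/n) over a marker's samples — nonnegative by construction — and the
sum of all bends totals the 11 per-marker RMS values. Failed frames leave
gaps that are excluded from n.

The dominant bending frequency is the largest non-DC bin of the magnitude
spectrum of the mean-subtracted trace; gaps are linearly interpolated
first because the transform needs uniform sampling. No window function is
applied by default (a Hann window is behind a flag): for 30–60 s traces
the leakage of a plain transform does not move the dominant bin. The
frequency resolution fs/n is reported with the estimate.

Maximum bend finds local maxima ≥ +20° (ventral peaks) and local minima
≤ −20° (dorsal troughs), enforces alternation by keeping the larger of
consecutive same-sign extrema, and reports mean(peaks) − mean(troughs).
This is the batch-mode equivalent of manually clicking alternating peaks
and troughs with a 20° qualification gate. The summary sheet reports
marker 6 (mid-body) by default; all 11 traces are computed.

## Body curvature

The dense midline is resampled to 100 points, smoothed with a 7-point
moving average, and its signed discrete curvature (three-point finite
difference) is cut at zero crossings. All three knobs are configuration;
the defaults suppress pixel-level jaggedness without flattening genuine
body bends, and the boundary band where asymmetric smoothing corrupts the
sign (half window + one stencil point) inherits the nearest interior sign.
Segments shorter than 3% of body length merge into a same-sign neighbor
when one exists and are dropped otherwise; one pass, not cascaded — a
second pass could only be triggered by sub-3% segments created by the
merge itself, which cannot happen because merging only grows segments.

Each retained segment gets a least-squares circle by the Kasa method
(linear least squares on the algebraic circle equation; exact on noiseless
circles) and the normalized curvature L/r, with L the same straightened
length used by the locomotion module. Sides (V/D) follow the bending sign
convention and ranks run head to tail per side. For strain comparisons a
primary-curvature filter excludes a first-ranked segment with curvature
below 2.5 and promotes the next rank, per side, until the first rank
passes or the side is exhausted.

## Sleep

Motion is classified per frame transition from centroid displacement:
motionless strictly below 10 µm, active at or above. The boundary case
(exactly 10 µm) is assigned active because the convention defines
motionless by a strict inequality; the choice is documented and the
threshold configurable. A bout opens at the first frame of ≥3 consecutive
motionless frames and its end is the end of the last run of ≥3 motionless
frames; what *terminates* scanning is an awakening of ≥3 consecutive
active frames — the onset rule mirrored, since the quiescence literature
and the bout definition itself are silent on the wake rule. `wake_k` is
therefore configurable and prominently documented as an interpretation.
Shorter interior active runs are recorded as active events; motionless
sleep duration is total bout duration minus active-event time, an exact
identity. Frames lost to segmentation failure break runs conservatively
(motionlessness cannot be asserted), and a caller-supplied invalid-range
mask flags bouts from frames where the animal touched the chamber edge.
Both the sum over bouts and the single longest bout are reported, since a
recording's "total sleep" is used in both senses in practice.

## Action potentials

Traces are uniform-dt voltage series (nominally 10 kHz). Peaks are local
maxima above −20 mV with ≥20 mV prominence and a 5 ms refractory gap —
parameters exposed because they are detection plumbing, not measurement
definitions. Two threshold methods are implemented:

* **fixed-lead** — the membrane potential at a user-defined time before
  the peak, for APs without a pre-upstroke inflection (*C. elegans*
  body-wall muscle). The lead deliberately has no default: it is a
  scientific choice that must be held constant across recordings.
* **inflection** — the last sample before the peak at which the smoothed
  dV/dt rises through a criterion (default 10 mV/ms, configurable) and
  stays above it to the peak. If the criterion is never reached the AP is
  flagged non-inflected and the fixed-lead method should be used.

RMP is the 20 ms mean before the reference point (fixed-lead mode) or the
lowest 3 ms sub-window mean within that window (inflection mode, robust to
the depolarizing ramp that precedes inflected APs). Amplitude is peak
minus threshold voltage; APD50 the width at half amplitude with sub-sample
linear interpolation; rise time threshold→peak; decay time peak→return to
the threshold voltage; AHP the actual voltage minimum between
repolarization and the next AP's threshold (capped at 200 ms). When the
voltage never recrosses the threshold before the next AP, decay and AHP
are reported unavailable rather than extrapolated. Phase plots use
central-difference dV/dt; their extrema are the maximum and minimum
slopes. Sweeps are analyzed independently and never concatenated.

## Synthetic data and what it does (not) show

The generators exist so every analysis path can be exercised against known
ground truth without hardware:

* `wormPose()`/`renderWorm()` draw a sinusoidal midline of true length
  400 px (a ~1 mm adult at the default 2.5 µm/px calibration) with a
  tapered width profile, tail sharper than head, dark body (40) on bright
  background (200) with Gaussian noise. The half-width is capped by the
  arc distance to the nearer tip so the painted body ends exactly at the
  midline endpoints — without the cap, the tip disks protrude and bias
  every length-dependent truth comparison. Body area at default scale is
  ≈7,500 px, comfortably above the 3,000 px debris cutoff.
* `simulateCrawl()` translates the pose at constant speed (default
  150 µm/s, a typical wild-type crawl; undulation 0.4 Hz) while a
  simulated stage recenters the field at 1 s intervals, and writes a
  complete recording bundle (frames, stage file, time file). The canvas
  is sized so the worm stays in frame between recenterings.
* `simulateSleepTrace()` plants quiescence bouts (steps ≪ 10 µm) in an
  active random walk (steps ≫ 10 µm), with isolated single-frame active
  spikes inside bouts; `simulateAPTrain()` plants piecewise-linear
  (closed-form metrics) or smooth exponential-take-off templates (analytic
  dV/dt threshold crossing) on a flat baseline.

These fixtures are deliberately clean: no lawn texture, no defocus, no
multi-worm contact, no electrode drift. Passing tests demonstrate that the
algorithms implement their definitions correctly and recover planted
parameters under realistic noise — not that segmentation thresholds or
detection parameters transfer unchanged to any particular microscope.

## Numerical choices and problem sizes

Sub-sample crossings (APD50, decay) use linear interpolation between
samples. The Kasa fit solves the normal equations by QR; collinear inputs
raise an error that callers report as curvature 0. Marker spacing is
validated to 2% by projecting markers onto the dense midline. All
generators are deterministic per seed.

The test suite and acceptance script run at desk scale on one CPU: 50
rendered poses for midline recovery, 8–20 simulated crawls for kinematics,
500 random label sequences against the brute-force sleep oracle, and AP
trains of 5–50 events. These sizes give stable statistics for the
tolerances asserted while keeping a full run in minutes.

## Known limitations

* Single worm per frame; contacting animals are not separated.
* ABF files are not parsed; export current-clamp sweeps to CSV first.
* Results export writes a directory of CSV sheets (one per metric family)
  with a manifest, readable back bit-exactly, rather than a binary
  spreadsheet container.
* The wake rule ending a sleep bout is an interpretation (see above).
* RMS bend is reported as the nonnegative root-mean-square; a signed
  variant is not defined.
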