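---
title: "Tracking and quantifying Drosophila negative geotaxis with geotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and quantifying Drosophila negative geotaxis with geotrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geotrack)
```

## The assay and the problem

When startled, *Drosophila melanogaster* climbs against gravity (negative
geotaxis). The classical assay taps a vial of flies to the bottom and counts
how many pass a target height within ~10 s. That endpoint count hides almost
everything of interest: individual variability, climbing speed, movement
direction, and transient events such as slips and falls. `geotrack`
implements the software half of an automated version of this assay: from a
backlit grayscale video of a vial containing up to about 7 flies, it
reconstructs a per-fly trajectory at frame resolution (1/30 s at the default
30 Hz) and derives climbing curves, speed--angle kinematics, a bootstrapped
directional-bias statistic, and slip/fall events.

The pipeline is: calibration → detection → tracking → analytics, plus a
synthetic-video simulator with known ground truth that serves as the
package's benchmarking harness.

## Detection

A background frame for each vial video is the per-pixel **median over all
frames**; since a moving fly occupies any one pixel in well under half the
frames, the median recovers the clean backlit field. Each frame is
subtracted from the background (flies are dark on a bright field, so the
difference `background − frame` is positive over a fly) and binarized at a
fixed threshold of 0.06 on `[0, 1]` intensities; differences at or below the
threshold are background. Connected components (8-connected by default;
configurable) are measured: centroid, pixel area, and major/minor axis
lengths of the ellipse with the same second central moments as the
component. The moment computation includes the 1/12 pixel-bin variance term,
so 1-px-wide components receive a small positive minor axis instead of a
degenerate zero; this is an approximation to "longest and shortest lines
across the object" and is documented as such.

**Calibration** turns labeled example objects (single fly / multiple flies /
noise) into classification thresholds:

* the lower area cutoff is the 16th percentile of single-fly areas
  (configurable; percentile computed by the standard linear interpolation
  between order statistics);
* the single/multi boundary is the maximum single-fly area, which removes
  the overlap between the two distributions by construction;
* anything larger than the maximum multi-fly area is noise;
* within each class, the minor/major axis ratio must lie in the observed
  `[min, max]` interval for that class (an optional symmetric trim fraction
  is exposed; the default keeps the full range).

Boundary ties go to the class whose extremum they equal: an area exactly at
the single-fly maximum is a single fly, exactly at the multi maximum a multi
blob, exactly at the lower cutoff a single fly. A multi-fly blob of area $A$
is split into $\lceil A / A_{\text{single,max}} \rceil$ individual
detections sharing the blob centroid, with an exact integer quotient staying
at that integer so that no phantom extra fly is created.

## Tracking

Each fly's state $(x, y, v_x, v_y)$ (px and px/frame) evolves under a
constant-velocity Kalman filter with white-acceleration process noise
(1 px/frame² s.d. by default), 1 px measurement noise, and an uninformative
initial velocity. For each frame, the cost of pairing track $t$ with
detection $d$ combines the distance to the Kalman prediction,
$d_\text{pred}$, and the distance to the track's previous coordinates,
$d_\text{prev}$. The shipped rule is
$\min(d_\text{pred}, d_\text{prev})$ — the previous position acts as a
fallback when erratic fly movement defeats the constant-velocity
extrapolation — with `mean` and `pred`-only variants available through
`cost_rule` so the ablation can be reproduced under any reading.

The $T \times D$ cost block is padded to a $(T+D)$-square matrix: phantom
columns and rows cost the **cost of non-assignment** (CON, default 11 px)
each, and the bottom-right block carries the transposed real costs. Under
this construction a lone track--detection pair is matched exactly when its
distance is below CON, which is the threshold semantics the CON sweep
optimizes. The padded matrix is solved exactly by the Hungarian method
(`clue::solve_LSAP`); the test suite cross-checks it against brute-force
permutation enumeration.

Track management follows the known fly count `n_flies`:

* assigned tracks take a measurement update and record the detection;
* unassigned tracks coast on their last known coordinates (recorded
  invisible) — a stationary or occluded fly is re-linked by the assignment
  itself when it reappears nearby;
* unassigned detections found new tracks only while fewer than `n_flies`
  tracks exist; at capacity, a surplus detection may instead *revive* a
  track that has been invisible for at least `max_invisible_frames`
  (default 3 frames), re-initializing its Kalman state at the detection.
  This is the lost-and-found path for flies displaced far beyond CON in a
  single frame — a slip of one body length is already ~22 px — which would
  otherwise leave a track coasting forever while its fly's detections are
  discarded. The latency is long enough that a one-frame occlusion blip
  never triggers relocation, short enough that a fall costs only a few
  coasted frames;
* remaining surplus detections are discarded farthest-first (distance to the
  nearest unassigned track's previous coordinates; ties by detection index);
* at finalization, frames before a track's first detection are backfilled
  with that first position, and any fly that never produced a track receives
  a constant coordinate drawn uniformly at the bottom 5% of the ROI,
  seeded by `rng_seed` for reproducibility.

The finalized `CoordinateMatrix` always has exactly `n_flies` rows and one
coordinate per frame per fly, with a `visibility()` matrix recording which
coordinates came from actual detections.

## Analytics

Coordinates convert to physics convention by `x_mm = x_px / px_per_mm` and
`y_mm = (H_ROI − y_px) / px_per_mm` (y up, origin at the vial bottom;
default scale 4.85 px/mm, i.e. 9.7 px ≈ 2 mm). All sign handling lives in
this one conversion.

For consecutive frames $i, i{+}1$ the displacement is
$\Delta r_i = \sqrt{\Delta x_i^2 + \Delta y_i^2}$, the speed
$s_i = \Delta r_i / \Delta t$, and the movement direction
$\theta_i = \operatorname{atan2}(\Delta y_i, |\Delta x_i|)$ in degrees.
Taking $|\Delta x|$ folds left and right together, so $\theta$ spans
$[-90°, 90°]$ with $+90°$ straight up. Pairs with
$\Delta r_i \geq 4$ mm (inclusive) are gated out of the speed--angle data as
abnormally large frame-to-frame locomotion — jump artifacts, slips, falls,
flight — which also caps speeds below 120 mm/s; stationary pairs have
undefined $\theta$. Per-fly `AveSpeed` and `AveAngle` average only the
defined, ungated values (gated pairs are omitted rather than zero-filled;
both choices are defensible and the omission is flagged here), and
`DistanceTraveled` is the average speed times the video duration.

**Climbing curves** record, per fly, the time of the first frame above a
target height; later positive geotaxis does not uncount a fly. Single-trial
curves are unit staircases; across $N$ trials the mean curve steps by $1/N$
with a s.e.m. band computed across trials on the union of step times.

**Slips and falls**: a single-frame vertical drop $-\Delta y$ between one
and three body lengths (4.5--12 mm, both ends inclusive) is a slip, larger
is a fall. Each event records the pre-drop height and the ratio of the drop
to its maximum possible size (the pre-drop height itself). Because
4.5 mm > 4 mm, every slip or fall pair is automatically excluded from the
speed--angle series; the tests assert this disjointness.

**Turning rate** counts non-zero changes between consecutive defined angles
per second; the default tolerance (10⁻⁶ degrees) is exact-change counting on
pixel-quantized data, and any gated or stationary pair breaks the chain.

**Directional bias**: speed--angle pairs are bootstrapped (resampled with
replacement at the full data size, 1000 replicates by default, seeded),
split by $\theta > 0$ versus $\theta < 0$, and the Spearman correlations
$\rho_+$ and $\rho_-$ and their ratio computed per replicate. The reported
estimate is the mean ± s.d. over replicates. Replicates where a stratum has
fewer than 3 pairs, a correlation is undefined, or $\rho_- = 0$ are
discarded and counted (`nDiscarded`) rather than imputed — near-zero
denominators otherwise dominate the distribution. Spearman uses average
ranks for ties.

## The synthetic harness

`simulateTrajectories()` generates ground truth from a per-fly state machine
over climb / pause / slip / fall. Climbing is an upward-biased correlated
random walk (heading relaxes toward vertical with Gaussian diffusion;
per-frame speeds drawn at mean 18 mm/s, in the range of real wild-type
strains); pauses have geometric duration; slips draw $-\Delta y$ uniformly
from [4.5, 12] mm and falls from (12, y] mm. Flies are simulated jointly
with a short-range avoidance turn (real flies rarely walk through one
another); without it, seven independent walkers in a 25 mm-wide projected
vial would overlap an order of magnitude more often than real cohorts do. A
fly reaching the top turns around and descends for a while rather than
accumulating at the ceiling, and fly centroids keep a 1.5 mm body clearance
from the walls so rendered blobs are never clipped by the ROI border.

`renderVideo()` draws each fly as a dark, velocity-oriented, anti-aliased
ellipse (per-fly semi-axes drawn from a configured range) on a bright field
(~0.9) with a smooth vertical illumination gradient and sub-threshold
Gaussian pixel noise; overlapping flies merge into one blob. Optional noise
objects come in two kinds: `streak` (long thin smears that the shape filter
rejects) and `aberration` (fly-sized spots that jitter far faster than a
walking fly — the "mobile illumination aberration" failure mode that tempts
the tracker at permissive CON). Everything is seeded: identical parameters
give bit-identical videos, coordinates and reports.

`evaluateTracking()` matches tracked to true positions per frame by
minimum-total-distance assignment — identity-agnostic, because the
downstream analytics use anonymized single-fly data — and reports the
fraction of positions within 10 px, the localization error distribution,
the identity-switch frame fraction (frame transitions at which the matching
permutation changes), the missing-coordinate fraction (coordinates not
backed by a detection), and a large-jump statistic (each track's top 1% of
frame-to-frame displacements, averaged and normalized to the vial length).
The evaluator scores *every* frame, which is strictly harder than sampling
every 15th.

### Default study conditions

The benchmark conditions (`benchmarkParams()`) are 7 flies, 300 frames at
30 Hz, a 120 × 680 px ROI at 4.85 px/mm (a 140 mm vial), start positions
bunched within 18 mm of the bottom, and avoidance parameters under which
about 3.5% of frames contain an overlapping fly pair — the collision
frequency observed in real recordings. These values were fixed once against
the overlap statistic alone. The CON sweep benchmark adds two aberration
noise objects so both error families (missing coordinates at low CON, bad
assignments and jumps at high CON) are present; the weighted error combines
the missing-coordinate rate (normalized to its maximum over the sweep) and
the large-jump statistic with weights 1 and 0.1.

## What passing tests do and do not show

The simulator emulates the features the tracker must survive — dark
ellipses on an uneven backlit field, merged blobs during collisions, pauses,
slips, falls, sub-threshold sensor noise, and mobile aberrations — but not
everything about real video: no motion blur, no legs/wings or postural area
changes, no specular highlights, no 3-D perspective (a fly walking on the
front versus back wall changes apparent size), and collisions are shaped by
the avoidance model rather than real contact behavior. Accuracy numbers on
the benchmark therefore validate the algorithmic pipeline under controlled
degradations, not camera-specific performance; for a new optical setup the
calibration step is the intended adaptation point.

## Numerical choices and degenerate inputs

* Even-length medians use the midpoint mean; the segmentation threshold is
  strict with a 10⁻¹² guard so a difference exactly at 0.06 stays
  background regardless of floating-point representation.
* Percentiles interpolate linearly between order statistics (R type 7).
* Surplus-detection removal and relocation are deterministic (distance
  ordering with index tie-breaks); bottom seeding is seeded by config.
* Degenerate inputs error early and by name: empty calibration, missing
  label classes, all-equal single areas (no valid ordering), ROIs out of
  bounds, non-finite cost entries, a coordinate CSV missing a fly in a
  frame.
* An empty video with a positive fly count yields all bottom-seeded
  constant tracks rather than an error, matching the end-of-run accounting
  for never-detected flies.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on simulated data
generated at run time: ten 300-frame, 7-fly videos for the accuracy
benchmark, two videos for the CON sweep, and smaller arenas (3--5 flies,
60--150 frames) for unit-level properties. On one CPU the full suite runs
in a few minutes.

## Limitations

* MP4/AVI containers are not decoded in-process; `readVideo()` consumes
  PNG/TIFF frame directories and tells the user how to extract frames.
* Identity persistence through collisions is not guaranteed (switches are
  tolerated and reported separately), so per-fly metrics describe
  anonymized individuals, not named ones.
* The multi-fly split assigns all clones the common blob centroid; during
  long merges single-fly resolution is positional, not individual.
* Turning rate reflects track direction, not body heading.
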