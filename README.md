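# geotrack

Multi-fly tracking and behavioral analytics for *Drosophila* negative
geotaxis (climbing) assays.

When startled, fruit flies climb against gravity. The classical assay counts
how many flies pass a height mark after ~10 s — a single number that hides
individual variability, kinematics, and transient events such as slips and
falls. `geotrack` is the software side of an automated version of the assay:
from a backlit grayscale video of a vial holding up to ~7 flies it
reconstructs one trajectory per fly at frame resolution, then derives the
behavioral metrics used to compare cohorts and genotypes.

The pipeline:

1. **Calibration** — labeled example objects (single fly / multiple flies /
   noise) define area and axis-ratio acceptance bounds: the lower area cutoff
   is the 16th percentile of single-fly areas, the single/multi boundary is
   the maximum single-fly area, anything above the maximum multi-fly area is
   noise, and shape (minor/major axis ratio) removes remaining non-fly
   objects.
2. **Detection** — per-vial background as the per-pixel median over all
   frames; frames are background-subtracted and thresholded at 0.06 on
   `[0, 1]` intensities; 8-connected components are measured (centroid, area,
   ellipse-equivalent axes); a multi-fly blob of area *A* splits into
   ⌈*A*/*A*<sub>single,max</sub>⌉ detections at the shared centroid.
3. **Tracking** — per fly, a constant-velocity Kalman filter; per frame, a
   cost matrix whose entries are min(*d*<sub>pred</sub>, *d*<sub>prev</sub>)
   (distance of a detection to the Kalman prediction and to the track's
   previous coordinates), padded with the **cost of non-assignment**
   (CON, default 11 px) and solved exactly with the Hungarian algorithm.
   Lost flies coast on last known coordinates and are re-linked on
   reappearance; flies never detected are seeded at the vial bottom.
4. **Analytics** — climbing curves (first-crossing times, mean ± s.e.m.
   across trials), frame-pair speed *s* = Δ*r*/Δ*t* and movement angle
   θ = atan2(Δ*y*, |Δ*x*|) with a 4 mm displacement gate, turning rate,
   slip (4.5–12 mm single-frame drop) and fall (> 12 mm) events with
   drop/max-drop ratios, and the bootstrapped directional-bias ratio
   ρ₊/ρ₋ of Spearman speed–angle correlations for upward vs downward
   movements.
5. **Synthetic harness** — a seeded simulator (upward-biased correlated
   random walks with pauses, slips, falls, collisions and noise objects),
   an ellipse renderer producing videos with known ground truth, and an
   evaluator reporting localization accuracy, identity switches and error
   rates.

## Worked example

Simulate a standard trial (7 flies, 10 s at 30 Hz), track it, and score the
result against the known ground truth:

```r
library(geotrack)

p     <- benchmarkParams(seed = 42)          # the standard study conditions
truth <- simulateTrajectories(p)             # ground-truth trajectories
stack <- renderVideo(truth)                  # 120 x 680 px vial video

calib <- calibrateFromSimulation(p)          # labeled size/shape examples
thr   <- deriveThresholds(calib)             # detection acceptance bounds

cfg <- geotaxisConfig()                      # CON = 11, 0.06 threshold, ...
cm  <- trackVideo(stack, thr, cfg)
cm
#> CoordinateMatrix: vial 1 - 7 flies x 300 frames; 99.0% coordinates from detections

evaluateTracking(truth, cm, tolPx = 10)
#> AccuracyReport ( 7 flies x 300 frames )
#>   fraction correct (tol 10 px): 0.9900
#>   mean localization error (correct frames): 0.107 px
#>   identity-switch frame fraction: 0.0167
#>   missing-coordinate fraction: 0.0095
#>   large-jump fraction (top 1%/vial length): 0.0319
```

99% of the 2100 per-fly positions land within 10 px (~2 mm) of the true
position, with a mean error of ~0.1 px; identity switches touch ~1.7% of
frame transitions (they occur when flies collide, and the downstream
analytics use anonymized single-fly data, so switches do not degrade the
metrics).

Behavioral metrics from the tracked coordinates:

```r
trajs <- toPhysical(cm, p$roiHeightPx, p$pxPerMm)    # mm, y up from bottom
s <- summarizeGroups(list(demo = list(trajs)), cfg)
s
#> GeotaxisSummary: 1 group(s)
#>   demo: 7 flies, mean AveSpeed 13.40 mm/s

fly1 <- s$Group[[1]]$Fly_no[[1]]
sprintf("AveSpeed %.2f mm/s, AveAngle %.1f deg, TurnRate %.1f turns/s",
        fly1$AveSpeed, fly1$AveAngle, fly1$TurnRate)
#> "AveSpeed 13.49 mm/s, AveAngle 40.7 deg, TurnRate 26.3 turns/s"
```

`AveSpeed` is the mean gated frame-pair speed, `AveAngle` the mean defined
movement angle (+90° is straight up, so 40.7° reflects a strong upward
bias), and `TurnRate` counts non-zero direction changes per second.
`s$Group[[g]]$ClimbCurves` holds the climbing curves at the configured
target heights, and `Fly_no[[f]]$Drops` the detected slips and falls.

A command-line interface wrapping the same functions is installed at
`exec/geotrack` (`track`, `analyze`, `simulate`, `evaluate` subcommands).

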