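---
title: "Models and design choices in mobisense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in mobisense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobisense)
```

mobisense processes passively sensed smartphone streams — location fixes,
activity-recognition labels, cumulative app-usage counters and inertial
bursts — into daily behavioral measures, with a privacy transform applied
to location before storage. This vignette explains the models behind each
stage, the parameters that matter, and the choices we made where the
design was genuinely open.

## Geodetic machinery

Coordinates arrive as WGS-84 geodetic latitude/longitude/height. The
package converts to Earth-centered Earth-fixed (ECEF) Cartesian
coordinates with the standard ellipsoid mapping (semi-major axis
a = 6 378 137 m, flattening f = 1/298.257223563, fixed and not
configurable), and back by fixed-point iteration on the latitude
(tolerance 1e−12 rad, capped at 15 iterations; round-trip position error
stays below 1e−6 m for |lat| ≤ 89.9° and heights in [−500, 9000] m). The
iteration was preferred over the closed-form alternative for clarity; at
the tolerance used the two are numerically indistinguishable. Local
East-North-Up (ENU) tangent frames provide the right-handed orthonormal
basis used to embed simulated paths and to express local offsets.

Distances use the haversine great-circle formula on the mean-Earth sphere
(R = 6 371 000 m). Against ellipsoidal geodesics this is at most ~0.6 %
off — far below the GPS-noise and windowing error of any daily-mobility
measure — and it makes the distance kernel symmetric, exact and cheap.
Ellipsoidal (Vincenty/Karney) geodesics, projected CRS support and
orthometric heights are deliberately out of scope.

## Keyed trajectory anonymization

Each subject's key holds a fake anchor — latitude area-uniform in
[−60°, 60°], longitude uniform — and a rotation angle uniform in
[0°, 360°), all deterministic in an integer seed. The transform is a
single rigid rotation of the sphere composed in Cartesian space: the
rotation carrying the true anchor direction onto the fake anchor
direction, preceded by a twist about the local vertical at the anchor.
Altitudes, timestamps and accuracies pass through unchanged; the anchor
maps exactly onto the fake anchor; the anonymized output contains only
`lat, lon, alt, t, accuracy` — no field from which the seed, angle or
true anchor could be read.

Three choices deserve comment:

* **Full anchor relocation.** Relocating only the latitude would leave the
  true longitude readable from the output, contradicting the guarantee
  the transform exists to provide; we relocate both coordinates and treat
  this as a deliberate strengthening.
* **Rotation of the sphere, not a tangent-plane re-embedding.** An
  alternative realization rotates ENU offsets at the true anchor and
  re-embeds them in the fake anchor's tangent frame. That variant
  preserves true 3D distances but *not* the haversine metric: geodetic
  latitude is a distorted coordinate on the ellipsoid, so carrying a
  trajectory across latitudes shifts haversine distances by up to ~0.5 %.
  Because every mobility measure downstream is defined in the haversine
  metric, we rotate the sphere itself: an orthogonal map preserves every
  central angle, hence every great-circle distance, exactly — at any
  span, with no small-trajectory assumption.
* **Fake-anchor latitude clamped to [−60°, 60°].** Polar anchors make
  longitude a near-degenerate coordinate for downstream consumers
  (display, binning); the clamp costs nothing in unlinkability.

The identity key (fake anchor = anchor, angle 0) reproduces the input to
below 1e−6 m, which pins the numerical floor of the whole round trip.

## Stream schemas

Records are JSON-Lines, one object per line, keys in a fixed per-modality
order, full numeric precision — so writing the same records twice is
byte-identical and MD5 manifests of a data tree are reproducible.
Readers validate everything: the six-class activity vocabulary (walking,
running, still, on_bicycle, in_vehicle, tilting) is closed and unknown
labels are rejected rather than coerced, since silent coercion would
corrupt the fusion; usage counters must be non-decreasing within a
(date, app) day; location timestamps strictly increasing. Daily
boundaries ("since the previous midnight") are taken in the study's IANA
time zone, default UTC. The on-disk layout
`data/<study>/<subject>/<YYYY-MM-DD>/<modality>.jsonl` makes per-day
completeness checks trivial.

Enrollment payloads carry exactly what a device needs to join — user ID,
study ID, server address, optional auth token — rendered as compact JSON
with fixed key order so derived code images are reproducible. Codes are
one-time: a registry marks each consumed on first redemption and rejects
replays; two backups per subject are generated by default so participants
can re-join or switch devices. The package generates the payload strings
and registry; rendering them as scannable images is left to any standard
QR encoder.

## Fusion parameters

The fusion thresholds are package defaults, overridable per study:

| parameter | default | unit | rationale |
|---|---|---|---|
| `confidence_min` | 50 | % | majority confidence from the recognizer |
| `foot_classes` | walking, running | — | locomotion by foot |
| `max_foot_speed_mps` | 4.0 | m/s | a fast run; faster segments are vehicle travel |
| `max_fix_accuracy_m` | 50 | m | ~3.5× the 14 m median accuracy of fused positioning |
| `activity_staleness_min` | 5 | min | one recognition period on either side of a segment |

A segment between consecutive fixes counts iff both fixes pass the
accuracy gate, a qualifying foot-class record falls within the widened
segment span, and the implied speed respects the cap; qualifying
great-circle distances are summed per the calendar date of the segment
midpoint (midnight-crossing segments go wholly to the midpoint's day —
a bias of less than one segment per day). Usage aggregation takes per-day
*maxima* of the cumulative counters; summing snapshots would double-count
by construction. Decreasing counters within a day are flagged and
resolved by the maximum. Calls and SMS are ordinary category entries of
the same pipeline.

## The synthetic cohort

The generator exists so that every stage has ground truth. Defaults
emulate a two-week pilot cohort of 21 subjects. Per subject-day:

* **Behavior** is a semi-Markov chain over the six classes with
  exponential dwell (means, minutes: still 60, walking 15, running 6,
  on_bicycle 12, in_vehicle 18, tilting 2). Every non-still bout returns
  to still — people pause between activities — and still exits to
  walking/running/bicycle/vehicle/tilting with weights
  .18/.05/.06/.12/.59. These settings yield roughly 3–6 km on foot and
  ~45 min of vehicle travel per day, a realistic adult profile.
* **Movement** integrates a piecewise-constant-speed path (still 0,
  walking 1.4, running 2.8, bicycle 4.5, vehicle 13 m/s, tilting 0) on a
  1-minute grid with a heading random walk (sd 4°/min) and a pull back
  toward the subject's home beyond a 5 km radius.
* **Location** fixes sample the path every 10 min with isotropic Gaussian
  noise (sd 10 m); the reported accuracy field is lognormal with median
  pinned at 14 m (sdlog 0.35), matching the median accuracy of fused
  GPS/network positioning.
* **Activity** records every 5 min label the current state with
  confidence ~ Uniform(60, 100); with probability 0.05 the label flips to
  the kinematically confusable partner (walking↔running,
  bicycle↔vehicle, still↔tilting). Structured confusion is what real
  recognizers produce; uniform confusion would let vehicle segments
  masquerade as walking, which no deployed recognizer does at meaningful
  rates.
* **Usage** draws per-app daily totals from a Gamma (shape 4) around each
  app's mean and emits six cumulative, non-decreasing snapshots; the last
  snapshot carries the full total, so a max-based aggregator recovers the
  truth exactly.
* **Inertial bursts** (generated on request; the streams are bulky at
  50 Hz) model the accelerometer as gravity on z plus a class cadence
  (walking 2 m/s² at 1.8 Hz, running 4 m/s² at 2.6 Hz) plus noise
  (sd 0.2), and the gyroscope as the same oscillation at 0.1× scale.
  Bursts of 10 s at each activity-segment start mirror duty-cycled
  capture that pauses while the phone is still.

The ground-truth odometer integrates haversine distance over the
minute-grid path during walking/running minutes — the same fine-step
integrator and metric the fixes are embedded with — so truth and streams
are consistent by construction. Everything is deterministic in the seed,
down to the emitted bytes.

What the generator does *not* emulate: road networks and urban geometry,
phone placement effects on the IMU, multipath/urban-canyon GPS error,
battery and sync dropout beyond a uniform per-record `dropout_frac`, and
any weekly or circadian structure in behavior. Passing tests therefore
show that the pipeline recovers truth under honest noise of the right
magnitudes, not that it is robust to every pathology of field data.

## Self-reports and correlation recovery

Self-reports distort truth multiplicatively:
`report = truth × (1 + bias) × exp(ε)`, ε ~ N(0, sd²) — positive,
right-skewed, perfectly rank-correlated with truth in the noiseless
limit. `calibrate_report_sd()` solves for the sd at which the expected
*sample* Pearson correlation with a fixed truth sample equals a target ρ,
by Monte Carlo with common random numbers (200 replicates). A closed-form
moment ratio was rejected: for right-skewed daily distances its
theoretical variance term overstates what a 300-point sample realizes,
which biases recovered correlations upward by ~0.05.

The association analysis pools all subject-days (no per-subject
averaging first); a subject-mean variant sits behind `by_subject = TRUE`
for sensitivity analysis. Cells with fewer than three aligned pairs are
reported missing rather than raising. Observed field correlations between
self-report and passive measures depend on participant data no simulation
can stand in for; the package's claim is parameter recovery on synthetic
cohorts of the same design (21 subjects × 14 days), with the sample r
landing in the Fisher 95 % band around the calibrated ρ.

## Quality control

Expected daily record counts derive from the study configuration
(144 location fixes at the 10-min period, 288 activity records at 5 min,
one usage snapshot, 86 400 × f inertial samples as an informational
figure). Completeness ratios are received/expected clipped to [0, 1.5];
labels are green ≥ 0.8, red < 0.3, yellow between — thresholds are
package defaults (the platform's actual dashboard thresholds are not
published) and overridable. The inertial modalities are labeled green
whenever any data arrived, red otherwise, because duty-cycled capture
legitimately pauses while the device is still. A subject is active iff
not left and data arrived within `inactivity_days` (default 3).

## Problem sizes and determinism

The test-suite and acceptance computations run at the scale the methods
are specified for: 100 random trajectories × 20 points for the isometry
property, 1 000 random points for geodesy round-trips, 50 simulated days
for foot-distance recovery (reported pooled: the ensemble total of the
estimate against the ensemble total of the odometer — single low-distance
days are noise-dominated, and the pooled figure is what a cohort analysis
consumes), one 21 × 14 cohort (294 subject-days) for correlation
recovery, and ≥ 10 000 fixes for the accuracy-median calibration. All
randomness flows from explicit integer seeds; simulation under a fixed
seed is byte-reproducible.

## Known limitations

* Foot distance is chord-based between 10-min fixes: it undercounts
  curved walks and cannot see movement between fixes; the staleness
  window admits small noise-chord contributions from still segments
  flanking a walking bout. The two effects partially cancel; pooled
  recovery error is a few percent under the generator's conditions.
* The anonymization preserves distances exactly but also *only*
  distances: bearing structure relative to true north is rotated, and
  any analysis needing absolute orientation must run before the
  transform.
* Completeness counts records, not information: a day of zero-accuracy
  fixes counts as complete.
* Correlation analysis treats subject-days as exchangeable; within-subject
  dependence inflates the nominal significance of pooled p-values.
  Mixed-effects modeling is out of scope by design.
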