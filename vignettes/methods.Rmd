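---
title: "Methods: models, conventions and the trial simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and the trial simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmapr)
```

## Scope

`fmapr` analyzes instrumented functional-mobility trials: a chair-based
movement sequence recorded with marker-based motion capture (lab frame:
x = anteroposterior, y = mediolateral, z = vertical, meters) and an
optional pressure mat (center-of-pressure trace, millimeters). Four
protocols are segmented and scored:

* **fmap** — stand up from a chair, walk a 3 m walkway passing a
  doorframe at 1.5 m, turn 180°, pick a key at 2.25 m on the return
  path, walk back, sit down;
* **tug** — the same without doorframe and key (plain Timed-Up-and-Go);
* **standing** — quiet stance, scored over a 10 s window;
* **locomotion** — straight overground walking.

## Preprocessing model and assumptions

Marker trajectories are assumed to be rigid-body landmarks sampled at a
constant rate (100 Hz in all defaults) with occasional occlusion gaps and
isolated reflection spikes.

* **Gap filling** (`fill_gaps`): gaps of at most 10 frames are
  reconstructed with a local cubic polynomial fitted to the surrounding
  valid frames; gaps of at most 100 frames use a cubic smoothing-free
  interpolation spline; longer gaps, and any gap touching the recording
  boundary (where interpolation would extrapolate), are excluded — the
  frames stay invalid and `exclusion_check()` decides whether the
  affected task windows are usable.
* **Despiking** (`despike`): a 15-sample centered moving average. This is
  deliberately linear: an isolated spike of height *h* survives as
  *h*/15 at its center (the suite tests exactly this attenuation), and
  linear trends pass through unchanged away from the boundaries.
* **COP filtering** (`filter_cop`): 5th-order Butterworth low-pass at
  10 Hz applied forward and backward (zero lag). Zero-phase filtering is
  load-bearing: event timing extracted from filtered signals must not be
  shifted against the marker clock.
* **Differentiation** (`deriv_central` on low-passed input): a 4th-order
  zero-lag Butterworth at 6 Hz precedes every central-difference
  derivative. Derived quantities such as jerk are therefore
  filter-dependent; the filter is part of the declared method, and jerk
  magnitudes are only comparable within this configuration.

## Events and segmentation

Footfalls from the pressure mat override marker-based detection: heel
strike is the first active frame of a stance, toe off the last. A stance
already active at the first recorded frame yields no heel strike, and one
still active at the last frame yields no toe off — those stances are
incompletely observed. Strides pair consecutive ipsilateral heel strikes
with exactly one toe off between them. Without a mat, events fall back to
coordinate-based detection from heel/toe marker kinematics.

Task segmentation walks the protocol's expected order using pelvis
height (chair transfers), pelvis anteroposterior position (walkway,
doorway passage at the doorframe plane), trunk yaw (the 180° turn, sign
normalized so clockwise and counterclockwise turns read identically) and
wrist excursion (functional reach). The reach segmenter clusters
below-threshold wrist-depth runs and merges runs closer than 1 s, so one
grab with a brief hesitation counts as one attempt. Walking resumes after
a task at the first toe off following the task's end; that convention
keeps gait re-initiation steps out of the turn and reach windows.

Trunk inclination for segmentation uses the heading-invariant bend angle
`atan2(sqrt(ap² + ml²), vertical)` of the trunk vector, so the signed
anteroposterior component flipping direction after the 180° turn cannot
break event detection.

## Metric definitions

Per segment, the pipeline (`analyze_trial`) computes trunk inclination
and dynamics, pelvis/knee flexion, segmental yaw profiles (absolute and
relative head/trunk/pelvis yaw, onset percentages — the craniocaudal
sequence), toe-off/heel-strike foot angles and minimum foot clearance,
spatiotemporal gait parameters with left/right asymmetry and
coefficient-of-variation summaries, signed arm swing and the arm-swing
asymmetry index, stance geometry during reach, COP displacement
statistics, and freezing-like events (speed below 10 % of a baseline for
at least 0.5 s, doorway-attributed on overlap). Metrics whose
preconditions fail are skipped with a warning, never fabricated.

```{r asa}
asa(30, 30)    # perfect symmetry
asa(30, -30)   # equal and opposite
asa(30, 15)    # 2:1 ratio
```

## Statistics

* **Imputation** (`impute_pmm`): predictive mean matching within
  group-by-protocol clusters, m = 5, donor pool 5, mean-pooled;
  fully seed-reproducible, imputed values are always observed donor
  values. Missingness between 5 % and 20 % is flagged as the band where
  multiple imputation is recommended; above 20 % a warning is raised.
* **Group analysis** (`run_group_analysis`): per metric, subject means
  per protocol are modeled as a mixed design — protocol within subject,
  group plus age, sex and height (plus foot length for foot-geometry
  metrics) between subjects — with type-III tests and sum-to-zero
  contrasts. Treating protocol as a within-subject factor keeps the
  group test calibrated when a subject's two protocol values are
  correlated; in null simulations the family-wise false-positive rate of
  the naive pooled model inflated to ~14 % while the mixed design stays
  at the nominal 5 %. With only two within levels sphericity holds
  trivially, so no correction is applied.
* **Multiplicity**: parameters are grouped into per-task families
  (`default_families`), each family's alpha split Bonferroni-style.
* **Phase analysis** (`run_phase_analysis`): Baseline/Pre/Post
  repeated-measures ANOVA with Mauchly's test and Greenhouse–Geisser
  correction on violation, followed (when significant) by the three
  paired contrasts with `p_adj = min(1, 3p)`.
* **Reliability** (`icc_oneway`): one-way random-effects ICC for single
  and averaged trials.

## The trial simulator: scope and limits

`simulate_trial` animates a marker-level avatar from an explicit step
schedule: footfall positions and times are generated first, and those
scheduled frames *are* the emitted ground truth — the simulator cannot
disagree with itself. Body segments (pelvis, trunk, head, arms, feet)
are driven by smooth cosine interpolants between postural keyframes;
scripted freezing episodes warp time with cosine ramps; marker noise and
COP noise are additive Gaussian.

Design choices worth knowing:

* On the 3 m walkway, integer step counts are fit to the scripted
  distance, so realized stride length is shorter than the open-ground
  parameter; the ground truth reports the realized schedule. Use the
  locomotion protocol for open-ground gait.
* Ground-truth gait is windowed to the walking segments exactly as the
  pipeline windows strides, so transition steps around the turn are in
  neither.
* Scripted turn direction mirrors the footfall pattern (inside foot is
  left for counterclockwise turns).
* Plateau-shaped extrema (e.g. held trunk bend) are scripted with short
  holds so that peak metrics are insensitive to one-frame timing error.
* Freeze durations recovered by the detector are slightly shorter than
  scripted because the cosine speed ramps spend their tails above the
  10 % threshold; tests allow 0.3 s for this.
* The simulator does not model soft-tissue artifact, marker relabeling
  errors, non-Gaussian mat noise, festination, dyskinesia or postural
  tremor. It validates the *analysis chain*, not clinical realism.

`simulate_cohort` additionally provides a fast metric-level generator
(subject random intercept + injected group/protocol/interaction/phase
effects + residual noise) for power and false-positive studies, and a
slow trial-level mode that runs full avatars through the pipeline.

## Open-design rationale

Every threshold in the package (gap limits, filter orders and cutoffs,
freeze threshold and minimum duration, stride minimums, family
memberships) is an explicit, documented function argument rather than a
buried constant, so a study can both reproduce the defaults exactly and
state its deviations precisely.
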