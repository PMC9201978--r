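---
title: "Marker-based gait event detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based gait event detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitevents)
```

## The problem

Spatio-temporal gait analysis rests on two events per foot and cycle: the
initial contact (IC), when the foot first touches the ground, and the final
contact (FC), when it leaves it. In an optical motion-capture laboratory
these events must be inferred from marker kinematics alone — here from a
minimal set of four foot markers (left/right heel and second metatarsal
head) and an optional four-marker rigid cluster on the pelvis. The package
implements ten published detection rules (M1–M10 below), classifies walking
conditions (straight walking, turning, step negotiation), derives stride
parameters, and quantifies agreement with reference events, so that the
whole chain can be validated end to end.

## Preprocessing

All trajectories are gap-filled (cubic natural splines, only for interior
gaps shorter than 0.5 s), then low-pass filtered with a zero-lag
fourth-order Butterworth filter at 7 Hz. Zero phase is obtained by
forward–backward filtering with odd-reflection padding and steady-state
initial conditions, so a constant signal passes through bit-faithfully and
time reversal commutes with the filter to numerical precision. Velocities,
accelerations and jerks are central differences of the filtered positions
(one-sided at segment edges; exact for polynomials up to degree two).

A pelvis anatomical frame is built per sample: the medio-lateral axis ML is
the unit vector from the left to the right cluster marker (P0 to P1); the
anterior–posterior axis AP is the unit normal of the plane through P0, P1
and P3; the vertical axis V = ML × AP. Two signs are not determined by the
geometry alone: AP ("forward") is disambiguated by its projection on the
smoothed pelvis-origin velocity, with a 0.05 m/s hysteresis so the sign
cannot flutter when the subject is nearly stationary, and V is flipped if
needed to point cranially (against the trial's vertical hint, by default
the laboratory +z). Derivative components are computed as the projection of
the *global* derivative onto the instantaneous frame axis — not as the
derivative of the decomposed scalar — which avoids spurious terms from
frame rotation during turns. The pelvis markers themselves are filtered
before the frame is built: with unfiltered cluster markers, millimeter-level
marker noise on a ~0.2 m baseline tilts the axes by several milliradians
per frame and leaks centimeter-scale artifacts into relative positions.

## The ten detectors

| Method | Signal | IC rule | FC rule |
|---|---|---|---|
| M1 | position | local maxima of heel AP relative to pelvis | local minima of toe AP relative to pelvis |
| M2 | position | first maximum of high-pass-filtered heel/toe AP | last minimum of the two |
| M3 | velocity | local minima of mid-foot vertical velocity | local maxima |
| M4 | velocity | sagittal heel speed < 0.5 m/s | sagittal toe speed > 0.5 m/s |
| M5 | velocity | 3D heel speed < 0.5 m/s (toe < 0.5 for forefoot) | 3D toe speed > 1.0 m/s, refined |
| M6 | velocity | sagittal heel speed < 0.78 × walking speed | sagittal toe speed > 0.66 × walking speed |
| M7 | velocity | 3D heel speed < 0.5 × ws (toe < 0.8 × ws) | 3D toe speed > 0.8 × ws, refined |
| M8 | acceleration | maxima of heel vertical acceleration, jerk ≈ 0 | maxima of toe AP acceleration, jerk ≈ 0 |
| M9 | acceleration | minima of heel AP acceleration | maxima of toe AP acceleration |
| M10 | fusion | M1 anchors refined by M7 | M1 anchors refined by M7 |

The 3D-velocity detectors (M5/M7) handle both strike patterns. Two
candidate sets are kept per cycle: downward threshold crossings of the heel
speed (`tIC_H`) and of the toe speed (`tIC_T`). If `tIC_H ≤ tIC_T` the
contact is a rearfoot strike at `tIC_H`; otherwise, if the toe marker is
below the heel marker at `tIC_T`, it is a forefoot strike at `tIC_T`; else
rearfoot at `tIC_H`. For the final contact, each upward toe-speed crossing
centers a 100 ms window in which a local peak of the heel speed is sought —
the signature of the foot starting to rotate about the ankle. If found, the
event is placed at the sample following the peak (the discrete
zero-acceleration instant; the continuous zero crossing is deliberately not
interpolated, since the native resolution is one sampling period);
otherwise the toe crossing itself is used.

The walking speed used by the adaptive detectors (M6/M7, and hence M10) is
the mean stride speed over both sides, with initial contacts bootstrapped
from the fixed-threshold M5 and stride displacement measured on the heel
marker in the horizontal plane.

M10 fuses position and velocity: M1 provides candidate events (its pelvis
anchor suppresses false positives), each refined to the nearest same-side,
same-type M7 event within 0.25 s (half the validation tolerance window; the
fusion window is a package choice, made once). Unmatched M1 events are
retained with unknown strike — M1 is the base estimate — while unmatched M7
events are discarded unless they fall where the pelvis markers are
occluded, in which case they are emitted directly. With the pelvis absent
or fully occluded, M10's output is exactly M7's.

### Numerical conventions shared by the detectors

* **Threshold crossings are debounced**: an event fires at the first sample
  satisfying the inequality after at least `min_event_separation` (default
  0.2 s) of continuous non-satisfaction. This suppresses chatter near
  thresholds — e.g. the small heel-speed bump during the ankle rocker never
  produces a spurious IC because the speed exceeds the threshold too
  briefly beforehand.
* **Peak detectors** (M1–M3, M8–M9) apply a prominence floor of 1% of the
  signal range and the same minimum separation.
* Candidate grouping for M5/M7 uses the interval between consecutive
  upward toe-speed crossings as the gait cycle.
* All quantiles, everywhere in the package, use linear interpolation
  between order statistics (R type 7).

## Walking conditions

**Curvilinear walking (CW)** is found from the pelvis yaw — the heading of
the AP axis projected on the horizontal plane, unwrapped, with its rate
smoothed by the same 7 Hz filter. Candidate cores are maximal runs with
|yaw rate| ≥ 15°/s, widened while the rotation continues (|yaw rate| ≥
1°/s) and merged across gaps below 0.2 s; a segment is accepted when the
**net** rotation is at least 45°, the peak rate at least 15°/s, and the
duration between 0.5 and 10 s. Two choices deserve a note. First, the
cumulative rotation is the net |yaw(end) − yaw(start)|, not the total
variation: merged gait-sway oscillations then cancel, so a ±15° sway never
accumulates into a spurious turn. Second, the widening threshold is 1°/s
rather than a larger value: a slow, wide rotation (say 50° spread over
11 s) then remains one segment whose net rotation passes the 45° test but
whose duration exceeds 10 s, and is rejected for that stated reason —
with a higher widening threshold the same maneuver would fragment and be
rejected for the wrong reason (insufficient rotation), which misreports the
rule that fired. The duration constraint applies to the widened segment.

**Step negotiation (SN)** compares the heel height (laboratory vertical —
a step is a world quantity, while the pelvis V axis tilts with posture) at
consecutive same-side initial contacts: a strict difference above 0.15 m
spans an SN segment between the two contacts. Unfiltered positions are
used: the heel is stationary at contact, and filtering would bleed swing
samples into the stance value, corrupting the exact-boundary case. The
strict inequality is guarded by a 1 nm representation-error epsilon.

Every event gets exactly one label: SN if inside any SN segment (SN takes
precedence over CW on overlap — a step during a turn is the rarer, more
specific stratum), else CW, else SW. A stride is SN if at least one of its
bounding ICs is SN, else CW by the same rule, else SW.

## Strides, bouts and parameters

A stride runs between consecutive same-side ICs; the unique same-side FC
strictly inside splits it into stance and swing (absent or ambiguous FCs
are flagged, not guessed). Stride length is the Euclidean norm of the
*horizontal-plane* heel displacement between the bounding ICs — the chord,
not the arc, so a turn shortens the stride rather than inflating it, and
vertical motion on a step does not enter (a `projection = "3d"` option
exists). Speed is length over duration. Unfiltered heel positions anchor
these quantities for the same reason as in SN detection. Walking bouts are
maximal episodes with inter-IC gaps below 3 s containing at least two left
and two right strides; strides outside bouts are excluded from validation.

## Validation metrics

Detections are matched to reference events one-to-one inside a tolerance
window of 0.5 s centered on each reference event: references are processed
in time order, each taking the nearest unmatched detection within ±0.25 s.
The assignment rule is a package choice (only the window is prescribed by
the validation conventions this package follows); the test suite compares
it against an exhaustive optimal matcher on random event sets and the
time-ordered greedy matcher occasionally (a few times per hundred random
sets) yields one fewer pair than the optimum — an accepted, documented
property. Reference events rendered undetectable by foot-marker occlusion
are excluded before matching.

From the matched sets: sensitivity S = TP/(TP+FN), positive predictive
value PPV = TP/(TP+FP), F1 their harmonic mean; timing errors Δt =
detected − reference (negative = anticipation) are summarized by the median
error (ME, bias), inter-quartile-range error (IQRE, precision) and median
absolute error (MAE, accuracy). For statistical summaries, false negatives
can be imputed: the method's maximum-magnitude observed error (keeping its
sign — "highest error" is read as worst, not largest positive) when more
than 5% of expected events are missing, the mean error otherwise; false
positives never enter the pool.

Stride-level errors are computed only for strides whose both bounding ICs
are true positives; the rest count as missing. Agreement uses the
single-measure, absolute-agreement, two-way intraclass correlation
ICC(2,1), computed from the ANOVA mean squares with the standard F-based
confidence interval, Spearman's ρ for relative agreement, and the
Bland–Altman quantities (bias, limits of agreement bias ± 1.96 SD, RMSE);
the Bland–Altman plot coordinates are exported rather than plotted.

## The synthetic simulator

Every property above is exercised against simulated trials with exact
ground truth. The foot model is built around the assumption the velocity
detectors rely on — **contact means a stationary marker**:

* During stance the markers do not move; ground truth takes the IC as the
  first stationary sample of the striking marker and the FC as the last
  stationary sample of the toe. Truth is recorded analytically before any
  noise is added.
* Swings follow raised-cosine displacement profiles along the walking
  path, with a single-hump heel clearance and a two-hump toe clearance.
* The heel performs a small "ankle rocker" velocity bump (0.35 m/s peak,
  below every IC threshold) peaking at toe-off — the physical feature the
  FC refinement keys on.
* The rearfoot pattern lands heel first (toe 80 ms later) and the forefoot
  pattern swaps the order, with the toe marker mounted lower than the heel
  marker so the forefoot height check discriminates.
* The pelvis cluster follows the path with small sinusoidal oscillations
  and a ±2° yaw sway at stride frequency; turns rotate the heading with a
  raised-cosine yaw-rate profile; steps add a smooth ground-height change
  along the path.
* Trials begin with both feet already in swing ("flying in" onto the first
  contact) and end with both feet planted. This realizes exact event
  counts — n+1 ICs and n FCs per side — without an initial toe-off that
  any velocity detector would correctly report but that would be absent
  from the ground truth.
* Gaussian noise (default off; 1 mm in the robustness conditions) is added
  i.i.d. per coordinate after truth extraction; occlusions blank requested
  spans; a given seed reproduces the trial bit-identically.

The validation corpus spans straight walks at 0.8/1.2/1.6 m/s, a forefoot
walk, a 180° U-turn, a 0.20 m step, a noisy walk and a pelvis-occluded
walk, all at 100 Hz with 10 strides per side by default (test fixtures use
4–10 strides to keep runtimes in seconds).

What the simulator does **not** emulate: soft-tissue artifact, residual
foot motion during stance (real feet are never perfectly still, so real
IC/FC definitions are softer), double-support timing consistency between
the two feet at the trial boundaries, pathological gait dynamics (impaired
gait is approximated only by slower speeds, shorter strides, noise and
occlusion), or camera-dependent noise spectra (noise is white). Perfect
scores on the simulator therefore demonstrate that the detectors implement
their rules faithfully under their own assumptions — not that they achieve
any particular accuracy on real recordings.

## Parameters at a glance

| Parameter | Default | Unit | Where |
|---|---|---|---|
| low-pass cutoff / order | 7 / 4 | Hz / – | preprocessing |
| gap-fill limit | 0.5 | s | preprocessing |
| forward-sign hysteresis | 0.05 | m/s | pelvis frame |
| `min_event_separation` (debounce) | 0.2 | s | all detectors |
| M4 thresholds (IC/FC) | 0.5 / 0.5 | m/s | detector |
| M5 thresholds (IC heel/toe, FC) | 0.5 / 0.5 / 1.0 | m/s | detector |
| M6 multipliers (IC/FC) | 0.78 / 0.66 | × walking speed | detector |
| M7 multipliers (IC heel/toe, FC) | 0.5 / 0.8 / 0.8 | × walking speed | detector |
| FC refinement window | 0.1 | s | M5/M7/M10 |
| M10 match window | 0.25 | s | fusion |
| M2 high-pass cutoff | 0.5 | Hz | detector (literature value not stated; exposed) |
| M3 height gate | 1.3 | × stance baseline | detector (exposed) |
| M8 jerk gate | 5 | % of jerk RMS | detector (exposed) |
| CW: rotation / rate / duration | 45 / 15 / 0.5–10 | ° / °/s / s | conditions |
| CW widening / merge gap | 1 / 0.2 | °/s / s | conditions (package choice) |
| SN height threshold | 0.15 (strict) | m | conditions |
| bout continuity gap | 3 | s | strides (package choice) |
| tolerance window TW | 0.5 | s | metrics |
| FN imputation switch | 5 | % missing | metrics |

## Known limitations

* The M2 high-pass cutoff and the M3 timing constraints are only sketched
  in the literature the rules come from; the defaults here are exposed in
  `detector_params()` and should be tuned before relying on M2/M3.
* The acceleration detectors (M8/M9) fire on every qualifying extremum;
  on the simulator they produce extra candidates at swing reversals, as
  acceleration-based rules are known to do.
* C3D support covers the common Intel-byte-order, marker-only case; analog
  channels are skipped and other byte orders rejected.
* Walking-speed estimation requires at least two initial contacts on one
  side; very short recordings must fall back to fixed-threshold methods.
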