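---
title: "Methods: grid-based hand-motion analytics and the behaviour simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid-based hand-motion analytics and the behaviour simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handmotion)
```

## The measurement model

A markerless hand-pose detector watching a surgeon emits, per video frame,
up to 21 landmarks per hand (wrist plus digit joints and tips). `handmotion`
treats that stream as the primary measurement and asks three questions:
how complete is the stream (detection accounting), where were the hands
(grid occupancy and dwell), and what was the surgeon doing away from the
field (workflow events)?

Coordinates are pixels with the origin at the top-left corner and y
increasing downward; "0 px" on the vertical axis is the top of the image,
which is where the microscope handles sit in the intended camera setup.
Frames are 0-based and each frame owns the half-open interval
`[i/fps, (i+1)/fps)`. The frame rate is mandatory session metadata with a
default of 30 fps, the common consumer-camera rate; every time-valued
statistic is frames divided by fps, so fps is the single time calibration.

Two distinct phenomena reduce the stream. *Tracking loss* — glare from the
microscope light at the frame centre, or a hand leaving the field of view —
is represented by the **absence** of records for that hand and frame.
A *null detection* — a detector emission without a left/right handedness
decision — is an explicit record with `hand = "none"` and no landmark
payload. Keeping these separate lets detection performance (which counts
all emissions) and per-hand occupancy (which needs handedness) stay
consistent with each other.

### Detection accounting

Detection performance is `100 * N_records / (N_frames * 42)`: the emitted
fraction of the theoretical stream of 21 landmarks x 2 hands x every
frame. Null records count toward the numerator but toward no hand and no
grid cell. Reported percentages and rates are **truncated** (floored) at
display precision, not rounded — this is the convention under which the
per-procedure performance and share figures derived from raw counts are
mutually consistent — while full precision is kept internally. One
published summary cell (the total null share, 0.07% of ~1.9 M records) is
printed at one decimal only under rounding; the tests treat that single
cell at its printed precision.

### The calibration grid

A 3x3 grid partitions the frame into cells numbered 1–9 row-major. Cell
semantics come from the scene: surgical field in cell 5, instrument table
in cell 4, microscope handles across the top row, trash bin in cell 7,
picture-in-picture microsurgical feed in cell 9 (geometry only). Equal
thirds of the frame is the parameter-free default; explicit edges can be
supplied when a calibration was drawn to scene landmarks instead. Bins are
half-open with the right/bottom frame edge closed into the last
column/row, so every in-frame point belongs to exactly one cell — the
partition property is tested exhaustively on small frames.

Occupancy uses landmark 12 (tip of the middle finger) by default; it is a
parameter because nothing in the metric depends on which landmark proxies
the hand. Dwell time per cell sums **both** hands, so per-cell totals are
bounded by twice the session duration, and undetected frames contribute to
no cell. This gives the exact conservation identity checked by the tests:
summed dwell frames plus undetected frames equal `2 * N_frames`.
Cross-procedure aggregation reports the arithmetic mean and sample SD
(n−1) per cell.

### Workflow events

Excursions of the dominant hand away from cell 5 are the visible
correlates of workflow: reaching the instrument table to change a drill
burr, reaching up to the microscope handles to adjust zoom/focus, visiting
the trash. Rather than thresholding raw coordinate spikes, events are
defined on the cell-occupancy series, which makes classification
parameter-light:

1. undetected runs shorter than `gap_fill_s` (default 0.5 s) inherit the
   preceding cell, so brief glare dropouts do not split one reach in two;
2. maximal runs outside cell 5 become candidate events;
3. consecutive same-kind candidates separated by less than `merge_gap_s`
   (default 1 s) merge, absorbing momentary returns to the field;
4. events shorter than `min_duration_s` (default 0.5 s) are dropped — no
   deliberate reach completes in half a second.

Classification is by cells visited with precedence microscope > instrument
> trash > other: a sweep to the handles necessarily crosses other cells,
so any top-row visit dominates; of the remainder, a visit to cell 4 marks
an instrument change, then cell 7 a trash visit. The defaults are
overridable; raising `min_duration_s` or `merge_gap_s` never increases the
event count in the realistic regime the property tests sample (with events
near the duration threshold, merging can in principle rescue an event that
filtering would have dropped, which is why the monotonicity checks run on
simulated surgeon behaviour rather than adversarial series).

Greedy interval matching against a known schedule (`match_events`) reports
precision, recall and per-boundary timing errors; it exists to validate
the segmentation against the simulator, not to score surgeons.

## The behaviour simulator

No public landmark recordings of this kind exist, so the package carries a
first-class simulator whose output feeds every pipeline stage and whose
internal schedule doubles as ground truth.

**Semi-Markov states, not frame-wise Markov.** Surgeon behaviour is
dwell-dominated — minutes of drilling punctuated by reaches of seconds —
and event *durations* are the quantity of interest, so states carry
explicit dwell distributions. Drilling bouts alternate with excursions
drawn by configurable transition probabilities (defaults 0.4 instrument
change, 0.4 microscope adjustment, 0.2 trash).

**Lognormal dwells with a physical floor.** Dwell durations are lognormal
(positive, right-skewed, matching the large SDs such reaches show),
parameterised by natural-scale mean/SD. Default excursion means follow the
regime the analysis targets: instrument changes 21.5 s (SD 12.4),
microscope adjustments 4.4 s (SD 5.7), trash visits 5.5 s (SD 9.1).
Drilling bouts default to mean 55 s (SD 25): with the transition defaults
this yields roughly four instrument changes and four microscope
adjustments per 600 s procedure, a realistic operating tempo. Draws below
a floor (2 s for excursions, 5 s for drilling) are resampled: a deliberate
reach physically takes a couple of seconds, and the floor keeps true
events from falling under the segmentation's own minimum-duration
threshold, which would make ground truth unrecoverable by construction. A
final excursion that cannot complete before the session ends is replaced
by drilling — procedures end mid-drilling, and truth never contains
truncated event stubs.

**Ornstein–Uhlenbeck trajectories.** Each wrist follows
`p[t+1] = p[t] + theta * (anchor - p[t]) * dt + sigma * sqrt(dt) * eps`,
a mean-reverting walk toward the active state's anchor: smooth, bounded,
with tunable micro-motion standing in for drilling tremor (defaults
`theta = 8`/s, `sigma = 30` px/sqrt(s), giving a stationary tremor SD of
~7.5 px and transition transients shorter than 5/theta ≈ 0.6 s). The
anchor is placed so that **landmark 12** — the occupancy proxy — sits at
the target cell centre; anchoring the wrist instead would let the
fingertip's travel path clip neighbouring cells (the trash reach would
graze the instrument-table cell) and misclassify excursions. The 21
landmarks are a rigid stylised hand template around the wrist (scale 60 px,
mirrored for the left hand) with 1.5 px per-landmark jitter; the two hands
sit 80 px either side of the shared anchor line. Microscope reaches sample
their handle from the top-row cells (weights 0.25/0.5/0.25), so top-row
activity spreads across cells 1–3 as real sessions show.

**Dropout and nulls.** Whole hand-frames are dropped with probability
`p0`, plus `p1` when the wrist is inside a disc of radius `radius_px`
around the frame centre — the minimal geometry consistent with
glare-driven loss at the centre of the image. Defaults `p0 = 0.10`,
`p1 = 0.05`, `radius = 150` px put default sessions near 86% detection
performance, the regime the analysis is calibrated against (a constant
`p0 = 0.14` reproduces it exactly in expectation, which is what the
calibration test uses, with agreement judged within three binomial
standard errors). Null records are injected per hand-frame at
`p_null = 0.02`, landing the null share near 0.1% of records. Coordinates
are clipped to the frame and written with two decimals, which makes
file round-trips bit-exact.

**What the simulator does not emulate.** Real detector noise is not
i.i.d.: dropout is autocorrelated with hand pose and lighting, landmark
jitter is structured, and real hands articulate rather than translate as a
rigid template. Bimanual coordination is reduced to "non-dominant hand
drills throughout". Passing the recovery tests therefore shows the
pipeline is correct *given* the session format and its statistical
envelope — not that any particular real-world detector meets that
envelope.

## Numerical choices and degenerate inputs

- Truncation (`trunc_decimal`) is the reporting convention; all
  computation keeps double precision. Conservation checks compare integer
  frame counts, which are exact.
- `findInterval` with a closed right edge implements the half-open bins;
  out-of-frame points return `NA` and behave as tracking loss downstream.
- Empty sessions are valid (performance 0%, empty event lists, header-only
  files); shares and aggregate SD stop with a clear error where they are
  undefined (no records; fewer than two procedures).
- Event boundary conventions: an event spans inclusive frames
  `[start_frame, end_frame]` with `duration = (end - start + 1)/fps` and
  half-open times `[start_frame/fps, (end_frame + 1)/fps)`.
- Seeds: batches derive per-session seeds from one master seed via
  `sample.int`, so any session of a batch is individually reproducible.

## Problem sizes used in the test suite

Unit and property tests run on 10–120 s sessions, which exercise every
code path at a few hundred thousand records total. The end-to-end checks
use the full study conditions — 600 s procedures at 30 fps (756,000
possible records each): twenty seeded sessions for event recovery, three
for dropout calibration, and a three-procedure batch for the heatmap
shape. These sizes were chosen so the complete suite documents the
full-scale behaviour while remaining a coffee-break run.

## Known limitations

- The event definitions are one consistent reading of "spikes toward a
  semantic cell"; sessions where instrument changes happen *within* the
  centre cell are invisible to a grid-occupancy definition.
- Dwell and event statistics inherit whatever bias the detector has
  (e.g. glare-correlated loss near the field deflates centre-cell dwell
  for both hands equally).
- The grid is 2-D and fixed; no perspective correction is attempted, so
  cell semantics assume the camera position that drew the calibration.
- Skill-level discrimination is out of scope: the package measures motion,
  it does not grade surgeons.
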