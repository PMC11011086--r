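---
title: "Scoring dog sleep from video: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring dog sleep from video: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dogsleep)
```

## The problem and the model

Behavioural sleep scoring treats a dog as asleep whenever it is in a
resting position with no perceivable movement. That operational
definition is what makes video automation possible: sleep versus
wakefulness reduces to *movement versus stillness* inside the region of
the frame occupied by the dog. `dogsleep` implements that reduction in
three layers.

**Detection is a contract, not a model.** In a deployed system the
per-frame dog locations come from a trained network. Training data,
architecture and weights are not reproducible from published
descriptions, so the package deliberately isolates everything
downstream of detection: any function producing boxes per frame can
drive the pipeline, and the bundled `groundTruthDetector()` /
`staticRoiDetector()` make the downstream algorithm testable in
isolation. Tracks are formed by greedy association in descending IoU
order with a default minimum IoU of 0.3 — kennelled dogs move slowly
relative to the frame rate, so greedy matching is adequate and an
optimal assignment solver would add complexity without changing
behaviour on this data. Ties in IoU are broken by detection order, so
association is deterministic. A subject that is not detected in a frame
is UNKNOWN for that frame; missing detections are never interpolated,
because interpolating a box would manufacture evidence of stillness
exactly where the detector failed.

**Motion is frame differencing.** For each tracked subject the crops of
the current and previous frame are compared by the classical six-step
recipe: grayscale conversion, Gaussian blur, absolute inter-frame
delta, thresholding, dilation, connected-component area. Both crops are
taken at the *current* frame's box: if the box drifts while the dog is
still, differencing two crops taken at each frame's own box would count
the drift itself as motion.

**Sleep is the absence of motion over a window.** Scoring a dog asleep
from a single motionless frame pair would make every between-step pause
count as sleep, so the classifier asks for stillness over a trailing
window: frame *t* is ASLEEP when at most `maxAwakeFramesInWindow` of
the last `window` frames were flagged as moved.

## Parameters, defaults, and why

| parameter | default | units | rationale |
|---|---|---|---|
| `blurKernel` | 21 | px | heavy smoothing; suppresses sensor noise and compression artefacts of low-quality CCTV so the delta responds to body motion, not grain |
| `deltaThreshold` | 25 | intensity (0–255) | the conventional frame-differencing threshold; about 10% of full scale, above infrared sensor noise |
| `dilateKernel`, `dilateIterations` | 3, 2 | px, — | fuses the fragmented delta pixels along a moving edge into one component |
| `minComponentArea` | 25 | px | discards specks smaller than any plausible limb movement at kennel-camera scale |
| `minMotionFraction` | 0.005 | fraction of crop | movement must cover a minimal share of the box so that a single noisy corner cannot wake a large crop |
| `window` | 3 s of frames | frames | long enough to suppress single-frame noise, short enough to catch the brief arousals that delimit bouts |
| `maxAwakeFramesInWindow` | 0 | frames | strict stillness: any detected movement in the window keeps the dog awake |
| `minIou` | 0.3 | — | generous association gate for slow-moving subjects |
| `sleepLabels` | `sleep`, `rest` | — | the observation labels counted as sleep when reading human logs |

None of these values is prescribed by the behavioural definition; they
are this package's configuration of the classical recipe, every one
overridable per run (`motion:`/`state:` blocks of the YAML config).
The qualifying area aggregates **all** components at or above
`minComponentArea`, not only the largest: a limb twitch and a
whole-body turn are both movement, and discarding secondary components
would bias against distributed motion.

Numerical conventions worth stating once: pixel intensities are 8-bit
and the blur output is rounded back to integers; the Gaussian sigma is
derived from the kernel width as `0.3((k-1)/2 - 1) + 0.8`, the standard
8-bit video convention; blur borders reflect the image (edge pixel
duplicated); the binarization is strictly greater-than, so a delta
exactly at threshold is background; dilation truncates its structuring
element at the image border; components are 8-connected, so diagonally
touching pixels merge; boxes are half-open `[x_min, x_max) × [y_min,
y_max)` with the origin at the top left, which makes areas exact pixel
counts and IoU an exact lattice computation.

## From states to bouts and summaries

A sleeping bout is one maximal episode of sleep delimited by
wakefulness, counted regardless of duration. Three edge rules are
design decisions rather than consequences of that definition:

* **Boundary bouts count.** A strict wake→sleep→wake reading would
  discard a run that touches the start or end of the session, and
  overnight recordings routinely begin or end mid-sleep; dropping those
  runs would systematically undercount fragmentation. The strict
  reading remains available (`strictWSW = TRUE`).
* **UNKNOWN breaks a run.** When the detector loses the dog, the
  conservative reading is that the ongoing bout ended; bridging gaps is
  an explicit opt-in (`bridgeUnknownMaxS`), because silently bridging
  would fabricate continuous sleep across arbitrarily long detector
  failures.
* **Durations are frame counts / fps**, and rendered `H:MM:SS` strings
  truncate sub-second remainders, so a printed table sums consistently.

The first `window − 1` frames of a session have no complete trailing
window; they inherit the first state computed from a complete one
rather than being scored from a partial window, which would make the
session opening hypersensitive to single flags.

The per-frame state representation is shared with the reader of human
observation logs (`readObservationLog()`), so system and observer enter
every comparison through exactly the same summarisation path — any
disagreement is then attributable to scoring, not bookkeeping. The
log dialect is the minimal BORIS-style export (`Time, Subject,
Behavior, Status` with START/STOP markers, column names configurable);
times are seconds from session start, and a log time-stamped on an
absolute clock must be normalized before reading. An unterminated START
is closed at session end with a warning — observers do stop sessions
mid-bout — while a STOP without a START, overlapping STARTs, or an
event beyond the session are hard errors naming the file line.

## Agreement statistics

`pairedTTest()` is the textbook two-sided paired *t*:
`t = mean(d)/(sd(d)/sqrt(n))` with the sample (n−1) standard deviation,
`df = n − 1`, and the p-value through the regularized incomplete beta
function. The sample-sd convention is applied uniformly; published
tables are not always explicit about it, which is one reason the
bundled fixture's bout columns (integers, convention-robust) are the
ones worth checking to printed precision. Zero variance of the
differences is not a t-test at all, so it is raised as a distinct
degenerate condition; `comparisonReport()` catches it and reports the
metric as "identical".

`andersonDarlingNormality()` computes A² on the standardized sorted
sample, applies the small-sample correction
`A*² = A²(1 + 0.75/n + 2.25/n²)`, and rejects at the 0.752 critical
value (α = 0.05, normal case with estimated parameters). The result is
reported as the corrected statistic plus the threshold decision; no
p-value is interpolated from tables, to avoid implying precision the
tabulated critical points do not offer. No multiple-testing correction
is applied anywhere — each test is reported at its raw α, matching the
analysis style this report format follows.

The per-session percent-difference columns of the bundled validation
table use denominators its source never defines and that are not
recoverable from the printed values. The report therefore (a)
summarises the externally supplied column as given, and (b) computes
its own clearly labelled symmetric percent difference
`100·|a−b| / ((a+b)/2)`.

**The observed-duration assumption.** Percent-of-time comparisons need
per-night observation windows, which the source table does not print.
The fixture ships a separate, explicitly synthetic observed-durations
file: an 18 h nominal system window per night (9 h for the one
short night), and manual windows derived from the published qualitative
finding that the two methods agreed on sleep *percentage* while
differing in total — i.e. equal sleep fractions, rounded to the minute.
The percent-of-time test on this fixture is therefore a consistency
demonstration of the machinery, not an independent reproduction of the
published percentage analysis, and the package says so here rather than
hiding the assumption in the data.

## What the synthetic generator does and does not emulate

`renderScenario()` draws each dog as a textured ellipse on a textured
static background, in colour (day) or single-channel (night) mode, with
up to two dogs per arena. While AWAKE the dog is displaced every frame
by a zero-mean symmetric step per axis,
`sign · (awakeMinStep + |N(0, awakeMotionSd)|)` (defaults 2 + |N(0,2)|
px), with a fresh texture perturbation standing in for limb motion;
while ASLEEP the body is pixel-static apart from optional transient
twitches. A `territory` radius confines each dog near its start
position, as a pen confines a real dog, and incidentally keeps
two-dog scenarios from occluding each other unless asked to. Nuisances
— global camera shake, sinusoidal light flicker, per-pixel sensor
noise — are composited after the dogs, from their own random
substream, so enabling a nuisance never changes a trajectory.

The step-magnitude floor (`awakeMinStep`) is the generator's way of
enforcing the statistical structure the classifier assumes: wakefulness
produces *perceivable* movement every frame. Without a floor, an awake
dog would occasionally sit sub-pixel-still and the ground truth itself
would be ambiguous about what "no perceivable movement" means.

What passing tests on this generator show: the six-step detector, the
windowed classifier, bout extraction, summarisation, tracking, and the
file formats compose correctly, and recovery degrades in the right
direction under shake. What they do not show: performance on real
kennel footage — real dogs have posture changes without translation,
deformable outlines, shadows, occlusions by kennel furniture, and
detector noise, none of which the blob model imitates. The generator is
a correctness instrument, not a realism benchmark.

The classifier's one systematic artefact is visible even on clean
synthetic data and worth knowing about: at each sleep onset the
trailing window keeps the dog "awake" for up to `window` frames, so
scored total sleep is short by up to one window per bout and per-frame
agreement on a session with *k* sleep onsets is bounded near
`1 − k·window/n`. Wake onsets are detected immediately, because the
first moved frame alone breaks the stillness criterion. Problem sizes
used in the bundled checks — 5-minute scenarios at 5 fps, 160×120 px,
one or two dogs with a single sleep onset each — were chosen so this
bound sits at about 1%, which is also why the bundled scenarios are not
a demonstration of accuracy on fragmented sleep; for a session with
many brief bouts the onset lag accumulates proportionally.

## Known limitations

* Video containers are not decoded; input is a directory of numbered
  PNG frames (consumer-CCTV exports and `ffmpeg` both produce these
  readily). Frame timing is index/fps with a user-supplied fps; CCTV
  container timestamps are not trusted even where present.
* Re-identification after a long occlusion is out of scope: a track
  that dies gets a fresh id, and under violent camera shake the greedy
  matcher can re-label a track mid-session.
* No sleep-stage discrimination (REM/NREM) and no posture
  classification; the behavioural definition scores any sustained
  stillness as sleep.
* No global shake compensation or background modelling; heavy shake is
  expected to raise the false-awake rate (the tests assert exactly that
  direction), mirroring the practice of excluding windy nights from
  manual analysis.
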