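---
title: "Methods: dual-sensor hand tracking, calibration, fusion and kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-sensor hand tracking, calibration, fusion and kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handfusion)
```

## The problem

Touchless skeletal hand trackers (small infrared stereo devices of the
Leap-Motion class) report the 3D positions of the hand joints at tens of
frames per second without any worn equipment, which makes them attractive
for at-home hand telerehabilitation: the patient exercises in front of
the device, and the therapist receives per-joint, quantitative mobility
data instead of a purely subjective impression. A single such sensor,
however, loses the hand whenever the palm turns perpendicular to its
viewing axis — the fingers occlude each other. Mounting two sensors
orthogonally (one looking up at the palm, one looking at it from the
side) removes the blind spot, at the cost of three new problems that this
package implements solutions for:

1. **calibration** — expressing both sensors' measurements in one
   reference frame;
2. **fusion** — deciding, at every instant, which sensor's hand model to
   trust;
3. **analytics** — turning the fused landmark streams into per-joint
   speed, acceleration, range-of-motion and progress statistics a
   therapist can act on.

A fourth component, the **synthetic simulator**, stands in for the
physical rig so that every stage can be exercised and validated at desk
scale, and a fifth, the **session store**, reproduces the clinical
server's document-collection scheme and role model on plain files.

## Data model

The hand is 25 named landmarks: four thumb joints (CMC, MCP, IP, TIP),
five per remaining finger (BASE, MCP, PIP, DIP, TIP) and the palm
center. The landmark names follow common hand-anatomy usage; the
canonical ordering (thumb to pinky, proximal to distal, palm last) fixes
the serialization order. Positions are in millimetres — the natural unit
of this sensor class — and timestamps in milliseconds, which makes the
nominal 40 fps frame interval an exact 25 ms.

Each time instant is stored as one record carrying up to three hand
models: the vertical sensor's, the horizontal sensor's, and the fused
one. A session is a header (patient, therapist, device, task parameters,
calibration reference) followed by the time-ordered records, serialized
as JSON Lines (`.vgs.jsonl`: header on line 1, one record per subsequent
line). JSON Lines rather than a single array matches the streaming,
append-during-session character of the data. Numbers are written with 17
significant digits, so a write/read cycle reproduces every double
bit-exactly; the file schema is published in
`inst/extdata/stream.schema.json`.

Raw frames show the hand from the sensor's point of view, so a right
hand reads as a left hand. `mirror_frame()` flips the presentation by
negating the X coordinate (reflection across the Y–Z plane) and swapping
the handedness label. "Mirroring with respect to the X-axis" admits a
second reading — reflection about the X axis line, negating Y and Z —
which is available via `mode = "about_x_axis"`; negate-X is the default
because it is the reading that turns a raw right hand into its
user-facing presentation. Both are involutions and isometries.

Per-joint tracking-reliability scores in [0, 1] are carried when a
sensor provides them; fused frames have none. The scores are stored for
future exploitation but do not yet drive fusion.

## Calibration

The two sensors are aligned by a two-step procedure operating on
corresponded point pairs: the same physical stick-tip position measured
by both devices (the stick is moved through the shared working volume on
a positioning rig, so correspondence is known — no iterative
closest-point search is needed).

**Step 1 — SVD registration.** `estimate_rigid_transform()` minimizes
$\sum_i \lVert s\,R\,a_i + t - b_i \rVert^2$ by the Kabsch–Umeyama
method: subtract centroids, form the cross-covariance
$H = \frac1n \sum_i \tilde a_i \tilde b_i^{\top}$, take its SVD
$H = U D V^{\top}$, and set $R = V \,\mathrm{diag}(1, 1, d)\, U^{\top}$
with $d = \operatorname{sign}\det(V U^{\top})$, which guarantees a
proper rotation ($\det R = +1$) even when the least-squares optimum over
all orthogonal matrices would be a reflection. The transform is rigid by
default ($s = 1$); the optimal uniform scale
$s = \operatorname{tr}(DS)/\sigma_a^2$ is computed only on request,
since both the rigid and the similarity reading of the deployment are
plausible and rigid is the documented default.

Degenerate geometry is rejected before the fit: if the smallest singular
value of the centered source cloud is below $10^{-9}$ times the largest,
the cloud is treated as rank-deficient. This conservative conditioning
check rejects collinear sticks (which leave a rotation axis genuinely
unconstrained) and also exactly planar clouds — the rotation would still
be recoverable from planar data thanks to the determinant correction,
but a cloud that thin signals a degenerate acquisition rather than a
usable calibration.

**Step 2 — axial-bias refinement.** Internal differences between the two
devices are measured by placing each sensor in turn at identical
physical poses; `estimate_axial_bias()` returns the per-axis mean of the
residuals $b - (sRa + t)$ under the step-1 transform, and
`integrate_axial_bias()` folds it into the translation. The mean is the
least-squares optimal pure-translation correction, so the refinement can
never increase the RMS residual on its own pairs. All three axes are
corrected; correcting a subset would be an undocumented restriction.

Transforms persist as JSON (row-major rotation, translation, scale,
residual) together with intrinsic Z-Y-X Euler angles in degrees — an
export convention for game-engine-style consumers; the matrix remains
the internal truth.

## Fusion

Both strategies are *switches*, never blends: every fused landmark is
bit-identical to one source model's landmark. Averaging sensors that
disagree because one of them is occluded would contaminate the good
estimate with the bad one.

**Binary switch.** The palm normal $p$ (unit vector orthogonal to the
palm) is projected onto the X–Y plane of the horizontal sensor's
reference system, and $\theta$ is the counterclockwise angle of that
projection from the X-axis. The horizontal sensor is active iff
$\theta \in [45°, 135°]$ (palm up) or $\theta \in [225°, 315°]$ (palm
down); the vertical sensor serves all other orientations. Boundary and
degenerate-case choices, none of which affect generic frames:

- The windows are *closed*, so the threshold angles themselves activate
  the horizontal sensor.
- Window membership carries a numerical slack of $10^{-9}$ degrees.
  An angle recomputed from a unit normal synthesized at exactly 225°
  lands at 224.99999999999997° in double precision; without the slack
  the closed window would miss its own boundary. The slack is far below
  sensor resolution and exists purely to make boundary membership
  robust to round-off.
- When the projection is undefined (the normal within $10^{-6}$ of the
  Z-axis), the previous decision is held; at stream start the horizontal
  sensor — the natural resting view — is assumed.
- There is no hysteresis: a frame at 44.9° flips to vertical
  immediately. The angle test is memoryless by design; hysteresis would
  be an undocumented addition.

**Joint-wise switch.** Per joint, the frame-to-frame speed
$v_s = \lVert p_s(t) - p_s(t-1) \rVert / \Delta t$ is computed for both
sensors in the common frame, on the heuristic that slower-tracked motion
signals more robust data (tracking failures show up as jumps). The joint
currently assigned to sensor $s$ switches to the other sensor iff
$v_s > \kappa\, v_{\text{other}}$ with margin $\kappa \ge 1$ (default
1); ties and within-margin cases keep the current assignment, so two
sensors reporting identical motion never oscillate. The underlying
"compare inter- with intra-sensor velocity" rule admits a second
reading based on the cross-sensor displacement
$\lVert p_{\text{other}}(t) - p_{\text{active}}(t-1) \rVert$; the
intra-vs-intra comparison is what drives the switch here, and
`speed_metrics()` exposes all four quantities so the alternative can be
built on the same surface.

A known limitation of the slower-is-more-robust heuristic: a sensor that
*freezes* (repeats a stale estimate, as real trackers do during dropout)
looks infinitely slow and therefore maximally trustworthy. The heuristic
rejects jump artifacts well and stale-value artifacts poorly; the
validation scenarios separate the two failure modes accordingly.

**Stream pairing.** Records of the two streams are matched by nearest
timestamp within half the nominal frame interval (12.5 ms at 40 fps),
injectively, unmatched records dropped. Fusion is a pure function of
(streams, transform, configuration); the per-record decisions (angle and
active sensor, or per-joint active map) are attached to the output
stream.

## Kinematics

Velocity is estimated by central differences on the actual timestamps
(non-uniform safe), one-sided at the stream ends, and acceleration by
applying the same operator to the velocity vectors; speed and
acceleration are the vector magnitudes, converted to mm/s and mm/s².
Central differences are exact on linear and quadratic trajectories at
uniform spacing and second-order accurate in general — both properties
are verified in the test suite, including the empirical $O(\Delta t^2)$
convergence rate on sinusoids. No smoothing is applied by default (the
estimator should not silently alter clinical data); an optional
moving-average pre-filter with configurable window is available for
noisy recordings.

Session summaries report, per joint: mean and maximum speed over
*interior* samples (the one-sided end estimates are first-order only and
are excluded), total path length $\sum_i \lVert \Delta p_i \rVert$, and
per-axis range of motion. Path length is invariant under rigid
transformation of the stream and under time reversal — properties the
suite checks. Session comparisons difference these statistics between
consecutive sessions and report a per-joint trend sign (the sign of the
mean consecutive delta). Reports export as JSON + CSV + PNG; a PDF
rendering layer is deliberately out of scope, and exporting never
modifies the stored stream data.

## The simulator

The generator emulates what the physical rig would measure, not how it
measures it: there is no image-level or biomechanical modelling.

- **Geometry**: representative adult segment lengths (20–90 mm) in a
  canonical right-hand pose; palm normal along +X, fingers along +Y.
  The pipeline itself is geometry-agnostic.
- **Motion**: each finger flexes rigidly about its pivot joint by
  $A \sin(2\pi f t + \varphi)$, so every joint's analytic peak speed is
  $2\pi f A r$ with $r$ its distance from the pivot — an exact oracle
  for the kinematics estimators. The whole hand follows a palm-normal
  angle profile $\theta(t)$ (constant, linear sweep, or sinusoid)
  realized as a rotation about the Z axis, which makes $\theta$ exactly
  the palm-normal projection angle the binary switch sees.
- **Observation**: the truth is mapped into each sensor's frame by the
  sensor pose, with i.i.d. Gaussian noise of SD 0.5 mm per axis by
  default — the few-millimetre-resolution class of these devices.
- **Occlusion**: when the palm normal comes within 30° of perpendicular
  to a sensor's viewing axis, that sensor's jitter inflates tenfold and
  each joint freezes (holds its last value) with probability 0.2 per
  frame. These three values are free parameters chosen once to make the
  occlusion problem — and the benefit of fusion — clearly visible at
  desk scale; the hardware this emulates publishes no such magnitudes.
  Dropout is hold-last-value rather than missing records, so streams
  stay dense as real tracker output does. In the default rig the
  horizontal sensor (view axis +Y) is occluded near θ = 0° and 180° and
  the vertical sensor (view axis +X) near 90° and 270° — exactly
  complementary to the binary-switch windows, as the physical geometry
  dictates.
- **Calibration clouds**: stick positions drawn uniformly in a
  ±150 mm cube, observed by the second sensor through the true
  transform plus noise.
- **Session lifecycle**: a wall-clock-free state machine (INFO → hand
  detection → 10 s countdown → task run → rest between repetitions →
  summary) so that lifecycle tests run instantly; the 10 s pre-task
  countdown gives the sensors time to lock onto the hand. The rest
  (15 s) and info (2 s) durations are configurable free parameters.
  A toy virtual-keyboard task scores a hit when the designated joint
  enters a target's activation radius while the target is lit.

What passing simulator-based tests do and do not show: they validate the
algebra and the decision logic under Gaussian noise, rigid sensor
offsets and the modelled occlusion process. Real trackers have
non-Gaussian, pose-dependent error, correlated joint estimates from the
internal hand-model fit, latency jitter, and occlusion behavior richer
than jitter-plus-freeze; conclusions about clinical accuracy require
real recordings.

Problem sizes used by the validation suite and the acceptance script
were chosen to keep every property measurable with comfortable margins
at interactive runtimes: 200-frame (5 s at 40 fps) sessions for fusion
equivalence and occlusion discrimination, 100 seeded replicates of
50-pair clouds at 0.5 mm noise for calibration recovery (median rotation
error well under 0.5°, median translation error under 0.5 mm), and
1000-frame static sessions for noise-calibration checks.

## Session store

The store is an embedded, schema-free document store on plain JSONL
files — one collection per file, atomic whole-file writes — exposing a
Mongo-like surface; a server-backed implementation could stand behind
the same interface. Three fixed collections (`User`, `Task`,
`Task_Parameters`) hold the actors and task configuration, and each
session lives in its own collection named by its identifier

```
Session_<patient>_<therapist>_<task-parameters>_<YYYYMMDD>
```

so the collection name alone carries all retrieval information. The
underscore is the join separator, so identifier components are sanitized
(anything outside `[A-Za-z0-9.-]` becomes `-`), making the join
injective and parseable; `YYYYMMDD` was chosen as the date rendering.
Therapist queries (by patient id or name, task type, or execution-time
range) resolve through the fixed collections and the parsed identifiers,
and the suite checks them against a brute-force scan oracle.

Access control is a total role matrix over
{patient, therapist, administrator} × {User, Task, Task_Parameters,
Session} × {create, read, update, delete}: therapists hold full CRUD
over patients, tasks and parameters and insert/read sessions;
administrators additionally manage therapists and patient–therapist
links and may delete old session collections; patients read their task
material and contribute session data. Session collections are immutable
once written — analyses always run on intact originals. The "identity"
here is a caller-supplied role token; real authentication and credential
management are out of scope.

Insertion emulates the buffering that protects against connection loss:
the stream is staged locally, then transferred into the store, and the
staging copy is cleared only after the transfer; a retry after a failed
transfer completes idempotently, leaving exactly one stored copy.

## Known limitations

- The joint-wise heuristic mistakes frozen (stale) data for robust data,
  as discussed above.
- The binary switch takes the palm-normal angle from the horizontal
  (reference) sensor's reported normal; a normal estimated by an
  occluded sensor is itself degraded, which the simulator does not model
  (it degrades positions only).
- Reliability scores are carried but unused by fusion.
- No hysteresis in the binary switch means rapid flipping is possible
  for a palm hovering at a window boundary.
- The simulator's left hand is a mirrored right hand; no independent
  left-hand geometry.
- Store atomicity is per call within one process; multi-process
  concurrency control is not attempted.
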