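---
title: "Calibrated motion amplification for accessible exergames: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated motion amplification for accessible exergames: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplimotion)
```

This vignette is the package's account of its model and of the design
decisions behind it: what is being computed, under which assumptions, which
parameters matter, and what the synthetic-data experiments do and do not
demonstrate.

## The amplification model

A depth sensor streams the positions of 20 skeletal joints at a nominal
30 Hz, in metres, with z vertical, y lateral and x along the depth axis. A
player with muscle weakness produces small limb displacements; the game
needs full-range avatar movement. The package maps one onto the other with a
per-limb linear model about the recorded resting point \(r\):

\[
p' \;=\; (r + \mathrm{offset}) + f \circ (p - r),
\]

with a separate factor per axis *and per direction of displacement*
(\(f^{+}, f^{-}\), six numbers per limb). Two deliberate properties follow:

* **Zero is a fixed point.** A resting limb maps exactly onto the avatar's
  resting limb, whatever the factors; the resting, raw and amplified marker
  points coincide. This is only achievable if the model acts on
  *displacements* from the resting point rather than on raw coordinates,
  which is how the package interprets the multiplication — a raw-coordinate
  product would translate the avatar by an arbitrary factor-dependent
  amount.
* **Linearity.** Half a maximal user movement yields half a maximal avatar
  movement, so within-game difficulty scales the same way for every player.

Factors are per-direction because impairments are commonly asymmetric (a
player may raise the hand but barely lower it); a single per-axis magnitude
would either under-amplify one direction or overshoot the other.

The engine-level realisation is a chain of \(n = 25\) bones, each copying
the local displacement of its parent, closed by a bone that imitates the
chain tip through per-axis restriction factors \(f_{\mathrm{res}} \in
[0,1]\); the global gain is \(f = n\,f_{\mathrm{res}}\), hence the factor
ceiling of 25. `amplify_chain()` implements the closed form and
`amplify_chain_iterative()` the explicit recurrence; they agree to the last
bit against a brute-force loop in the tests. Factors are floored at 1: a
capable user is never attenuated.

Only the outer limbs (hands, feet) are amplified. Elbows, knees, wrists and
ankles follow by analytic two-bone inverse kinematics (`solve_two_bone_ik()`),
which preserves segment lengths exactly and clamps unreachable targets to
the nearest reachable point on the root–target line; the bend plane is taken
from the user's own elbow/knee position, with a forward default when that is
degenerate. Trunk and head are copied unamplified — the flying game reads
raw trunk lean by design.

## Calibration

`calibrate()` estimates, per limb, from one trace containing a resting phase
followed by maximal stretches along every axis:

* **Resting point** — per-axis median over the stillest window (default
  4 s). Stillness is scored on a denoised copy of the track (5-point running
  median, then a 1/3 s moving average) because raw sensor scattering swamps
  frame-to-frame speeds; among near-tied windows the earliest is taken,
  since the protocol records rest first and a weak user's stretch plateau is
  nearly as still as rest.
* **Ranges** — per axis and direction, the maximal displacement after
  filtering (running median, then a 1.5 s moving average) and rejection of
  values beyond 3 MADs of the top decile's median. The filtering matters
  quantitatively: the *maximum* of jittered samples is biased upwards by
  several millimetres, which for a user with a 2 cm usable range misstates
  the gain by 10–30 % and, worse, makes the in-game maximum unreachable.
  With the filter the residual bias is well under a millimetre.
* **Factors** — the ratio of the avatar's required range to the user's
  measured range, clipped to [1, 25]; axes with under 1 cm of usable range
  are flagged unusable and left at factor 1.
* **Offset** — avatar resting point minus user resting point, so a seated
  player's lap-level rest maps onto the avatar's standing rest posture.

The avatar's required ranges are derived from its skeleton rather than
hard-coded: per axis and direction, the straight-line distance the limb can
travel from rest before the two-segment chain would over-extend, capped at
80 % of the arm reach (30 % of leg reach for feet). All computations live in
displacement space relative to the resting point, which makes profiles
independent of where the player sits — no per-session re-calibration.

Everything is fitted robustly (medians, MAD rejection) because depth-sensor
capture intermittently produces large position spikes ("scattering").

## Gadgets and game-control gestures

Two measurement primitives drive all game logic. The *rope* measures the
distance between two attachments (joints or world points) and fires
activation/release events around a trigger length, with a hysteresis margin
(default 10 % of the trigger) so that jitter cannot chatter; activations and
releases strictly alternate. The *accelerometer* reports the speed of an
attachment via a backward difference over a short window (default 2 frames —
despite the name it measures speed, which is what the games need).
Game-control actions (open a menu, pause) are separated from exercise
movements by dwell gestures: a pose predicate that must hold continuously
for a dwell time (default 1.5 s) before an event fires.

The game layer smooths the avatar stream with a 1/6 s moving average before
event detection. The amplifier itself never filters: it stays stateless and
exactly linear, and different games can choose their own smoothing.

## The four mini-games

All four are deterministic state machines over the amplified stream;
identical trace, configuration and seed give identical results.

* **Ladder (climbing).** A grab is detected by a rope between the hand and
  the current rung point (the avatar rest position plus the vertical
  required range); hands must alternate and release before re-grabbing; the
  completion time over `n_rungs` rungs is the outcome. The grab band is
  80–100 % of the calibrated range. A tighter band (e.g. 95 %) looks
  natural but is unreachable *in principle* for the weakest users: jitter
  inflates their measured range by a larger fraction than the band leaves as
  margin, so their true maximum sits below the threshold. The band width is
  a config parameter (`band`).
* **Boat (rowing).** Four ropes — fore and aft on each side, placed at 70 %
  of the per-direction fore/aft ranges — must all activate, in any order,
  to complete one stroke; the boat advances a fixed distance per stroke.
  Order-free completion is deliberate: players who row in diagonal or
  circular patterns still touch all four ropes per cycle, where a strict
  fore-then-aft sequence would respond inconsistently.
* **Whack-a-Mole (hitting).** Twenty moles appear one at a time out of four
  holes (uniformly drawn from the seed) over two minutes, each visible for
  3 s. A hit requires the hammer hand inside the hole radius *and* moving
  downward at or above a minimum speed — position alone is not enough. The
  spawn times are fixed (every `duration/n_moles` seconds) so the schedule
  is open-loop and reproducible.
* **Paper-Bird (flying).** The difference in hand heights steers the bird
  (lower left hand: left turn, at `yaw_gain` rad/s per metre), trunk lean
  controls pitch (forward lean dives), and the bird advances at constant
  speed. Rings count once each, when the flight segment crosses the ring
  plane inside the radius. There is no goal; the played duration and the
  ring count are the outcomes.

## The synthetic players

No public motion data exist for this setting, so the package ships a seeded
generator (`player_params()`, `generate_*()`) that emulates the study
conditions:

* **Amplitude scale `s`** ∈ (0, 1]: limbs travel `s` times the full range
  (defined by the same geometric rule as the avatar's required ranges,
  applied to the player's own skeleton — this is what makes a calibration
  on a same-sized player recover factors of exactly 1/s in the noiseless
  case). Control players draw s ~ U(0.9, 1), the impaired target group
  s ~ U(0.05, 0.5), spanning hands-only movement up to moderate weakness.
* **Sensor scattering**: i.i.d. Gaussian jitter per joint, axis and frame,
  default 5 mm — the magnitude of depth-sensor noise at the limbs.
* **Posture**: target players are seated (wheelchair), with lap-level hand
  rest; controls stand.
* **Cadence** ~ U(0.8, 1.2) Hz in *both* groups: the equalisation claim is
  about matched intent, so the groups must not differ in tempo by
  construction.
* **Precision and reaction**: `aim_error` (aim scatter as a fraction of the
  movement range) and `reaction_time` are drawn larger for the target group.
  These model the deficits that gain cannot fix — they drive the residual
  group differences in the hitting and flying games, mirroring the
  observation that amplification helps amplitude but not precision or speed.
* Movements interpolate between keyposes with quintic minimum-jerk profiles;
  calibration stretches hold each extreme for several seconds (what a real
  calibration protocol would ask for, and what lets the range estimator
  average the noise); intermediate joints are solved by IK on the player's
  own skeleton, so generated streams are kinematically consistent.
* The flying exercise uses a ring-seeking pilot that forward-simulates the
  bird's control law under its own commands, with slowly varying command
  noise scaled by `aim_error`.

What passing tests on these data show: the estimator recovers known gains,
the amplification pipeline equalises amplitude-limited outcomes between
groups, and the games respond deterministically and geometrically correctly.
What they do not show: robustness to real depth-sensor failure modes
(occlusion, limb swapping, wheelchair reflections), to spasticity-like
non-stationary motion, or to fatigue within a session — none of which the
generator models.

## Numerical and design notes

* Timestamps must be strictly increasing and, by default, uniform at the
  nominal rate within 1 ms.
* IK tie-breaks: unreachable targets clamp to the chord; a bend hint
  collinear with the chord falls back to an arbitrary perpendicular; a
  zero-length chord extends along the hint.
* The BVH writer emits a position-channel dialect (root six channels, other
  joints three position channels with residual translations), because the
  canonical data are joint positions and position channels round-trip
  exactly; the reader additionally handles conventional rotation channels
  (degrees, applied in channel order).
* Joint-stream files are written with 17 significant digits so CSV and JSONL
  dialects parse bit-identically.
* Statistical conventions: Levene uses mean centring; p(t) is two-sided
  (one-sided is also returned); for two groups the one-way ANOVA F equals
  the squared pooled t, which the tests assert to 1e-9; the group verdict is
  "different" when the t test rejects at 5 % and Kruskal-Wallis corroborates
  (Kruskal-Wallis alone decides when the Levene gate fails); Levene p in
  (0.05, 0.10] is flagged as weak. Report rounding follows the conventions
  of published comparison tables: two decimals for p and F, integer percent
  differences.
* Problem sizes in the tests: cohorts of 8 + 8 subjects, 10-rung ladders at
  around 1 Hz cadence, 20 replicates for the equalisation property, 1000
  replicates for null calibration of the statistical pipeline, 1000 random
  cases for the chain and IK identities.

## The equalisation experiment

The central claim is behavioural: after calibration, impaired and unimpaired
players at matched cadence should finish the climbing game in the same time,
and disabling amplification should break this. The test suite runs 20 seeded
replicates of an 8 + 8 cohort through calibration and the ladder with
amplification on and off. With amplification the group mean times differ by
a few percent (the residue comes from jitter-induced calibration error at
extreme gains); without it, impaired players cannot reach the rungs at all
and the gap exceeds 100 % in every replicate. `run_demo()` packages the same
experiment, plus the other three games and the group-comparison report, into
one seeded call.

## Known limitations

* Amplification is linear and static; fatigue-adaptive or nonlinear gain
  scheduling is out of scope.
* A user exceeding the calibrated range mid-session overshoots the avatar
  target linearly (the IK clamp is the only guard); the contract makes this
  explicit rather than guessing a clamp policy.
* Rotational retargeting (bone orientations, skinning) is not modelled;
  poses are positions only.
* The statistical pipeline applies no multiple-testing correction, matching
  the reporting conventions it reproduces; with five metrics per report the
  family-wise error is correspondingly higher.
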