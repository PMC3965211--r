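---
title: "Simulating and analysing single-kinesin motility on microtubule networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing single-kinesin motility on microtubule networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinetrax)
```

## What this package models

kinetrax is built around a single question: given the kind of data a
single-molecule TIRF or optical-trap experiment produces for a processive,
track-switching kinesin — motor tracks on polarity-marked microtubules,
photobleaching intensity traces, bead position traces in a harmonic trap,
bead-binding dilution series and microtubule co-sedimentation curves — can a
fully automated pipeline recover the generative motility parameters? The
package therefore has two halves that are deliberately independent:

* a **generator** (`simulate_trajectory()`, `simulate_intensity_trace()`,
  `simulate_trap_trace()`, `simulate_bead_binding()`, `simulate_cosed()`)
  that implements an explicit stochastic state machine for a tetrameric
  motor, and
* an **analysis pipeline** (`segment_track()`, `compute_run_metrics()`,
  `classify_events()`, `detect_steps()`, `detect_detachments()`,
  `fit_distribution()`, `fit_poisson_binding()`, `fit_kd()`) that never sees
  the generator's internal state and works only from the observable tables.

Parameter recovery — simulate with known values, analyse, compare — is the
package's validation strategy, implemented in the test suite and in
`scripts/acceptance.R`.

## The motor state machine

A motor attaches at a uniformly random lattice position and is plus-end
directed with probability `p_plus` (default 0.875; minus-directed runs never
reverse). Each run draws a velocity from a truncated Gaussian (median
137.8 nm/s, sd 60 nm/s on [30, 550] nm/s) and a run-length budget from an
exponential parameterised by its **median** (1.9 µm; rate = ln 2 / median
throughout, because single-molecule studies report medians). Pauses arrive
as a Poisson process per micrometre of processive path (0.30 µm⁻¹), with
durations drawn from a truncated exponential on [2, 20.5] s. On reaching the
plus end the motor detaches with probability 0.1 and otherwise dwells
(shifted exponential, median 18.8 s) before roaming the end-proximal lattice
diffusively. When the run budget is exhausted mid-lattice the motor enters a
weakly bound diffusive *linger* state (D = 0.04 µm²/s) and detaches from it
at a calibrated rate. At a microtubule intersection a processive motor draws
one of four outcomes — pass, switch, pause, dissociate — with configurable
probabilities (equal by default); a switch relocates the motor to the
crossing microtubule at the crossing point, so its xy path never leaves the
lattice.

Everything is a pure function of `(params, network, seed)`: rerunning with
the same seed reproduces the trajectory bit for bit, and ensembles derive
child seeds by a fixed affine rule so that nearby base seeds do not share
streams.

### Three observability choices, and one calibration

Three places in the generator deviate from "draw a plain exponential", and
all three exist for the same reason: the published summary statistics
describe what a kymograph scorer can *see*, and a generator that emulates
data must emulate the observable population, not an idealised one.

1. **Pause floor.** Pause durations are drawn on [2, 20.5] s with the base
   rate solved (`truncated_exp_rate_for_median()`) so the truncated law's
   median equals the configured 5.0 s. Sub-frame pauses cannot be scored at
   2 fps; generating them would make the detected pause median and the
   pause frequency systematically miss their configured values for purely
   observational reasons.
2. **Dwell floor.** End dwells are `2 s + Exp(median 16.8 s)`, so the
   generated median is the configured 18.8 s and no unobservable sub-frame
   dwell tail exists.
3. **Velocity floor.** Per-run velocities are truncated below at 30 nm/s: a
   motor slower than the 20 nm/s pause-scoring threshold is indistinguishable
   from a stationary one over an entire track and would be scored static,
   which the published velocity distribution does not contain. The median is
   insensitive to this floor (~1%).

The one genuine calibration is the **residency linger rate**. The three
headline numbers — velocity median 137.8 nm/s, run-length median 1.9 µm,
residency median 26.3 s — are mutually inconsistent if detachment coincides
with run end: 1.9 µm at 137.8 nm/s is only ~14 s of moving time, and adding
pauses still falls well short of 26.3 s. Treating detachment as a competing
exponential clock instead truncates runs and drags the run-length median to
~1.2 µm. The model adopted here is the two-phase attachment familiar from
motors with a weakly bound state: the processive run completes in full, and
the excess residency is spent in the diffusive linger state. The linger
detachment rate is solved numerically at `motility_params()` construction
(40 000 internal draws under a fixed private seed, so the result is a
deterministic function of the parameters) such that the **median of total
realized residency equals `residency_med`**. A consequence worth stating
plainly: realized residency is hypoexponential, not exponential, so
distribution-shape tests on residency are not expected to pass against a
plain exponential — the package's fidelity tests check the median instead,
while run lengths, pause durations and end dwells are tested against their
exact generative laws by Kolmogorov–Smirnov.

## Track segmentation

The reference assays classified motor behaviour by eye on kymographs; the
package replaces that with explicit thresholds (`seg_config()`):

* local velocity from a 5-frame sliding least-squares slope;
* **stationarity from single-interval displacements** (< 20 nm/s): the
  windowed slope smears pause boundaries by half a window, which would bias
  pause durations short by ~2 s, whereas a run of slow intervals estimates
  the duration without bias;
* stationary stretches ≥ 1.5 s become pauses, or end dwells when entirely
  within 150 nm of the plus end;
* moving stretches, split by slope sign, become processive segments when
  they last ≥ 2 s, their MSD exponent is ≥ 1.5, they are straight (RMS
  residual ≤ 60 nm about the fitted line), and their frame-to-frame speeds
  are uniform (≥ 70% of interior intervals within [0.4, 2.5]× the median
  interval speed, same sign). The last two criteria exist because a
  diffusive excursion is occasionally straight over five frames; a true run
  advances by nearly the same displacement every frame, a walk does not.
  Everything else that moves is diffusive;
* two rescue passes: a straight, sign-consistent stretch below the 2 s
  minimum is still a (short) run when it is the motor's first act after
  attachment or the continuation of a run across a pause — without this the
  run-length sample is truncated from below — and a single-frame blip
  between two pauses is folded into the pause.

Segments tile the track; on generator-truth comparisons the labels agree
with the true state on ≈ 96% of attached time, with the residual
disagreement concentrated in the unavoidable one-frame transition zones.

Run metrics follow the field's conventions: a run bridges internal pauses
(the motor has not dissociated) and terminates at conversions to diffusion,
microtubule switches, end arrival or dissociation; run length is net arc
displacement; residency is the attached time span, with right-censored
tracks (still attached at the window end) flagged and excluded from
residency fits; runs that arrive at the plus end are flagged end-censored
and excluded from run-length fits. Pauses "during processive movement" are
PAUSED segments flanked on at least one side by processive motion, which
keeps the pause count honest when a pause is the run's final act. Fits are
maximum likelihood on raw values; the headline statistic is always the
sample median with a bootstrap (default 1000 resamples, seeded) SEM, with
the observed maximum reported alongside.

## Intersections

`detect_approaches()` finds contiguous intervals within the 200 nm capture
radius of a crossing (on either partner microtubule, so a switch is one
event); approaches must begin processively. `classify_event()` applies, in
order: detachment within one frame → DISSOCIATE; continued movement beyond
the radius on the other microtubule → SWITCH, on the same microtubule *and
through the crossing* → PASS (a pause at the intersection is folded into
either, with the in-radius time recorded); a dwell > 5 s without
continuation → PAUSE; shorter dwells ending in detachment → DISSOCIATE; a
trace ending in the radius at the observation-window end is indeterminate
and excluded from fractions but counted. The traversal requirement exists
because a run that happens to *end* inside the radius drifts back out
diffusively without crossing — that is not an intersection behaviour, and
without the check such events inflate the pass fraction by several points.

Because each switch starts an independent run on a new microtubule, the
effective reach of a single motor is `median run length × (n_switches + 1)`
(`predicted_reach()`), and `effective_path_length()` sums the realized
per-track runs.

## Photobleaching

`detect_steps()` fits a piecewise-constant signal by greedy binary
segmentation with a Schwarz-type criterion
`n·ln(RSS/n) + penalty·k·ln(n)`, ties toward fewer steps. On noiseless
staircases it is exact (the test suite checks equivalence against an
exhaustive dynamic-programming search). The penalty default is 3, not the
textbook 2: the greedy search maximises the gain over all split positions,
so the plain BIC penalty over-segments pure noise (~12% false positives at
n = 60 versus ~1.5% at penalty 3, with no loss of power at
step-height/noise ≥ 3). The default bleaching model (`fluor_model()`) uses
four fluorophores at 0.08 s⁻¹ over 75 s at 4 fps so that successive bleaches
of a tetramer are usually ≥ 2 frames apart; at much faster bleaching the
modal detected count drops to 3 because two fluorophores genuinely bleach
within one frame — a physical limit, not an algorithmic one.

## Optical trap

`simulate_trap_trace()` steps the bead away from the trap centre in 8 nm
increments (17.2 s⁻¹, i.e. ~138 nm/s at zero load) until the load reaches a
threshold drawn uniformly on [1.5, 3.5] pN per engagement; the motor
releases exactly at threshold (partial final step), holds for a short
latency (2 ms plus one exponential step-wait), then the bead snaps back and
the motor may re-engage. The latency is a rendering choice: without it, the
~2% of engagements whose final level lasts under the 1 ms boxcar width would
under-read the terminal load by up to one step (0.4 pN) in the filtered
trace. There is no force–velocity relation (none is available for this
motor) and the bead–motor linkage is rigid; positional noise is
phenomenological Gaussian. Detachment detection looks for snap-backs faster
than 10× the stepping speed from loads above half the minimum threshold and
reads the load from the pre-snap filtered position; on noiseless traces it
recovers every event with numerically exact loads. The lattice-inhibited
scenario (`tpx2_static = TRUE`) walks the motor to a super-threshold load
and holds indefinitely — the observable signature is a sustained
super-threshold excursion with no detected detachment.

## Binding statistics

`poisson_binding_prob()` implements P(≥1) = 1 − e^(−m) and
P(≥2) = 1 − e^(−m)(1 + m); `fit_poisson_binding()` fits both one-parameter
curves to a dilution series by least squares (unweighted by default, with an
optional `n_beads` weighting) and prefers the lower-SSE order, flagging the
comparison unresolved when the SSE difference is below both an absolute
floor and 1% of the series variance (saturated designs). The
co-sedimentation affinity uses the standard single-site hyperbola
`frac = bmax·[MT]/(Kd + [MT])` with free `bmax`, fitted by
Levenberg–Marquardt from a profiled 1-D start (with `bmax` linear given Kd,
the profile start makes the fit robust; designs that do not span Kd fall
back to the profile optimum with infinite standard errors and a warning).
Concentration (x-axis) error is outside the model.

## Problem sizes and what the tests do and do not show

The validation ensembles are 400–500 tracks for motility statistics (the
sample size of the reference velocity distributions), ~2600 short tracks for
≥ 800 classified intersection events, 500 trap engagements, ~200
photobleaching traces and 200 co-sedimentation replicates; at these sizes
the sample median of an exponential with ~400 observations carries a ~7%
standard error, which is the dominant term in the recovery spread. The
generator produces noiseless positions (localisation error and EMCCD noise
are out of scope, apart from Gaussian intensity/kymograph noise), so passing
recovery tests demonstrates that the analysis chain is faithful to the state
machine — not that it is robust to every artefact of real microscopy data.
Real tracks with heavy localisation noise would need the stationarity
detector's interval test replaced by a noise-aware one; the thresholds are
all exposed in `seg_config()` for that purpose.

## Known limitations

* 2-D geometry only; crossings have no axial separation, and microtubules
  do not grow, shrink or slide.
* Pause arrivals are path-length driven (per µm), matching the reported
  per-µm frequency; whether real pauses are positional or temporal is not
  distinguishable from the published statistics.
* Minus-end parameters (velocity, run length) are only loosely constrained
  by the source distributions; defaults are configurable and excluded from
  recovery targets.
* The intersection outcome probabilities are a free 4-vector; the default
  equal-likelihood setting reflects the qualitative statement in the source
  work, which also quotes a one-in-five switching rate — both statistics are
  surfaced by `summarize_event_fractions()` and the package does not
  adjudicate between them.
* Detachment under load is a hard threshold, not a Bell-type hazard; the
  published range is a range, and a uniform threshold draw is its most
  direct reading.
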