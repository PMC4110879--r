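---
title: "A minimal spiking micro-circuit for operant conditioning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal spiking micro-circuit for operant conditioning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeOC)
```

## The model

`spikeOC` simulates networks of discrete-time leaky integrate-and-fire
neurons in which every dynamical primitive is an integer lookup-table
curve on a normalized 0–100 scale.  The choice of integer lookup
tables over continuous membrane equations is deliberate: the dynamics
are exactly reproducible, cheap enough for embedded robot controllers,
and directly inspectable — a synaptic weight *w* indexes a 5-entry
curve of per-cycle membrane deltas, and that curve is the entire
transfer function of the synapse.

A neuron holds an integer potential in [0, 100] (0 = hyperpolarization
floor, 50 = rest, 63 = firing threshold, 100 = emitted spike).  Each
cycle it sums the current slices of all curves in flight; if the sum
drives it to threshold it spikes, resets to 20 and ignores input for 4
refractory cycles, after which the potential leaks back toward rest at
up to 8 units per cycle.  On input-free cycles the leak acts alone;
on input cycles the lookup deltas act alone.  This "inputs dominate
the cycle" contract is what makes the spec-level behavior of a single
curve exact: a curve's cumulative sum, added to the resting potential,
tells precisely when the neuron fires.

Sensory transducers convert a stimulus intensity into the same curve
family (a graded receptor potential), and motor neurons feed an
actuator accumulator that fires a discrete world action when it
crosses a trigger threshold, then resets (debouncing: one spike, one
action).

### Timing contract

Within every cycle the order is fixed: sense → transduce →
integrate/fire → plasticity update → actuate → world update.  A spike
emitted at cycle *t* contributes its 5-entry curve at cycles *t*+1 …
*t*+5, so all integrations read the previous cycle's spikes and the
trace is independent of the order in which neurons are declared (a
property test permutes the declaration order and asserts identical
traces).  A presynaptic re-spike starts a fresh curve that superposes
with the tail of the previous one.

### The three learning rules

*Sensory adaptation* guards transducers against constant stimuli: the
gain decays by ~12% of its current value per stimulated cycle (floor
10%) and recovers at 10%/cycle at stimulus offset, so a 1-in-20 duty
cycle leaves it essentially untouched while a constant color underfoot
slows the cue neuron's firing without silencing it.

*Habituation* multiplies a synapse's curve amplitude by an efficacy
that drops on every presynaptic spike — by 10 units for inter-spike
intervals ≤ 4 cycles, 6 for intervals up to 50, 3 beyond — and
recovers by 1 unit/cycle after 62 silent cycles.  Two choices here are
load-bearing.  First, the floor is 25%, not zero: a residual
transmission always remains, and the expectation behavior (below)
works *by temporal summation* of that residual with the predictor
pathway.  Second, the 62-cycle recovery delay is placed between the
longest same-color gap of the conveyor scenario (≤ 60 cycles — the
extinguished ejection reflex must not spontaneously recover there) and
the 100-cycle zone length of the floor-pressing scenario (where
recovery is exactly what lets a previously suppressed color be
re-sampled after the contingencies reverse).

*STDP* is pair-based with nearest-neighbor pairing: each spike
participates in at most one pairing, formed when the later spike of a
pre/post pair arrives within the ±15-cycle window.  The increment is
10 units at a 1-cycle gap, tapering linearly to 1 at the window edge;
depression mirrors it.  When no pairings occur for 60 cycles the
weight drifts back toward its baseline at 1 unit/cycle — forgetting,
which is the extinction mechanism when a cue is withdrawn, and the
re-sampling mechanism across contingency reversals.  Note that while a
cue keeps firing a potentiated link, the cue-driven predictor spikes
re-pair every volley, so acquired expectations persist indefinitely
under continued cueing without any special "memory" term.

## The conditioning kernel

The invariant micro-circuit is three neurons and three typed links:

| link | weight | rule |
|---|---|---|
| Cue → Action | 90 (strong) | habituation |
| Cue → Predictor | 20 (weak) | STDP |
| Predictor → Action | 40 (intermediate) | static |

with an outer box of two transducers (cue sense, reinforcer sense),
one actuator and three connecting synapses.  On this PSP table a
weight of 42 is the smallest that can fire a resting neuron on its
own (`soloFiringWeight()`), which gives the three weights their roles:
the cue alone fires the Action (90 ≥ 42, the reflex); the cue alone
cannot fire the Predictor (20 < 42); and — deliberately — the
Predictor alone cannot fire the Action either (40 < 42).  The
intermediate link only works by temporal summation with the residual
habituated cue PSP.  An intermediate weight above the solo-firing
point would let the reinforcer-driven predictor spike re-trigger the
action by itself, creating a reward–action loop that never
extinguishes; keeping it subthreshold makes the cue necessary for the
conditioned behavior, matching the observation that the action fires
only when the summed PSPs suffice.

For punishment-avoiding behavior the kernel's output coupling is
inhibitory.  In the dual kernel (reward and punishment on the same cue
and action) the punishment predictor inhibits the shared Action neuron
directly with the equal-and-opposite curve of the reward predictor's
excitation.  We considered routing this through dedicated inhibitory
interneurons, but with 5-cycle curves each interneuron hop costs ~2
cycles and the inhibition then always loses the race against the
excitatory threshold crossing; direct opposing convergence implements
the same mutual exclusion (when both predictors fire, at most the
withholding behavior is expressed) without the race.

## Scenario protocols and their timings

**Scenario A** (cued sound, delayed light reward, 300 cycles).  The
cue pulses every 13 cycles; each sound is rewarded with latency 2
until cycle 175.  The full action chain — cue relay, Action, motor,
actuator, world, reinforcer sense, Predictor — takes ≈ 12 cycles, so
the reward-driven Predictor spike pairs with the cue spike of its own
volley at a gap of 11–12 cycles (+3 per pairing).  The cue period of
13 was chosen against exactly this chain length: with a 10-cycle
period the predictor spike lands after the *next* volley's cue spike,
the pairing gap collapses to 1–2 cycles and acquisition completes
around cycle 45 — far too fast for a reflex phase to be observable at
all.  With the shipped configuration the reflex-driven phase ends at
cycle 96 and the handover to the predictor-driven pathway is seamless
(no action-free gap), because the volley-*k* predictor spike summates
with volley *k*+1's cue PSP.

**Scenario B** (reversal, 800 cycles) adds the punishment-avoiding
kernel on the same cue and action; reward during [0, 250), punishment
from cycle 500.  Once the Cue → PredictorP link crosses ~75 the
inhibition arrives aligned with the excitation and sounds cease — by
cycle ~584 with the defaults, i.e. well before the final quarter — and
PredictorP keeps firing from the cue alone without any further
punishment being delivered.

**Scenario C** (floor pressing, 8 zones × 100 cycles) duplicates the
kernel per color with a shared Action and both reinforcer polarities,
plus an arm-up touch reflex that caps the press rate.  Zones alternate
green/red; pressing green is rewarded and red punished until cycle
400, then reversed.  Re-sampling after the reversal rests on two decays
working together: the suppressed color's punishment expectation
forgets across a 100-cycle zone without its cue, and the habituated
reflex recovers ~38 units in the same gap — enough for the returning
reflex to beat the (defused) inhibition and rediscover the new
contingency.  The end state is evaluated on the final green window
(cycles 650–700, after the within-zone re-learning transient) and the
final red zone (700–800): zero green presses, continuing red presses.

**Scenario D** (conveyor sorting) is the only stochastic protocol: 44
pieces, inter-piece intervals 18–20 cycles, colors randomized in
balanced pairs, the color sensor seeing each piece for 4 cycles with
the piece in the flipper arm's reach from 4 to 14 cycles after
appearance, and the touch reward following a reinforced ejection with
latency 1–2 cycles.  All jitters are drawn once from the protocol
seed; the run itself is deterministic.  These bounds are not
arbitrary: the eject-to-predictor chain is ≈ 13 cycles, so intervals
much below 18 let the reward alias onto the *next* piece's cue
(cross-color credit corruption), while same-color gaps above the
62-cycle habituation recovery delay would revive the extinguished
reflex for the unreinforced color.  Within these conditions the
steady-state outcome over the last 15 pieces is exact across seeds:
reinforced color ejected at frequency 1.0, the other at 0.0, and
without any reinforcement ejection extinguishes for both colors.

## Calibration

Free dynamical parameters are fixed by `calibrateDefaults()`, a
deterministic first-hit grid search (habituation mid-ISI step × STDP
maximum change × Cue → Action weight, in a fixed order) against
protocol-level constraints: reflex cessation at cycle 100 ± 15,
predictor-driven resumption before the reward ends at 175, persistence
after reward removal, and completion of the scenario-B reversal before
the final quarter.  The shipped bundle (`ocDefaults()`) is the search's
output — mid-ISI step 6, maximum pair change 10, cue-action weight
90 — and a regression test asserts the rerun reproduces it
bit-exactly.

## Numerical choices

All state is integer; every scaling step (curve amplitudes, efficacy
rescaling) rounds half away from zero, applied to cumulative sums so a
rescaled curve's total equals the rounded total amplitude exactly.
Potentials clamp to [0, 100] after summation.  Ties and degenerate
cases are fixed by contract: simultaneous pre/post spikes (gap 0) form
no STDP pairing; a spike at the threshold reports the 100-unit spike
level in the trace while the stored state holds the reset value;
curves delivered during the refractory period are discarded entirely
rather than queued.  Cycle indexing is 0-based and phase intervals are
half-open.

## What the synthetic scenarios do and do not show

The worlds here are idealized: stimuli arrive on exact schedules (or
with small seeded jitter), reinforcers are perfectly contingent and
non-depleting, sensors are noiseless, and the integer dynamics are
fully deterministic.  Passing scenarios therefore demonstrate that the
kernel's mechanism — habituation gating, timing-based credit
assignment, summation-gated expression, forgetting-driven reversal —
is sufficient under its stated timing conditions, and the latency
probes show where it breaks (a reinforcer outside the STDP window
produces no selective learning).  They do not show robustness to
sensor noise, to reinforcer schedules sparser than the pairing window,
to overlapping multi-cue episodes, or to real-robot actuation delays;
on physical hardware every timing argument above would need to be
re-made against measured latencies.

## Limitations

Single elemental associations only: no eligibility traces or
distal-reward bridging (a reinforcer must land inside the STDP
window), no value system or action selection beyond opposing
convergence, no neuromodulator-specific curve shapes, and no
non-elemental discriminations.  The weight-ordering analysis further
shows success requires a strong cue–action and weak cue–predictor
link but does *not* require the intermediate link to be strictly
between them — the ordering is sufficient, not necessary, in this
implementation.
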