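# spikeOC

Operant conditioning (OC) — learning to do, or stop doing, a behavior
from its rewarding or punishing consequences — can be sustained by a
remarkably small spiking micro-circuit.  `spikeOC` implements that
minimal circuit and the discrete-time spiking-network simulator around
it, for computational neuroscientists and neuroroboticists who want a
fully inspectable, integer-exact testbed for elemental conditioning:
acquisition, expectation, reversal and extinction, in closed loop with
a simulated environment.

## The model

**Neurons.** Discrete-time leaky integrate-and-fire units on a
normalized integer scale: membrane potential *u* ∈ [0, 100], with 0 the
hyperpolarization floor, rest at 50, firing threshold θ = 63 and spike
level 100.  After a spike the neuron resets to θ₀ = 20 and is
absolutely refractory for T_r = 4 cycles; the potential then leaks back
toward rest.  In place of continuous membrane equations, all
time-extended quantities — post-synaptic potentials, graded receptor
potentials from sensors, graded motor potentials to actuators — are
5-cycle lookup-table curves indexed by synaptic weight (or stimulus
intensity) *w* ∈ [0, 100], each per-cycle entry bounded by 10 units.
Concurrent curves summate (temporal summation) before thresholding.

**Plasticity.** Three additive rules, all integer lookup curves:

- *Sensory adaptation* (transducers): fast proportional decay of gain
  under constant stimulation, fast recovery at stimulus offset.
- *Habituation* (synapses): per-spike decrement of synaptic efficacy
  whose step depends on the recent inter-stimulus interval, with slow
  recovery after prolonged silence — the mechanism that stops reflexive
  responding to a persistent cue.
- *STDP* (synapses): pair-based, nearest-neighbor spike-timing
  dependent plasticity in a ±15-cycle window (pre-before-post
  potentiates, post-before-pre depresses, magnitude tapering with the
  gap), plus a slow drift back to baseline when pairing ceases — the
  forgetting/extinction mechanism.

**The OC kernel.** Three neurons and three typed links: Cue → Action
(strong, habituating), Cue → Predictor (weak, STDP), Predictor → Action
(intermediate, static), plus an outer box of two transducers (cue and
reinforcer senses), one actuator, and three connecting synapses.  A
reinforcer that follows the agent's own action drives the Predictor
shortly after the Cue fired; STDP turns that correlation into a
strengthened Cue → Predictor link until the cue alone predicts the
reinforcer and — by summation with the residual habituated cue PSP —
sustains the action.  Swapping the action output to inhibitory yields
the punishment-avoiding variant; duplicating the kernel over cues or
reinforcer polarities composes the richer scenarios.

## A worked example

```r
library(spikeOC)

net <- buildKernel()          # the minimal OC circuit
kernelCensus(net)
#>     neurons    synapses habituation        stdp
#>           3           3           1           1

protocol <- scenarioA()       # cued sound task with delayed light reward
trace <- runScenario(protocol)
reflexCessationCycle(trace)
#> [1] 96
classifyPhases(trace, protocol)
#>         phase start end n_actions first_action last_action predictor_fraction n_reward n_punish classification
#> 1      reflex     0 100         7           10          87          0.857...        7        0    acquisition
#> 2  transition   100 175         6          100         166          1.0             6        0    acquisition
#> 3 expectation   175 300        10          179         298          1.0             0        0    expectation
```

The reflex-driven phase ends at cycle 96 (the last Action spike while
the Cue → Predictor weight is still too weak to fire the Predictor on
its own): habituation has silenced the direct pathway around cycle 100.
The reward stops at cycle 175, yet 10 further actions occur, every one
preceded by a Predictor spike — the behavior now runs on the learned
expectation of the reward, which is the operant-conditioning outcome.

Other entry points: `scenarioB()` (reward-then-punishment reversal),
`scenarioC()` (moving agent pressing colored floor zones, contingencies
reversed mid-run), `scenarioDSim(seed)` (conveyor-belt color sorting
with jittered timing), `runAblation()` (the four control conditions),
`calibrateDefaults()` (the deterministic parameter search behind the
shipped defaults), `plotTrace()`, and YAML/CSV round-tripping via
`writeConfig()` / `loadConfig()` / `writeTrace()`.  A thin command-line
wrapper is installed at `inst/cli/spikeoc`.

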