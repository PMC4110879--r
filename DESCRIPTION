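Package: spikeOC
Title: Operant Conditioning in Discrete-Time Spiking Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A discrete-time, integer-valued leaky integrate-and-fire
    spiking network simulator in which post-synaptic potentials, receptor
    potentials and motor potentials are all realized as short lookup-table
    curves on a normalized 0-100 scale.  Three plasticity rules (sensory
    adaptation at transducers, habituation and spike-timing dependent
    plasticity at synapses) are composed into a minimal three-neuron
    operant-conditioning kernel (Cue, Action, Predictor) that acquires,
    expresses, reverses and extinguishes conditioned behavior in
    closed-loop agent-environment scenarios: a cued sound-emission task
    with delayed reward, a reward-then-punishment reversal task, a moving
    agent pressing colored floor zones, and a simulated conveyor-belt
    color-sorting task.  Includes an ablation harness for the kernel's
    control conditions, a trace-phase classifier, a deterministic
    parameter calibration search, YAML network/scenario configuration,
    CSV trace output and trace plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
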