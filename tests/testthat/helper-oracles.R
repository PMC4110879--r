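# Shared fixtures and independent oracles for the suite.

# One default run per protocol, computed lazily and cached across tests.
.trace_cache <- new.env(parent = emptyenv())
cachedTrace <- function(key, builder) {
  if (is.null(.trace_cache[[key]])) {
    p <- builder()
    .trace_cache[[key]] <- list(protocol = p, trace = runScenario(p))
  }
  .trace_cache[[key]]
}
scenarioARun <- function() cachedTrace("A", scenarioA)
scenarioBRun <- function() cachedTrace("B", scenarioB)
scenarioCRun <- function() cachedTrace("C", scenarioC)

# A two-neuron relay network: a transducer drives `Pre`, which drives
# `Post` through a single synapse.
relayNet <- function(weight = 95L, polarity = "excitatory",
                     habituation = NULL, stdp = NULL) {
  net <- ocNetwork()
  net <- addNeuron(net, "Pre")
  net <- addNeuron(net, "Post")
  net <- addSynapse(net, "Pre", "Post", weight, polarity = polarity,
                    habituation = habituation, stdp = stdp)
  net <- addTransducer(net, "x", "Pre")
  net
}

pulseWorld <- function(cycles, period = 100L, width = 1L,
                       channels = "x") {
  ocWorld(channels = channels, cycles = cycles,
          schedules = list(list(channel = "x", period = period,
                                width = width, intensity = 100L)))
}

# Independent single-neuron oracle: replays a delta stream through the
# exported per-neuron operation, cycle by cycle.  Used to cross-check
# the vectorized engine.
oracleNeuronTrajectory <- function(params, delta_stream) {
  st <- neuronStateInit(params)
  out <- integer(length(delta_stream))
  for (i in seq_along(delta_stream)) {
    st <- integrateCycle(st, params, delta_stream[[i]], i - 1L)
    out[i] <- if (st$spiked_this_cycle) params$spike_level else st$potential
  }
  out
}

actionEvents <- function(run) actionCycles(run$trace, run$protocol)

# Plain data frame view of a trace, attributes stripped, for equality
# comparisons across subsetting.
stripTrace <- function(tr) {
  out <- as.data.frame(tr)
  attr(out, "phases") <- NULL
  attr(out, "pieces") <- NULL
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}
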