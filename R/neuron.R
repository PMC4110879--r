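#' Parameters of a discrete-time integer leaky integrate-and-fire neuron
#'
#' All quantities live on the normalized 0--100 membrane scale: 0 is
#' maximal hyperpolarization, 100 the level of an emitted spike, and the
#' firing threshold sits at 63 by default.  The leak is a per-cycle pull
#' of the potential toward `resting_potential`, applied on cycles with no
#' synaptic input (input cycles are dominated by their lookup-table
#' deltas).
#'
#' @param threshold Firing threshold (normalized units).  Default 63.
#' @param spike_level Reported potential on a spike cycle.  Fixed 100.
#' @param hyperpolarized_reset Potential entered after a spike.
#' @param resting_potential Equilibrium potential.
#' @param refractory_cycles Absolute refractory span in cycles during
#'   which incoming deltas are discarded.
#' @param leak_rate Maximum per-cycle decay step toward rest.
#'
#' @return An object of class `NeuronParams`.
#' @export
neuronParams <- function(threshold = 63L,
                         spike_level = 100L,
                         hyperpolarized_reset = 20L,
                         resting_potential = 50L,
                         refractory_cycles = 4L,
                         leak_rate = 8L) {
  p <- list(threshold = as.integer(threshold),
            spike_level = as.integer(spike_level),
            hyperpolarized_reset = as.integer(hyperpolarized_reset),
            resting_potential = as.integer(resting_potential),
            refractory_cycles = as.integer(refractory_cycles),
            leak_rate = as.integer(leak_rate))
  with(p, {
    if (!(0L <= hyperpolarized_reset &&
          hyperpolarized_reset < resting_potential &&
          resting_potential < threshold &&
          threshold < spike_level && spike_level == 100L))
      stop("neuron parameters must satisfy 0 <= hyperpolarized_reset < ",
           "resting_potential < threshold < spike_level = 100")
    if (refractory_cycles < 1L) stop("refractory_cycles must be >= 1")
    if (leak_rate < 1L) stop("leak_rate must be >= 1")
  })
  structure(p, class = "NeuronParams")
}

#' Initial state of a neuron
#'
#' @param params A [neuronParams()] object.
#' @return An object of class `NeuronState` with integer fields
#'   `potential`, `refractory_remaining`, `spiked_this_cycle`,
#'   `last_spike_cycle` (`NA` when the neuron has never spiked).
#' @export
neuronStateInit <- function(params) {
  structure(list(potential = params$resting_potential,
                 refractory_remaining = 0L,
                 spiked_this_cycle = FALSE,
                 last_spike_cycle = NA_integer_),
            class = "NeuronState")
}

# One leak step toward rest; returns the signed delta.
leakStep <- function(potential, params) {
  d <- params$resting_potential - potential
  as.integer(sign(d) * min(abs(d), params$leak_rate))
}

#' Advance a neuron by one simulation cycle
#'
#' Implements the per-cycle timing contract of the simulator.  If the
#' neuron is refractory, incoming deltas are discarded, the refractory
#' counter is decremented and the potential follows the post-spike
#' recovery trajectory toward rest.  Otherwise the incoming per-cycle
#' deltas (one slice of each active PSP, excitatory positive and
#' inhibitory negative) are summed; on cycles with no input a single leak
#' step toward rest is applied instead.  If the resulting potential
#' reaches the threshold the neuron spikes: `spiked_this_cycle` is set,
#' the trace-visible potential for the cycle is `spike_level`, and the
#' stored state enters `hyperpolarized_reset` with a full refractory
#' countdown.  The potential is clamped to 0--100 at every step.
#'
#' @param state A `NeuronState`.
#' @param params A `NeuronParams`.
#' @param incoming_deltas Integer vector (possibly empty) of signed
#'   per-cycle deltas from active PSPs.
#' @param cycle Current cycle index (0-based).
#' @return The updated `NeuronState`.
#' @export
integrateCycle <- function(state, params, incoming_deltas = integer(0),
                           cycle = 0L) {
  state$spiked_this_cycle <- FALSE
  if (state$refractory_remaining > 0L) {
    state$refractory_remaining <- state$refractory_remaining - 1L
    state$potential <- clamp01(state$potential + leakStep(state$potential, params))
    return(state)
  }
  total <- as.integer(sum(incoming_deltas))
  if (length(incoming_deltas) == 0L || total == 0L && all(incoming_deltas == 0L)) {
    pot <- clamp01(state$potential + leakStep(state$potential, params))
  } else {
    pot <- clamp01(state$potential + total)
  }
  if (pot >= params$threshold) {
    state$spiked_this_cycle <- TRUE
    state$last_spike_cycle <- as.integer(cycle)
    state$potential <- params$hyperpolarized_reset
    state$refractory_remaining <- params$refractory_cycles
  } else {
    state$potential <- as.integer(pot)
  }
  state
}

#' @export
print.NeuronParams <- function(x, ...) {
  cat("NeuronParams: threshold ", x$threshold, ", rest ",
      x$resting_potential, ", reset ", x$hyperpolarized_reset,
      ", refractory ", x$refractory_cycles, " cycles, leak ",
      x$leak_rate, "/cycle\n", sep = "")
  invisible(x)
}
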