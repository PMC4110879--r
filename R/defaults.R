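#' Shipped calibrated default configuration
#'
#' The simulator's free parameters — inner kernel weights, habituation
#' decay/recovery steps, STDP window and increments, adaptation rates and
#' the scenario protocol timings — in one bundle.  The values are the
#' output of the deterministic calibration search
#' ([calibrateDefaults()]), which fixes them against three protocol-level
#' constraints: the cued reflex must cease around cycle 100 under
#' habituation, reward-prediction must be acquired before reward removal
#' at cycle 175, and the reward-to-punishment reversal must complete
#' within the punishment phase.  A regression test asserts that rerunning
#' the calibration reproduces this bundle exactly.
#'
#' @return A named list of parameter groups.
#' @export
ocDefaults <- function() {
  list(
    weights = c(cue_action = 90L, predictor_action = 40L,
                cue_predictor = 20L, relay = 95L),
    habituation = list(decay_steps = c(short = 10L, mid = 6L, long = 3L),
                       isi_breaks = c(4L, 50L),
                       recovery_delay = 62L, recovery_step = 1L,
                       floor = 25L),
    stdp = list(window = 15L, max_change = 10L,
                forget_delay = 60L, forget_step = 1L),
    adaptation = list(decay_fraction = 0.12, min_decay_step = 3L,
                      recovery_step = 10L, floor = 10L),
    actuator = list(trigger_threshold = 15L),
    scenario_a = list(cycles = 300L, cue_period = 13L,
                      cue_intensity = 100L, reward_end = 175L,
                      reward_latency = 2L),
    scenario_b = list(cycles = 800L, cue_period = 13L,
                      reward_end = 250L, punish_start = 500L,
                      latency = 2L),
    scenario_c = list(zones = c("color-green", "color-red",
                                "color-green", "color-red",
                                "color-green", "color-red",
                                "color-green", "color-red"),
                      cycles_per_zone = 100L, reversal_zone = 5L,
                      latency = 2L),
    scenario_d = list(n_pieces = 44L, base_interval = 18L,
                      interval_jitter = 2L, piece_window = 14L,
                      stim_window = 4L, reach_delay = 4L,
                      eject_threshold = 8L,
                      touch_latency_range = c(1L, 2L))
  )
}

# Plasticity-state constructors from a defaults bundle.
defaultHabituation <- function(defaults = ocDefaults()) {
  do.call(habituationState, defaults$habituation)
}
defaultStdp <- function(baseline, defaults = ocDefaults()) {
  h <- defaults$stdp
  stdpState(window = h$window, max_change = h$max_change,
            baseline = baseline, forget_delay = h$forget_delay,
            forget_step = h$forget_step)
}
defaultAdaptation <- function(defaults = ocDefaults()) {
  do.call(adaptationState, defaults$adaptation)
}

#' Minimum synaptic weight able to fire a resting neuron with one PSP
#'
#' The smallest weight whose lookup-table curve, arriving with the
#' post-synaptic neuron at rest, cumulatively crosses the firing
#' threshold on its own.  Weights below this value are "weak" in the
#' kernel sense: they need reinforcer-driven or temporally summated help.
#'
#' @param table A `PspTable`.
#' @param params A `NeuronParams`.
#' @return Integer weight in 0--100 (or `NA` if no weight suffices).
#' @export
soloFiringWeight <- function(table = buildPspTable(),
                             params = neuronParams()) {
  gap <- params$threshold - params$resting_potential
  peaks <- apply(unclass(table), 1L, function(cv) max(cumsum(cv)))
  w <- which(peaks >= gap)
  if (!length(w)) NA_integer_ else as.integer(w[1] - 1L)
}
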