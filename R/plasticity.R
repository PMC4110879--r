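#' Sensory adaptation state for a transducer
#'
#' Fast, transducer-level gain control: under stimulation the efficacy
#' (percent multiplying the transducer output) falls along a fast
#' proportional decay; as soon as stimulation ceases it recovers quickly.
#' Adaptation restricts the data flow of constant stimuli without ever
#' silencing a transducer completely.
#'
#' @param decay_fraction Fraction of the current efficacy shed per
#'   stimulated cycle (applied with integer rounding, minimum step
#'   `min_decay_step`).
#' @param min_decay_step Smallest per-cycle decay step.
#' @param recovery_step Efficacy gained per unstimulated cycle.
#' @param floor Minimum efficacy under sustained stimulation.
#' @return An object of class `AdaptationState` with `efficacy` 100.
#' @export
adaptationState <- function(decay_fraction = 0.12,
                            min_decay_step = 3L,
                            recovery_step = 10L,
                            floor = 10L) {
  structure(list(efficacy = 100L,
                 decay_fraction = decay_fraction,
                 min_decay_step = as.integer(min_decay_step),
                 recovery_step = as.integer(recovery_step),
                 floor = as.integer(floor),
                 cycles_since_stimulus = 0L),
            class = "AdaptationState")
}

#' Apply one cycle of sensory adaptation
#'
#' @param state An `AdaptationState`.
#' @param stimulus_present Logical: is the transducer's channel active
#'   this cycle?
#' @return The updated state; `efficacy` stays in `[floor, 100]` while
#'   stimulated and recovers to 100 when stimulation ceases.
#' @export
applyAdaptation <- function(state, stimulus_present) {
  if (isTRUE(stimulus_present)) {
    step <- max(state$min_decay_step,
                as.integer(rha(state$decay_fraction * state$efficacy)))
    state$efficacy <- max(state$floor, state$efficacy - step)
    state$cycles_since_stimulus <- 0L
  } else {
    state$efficacy <- min(100L, state$efficacy + state$recovery_step)
    state$cycles_since_stimulus <- state$cycles_since_stimulus + 1L
  }
  state
}

#' Habituation state for a synapse
#'
#' Habituation multiplies the synapse's PSP amplitude by an efficacy
#' percentage that decrements on every presynaptic spike and recovers
#' slowly during prolonged silence.  The per-spike decrement depends on
#' the recent inter-stimulus interval (ISI): dense spike trains habituate
#' faster than sparse ones.  The efficacy never falls below `floor`, so a
#' residual transmission always remains available for temporal summation
#' with other inputs.
#'
#' @param decay_steps Named integer vector of per-spike decrements for
#'   the three ISI buckets `short`, `mid`, `long`.
#' @param isi_breaks Two integers: ISIs `<= isi_breaks[1]` fall in the
#'   `short` bucket, ISIs `<= isi_breaks[2]` in `mid`, larger ones (and
#'   the first spike ever) in `long`.
#' @param recovery_delay Silent cycles before recovery begins.
#' @param recovery_step Efficacy gained per cycle once recovering.
#' @param floor Minimum efficacy (percent).
#' @return An object of class `HabituationState` with `efficacy` 100.
#' @export
habituationState <- function(decay_steps = c(short = 10L, mid = 8L, long = 3L),
                             isi_breaks = c(4L, 30L),
                             recovery_delay = 50L,
                             recovery_step = 1L,
                             floor = 25L) {
  structure(list(efficacy = 100L,
                 decay_steps = decay_steps,
                 isi_breaks = as.integer(isi_breaks),
                 recovery_delay = as.integer(recovery_delay),
                 recovery_step = as.integer(recovery_step),
                 floor = as.integer(floor),
                 last_pre_cycle = NA_integer_,
                 cycles_since_pre = 0L),
            class = "HabituationState")
}

#' Apply one cycle of habituation
#'
#' On a presynaptic spike the efficacy is decremented by the decay step
#' for the current ISI bucket; after `recovery_delay` cycles of
#' presynaptic silence it recovers by `recovery_step` per cycle back
#' toward 100.
#'
#' @param state A `HabituationState`.
#' @param pre_spiked Logical: did the presynaptic neuron spike this
#'   cycle?
#' @param cycle Current cycle index.
#' @return The updated state.
#' @export
applyHabituation <- function(state, pre_spiked, cycle) {
  if (isTRUE(pre_spiked)) {
    isi <- if (is.na(state$last_pre_cycle)) NA_integer_
           else as.integer(cycle) - state$last_pre_cycle
    bucket <- if (is.na(isi) || isi > state$isi_breaks[2]) "long"
              else if (isi <= state$isi_breaks[1]) "short"
              else "mid"
    state$efficacy <- max(state$floor,
                          state$efficacy - state$decay_steps[[bucket]])
    state$last_pre_cycle <- as.integer(cycle)
    state$cycles_since_pre <- 0L
  } else {
    state$cycles_since_pre <- state$cycles_since_pre + 1L
    if (state$cycles_since_pre > state$recovery_delay) {
      state$efficacy <- min(100L, state$efficacy + state$recovery_step)
    }
  }
  state
}

#' Spike-timing dependent plasticity state for a synapse
#'
#' Pair-based STDP with nearest-neighbor pairing: within a coincidence
#' window of `window` cycles, a presynaptic spike followed by a
#' postsynaptic spike potentiates the weight and the reverse order
#' depresses it, with a magnitude that decreases linearly with the timing
#' gap.  Each spike participates in at most one pairing.  When no
#' pairings occur for `forget_delay` cycles the weight drifts back toward
#' its configured baseline by `forget_step` per cycle — the forgetting /
#' extinction mechanism.
#'
#' @param window Coincidence half-window in cycles.
#' @param max_change Largest single-pair weight change (at a 1-cycle
#'   gap); changes are bounded by the global 10-unit convention.
#' @param baseline Weight toward which the synapse drifts when idle.
#' @param forget_delay Pairing-free cycles before drift begins.
#' @param forget_step Drift per cycle once forgetting.
#' @return An object of class `StdpState`.
#' @export
stdpState <- function(window = 15L,
                      max_change = 10L,
                      baseline = 20L,
                      forget_delay = 60L,
                      forget_step = 1L) {
  stopifnot(max_change <= 10L, window >= 1L)
  structure(list(window = as.integer(window),
                 max_change = as.integer(max_change),
                 baseline = as.integer(baseline),
                 forget_delay = as.integer(forget_delay),
                 forget_step = as.integer(forget_step),
                 last_pre = NA_integer_,
                 last_post = NA_integer_,
                 pre_paired = TRUE,
                 post_paired = TRUE,
                 cycles_since_pairing = 0L),
            class = "StdpState")
}

#' STDP weight increment for a signed spike-timing gap
#'
#' @param state A `StdpState`.
#' @param dt Signed gap `t_post - t_pre` in cycles.
#' @return Positive integer for `dt` in `(0, window]`, negative for `dt`
#'   in `[-window, 0)`, zero at `dt = 0` and outside the window.  The
#'   magnitude is non-increasing in `abs(dt)`.
#' @export
stdpIncrement <- function(state, dt) {
  a <- abs(dt)
  if (dt == 0L || a > state$window) return(0L)
  mag <- as.integer(rha(state$max_change * (state$window + 1L - a) /
                          state$window))
  mag <- max(1L, mag)
  if (dt > 0L) mag else -mag
}

#' Apply one cycle of STDP to a synaptic weight
#'
#' Call once per cycle with this cycle's pre/post spike flags.  At most
#' one new nearest-neighbor pairing is formed per cycle; the weight is
#' clamped to 0--100.  Pairing-free stretches longer than the forgetting
#' delay drift the weight toward its baseline.
#'
#' @param state A `StdpState`.
#' @param weight Current integer weight.
#' @param pre_spiked,post_spiked Logical spike flags for this cycle.
#' @param cycle Current cycle index.
#' @return List with the updated `state` and `weight`.
#' @export
applyStdp <- function(state, weight, pre_spiked, post_spiked, cycle) {
  cycle <- as.integer(cycle)
  paired <- FALSE
  if (isTRUE(pre_spiked)) {
    state$last_pre <- cycle
    state$pre_paired <- FALSE
  }
  if (isTRUE(post_spiked)) {
    state$last_post <- cycle
    state$post_paired <- FALSE
  }
  # Nearest-neighbor pairing: the most recent unpaired pre/post pair,
  # evaluated when the later of the two spikes arrives.
  if (!is.na(state$last_pre) && !is.na(state$last_post) &&
      !(state$pre_paired && state$post_paired)) {
    dt <- state$last_post - state$last_pre
    if (dt != 0L && abs(dt) <= state$window &&
        !state$pre_paired && !state$post_paired) {
      weight <- clamp01(weight + stdpIncrement(state, dt))
      state$pre_paired <- TRUE
      state$post_paired <- TRUE
      paired <- TRUE
    }
  }
  if (paired) {
    state$cycles_since_pairing <- 0L
  } else {
    state$cycles_since_pairing <- state$cycles_since_pairing + 1L
    if (state$cycles_since_pairing > state$forget_delay &&
        weight != state$baseline) {
      d <- sign(state$baseline - weight)
      weight <- weight + d * min(state$forget_step,
                                 abs(state$baseline - weight))
    }
  }
  list(state = state, weight = as.integer(weight))
}
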