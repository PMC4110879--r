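#' Create an empty network specification
#'
#' A network is a set of named neurons, directed synapses, sensory
#' transducers bridging world stimulus channels onto neurons, and
#' actuators mapping motor-neuron spike trains onto discrete world
#' actions.  All potentials, weights and intensities live on the
#' normalized integer 0--100 scale and all time-extended quantities are
#' 5-cycle lookup-table curves drawn from one shared [buildPspTable()]
#' family.
#'
#' @param psp_table The shared `PspTable`; defaults to the package
#'   default table.
#' @return An object of class `ocNetwork`.
#' @export
ocNetwork <- function(psp_table = buildPspTable()) {
  structure(list(neurons = list(), synapses = list(),
                 transducers = list(), actuators = list(),
                 psp_table = psp_table),
            class = "ocNetwork")
}

#' @rdname ocNetwork
#' @param net An `ocNetwork`.
#' @param id Neuron identifier (character).
#' @param params A [neuronParams()] object.
#' @export
addNeuron <- function(net, id, params = neuronParams()) {
  stopifnot(inherits(net, "ocNetwork"), is.character(id))
  if (id %in% names(net$neurons)) stop("duplicate neuron id: ", id)
  net$neurons[[id]] <- params
  net
}

#' @rdname ocNetwork
#' @param pre,post Neuron ids of the synapse endpoints.
#' @param weight Integer synaptic weight in 0--100.
#' @param polarity `"excitatory"` or `"inhibitory"`; inhibitory synapses
#'   deliver negated PSP deltas.
#' @param habituation Optional [habituationState()] attached to the
#'   synapse.
#' @param stdp Optional [stdpState()] attached to the synapse.
#' @param synapse_id Optional explicit id; defaults to `"pre->post"`.
#' @export
addSynapse <- function(net, pre, post, weight,
                       polarity = c("excitatory", "inhibitory"),
                       habituation = NULL, stdp = NULL,
                       synapse_id = NULL) {
  polarity <- match.arg(polarity)
  weight <- as.integer(weight)
  if (weight < 0L || weight > 100L)
    stop("synaptic weight must lie in [0, 100]")
  id <- if (is.null(synapse_id)) paste0(pre, "->", post) else synapse_id
  if (id %in% names(net$synapses)) stop("duplicate synapse id: ", id)
  net$synapses[[id]] <- list(pre = pre, post = post, weight = weight,
                             polarity = polarity,
                             habituation = habituation, stdp = stdp)
  net
}

#' @rdname ocNetwork
#' @param channel Named world stimulus channel (e.g. `"vibration"`,
#'   `"light"`, `"heat"`, `"color-green"`, `"color-red"`,
#'   `"color-blue"`, `"touch"`, `"sound"`).
#' @param target Neuron id receiving the graded receptor potential.
#' @param adaptation Optional [adaptationState()] attached to the
#'   transducer.
#' @export
addTransducer <- function(net, channel, target, adaptation = NULL) {
  id <- paste0("t:", channel, "->", target)
  if (id %in% names(net$transducers)) stop("duplicate transducer: ", id)
  net$transducers[[id]] <- list(channel = channel, target = target,
                                adaptation = adaptation)
  net
}

#' @rdname ocNetwork
#' @param action Named world action the actuator produces (e.g.
#'   `"emit-sound"`, `"arm-down"`, `"arm-up"`, `"eject"`).
#' @param source Motor neuron id feeding the actuator.
#' @param trigger_threshold Accumulated motor potential required to fire
#'   the world action, after which the accumulator resets (debouncing).
#' @export
addActuator <- function(net, action, source, trigger_threshold = 15L) {
  if (action %in% names(net$actuators))
    stop("duplicate actuator for action: ", action)
  net$actuators[[action]] <- list(action = action, source = source,
                                  trigger_threshold = as.integer(trigger_threshold))
  net
}

#' Validate a network specification
#'
#' Checks referential integrity (every synapse, transducer and actuator
#' endpoint names an existing neuron) and value ranges.  Called at load
#' time so that malformed configurations fail before any simulation.
#'
#' @param net An `ocNetwork`.
#' @param channels Optional character vector of world channels; when
#'   given, transducer channels must be among them.
#' @return `net`, invisibly, or an error naming the offending id.
#' @export
validateNetwork <- function(net, channels = NULL) {
  ids <- names(net$neurons)
  for (sid in names(net$synapses)) {
    s <- net$synapses[[sid]]
    if (!s$pre %in% ids)
      stop("synapse ", sid, " references unknown presynaptic neuron: ", s$pre)
    if (!s$post %in% ids)
      stop("synapse ", sid, " references unknown postsynaptic neuron: ", s$post)
  }
  for (tid in names(net$transducers)) {
    tr <- net$transducers[[tid]]
    if (!tr$target %in% ids)
      stop("transducer ", tid, " references unknown neuron: ", tr$target)
    if (!is.null(channels) && !tr$channel %in% channels)
      stop("transducer ", tid, " references unknown channel: ", tr$channel)
  }
  for (aid in names(net$actuators)) {
    a <- net$actuators[[aid]]
    if (!a$source %in% ids)
      stop("actuator ", aid, " references unknown neuron: ", a$source)
  }
  invisible(net)
}

#' @export
print.ocNetwork <- function(x, ...) {
  cat("ocNetwork: ", length(x$neurons), " neurons, ",
      length(x$synapses), " synapses, ", length(x$transducers),
      " transducers, ", length(x$actuators), " actuators\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------
# Simulation engine.
#
# Timing contract (fixed, global): within every cycle the order is
# sense -> transduce -> integrate/fire -> plasticity -> actuate -> world
# update.  A spike emitted at cycle t schedules one 5-entry delta
# sequence per outgoing synapse, applied at cycles t+1 .. t+5, so all
# integrations read the previous cycle's spike outputs and the trace is
# independent of neuron ordering.  In-flight PSPs live in a per-neuron
# shift register; a presynaptic re-spike starts a fresh curve that
# superposes with the tail of the previous one.
# ---------------------------------------------------------------------

#' Initialize the runtime state of a network
#'
#' @param net A validated `ocNetwork`.
#' @return An opaque state list consumed by [stepNetwork()].
#' @export
networkStateInit <- function(net) {
  ids <- names(net$neurons) %||% character(0)
  n <- length(ids)
  getp <- function(f) vapply(net$neurons, `[[`, integer(1), f)
  len <- attr(net$psp_table, "curve_length")
  list(
    ids = ids,
    thr = getp("threshold"), rest = getp("resting_potential"),
    reset = getp("hyperpolarized_reset"), refr = getp("refractory_cycles"),
    leak = getp("leak_rate"), spike_level = getp("spike_level"),
    potential = getp("resting_potential"),
    refractory = integer(n),
    spiked = logical(n),
    last_spike = rep(NA_integer_, n),
    pending = matrix(0L, n, len, dimnames = list(ids, NULL)),
    pending_abs = matrix(0L, n, len, dimnames = list(ids, NULL)),
    syn_weight = vapply(net$synapses, `[[`, integer(1), "weight"),
    habituation = lapply(net$synapses, `[[`, "habituation"),
    stdp = lapply(net$synapses, `[[`, "stdp"),
    adaptation = lapply(net$transducers, `[[`, "adaptation"),
    act_accum = stats::setNames(integer(length(net$actuators)),
                                names(net$actuators)),
    act_pending = matrix(0L, length(net$actuators), len,
                         dimnames = list(names(net$actuators), NULL))
  )
}

# Add an integer curve to a neuron's shift register.
queueCurve <- function(st, target, curve) {
  cv <- as.integer(curve)
  st$pending[target, ] <- st$pending[target, ] + cv
  st$pending_abs[target, ] <- st$pending_abs[target, ] + abs(cv)
  st
}

#' Advance a network by one synchronous cycle
#'
#' Executes the fixed per-cycle order (sense, transduce, integrate/fire,
#' plasticity, actuate) for one cycle.  World bookkeeping (contingent
#' reinforcers, arm and conveyor mechanics) is handled by [runNetwork()].
#'
#' @param net A validated `ocNetwork`.
#' @param st State from [networkStateInit()] or a previous step.
#' @param world_inputs Named integer vector of stimulus intensities per
#'   channel for this cycle (missing channels are silent).
#' @param cycle 0-based cycle index.
#' @return List with elements `state`, `actions` (character vector of
#'   world actions fired this cycle) and `row` (named integer vector: the
#'   trace row for this cycle).
#' @export
stepNetwork <- function(net, st, world_inputs = integer(0), cycle = 0L) {
  len <- ncol(st$pending)
  nn <- nrow(st$pending)
  deltas <- st$pending[, 1L]
  has_input <- st$pending_abs[, 1L] > 0L
  st$pending <- cbind(st$pending[, -1L, drop = FALSE], rep(0L, nn))
  st$pending_abs <- cbind(st$pending_abs[, -1L, drop = FALSE], rep(0L, nn))

  # -- transduce: stimuli inject receptor-potential curves (visible from
  #    the next cycle on), attenuated by sensory adaptation.
  for (tid in names(net$transducers)) {
    tr <- net$transducers[[tid]]
    inten <- world_inputs[tr$channel]
    inten <- if (is.na(inten) || length(inten) == 0L) 0L else as.integer(inten)
    ad <- st$adaptation[[tid]]
    eff <- 100L
    if (!is.null(ad)) {
      ad <- applyAdaptation(ad, inten > 0L)
      st$adaptation[[tid]] <- ad
      eff <- ad$efficacy
    }
    if (inten > 0L) {
      st <- queueCurve(st, tr$target,
                       scaledCurve(net$psp_table, inten, eff))
    }
  }

  # -- integrate / fire (vectorized over neurons).
  refr_now <- st$refractory > 0L
  lk <- as.integer(sign(st$rest - st$potential) *
                     pmin(abs(st$rest - st$potential), st$leak))
  pot <- ifelse(has_input, clamp01(st$potential + deltas),
                st$potential + lk)
  pot[refr_now] <- (st$potential + lk)[refr_now]
  spiked <- !refr_now & pot >= st$thr
  st$refractory[refr_now] <- st$refractory[refr_now] - 1L
  report <- as.integer(pot)
  report[spiked] <- st$spike_level[spiked]
  pot[spiked] <- st$reset[spiked]
  st$refractory[spiked] <- st$refr[spiked]
  st$last_spike[spiked] <- as.integer(cycle)
  st$potential <- as.integer(pot)
  st$spiked <- spiked

  # -- plasticity and synaptic packet emission (this cycle's spikes feed
  #    the next cycle's integration).
  syn_eff <- integer(length(net$synapses))
  names(syn_eff) <- names(net$synapses)
  for (k in seq_along(net$synapses)) {
    s <- net$synapses[[k]]
    sid <- names(net$synapses)[k]
    pre_spk <- st$spiked[[match(s$pre, st$ids)]]
    post_spk <- st$spiked[[match(s$post, st$ids)]]
    hb <- st$habituation[[sid]]
    eff <- if (is.null(hb)) 100L else hb$efficacy
    if (pre_spk) {
      sgn <- if (s$polarity == "inhibitory") -1L else 1L
      st <- queueCurve(st, s$post,
                       scaledCurve(net$psp_table, st$syn_weight[[sid]],
                                   eff, sgn))
    }
    if (!is.null(hb)) {
      hb <- applyHabituation(hb, pre_spk, cycle)
      st$habituation[[sid]] <- hb
      eff <- hb$efficacy
    }
    sp <- st$stdp[[sid]]
    if (!is.null(sp)) {
      res <- applyStdp(sp, st$syn_weight[[sid]], pre_spk, post_spk, cycle)
      st$stdp[[sid]] <- res$state
      st$syn_weight[[sid]] <- res$weight
    }
    syn_eff[[sid]] <- eff
  }

  # -- actuate: motor spikes feed graded motor-potential curves into the
  #    actuator accumulator; crossing the trigger threshold fires the
  #    world action and resets (debouncing).
  actions <- character(0)
  if (length(net$actuators)) {
    acc_in <- st$act_pending[, 1L]
    st$act_pending <- cbind(st$act_pending[, -1L, drop = FALSE], 0L)
    st$act_accum <- st$act_accum + acc_in
    for (aid in names(net$actuators)) {
      a <- net$actuators[[aid]]
      if (st$spiked[[match(a$source, st$ids)]]) {
        st$act_pending[aid, ] <- st$act_pending[aid, ] +
          pspCurve(net$psp_table, 100L)
      }
      if (st$act_accum[[aid]] >= a$trigger_threshold) {
        actions <- c(actions, aid)
        st$act_accum[[aid]] <- 0L
        st$act_pending[aid, ] <- 0L
      }
    }
  }

  row <- c(cycle = as.integer(cycle),
           if (length(st$ids))
             stats::setNames(report, paste0("pot_", st$ids)),
           if (length(st$ids))
             stats::setNames(as.integer(spiked), paste0("spk_", st$ids)),
           if (length(net$synapses))
             stats::setNames(as.integer(st$syn_weight),
                             paste0("w_", names(net$synapses))),
           if (length(net$synapses))
             stats::setNames(as.integer(syn_eff),
                             paste0("eff_", names(net$synapses))),
           if (length(net$transducers))
             stats::setNames(vapply(names(net$transducers), function(tid) {
               ad <- st$adaptation[[tid]]
               if (is.null(ad)) 100L else ad$efficacy
             }, integer(1)), paste0("adapt_", names(net$transducers))))
  list(state = st, actions = actions, row = row)
}
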