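#' The minimal operant-conditioning kernel
#'
#' The invariant inner micro-circuit is three neurons and three typed
#' synapses: a Cue neuron drives an Action neuron through a strong,
#' habituating link and a Predictor neuron through a weak link carrying
#' spike-timing dependent plasticity; the Predictor drives the Action
#' through a static link of intermediate strength.  The contextual outer
#' box supplies at least two transducers (cue input and reinforcer
#' input), one actuator, and three connecting synapses: a sensory relay
#' into Cue, the reinforcer sense onto Predictor, and the Action output
#' onto a motor neuron feeding the actuator.  When the reinforcer-driven
#' Predictor spike follows a Cue spike within the STDP window, the weak
#' Cue-Predictor link strengthens until the cue alone predicts the
#' reinforcer and sustains the behavior.
#'
#' `buildKernel` appends the kernel (inner and outer box) to a network.
#' For a `"punishment-avoiding"` kernel the Action-to-motor coupling is
#' inhibitory, so learning decreases the behavior instead of increasing
#' it.
#'
#' @param net An `ocNetwork` to extend (a fresh one by default).
#' @param cue_channel World channel sensed as the cue.
#' @param reinforcer_channel World channel sensed as the reinforcer.
#' @param action_name World action driven by the kernel.
#' @param polarity `"reward-seeking"` (excitatory action output) or
#'   `"punishment-avoiding"` (inhibitory action output).
#' @param weights Optional named overrides of
#'   `c(cue_action, predictor_action, cue_predictor, relay)`.
#' @param prefix Id prefix, so kernels can be composed in one network.
#' @param defaults Parameter bundle from [ocDefaults()].
#' @param validate Check the kernel invariants (disable only for
#'   deliberate exploration of invalid weight orderings).
#' @return The extended `ocNetwork`, with the kernel recorded in
#'   `attr(net, "kernels")` as an `OcKernelSpec`.
#' @export
buildKernel <- function(cue_channel = "vibration",
                        reinforcer_channel = "light",
                        action_name = "emit-sound",
                        polarity = c("reward-seeking", "punishment-avoiding"),
                        weights = NULL,
                        prefix = "",
                        net = ocNetwork(),
                        defaults = ocDefaults(),
                        validate = TRUE) {
  polarity <- match.arg(polarity)
  w <- defaults$weights
  if (!is.null(weights)) w[names(weights)] <- as.integer(weights)
  p <- function(id) paste0(prefix, id)

  for (id in c("CueInput", "Cue", "Action", "Predictor", "Reinforcer",
               "Motor"))
    net <- addNeuron(net, p(id))

  net <- addSynapse(net, p("Cue"), p("Action"), w[["cue_action"]],
                    habituation = defaultHabituation(defaults))
  net <- addSynapse(net, p("Cue"), p("Predictor"), w[["cue_predictor"]],
                    stdp = defaultStdp(w[["cue_predictor"]], defaults))
  net <- addSynapse(net, p("Predictor"), p("Action"),
                    w[["predictor_action"]])
  net <- addSynapse(net, p("CueInput"), p("Cue"), w[["relay"]])
  net <- addSynapse(net, p("Reinforcer"), p("Predictor"), w[["relay"]])
  net <- addSynapse(net, p("Action"), p("Motor"), w[["relay"]],
                    polarity = if (polarity == "punishment-avoiding")
                      "inhibitory" else "excitatory")
  net <- addTransducer(net, cue_channel, p("CueInput"))
  net <- addTransducer(net, reinforcer_channel, p("Reinforcer"))
  net <- addActuator(net, action_name, p("Motor"),
                     defaults$actuator$trigger_threshold)

  spec <- structure(list(cue = p("Cue"), action = p("Action"),
                         predictor = p("Predictor"),
                         cue_action = paste0(p("Cue"), "->", p("Action")),
                         cue_predictor = paste0(p("Cue"), "->", p("Predictor")),
                         predictor_action = paste0(p("Predictor"), "->", p("Action")),
                         polarity = polarity),
                    class = "OcKernelSpec")
  attr(net, "kernels") <- c(attr(net, "kernels"), list(spec))
  if (validate) validateKernel(net, spec)
  net
}

#' Validate the kernel invariants
#'
#' Checks the structural contract of the minimal operant-conditioning
#' kernel: exactly three inner neurons and three inner synapses, the
#' weight ordering `cue_action > predictor_action > cue_predictor`, a
#' habituation rule (and no STDP) on the Cue-Action link, an STDP rule
#' (and no habituation) on the Cue-Predictor link, and a plain static
#' Predictor-Action link.
#'
#' @param net An `ocNetwork` containing the kernel.
#' @param kernel An `OcKernelSpec` (default: the first recorded kernel).
#' @return `TRUE` invisibly, or an error naming the violated invariant.
#' @export
validateKernel <- function(net, kernel = attr(net, "kernels")[[1]]) {
  syn <- net$synapses
  need <- c(kernel$cue_action, kernel$cue_predictor,
            kernel$predictor_action)
  missing <- setdiff(need, names(syn))
  if (length(missing))
    stop("kernel synapse missing: ", paste(missing, collapse = ", "))
  inner <- c(kernel$cue, kernel$action, kernel$predictor)
  if (length(unique(inner)) != 3L || !all(inner %in% names(net$neurons)))
    stop("kernel must contain exactly 3 distinct inner neurons")
  wca <- syn[[kernel$cue_action]]$weight
  wpa <- syn[[kernel$predictor_action]]$weight
  wcp <- syn[[kernel$cue_predictor]]$weight
  if (!(wca > wpa))
    stop("kernel weight ordering violated: weight(cue_action) = ", wca,
         " must exceed weight(predictor_action) = ", wpa)
  if (!(wpa > wcp))
    stop("kernel weight ordering violated: weight(predictor_action) = ",
         wpa, " must exceed weight(cue_predictor) = ", wcp)
  if (is.null(syn[[kernel$cue_action]]$habituation) ||
      !is.null(syn[[kernel$cue_action]]$stdp))
    stop("cue_action link must carry habituation and no STDP")
  if (is.null(syn[[kernel$cue_predictor]]$stdp) ||
      !is.null(syn[[kernel$cue_predictor]]$habituation))
    stop("cue_predictor link must carry STDP and no habituation")
  if (!is.null(syn[[kernel$predictor_action]]$stdp) ||
      !is.null(syn[[kernel$predictor_action]]$habituation))
    stop("predictor_action link must be static")
  invisible(TRUE)
}

#' Census of a kernel's inner box
#'
#' @param net An `ocNetwork`.
#' @param kernel An `OcKernelSpec`.
#' @return Named integer vector: inner neurons, inner synapses,
#'   habituation rules and STDP rules inside the kernel.
#' @export
kernelCensus <- function(net, kernel = attr(net, "kernels")[[1]]) {
  sids <- c(kernel$cue_action, kernel$cue_predictor,
            kernel$predictor_action)
  c(neurons = length(unique(c(kernel$cue, kernel$action,
                              kernel$predictor))),
    synapses = length(sids),
    habituation = sum(vapply(net$synapses[sids],
                             function(s) !is.null(s$habituation),
                             logical(1))),
    stdp = sum(vapply(net$synapses[sids],
                      function(s) !is.null(s$stdp), logical(1))))
}

#' Canonical form of a kernel's typed inner structure
#'
#' Used to check kernel invariance across scenarios: two kernels are
#' considered structurally identical (graph-isomorphic with typed edges)
#' when their canonical forms match.
#'
#' @param net An `ocNetwork`.
#' @param kernel An `OcKernelSpec`.
#' @return Character vector describing the typed edges with roles
#'   substituted for ids.
#' @export
kernelShape <- function(net, kernel = attr(net, "kernels")[[1]]) {
  syn <- net$synapses
  edge <- function(sid, from, to) {
    s <- syn[[sid]]
    paste0(from, "->", to, ":",
           if (!is.null(s$habituation)) "habituation"
           else if (!is.null(s$stdp)) "stdp" else "static",
           ":", s$polarity)
  }
  c(edge(kernel$cue_action, "cue", "action"),
    edge(kernel$cue_predictor, "cue", "predictor"),
    edge(kernel$predictor_action, "predictor", "action"))
}

#' Build the dual kernel of two opposing conditioning procedures
#'
#' Two kernels sharing the cue path and the Action neuron: a
#' reward-seeking kernel whose Predictor (driven by the reward sense)
#' excites the Action, and a punishment-avoiding kernel whose Predictor
#' (driven by the punishment sense) inhibits it.  The two behaviors —
#' doing and withholding the action — are mutually exclusive by
#' construction: the opposing predictor outputs converge on the shared
#' Action neuron with equal and opposite curves, so when both predictors
#' fire at most the withholding behavior is expressed.  With the
#' punishment channel silent forever the added circuitry never
#' activates and the shared columns of the trace reproduce the single
#' kernel exactly.
#'
#' @inheritParams buildKernel
#' @param reward_channel,punishment_channel World channels sensed as the
#'   positive and negative reinforcers.
#' @return An `ocNetwork` with two recorded `OcKernelSpec`s (reward
#'   first).
#' @export
buildDualKernel <- function(cue_channel = "vibration",
                            reward_channel = "light",
                            punishment_channel = "heat",
                            action_name = "emit-sound",
                            weights = NULL,
                            net = ocNetwork(),
                            defaults = ocDefaults()) {
  w <- defaults$weights
  if (!is.null(weights)) w[names(weights)] <- as.integer(weights)
  net <- buildKernel(cue_channel, reward_channel, action_name,
                     polarity = "reward-seeking", weights = w,
                     prefix = "", net = net, defaults = defaults)
  # punishment-side kernel: shares CueInput/Cue/Action/Motor; its
  # predictor-action link is inhibitory.
  net <- addNeuron(net, "PredictorP")
  net <- addNeuron(net, "Punisher")
  net <- addSynapse(net, "Cue", "PredictorP", w[["cue_predictor"]],
                    stdp = defaultStdp(w[["cue_predictor"]], defaults))
  net <- addSynapse(net, "PredictorP", "Action", w[["predictor_action"]],
                    polarity = "inhibitory")
  net <- addSynapse(net, "Punisher", "PredictorP", w[["relay"]])
  net <- addTransducer(net, punishment_channel, "Punisher")
  spec <- structure(list(cue = "Cue", action = "Action",
                         predictor = "PredictorP",
                         cue_action = "Cue->Action",
                         cue_predictor = "Cue->PredictorP",
                         predictor_action = "PredictorP->Action",
                         polarity = "punishment-avoiding"),
                    class = "OcKernelSpec")
  attr(net, "kernels") <- c(attr(net, "kernels"), list(spec))
  validateKernel(net, spec)
  net
}

#' Duplicate the kernel over several cues sharing one Action neuron
#'
#' One kernel per cue channel, all feeding a common Action neuron (and a
#' common motor path and reinforcer sense).  Per-cue transducers carry
#' sensory adaptation so constant cue stimuli do not flood the network.
#' With a `punishment_channel`, each cue additionally gets a
#' punishment-avoiding predictor, as in the dual kernel.
#'
#' Credit assignment between cues needs no extra wiring: the shared
#' reinforcer sense drives every predictor, but only the predictor whose
#' cue spiked within the STDP window is potentiated.
#'
#' @inheritParams buildDualKernel
#' @param cue_channels Character vector (length at least 2) of cue
#'   channels.
#' @param reward_channel Channel of the shared positive reinforcer.
#' @param punishment_channel Optional channel of the shared negative
#'   reinforcer.
#' @return An `ocNetwork` with one (or two, with punishment) recorded
#'   kernels per cue.
#' @export
buildMulticueKernels <- function(cue_channels,
                                 action_name = "arm-down",
                                 reward_channel = "touch",
                                 punishment_channel = NULL,
                                 weights = NULL,
                                 net = ocNetwork(),
                                 defaults = ocDefaults()) {
  stopifnot(length(cue_channels) >= 2L)
  w <- defaults$weights
  if (!is.null(weights)) w[names(weights)] <- as.integer(weights)
  net <- addNeuron(net, "Action")
  net <- addNeuron(net, "Motor")
  net <- addNeuron(net, "Reinforcer")
  net <- addSynapse(net, "Action", "Motor", w[["relay"]])
  net <- addTransducer(net, reward_channel, "Reinforcer")
  net <- addActuator(net, action_name, "Motor",
                     defaults$actuator$trigger_threshold)
  if (!is.null(punishment_channel)) {
    net <- addNeuron(net, "Punisher")
    net <- addTransducer(net, punishment_channel, "Punisher")
  }
  for (ch in cue_channels) {
    tag <- gsub("^color-", "", ch)
    tag <- paste0(toupper(substring(tag, 1, 1)), substring(tag, 2))
    cue <- paste0("Cue", tag)
    predR <- paste0("PredictorR", tag)
    net <- addNeuron(net, cue)
    net <- addNeuron(net, predR)
    net <- addSynapse(net, cue, "Action", w[["cue_action"]],
                      habituation = defaultHabituation(defaults))
    net <- addSynapse(net, cue, predR, w[["cue_predictor"]],
                      stdp = defaultStdp(w[["cue_predictor"]], defaults))
    net <- addSynapse(net, predR, "Action", w[["predictor_action"]])
    net <- addSynapse(net, "Reinforcer", predR, w[["relay"]])
    net <- addTransducer(net, ch, cue,
                         adaptation = defaultAdaptation(defaults))
    spec <- structure(list(cue = cue, action = "Action", predictor = predR,
                           cue_action = paste0(cue, "->Action"),
                           cue_predictor = paste0(cue, "->", predR),
                           predictor_action = paste0(predR, "->Action"),
                           polarity = "reward-seeking"),
                      class = "OcKernelSpec")
    attr(net, "kernels") <- c(attr(net, "kernels"), list(spec))
    validateKernel(net, spec)
    if (!is.null(punishment_channel)) {
      predP <- paste0("PredictorP", tag)
      net <- addNeuron(net, predP)
      net <- addSynapse(net, cue, predP, w[["cue_predictor"]],
                        stdp = defaultStdp(w[["cue_predictor"]], defaults))
      net <- addSynapse(net, predP, "Action", w[["predictor_action"]],
                        polarity = "inhibitory")
      net <- addSynapse(net, "Punisher", predP, w[["relay"]])
      specP <- structure(list(cue = cue, action = "Action",
                              predictor = predP,
                              cue_action = paste0(cue, "->Action"),
                              cue_predictor = paste0(cue, "->", predP),
                              predictor_action = paste0(predP, "->Action"),
                              polarity = "punishment-avoiding"),
                         class = "OcKernelSpec")
      attr(net, "kernels") <- c(attr(net, "kernels"), list(specP))
      validateKernel(net, specP)
    }
  }
  net
}

#' @export
print.OcKernelSpec <- function(x, ...) {
  cat("OcKernelSpec (", x$polarity, "): ", x$cue, " -> ", x$action,
      " (habituating), ", x$cue, " -> ", x$predictor, " (STDP), ",
      x$predictor, " -> ", x$action, " (static)\n", sep = "")
  invisible(x)
}
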