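#' Scenario A: cued action with delayed reward
#'
#' A static agent hears periodic vibration pulses (the cue) and emits a
#' sound by reflex.  During the supervised phase the world answers each
#' sound with a light flash (the reward) after a short latency.
#' Habituation of the Cue-Action link extinguishes the reflex around
#' cycle 100; meanwhile STDP on the Cue-Predictor link, paired by the
#' reward-driven Predictor spikes, strengthens until the cue alone
#' drives the Predictor and — by temporal summation with the residual
#' habituated Cue PSP — the Action.  The reward is discontinued at cycle
#' 175; the behavior persists in expectation of it.
#'
#' @param defaults Parameter bundle from [ocDefaults()].
#' @return A `ScenarioProtocol`.
#' @export
scenarioA <- function(defaults = ocDefaults()) {
  sa <- defaults$scenario_a
  net <- buildKernel("vibration", "light", "emit-sound",
                     defaults = defaults)
  world <- ocWorld(
    channels = c("vibration", "light"),
    cycles = sa$cycles,
    schedules = list(list(channel = "vibration", period = sa$cue_period,
                          width = 1L, intensity = sa$cue_intensity)),
    contingencies = data.frame(action = "emit-sound", channel = "light",
                               start = 0L, end = sa$reward_end,
                               latency = sa$reward_latency,
                               intensity = 100L),
    phases = list(reflex = c(0L, 100L),
                  transition = c(100L, sa$reward_end),
                  expectation = c(sa$reward_end, sa$cycles)))
  newProtocol("A", net, world, defaults,
              primary_action = "emit-sound",
              reward_channels = "light", punish_channels = character(0))
}

#' Scenario B: reward acquisition followed by punishment reversal
#'
#' The dual kernel on a shared cue and action.  For the first 250 cycles
#' each sound is rewarded with light; the reward then stops but the
#' behavior persists in expectation.  From cycle 500 the world answers
#' each sound with a punishing heat wave instead: the punishment-side
#' predictor is potentiated until the cue alone predicts punishment and
#' its inhibitory output cancels the reward pathway — the agent ceases
#' the behavior without further punishment.
#'
#' @inheritParams scenarioA
#' @return A `ScenarioProtocol`.
#' @export
scenarioB <- function(defaults = ocDefaults()) {
  sb <- defaults$scenario_b
  net <- buildDualKernel("vibration", "light", "heat", "emit-sound",
                         defaults = defaults)
  world <- ocWorld(
    channels = c("vibration", "light", "heat"),
    cycles = sb$cycles,
    schedules = list(list(channel = "vibration", period = sb$cue_period,
                          width = 1L, intensity = 100L)),
    contingencies = data.frame(
      action = c("emit-sound", "emit-sound"),
      channel = c("light", "heat"),
      start = c(0L, sb$punish_start),
      end = c(sb$reward_end, sb$cycles),
      latency = c(sb$latency, sb$latency),
      intensity = c(100L, 100L)),
    phases = list(reward = c(0L, sb$reward_end),
                  expectation = c(sb$reward_end, sb$punish_start),
                  punishment = c(sb$punish_start, 600L),
                  suppressed = c(600L, sb$cycles)))
  newProtocol("B", net, world, defaults,
              primary_action = "emit-sound",
              reward_channels = "light", punish_channels = "heat")
}

#' Scenario C: pressing colored floor zones under reversible contingencies
#'
#' A moving agent traverses eight colored floor zones at constant speed
#' (a fixed number of cycles per zone).  Seeing a color drives an
#' arm-down press by reflex; a touch reflex raises the arm again,
#' capping the press rate.  In the first half of the run, pressing green
#' is rewarded (light) and pressing red punished (heat); from the
#' reversal zone onward the contingencies are swapped.  Per-cue
#' adaptation and habituation let a previously suppressed color be
#' re-sampled after a zone without it, so the reversed contingencies are
#' discovered and the end state flips: green presses stop, red presses
#' resume.
#'
#' @inheritParams scenarioA
#' @param reinforced With `FALSE`, no reinforcers are ever delivered:
#'   pressing fades under adaptation and habituation alone and recovers
#'   on color change.
#' @return A `ScenarioProtocol`.
#' @export
scenarioC <- function(defaults = ocDefaults(), reinforced = TRUE) {
  sc <- defaults$scenario_c
  zones <- sc$zones
  cpz <- sc$cycles_per_zone
  cycles <- length(zones) * cpz
  net <- buildMulticueKernels(unique(zones), "arm-down",
                              reward_channel = "light",
                              punishment_channel = "heat",
                              defaults = defaults)
  net <- addNeuron(net, "TouchSense")
  net <- addNeuron(net, "ArmUpMotor")
  net <- addSynapse(net, "TouchSense", "ArmUpMotor",
                    defaults$weights[["relay"]])
  net <- addTransducer(net, "touch", "TouchSense")
  net <- addActuator(net, "arm-up", "ArmUpMotor",
                     defaults$actuator$trigger_threshold)
  conting <- NULL
  if (reinforced) {
    rows <- lapply(seq_along(zones), function(z) {
      reversed <- z >= sc$reversal_zone
      green <- zones[z] == "color-green"
      rewarding <- xor(green, reversed)
      data.frame(action = "press",
                 channel = if (rewarding) "light" else "heat",
                 start = (z - 1L) * cpz, end = z * cpz,
                 latency = sc$latency, intensity = 100L)
    })
    conting <- do.call(rbind, rows)
  }
  world <- ocWorld(
    channels = c("color-green", "color-red", "light", "heat", "touch"),
    cycles = cycles,
    schedules = list(list(zone_channels = zones, cycles_per_zone = cpz,
                          intensity = 100L)),
    contingencies = conting,
    phases = stats::setNames(
      lapply(seq_along(zones), function(z) c((z - 1L) * cpz, z * cpz)),
      paste0("zone", seq_along(zones))),
    arm = TRUE)
  newProtocol("C", net, world, defaults,
              primary_action = "press",
              reward_channels = "light", punish_channels = "heat")
}

#' Scenario D (simulated): conveyor-belt color sorting
#'
#' A static agent watches a conveyor stream of red and blue pieces with
#' jittered inter-piece intervals.  Any perceived piece is at first
#' ejected by reflex; without reinforcement, adaptation and habituation
#' extinguish the behavior for every color.  When ejections of the
#' reinforced color are followed (with jittered latency, inside the STDP
#' window) by a touch reward, the corresponding predictor is potentiated
#' and that color keeps being ejected while the other is retained.  The
#' piece stream and both jitters are drawn once, from `seed`, when the
#' protocol is built; the run itself is deterministic.
#'
#' @inheritParams scenarioA
#' @param seed Integer seed for the piece stream and jitters.
#' @param reinforced_channel Color channel whose ejection is rewarded
#'   (`"color-red"` by default), or `NA` to withhold all reinforcement.
#' @param touch_latency_range Inclusive integer range of the
#'   ejection-to-touch latency in cycles.
#' @param base_interval Minimum inter-piece interval in cycles (jitter
#'   is added on top); widen it to probe reinforcer latencies beyond the
#'   STDP window without aliasing onto the following piece.
#' @return A `ScenarioProtocol`.
#' @export
scenarioDSim <- function(seed = 1L, defaults = ocDefaults(),
                         reinforced_channel = "color-red",
                         touch_latency_range =
                           ocDefaults()$scenario_d$touch_latency_range,
                         base_interval =
                           ocDefaults()$scenario_d$base_interval) {
  sd <- defaults$scenario_d
  set.seed(seed)
  n <- sd$n_pieces
  gaps <- base_interval + sample.int(sd$interval_jitter + 1L, n,
                                     replace = TRUE) - 1L
  appear <- cumsum(gaps)
  # randomized color order in balanced pairs (runs of at most two), the
  # way a human feeder alternates pieces on a demonstration belt
  colors <- as.vector(vapply(seq_len(ceiling(n / 2)), function(i)
    sample(c("color-red", "color-blue")), character(2)))[seq_len(n)]
  lat <- sample(seq(touch_latency_range[1], touch_latency_range[2]),
                n, replace = TRUE)
  pieces <- data.frame(appear = appear, channel = colors,
                       window = sd$piece_window,
                       stim_window = sd$stim_window,
                       reach_delay = sd$reach_delay,
                       touch_latency = lat)
  cycles <- appear[n] + sd$piece_window + 40L
  split <- if (n > 15L) appear[n - 15L] else 0L
  net <- buildMulticueKernels(c("color-red", "color-blue"), "eject",
                              reward_channel = "touch",
                              defaults = defaults)
  # the eject flipper is a fast side-arm: lower trigger threshold than
  # the sound / pressing actuators
  net$actuators[["eject"]]$trigger_threshold <- sd$eject_threshold
  world <- ocWorld(
    channels = c("color-red", "color-blue", "touch"),
    cycles = cycles,
    phases = list(learning = c(0L, split), steady = c(split, cycles)),
    pieces = pieces,
    reinforced_channel = reinforced_channel)
  newProtocol("D", net, world, defaults,
              primary_action = "eject",
              reward_channels = "touch", punish_channels = character(0))
}

newProtocol <- function(name, net, world, defaults, primary_action,
                        reward_channels, punish_channels) {
  baselines <- vapply(net$synapses, function(s)
    if (is.null(s$stdp)) NA_integer_ else s$stdp$baseline, integer(1))
  structure(list(name = name, network = net, world = world,
                 defaults = defaults, primary_action = primary_action,
                 reward_channels = reward_channels,
                 punish_channels = punish_channels,
                 stdp_baselines = baselines[!is.na(baselines)]),
            class = "ScenarioProtocol")
}

#' @export
print.ScenarioProtocol <- function(x, ...) {
  cat("ScenarioProtocol ", x$name, ": ", length(x$network$neurons),
      " neurons, ", x$world$cycles, " cycles, action '",
      x$primary_action, "'\n", sep = "")
  invisible(x)
}

#' Run a scenario protocol
#'
#' @param protocol A `ScenarioProtocol`.
#' @param cycles Cycles to simulate (default: the protocol's schedule).
#' @param seed Integer seed.
#' @return A `SimulationTrace`.
#' @export
runScenario <- function(protocol, cycles = protocol$world$cycles,
                        seed = 1L) {
  runNetwork(protocol$network, protocol$world, cycles, seed)
}

#' Cycle indices of the protocol's primary action events in a trace
#'
#' @param trace A `SimulationTrace`.
#' @param protocol The matching `ScenarioProtocol`.
#' @return Integer vector of cycles at which the protocol's primary
#'   world action (actuator event, press or ejection) occurred.
#' @export
actionCycles <- function(trace, protocol) {
  col <- if (protocol$primary_action %in% c("press", "eject"))
    paste0("evt_", protocol$primary_action)
  else paste0("act_", protocol$primary_action)
  if (!col %in% names(trace))
    stop("trace does not match protocol: missing column ", col)
  trace$cycle[trace[[col]] > 0L]
}

# Onset cycles of pulses on a stimulus channel.
stimulusOnsets <- function(trace, channel) {
  v <- trace[[paste0("stim_", channel)]]
  if (is.null(v)) return(integer(0))
  trace$cycle[v > 0L & c(0L, v[-length(v)]) == 0L]
}

#' Classify the phases of a simulation trace
#'
#' Produces the per-phase report used throughout the scenario analyses:
#' action-event counts, first and last action cycle, the fraction of
#' actions preceded by a predictor spike (within 10 cycles), reinforcer
#' counts, and a rule-based label.  The labels are, in order of
#' precedence: `acquisition` (actions together with reinforcers),
#' `expectation` (actions, no reinforcers, mostly predictor-driven),
#' `reflex` (actions, no reinforcers, cue-driven), `reversal` (no
#' actions, with the punishment pathway active in or before the phase),
#' `extinction` (no actions, learned weights back at baseline after
#' earlier activity), and `habituated` (no actions otherwise).
#'
#' @param trace A `SimulationTrace` produced under `protocol`.
#' @param protocol The matching `ScenarioProtocol`.
#' @return A `PhaseReport`: data frame with one row per phase.
#' @export
classifyPhases <- function(trace, protocol) {
  phases <- attr(trace, "phases") %||% protocol$world$phases
  acts <- actionCycles(trace, protocol)
  pred_cols <- grep("^spk_Predictor", names(trace), value = TRUE)
  pred_cycles <- if (length(pred_cols))
    trace$cycle[rowSums(trace[pred_cols]) > 0L]
  else integer(0)
  rew <- unlist(lapply(protocol$reward_channels, stimulusOnsets,
                       trace = trace))
  pun <- unlist(lapply(protocol$punish_channels, stimulusOnsets,
                       trace = trace))
  wcols <- intersect(paste0("w_", names(protocol$stdp_baselines)),
                     names(trace))
  rows <- lapply(names(phases), function(ph) {
    lo <- phases[[ph]][1]; hi <- phases[[ph]][2]
    a <- acts[acts >= lo & acts < hi]
    nr <- sum(rew >= lo & rew < hi)
    np <- sum(pun >= lo & pun < hi)
    predfrac <- if (length(a)) {
      mean(vapply(a, function(t)
        any(pred_cycles >= t - 10L & pred_cycles < t), logical(1)))
    } else NA_real_
    at_base <- if (length(wcols)) {
      wend <- as.integer(trace[min(nrow(trace), hi), wcols])
      all(abs(wend - protocol$stdp_baselines[sub("^w_", "", wcols)]) <= 2L)
    } else TRUE
    label <- if (length(a) == 0L) {
      earlier_acts <- any(acts < lo)
      pun_active <- np > 0L || any(pun < lo)
      preds_here <- any(pred_cycles >= lo & pred_cycles < hi)
      if (pun_active && preds_here) "reversal"
      else if (earlier_acts && at_base && !preds_here) "extinction"
      else "habituated"
    } else {
      if (nr + np > 0L) "acquisition"
      else if (!is.na(predfrac) && predfrac >= 0.5) "expectation"
      else "reflex"
    }
    data.frame(phase = ph, start = lo, end = hi,
               n_actions = length(a),
               first_action = if (length(a)) a[1] else NA_integer_,
               last_action = if (length(a)) a[length(a)] else NA_integer_,
               predictor_fraction = predfrac,
               n_reward = nr, n_punish = np,
               classification = label)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("PhaseReport", "data.frame")
  out
}

#' Cycle at which the cue-driven reflex ceases
#'
#' The last cycle at which the Action neuron spikes while the
#' Cue-Predictor weight is still below the weight able to fire the
#' Predictor on its own (see [soloFiringWeight()]) — i.e. the end of the
#' initial, purely reflex-driven phase, before any predictor-driven
#' resumption.
#'
#' @param trace A `SimulationTrace`.
#' @param action_col Spike column of the Action neuron.
#' @param weight_col Weight column of the Cue-Predictor synapse.
#' @param drive_weight Threshold weight; default computed from the
#'   default PSP table and neuron parameters.
#' @return Integer cycle (or `NA` if the Action never spiked there).
#' @export
reflexCessationCycle <- function(trace,
                                 action_col = "spk_Action",
                                 weight_col = "w_Cue->Predictor",
                                 drive_weight = soloFiringWeight()) {
  i <- trace[[action_col]] > 0L & trace[[weight_col]] < drive_weight
  if (!any(i)) return(NA_integer_)
  max(trace$cycle[i])
}

#' Per-piece sorting outcome of a conveyor run
#'
#' @param trace A `SimulationTrace` from [scenarioDSim()].
#' @param last_n Number of trailing (steady-state) pieces to evaluate.
#' @return List with the per-color ejection frequency over the last
#'   `last_n` pieces (`steady`) and over all pieces (`overall`).
#' @export
sortingPerformance <- function(trace, last_n = 15L) {
  pieces <- attr(trace, "pieces")
  if (is.null(pieces)) stop("trace has no conveyor pieces")
  freq <- function(df) vapply(split(df, df$channel),
                              function(d) mean(!is.na(d$ejected)),
                              numeric(1))
  tail_df <- pieces[seq(max(1L, nrow(pieces) - last_n + 1L),
                        nrow(pieces)), ]
  list(steady = freq(tail_df), overall = freq(pieces), pieces = pieces)
}

#' Did a run achieve conditioned acquisition with expectation?
#'
#' The operational definition of a successful operant-conditioning
#' outcome, used by the weight-ordering and rule-permutation analyses:
#' (1) the run ends with actions that are predictor-led (at least one
#' action in the final quarter, with a predictor spike shortly before at
#' least half of the late actions); (2) the direct cue-to-action drive
#' is subthreshold by then (the habituated reflex alone no longer fires
#' the Action neuron); (3) the run began with reflex actions; and
#' (4) the cue-to-predictor link started subthreshold, so the
#' prediction was acquired rather than prewired.
#'
#' @param trace A `SimulationTrace` from a scenario-A-compatible run.
#' @param protocol The matching `ScenarioProtocol`.
#' @param kernel Kernel whose links are examined (first kernel by
#'   default).
#' @return Logical.
#' @export
acquisitionExpectation <- function(trace, protocol,
                                   kernel = attr(protocol$network,
                                                 "kernels")[[1]]) {
  net <- protocol$network
  tab <- net$psp_table
  params <- net$neurons[[kernel$action]]
  gap <- params$threshold - params$resting_potential
  acts <- actionCycles(trace, protocol)
  n <- nrow(trace)
  late <- acts[acts >= trace$cycle[n] * 3 / 4]
  pred_cycles <- trace$cycle[trace[[paste0("spk_", kernel$predictor)]] > 0L]
  led <- if (length(late))
    mean(vapply(late, function(t)
      any(pred_cycles >= t - 10L & pred_cycles < t), logical(1)))
  else 0
  wca_end <- trace[[paste0("w_", kernel$cue_action)]][n]
  eff_end <- trace[[paste0("eff_", kernel$cue_action)]][n]
  amp_end <- rha(sum(pspCurve(tab, wca_end)) * eff_end / 100)
  wcp0 <- trace[[paste0("w_", kernel$cue_predictor)]][1]
  solo <- soloFiringWeight(tab, params)
  length(late) >= 1L && led >= 0.5 &&
    amp_end < gap &&
    any(acts < 50L) &&
    wcp0 < solo
}

#' Run one of the four control ablations of the conditioning kernel
#'
#' The four controls that delimit the kernel's mechanism:
#' `"no-habituation"` removes the habituation rule (the reflex never
#' stops); `"no-stdp"` removes the STDP rule (the behavior stops with
#' the habituated reflex and never resumes — the reward is always
#' required); `"reward-precedes-action"` schedules the reward pulses
#' just before each cue volley instead of after the action, so the
#' Predictor fires before the Cue and STDP depresses the link; and
#' `"cue-removed"` stops the cue mid-run, after which pairing ceases and
#' the learned weight drifts back to baseline (extinction).
#'
#' @param protocol A scenario-A-compatible `ScenarioProtocol`.
#' @param ablation One of the four control names.
#' @param seed Integer seed.
#' @return List of class `AblationReport` with the ablation name, the
#'   `PhaseReport`, and the full trace.
#' @export
runAblation <- function(protocol,
                        ablation = c("no-habituation", "no-stdp",
                                     "reward-precedes-action",
                                     "cue-removed"),
                        seed = 1L) {
  ablation <- match.arg(ablation)
  net <- protocol$network
  world <- protocol$world
  kern <- attr(net, "kernels")[[1]]
  if (ablation == "no-habituation") {
    net$synapses[[kern$cue_action]]$habituation <- NULL
  } else if (ablation == "no-stdp") {
    net$synapses[[kern$cue_predictor]]$stdp <- NULL
  } else if (ablation == "reward-precedes-action") {
    # the premature reward must fall outside the STDP window of the
    # previous volley to isolate the post-before-pre (depression) side,
    # so this control paces the cue above the window length and lights
    # the reward three cycles before each volley
    world$contingencies <- NULL
    period <- 20L
    world$schedules <- list(list(channel = "vibration", period = period,
                                 width = 1L, intensity = 100L),
                            list(channel = "light", period = period,
                                 offset = period - 3L, width = 1L,
                                 intensity = 100L,
                                 end = protocol$defaults$scenario_a$reward_end))
  } else if (ablation == "cue-removed") {
    world$schedules[[1]]$end <- 150L
    ext <- 400L
    world$cycles <- ext
    # the uncued phase starts after the last volley's chain has drained
    world$phases <- list(cued = c(0L, 165L), uncued = c(165L, ext))
  }
  proto2 <- protocol
  proto2$network <- net
  proto2$world <- world
  trace <- runScenario(proto2, seed = seed)
  structure(list(ablation = ablation,
                 report = classifyPhases(trace, proto2),
                 trace = trace),
            class = "AblationReport")
}

#' @export
print.AblationReport <- function(x, ...) {
  cat("AblationReport:", x$ablation, "\n")
  print(as.data.frame(x$report))
  invisible(x)
}

#' Deterministic calibration of the shipped defaults
#'
#' Grid search over the free dynamical parameters (habituation mid-ISI
#' decay step, maximum STDP pair change, Cue-Action weight), accepting
#' the first configuration — in a fixed grid order — that satisfies the
#' protocol-level constraints: the scenario-A reflex ceases within
#' `cessation_tol` of `cessation_target`, a predictor-driven resumption
#' occurs before `acquisition_by`, at least one action follows reward
#' removal, and the scenario-B reversal completes (no actions from
#' `reversal_quiet_from` onward while the reward phase stays active).
#' The search is deterministic; rerunning it reproduces the shipped
#' bundle exactly.
#'
#' @param constraints Named list: `cessation_target`, `cessation_tol`,
#'   `acquisition_by`, `reversal_quiet_from`.
#' @param grid Named list of candidate values `hab_mid`, `stdp_max`,
#'   `cue_action`, scanned in order.
#' @return List with the winning `defaults` bundle and `params`.
#' @export
calibrateDefaults <- function(constraints = list(cessation_target = 100L,
                                                 cessation_tol = 15L,
                                                 acquisition_by = 175L,
                                                 reversal_quiet_from = 600L),
                              grid = list(hab_mid = c(6L, 7L, 8L),
                                          stdp_max = c(10L, 8L),
                                          cue_action = c(90L, 85L, 95L))) {
  unsatisfied <- character(0)
  for (hm in grid$hab_mid) for (sm in grid$stdp_max)
    for (ca in grid$cue_action) {
      d <- ocDefaults()
      d$habituation$decay_steps[["mid"]] <- hm
      d$stdp$max_change <- sm
      d$weights[["cue_action"]] <- ca
      bad <- checkCalibration(d, constraints)
      if (!length(bad))
        return(list(defaults = d,
                    params = c(hab_mid = hm, stdp_max = sm,
                               cue_action = ca)))
      unsatisfied <- union(unsatisfied, bad)
    }
  stop("calibration failed; unsatisfied constraints: ",
       paste(unsatisfied, collapse = ", "))
}

checkCalibration <- function(d, cs) {
  bad <- character(0)
  pa <- scenarioA(d)
  ta <- runScenario(pa)
  cess <- reflexCessationCycle(ta)
  acts <- actionCycles(ta, pa)
  if (is.na(cess) ||
      abs(cess - cs$cessation_target) > cs$cessation_tol)
    bad <- c(bad, "reflex cessation within tolerance of target")
  resumed <- acts[!is.na(cess) & acts > cess + 5L]
  if (!length(resumed) || resumed[1] >= cs$acquisition_by)
    bad <- c(bad, "predictor-driven resumption before reward removal")
  if (!any(acts >= d$scenario_a$reward_end))
    bad <- c(bad, "expectation persists after reward removal")
  pb <- scenarioB(d)
  tb <- runScenario(pb)
  actsB <- actionCycles(tb, pb)
  if (!any(actsB < d$scenario_b$reward_end))
    bad <- c(bad, "actions present during the reward phase")
  if (any(actsB >= cs$reversal_quiet_from))
    bad <- c(bad, "reversal completes within the punishment phase")
  bad
}
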