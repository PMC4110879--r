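CONFIG_SCHEMA_VERSION <- 1L

# Keys accepted at each level of the configuration document.
.config_keys <- list(
  top = c("schema_version", "network", "world", "run"),
  network = c("neurons", "synapses", "transducers", "actuators"),
  neuron = c("id", "threshold", "spike_level", "hyperpolarized_reset",
             "resting_potential", "refractory_cycles", "leak_rate"),
  synapse = c("pre", "post", "weight", "polarity", "habituation", "stdp"),
  habituation = c("decay_steps", "isi_breaks", "recovery_delay",
                  "recovery_step", "floor"),
  stdp = c("window", "max_change", "baseline", "forget_delay",
           "forget_step"),
  adaptation = c("decay_fraction", "min_decay_step", "recovery_step",
                 "floor"),
  transducer = c("channel", "target", "adaptation"),
  actuator = c("action", "source", "trigger_threshold"),
  world = c("channels", "cycles", "schedules", "contingencies", "phases",
            "arm", "reinforced_channel"),
  run = c("cycles", "seed", "out")
)

checkKeys <- function(x, level, where) {
  extra <- setdiff(names(x), .config_keys[[level]])
  if (length(extra))
    stop("unknown key", if (length(extra) > 1) "s", " in ", where, ": ",
         paste(extra, collapse = ", "))
  invisible(x)
}

requireInteger <- function(x, where) {
  if (!is.numeric(x) || any(x != as.integer(x)))
    stop("non-integer value in ", where, ": ", paste(x, collapse = ", "))
  out <- as.integer(x)
  names(out) <- names(x)
  out
}

#' Serialize a network (and optionally a world) to a configuration list
#'
#' The configuration document is a plain nested list with an explicit
#' `schema_version`, suitable for YAML round-tripping: all numerics are
#' integers (the normalized integer scale is a hard contract of the
#' simulator) except the adaptation decay fraction.
#'
#' @param net An `ocNetwork`.
#' @param world Optional `ocWorld`.
#' @param run Optional run section (`cycles`, `seed`, `out`).
#' @return A named list, the `ConfigDocument`.
#' @export
configFromNetwork <- function(net, world = NULL, run = NULL) {
  plasticityCfg <- function(s, keys) {
    if (is.null(s)) return(NULL)
    out <- unclass(s)[keys]
    lapply(out, function(v) {
      if (is.numeric(v) && all(v == round(v))) {
        i <- as.integer(v)
        names(i) <- names(v)
        # named vectors become YAML maps, so the names survive the trip
        if (!is.null(names(i))) as.list(i) else i
      } else v
    })
  }
  doc <- list(
    schema_version = CONFIG_SCHEMA_VERSION,
    network = list(
      neurons = lapply(names(net$neurons), function(id)
        c(list(id = id), unclass(net$neurons[[id]]))),
      synapses = lapply(names(net$synapses), function(sid) {
        s <- net$synapses[[sid]]
        c(list(pre = s$pre, post = s$post, weight = s$weight,
               polarity = s$polarity),
          if (!is.null(s$habituation))
            list(habituation = plasticityCfg(s$habituation,
                                             .config_keys$habituation)),
          if (!is.null(s$stdp))
            list(stdp = plasticityCfg(s$stdp, .config_keys$stdp)))
      }),
      transducers = lapply(net$transducers, function(tr)
        c(list(channel = tr$channel, target = tr$target),
          if (!is.null(tr$adaptation))
            list(adaptation = plasticityCfg(tr$adaptation,
                                            .config_keys$adaptation)))),
      actuators = lapply(net$actuators, function(a)
        list(action = a$action, source = a$source,
             trigger_threshold = a$trigger_threshold))))
  names(doc$network$transducers) <- NULL
  names(doc$network$actuators) <- NULL
  if (!is.null(world)) {
    doc$world <- list(channels = world$channels, cycles = world$cycles,
                      schedules = world$schedules,
                      contingencies = if (!is.null(world$contingencies))
                        lapply(seq_len(nrow(world$contingencies)),
                               function(i) as.list(world$contingencies[i, ])),
                      phases = world$phases, arm = world$arm,
                      reinforced_channel = world$reinforced_channel)
    doc$world <- doc$world[!vapply(doc$world, is.null, logical(1))]
  }
  if (!is.null(run)) doc$run <- run
  doc
}

#' Rebuild a network (and world) from a configuration document
#'
#' @param doc A `ConfigDocument` as produced by [configFromNetwork()] or
#'   read by [loadConfig()].
#' @return List with elements `network` (validated `ocNetwork`), `world`
#'   (`ocWorld` or `NULL`) and `run`.
#' @export
networkFromConfig <- function(doc) {
  checkKeys(doc, "top", "configuration")
  if (is.null(doc$schema_version) ||
      doc$schema_version != CONFIG_SCHEMA_VERSION)
    stop("unsupported schema_version: ", doc$schema_version)
  nc <- checkKeys(doc$network, "network", "network")
  net <- ocNetwork()
  for (nu in nc$neurons) {
    checkKeys(nu, "neuron", paste0("neuron '", nu$id, "'"))
    args <- nu[setdiff(names(nu), "id")]
    args <- lapply(args, requireInteger, where = paste0("neuron '", nu$id, "'"))
    net <- addNeuron(net, nu$id, do.call(neuronParams, args))
  }
  for (sy in nc$synapses) {
    checkKeys(sy, "synapse", paste0("synapse ", sy$pre, "->", sy$post))
    hab <- if (!is.null(sy$habituation)) {
      h <- checkKeys(sy$habituation, "habituation", "habituation rule")
      do.call(habituationState, lapply(h, function(v) {
        v <- unlist(v)
        requireInteger(v, "habituation rule")
      }))
    }
    sp <- if (!is.null(sy$stdp)) {
      h <- checkKeys(sy$stdp, "stdp", "stdp rule")
      do.call(stdpState, lapply(h, requireInteger, where = "stdp rule"))
    }
    net <- addSynapse(net, sy$pre, sy$post,
                      requireInteger(sy$weight, "synapse weight"),
                      polarity = sy$polarity %||% "excitatory",
                      habituation = hab, stdp = sp)
  }
  for (tr in nc$transducers) {
    checkKeys(tr, "transducer", paste0("transducer ", tr$channel))
    ad <- if (!is.null(tr$adaptation)) {
      h <- checkKeys(tr$adaptation, "adaptation", "adaptation rule")
      do.call(adaptationState, h)
    }
    net <- addTransducer(net, tr$channel, tr$target, adaptation = ad)
  }
  for (a in nc$actuators) {
    checkKeys(a, "actuator", paste0("actuator ", a$action))
    net <- addActuator(net, a$action, a$source,
                       requireInteger(a$trigger_threshold,
                                      "actuator threshold"))
  }
  world <- NULL
  if (!is.null(doc$world)) {
    wc <- checkKeys(doc$world, "world", "world")
    conting <- if (!is.null(wc$contingencies))
      do.call(rbind, lapply(wc$contingencies, as.data.frame))
    world <- ocWorld(channels = unlist(wc$channels),
                     cycles = requireInteger(wc$cycles, "world cycles"),
                     schedules = wc$schedules %||% list(),
                     contingencies = conting,
                     phases = lapply(wc$phases, function(p)
                       requireInteger(unlist(p), "phase bounds")),
                     arm = isTRUE(wc$arm),
                     reinforced_channel = wc$reinforced_channel %||%
                       NA_character_)
  }
  validateNetwork(net, if (!is.null(world)) world$channels)
  list(network = net, world = world, run = doc$run)
}

#' Load and validate a YAML configuration file
#'
#' Validation happens entirely at load time: unknown keys, non-integer
#' numerics, dangling neuron ids and unknown channels are all rejected
#' with an error naming the offending field; a simulation never starts
#' from a malformed configuration.
#'
#' @param path Path to a YAML configuration.
#' @return A validated `ConfigDocument` (with the parsed network
#'   available through [networkFromConfig()]).
#' @export
loadConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  networkFromConfig(doc)   # full validation; discard the parsed objects
  doc
}

#' Write a configuration document to YAML
#'
#' @param doc A `ConfigDocument`.
#' @param path Output path.  The write is atomic: the file appears only
#'   once completely written.
#' @return The path, invisibly.
#' @export
writeConfig <- function(doc, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".yaml")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  yaml::write_yaml(doc, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a simulation trace as CSV
#'
#' One row per cycle; the column order of the trace (cycle, per-neuron
#' potentials and spikes, per-synapse weights and efficacies,
#' per-transducer adaptation, per-channel stimuli, actions, world
#' events) is preserved.  The write is atomic.
#'
#' @param trace A `SimulationTrace`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeTrace <- function(trace, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.csv(as.data.frame(trace), tmp, row.names = FALSE,
                   quote = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a simulation trace written by [writeTrace()]
#'
#' @param path CSV path.
#' @return A `SimulationTrace` data frame.
#' @export
readTrace <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE)
  class(out) <- c("SimulationTrace", "data.frame")
  out
}

#' Plot the panels of a simulation trace
#'
#' Stacked per-cycle panels in the style of the scenario figures:
#' membrane potentials, spike rasters, synaptic weights, plasticity
#' efficacies, stimuli and actions.  Presentation only; the trace is
#' never altered.
#'
#' @param trace A `SimulationTrace`.
#' @param panels Character vector choosing among `"potentials"`,
#'   `"spikes"`, `"weights"`, `"efficacies"`, `"stimuli"`, `"actions"`.
#' @param file Optional PNG path; when given the plot is written there.
#' @return The input trace, invisibly.
#' @export
plotTrace <- function(trace,
                      panels = c("spikes", "weights", "efficacies",
                                 "stimuli", "actions"),
                      file = NULL) {
  groups <- list(
    potentials = grep("^pot_", names(trace), value = TRUE),
    spikes = grep("^spk_", names(trace), value = TRUE),
    weights = grep("^w_", names(trace), value = TRUE),
    efficacies = grep("^(eff|adapt)_", names(trace), value = TRUE),
    stimuli = grep("^stim_", names(trace), value = TRUE),
    actions = grep("^(act|evt)_", names(trace), value = TRUE))
  panels <- panels[vapply(groups[panels], length, integer(1)) > 0]
  if (!is.null(file)) {
    grDevices::png(file, width = 1000, height = 220 * length(panels))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mfrow = c(length(panels), 1),
                      mar = c(2.5, 4, 1.5, 6), xpd = FALSE)
  # restoring par on a device we are about to close would reopen a
  # default device; only restore when drawing on the caller's device
  if (is.null(file)) on.exit(graphics::par(op), add = TRUE)
  for (p in panels) {
    cols <- groups[[p]]
    if (p %in% c("spikes", "actions")) {
      graphics::plot(NULL, xlim = range(trace$cycle),
                     ylim = c(0.5, length(cols) + 0.5),
                     xlab = "cycle", ylab = "", yaxt = "n", main = p)
      graphics::axis(2, at = seq_along(cols),
                     labels = sub("^[a-z]+_", "", cols), las = 2,
                     cex.axis = 0.7)
      for (i in seq_along(cols)) {
        at <- trace$cycle[trace[[cols[i]]] > 0]
        if (length(at))
          graphics::segments(at, i - 0.4, at, i + 0.4)
      }
    } else {
      graphics::matplot(trace$cycle, as.matrix(trace[cols]), type = "l",
                        lty = 1, xlab = "cycle", ylab = "value",
                        main = p)
      graphics::legend("topright", inset = c(-0.08, 0), legend = cols,
                       lty = 1, col = seq_along(cols), cex = 0.6,
                       xpd = TRUE, bty = "n")
    }
  }
  invisible(trace)
}
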