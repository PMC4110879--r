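#' Construct a closed-loop world model
#'
#' A world owns the stimulus channels, their open-loop schedules
#' (periodic pulses or zone traversal), the reinforcement contingencies
#' (a world action triggers a reinforcer channel after a latency, during
#' an active phase), the named phase intervals used by the trace
#' classifier, and optional arm or conveyor mechanics.
#'
#' @param channels Character vector of stimulus channel names.
#' @param cycles Total scheduled cycles.
#' @param schedules List of pulse schedules, each a list with fields
#'   `channel`, `start`, `end`, `period`, `width`, `intensity` (and
#'   optional `offset`).  A zone traversal is expressed with
#'   `zone_channels` / `cycles_per_zone` instead of `period`.
#' @param contingencies Data frame with columns `action`, `channel`,
#'   `start`, `end`, `latency`, `intensity`: while `start <= t < end`, an
#'   occurrence of `action` at cycle `t` delivers a 1-cycle pulse on
#'   `channel` at `t + latency`.  Latency must be at least 1 so the
#'   reinforcer always follows the action.
#' @param phases Named list of 2-vectors `c(start, end)` partitioning
#'   `[0, cycles)` into half-open intervals.
#' @param arm Logical: enable arm mechanics (an `"arm-down"` action while
#'   the arm is raised produces a `press` world event and a touch
#'   stimulus; an `"arm-up"` action raises the arm again).
#' @param pieces Optional data frame for conveyor mechanics: columns
#'   `appear`, `channel`, `window`, `touch_latency`.  A piece is visible
#'   on its color channel from `appear` for `window` cycles or until an
#'   `"eject"` action removes it; ejecting a piece on the
#'   `reinforced_channel` delivers a touch pulse after its latency.
#' @param reinforced_channel Color channel whose ejection is rewarded
#'   (conveyor worlds), or `NA` for unreinforced runs.
#' @return An object of class `ocWorld`.
#' @export
ocWorld <- function(channels, cycles,
                    schedules = list(),
                    contingencies = NULL,
                    phases = list(all = c(0L, cycles)),
                    arm = FALSE,
                    pieces = NULL,
                    reinforced_channel = NA_character_) {
  if (!is.null(contingencies) && nrow(contingencies) > 0 &&
      any(contingencies$latency < 1L))
    stop("contingency latency must be >= 1 cycle")
  ph <- do.call(rbind, phases)
  if (!is.null(ph)) {
    o <- order(ph[, 1])
    if (ph[o[1], 1] != 0 || ph[o[length(o)], 2] != cycles ||
        (length(o) > 1 && any(ph[o[-length(o)], 2] != ph[o[-1], 1])))
      stop("phases must partition [0, cycles) into half-open intervals")
  }
  structure(list(channels = channels, cycles = as.integer(cycles),
                 schedules = schedules, contingencies = contingencies,
                 phases = phases, arm = arm, pieces = pieces,
                 reinforced_channel = reinforced_channel),
            class = "ocWorld")
}

# Precompute the open-loop stimulus matrix (cycles x channels).
scheduleMatrix <- function(world, cycles) {
  m <- matrix(0L, cycles, length(world$channels),
              dimnames = list(NULL, world$channels))
  for (sc in world$schedules) {
    if (!is.null(sc$zone_channels)) {
      zc <- sc$zone_channels
      cpz <- sc$cycles_per_zone
      for (z in seq_along(zc)) {
        if (is.na(zc[z])) next
        lo <- (z - 1L) * cpz
        hi <- min(z * cpz, cycles)
        if (lo < cycles)
          m[(lo + 1L):hi, zc[z]] <- as.integer(sc$intensity)
      }
    } else {
      start <- sc$start %||% 0L
      end <- min(sc$end %||% cycles, cycles)
      off <- sc$offset %||% 0L
      width <- sc$width %||% 1L
      t0 <- seq(start + off, length.out = max(0L, ceiling((end - start - off) / sc$period)),
                by = sc$period)
      for (t in t0) {
        idx <- t:(t + width - 1L)
        idx <- idx[idx >= start & idx < end]
        if (length(idx)) m[idx + 1L, sc$channel] <- as.integer(sc$intensity)
      }
    }
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a network in closed loop against a world
#'
#' Deterministic for a fixed (network, world, cycles, seed): the only
#' stochastic scenario (conveyor sorting) draws its jitter when the world
#' is built, from its own seed.  Each cycle executes sense, transduce,
#' integrate/fire, plasticity, actuate, then the world update that
#' schedules contingent reinforcers and runs arm / conveyor mechanics.
#'
#' @param net A validated `ocNetwork`.
#' @param world An [ocWorld()].
#' @param cycles Number of cycles to simulate (default: the world's).
#' @param seed Integer seed applied before the run.
#' @return A `SimulationTrace`: a data frame with one row per cycle and
#'   integer columns `cycle`, per-neuron `pot_*` and `spk_*`, per-synapse
#'   `w_*` and `eff_*`, per-transducer `adapt_*`, per-channel `stim_*`,
#'   per-action `act_*`, and world-event columns `evt_press` /
#'   `evt_eject` where the mechanics are enabled.
#' @export
runNetwork <- function(net, world, cycles = world$cycles, seed = 1L) {
  validateNetwork(net, world$channels)
  set.seed(seed)
  cycles <- as.integer(cycles)
  stopifnot(cycles >= 1L)
  stim <- scheduleMatrix(world, cycles)
  extra <- matrix(0L, cycles + 64L, length(world$channels),
                  dimnames = list(NULL, world$channels))
  st <- networkStateInit(net)
  arm_up <- TRUE
  pieces <- world$pieces
  if (!is.null(pieces)) pieces$ejected <- NA_integer_
  probe <- stepNetwork(net, st, integer(0), 0L)$row
  act_names <- names(net$actuators)
  evt_names <- c(if (world$arm) "press", if (!is.null(pieces)) "eject")
  ncols <- length(probe) + length(world$channels) + length(act_names) +
    length(evt_names)
  tr <- matrix(0L, cycles, ncols)
  colnames(tr) <- c(names(probe), paste0("stim_", world$channels),
                    if (length(act_names)) paste0("act_", act_names),
                    if (length(evt_names)) paste0("evt_", evt_names))
  conting <- world$contingencies

  for (t in seq_len(cycles) - 1L) {
    inputs <- stim[t + 1L, ] + extra[t + 1L, ]
    if (!is.null(pieces)) {
      # the color sensor sees a piece briefly on arrival; the piece
      # stays within the arm's reach for its full window
      seen <- which(is.na(pieces$ejected) & pieces$appear <= t &
                      t < pieces$appear + pieces$stim_window)
      for (p in seen) inputs[pieces$channel[p]] <- 100L
    }
    inputs <- clamp01(inputs)
    res <- stepNetwork(net, st, inputs, t)
    st <- res$state
    actions <- res$actions
    events <- character(0)

    # world update -----------------------------------------------------
    if (world$arm && "arm-up" %in% actions) arm_up <- TRUE
    if (world$arm && "arm-down" %in% actions) {
      if (arm_up) {
        arm_up <- FALSE
        events <- c(events, "press")
        if ("touch" %in% world$channels && t + 2L <= nrow(extra))
          extra[t + 2L, "touch"] <- 100L
      }
      actions <- setdiff(actions, "arm-down")
    }
    if (!is.null(pieces) && "eject" %in% actions) {
      # the arm sits downstream of the color sensor: a piece comes into
      # reach a few cycles after it was seen
      reach <- if ("reach_delay" %in% names(pieces)) pieces$reach_delay else 0L
      live <- which(is.na(pieces$ejected) &
                      pieces$appear + reach <= t &
                      t < pieces$appear + pieces$window)
      if (length(live)) {
        p <- live[1L]
        pieces$ejected[p] <- t
        events <- c(events, "eject")
        if (!is.na(world$reinforced_channel) &&
            pieces$channel[p] == world$reinforced_channel) {
          lat <- pieces$touch_latency[p]
          if (t + lat + 1L <= nrow(extra))
            extra[t + lat + 1L, "touch"] <- 100L
        }
      }
    }
    fired <- c(res$actions, events)
    if (!is.null(conting) && nrow(conting) > 0 && length(fired)) {
      hit <- which(conting$action %in% fired & conting$start <= t &
                     t < conting$end)
      for (k in hit) {
        at <- t + conting$latency[k] + 1L
        if (at <= nrow(extra))
          extra[at, conting$channel[k]] <-
            max(extra[at, conting$channel[k]], as.integer(conting$intensity[k]))
      }
    }

    row <- c(res$row, stats::setNames(as.integer(inputs),
                                      paste0("stim_", world$channels)),
             if (length(act_names))
               stats::setNames(as.integer(act_names %in% res$actions),
                               paste0("act_", act_names)),
             if (length(evt_names))
               stats::setNames(as.integer(evt_names %in% events),
                               paste0("evt_", evt_names)))
    tr[t + 1L, ] <- row[colnames(tr)]
  }
  out <- as.data.frame(tr)
  names(out) <- colnames(tr)
  attr(out, "pieces") <- pieces
  attr(out, "phases") <- world$phases
  class(out) <- c("SimulationTrace", "data.frame")
  out
}

#' @export
print.SimulationTrace <- function(x, ...) {
  cat("SimulationTrace: ", nrow(x), " cycles, ", ncol(x), " columns\n",
      sep = "")
  spk <- grep("^spk_", names(x), value = TRUE)
  for (s in spk)
    cat("  ", sub("^spk_", "", s), ": ", sum(x[[s]]), " spikes\n", sep = "")
  invisible(x)
}
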