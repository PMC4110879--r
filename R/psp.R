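# Round half away from zero.  Every scaling step in the simulator goes
# through this helper so that all state stays integer-valued.
rha <- function(x) trunc(x + sign(x) * 0.5)

# Clamp to the normalized scale (attribute-preserving: x comes first).
clamp01 <- function(x, lo = 0L, hi = 100L) pmin(pmax(x, lo), hi)

#' Default curve-shape profile for lookup-table potentials
#'
#' The cumulative fractions of a curve's total amplitude delivered after
#' each of its five cycles.  The shape is a discretized rise-then-decay
#' template: large early per-cycle steps and small trailing ones, the
#' integer analogue of an exponentially decaying post-synaptic current.
#'
#' @return Numeric vector of length 5, non-decreasing, ending at 1.
#' @export
pspShapeProfile <- function() c(0.25, 0.55, 0.80, 0.95, 1.00)

# Per-cycle integer deltas for one curve of total amplitude `amp`
# (signed), under a cumulative shape profile.  Rounding is applied to the
# cumulative sums so the entries always total exactly rha(amp).
curveFromAmplitude <- function(amp, shape = pspShapeProfile()) {
  cum <- rha(amp * shape)
  diff(c(0, cum))
}

#' Build the weight-indexed lookup table of post-synaptic potential curves
#'
#' Each synaptic weight (0--100) indexes a 5-entry sequence of per-cycle
#' membrane-potential deltas on the normalized 0--100 scale.  The same
#' table family serves synapses, sensory transducers (indexed by stimulus
#' intensity) and motor outputs, so a single coherent format flows through
#' the whole network.  Curve amplitude grows with weight
#' (`amplitude_scale` units at weight 100) and every per-cycle entry is
#' bounded by `max_step`.
#'
#' @param shape_profile Cumulative rise-then-decay template, a
#'   non-decreasing numeric vector of length `curve_length` ending at 1.
#' @param calibration List with elements `weight`, `resting_potential`,
#'   `threshold`: a single curve at `weight`, arriving with the membrane
#'   at `resting_potential`, must cumulatively cross `threshold` within
#'   the curve length.  Set to `NULL` to skip the check.
#' @param amplitude_scale Total amplitude (normalized units) of the curve
#'   at weight 100.  Default 30.
#' @param max_step Bound on each per-cycle entry (normalized units per
#'   cycle).  Default 10.
#' @param curve_length Curve duration in cycles.  Default 5.
#'
#' @return An object of class `PspTable`: an integer matrix with 101 rows
#'   (weights 0--100) and `curve_length` columns, plus attributes
#'   recording the construction parameters.
#'
#' @details The table satisfies, by construction: weight 0 maps to the
#'   all-zero curve; cumulative amplitude is non-decreasing in weight;
#'   every entry is at most `max_step` in magnitude.  If the calibration
#'   constraint cannot be met under the `max_step` bound an error of class
#'   `spikeOC_calibration_error` is signalled.
#' @export
buildPspTable <- function(shape_profile = pspShapeProfile(),
                          calibration = list(weight = 95L,
                                             resting_potential = 50L,
                                             threshold = 63L),
                          amplitude_scale = 30,
                          max_step = 10L,
                          curve_length = 5L) {
  stopifnot(length(shape_profile) == curve_length,
            !is.unsorted(shape_profile),
            abs(shape_profile[curve_length] - 1) < 1e-9)
  amps <- rha(amplitude_scale * (0:100) / 100)
  tab <- t(vapply(amps, curveFromAmplitude, numeric(curve_length),
                  shape = shape_profile))
  storage.mode(tab) <- "integer"
  if (any(abs(tab) > max_step)) {
    stop(structure(class = c("spikeOC_calibration_error", "error",
                             "condition"),
                   list(message = paste0(
                     "PSP table infeasible: per-cycle step exceeds ",
                     max_step, " normalized units"),
                     call = sys.call(-1))))
  }
  out <- structure(tab,
                   class = "PspTable",
                   curve_length = curve_length,
                   max_step = max_step,
                   amplitude_scale = amplitude_scale,
                   shape_profile = shape_profile)
  if (!is.null(calibration)) {
    cum <- calibration$resting_potential + cumsum(pspCurve(out, calibration$weight))
    if (!any(cum >= calibration$threshold)) {
      stop(structure(class = c("spikeOC_calibration_error", "error",
                               "condition"),
                     list(message = paste0(
                       "PSP table infeasible: a curve at weight ",
                       calibration$weight, " starting from potential ",
                       calibration$resting_potential,
                       " never crosses threshold ", calibration$threshold,
                       " within ", curve_length, " cycles"),
                       call = sys.call(-1))))
    }
  }
  out
}

#' Look up the delta curve for one weight (or stimulus intensity)
#'
#' @param table A `PspTable`.
#' @param weight Integer in 0--100.
#' @return Integer vector of per-cycle membrane deltas.
#' @export
pspCurve <- function(table, weight) {
  stopifnot(inherits(table, "PspTable"))
  w <- as.integer(clamp01(weight))
  table[w + 1L, ]
}

# Curve for a given weight rescaled by a percent efficacy, preserving the
# total-amplitude rounding discipline.
scaledCurve <- function(table, weight, efficacy = 100L, sign = 1L) {
  amp <- sum(pspCurve(table, weight)) * efficacy / 100
  sign * curveFromAmplitude(amp, attr(table, "shape_profile"))
}

#' @export
print.PspTable <- function(x, ...) {
  cat("PspTable: ", nrow(x), " weight-indexed curves of length ",
      attr(x, "curve_length"), " (max step ", attr(x, "max_step"),
      ", amplitude ", attr(x, "amplitude_scale"), " at weight 100)\n",
      sep = "")
  invisible(x)
}

#' Export a PSP table as a plain integer CSV
#'
#' Writes a 101-row table (one row per weight, columns `weight`,
#' `cycle1`..`cycleN`) for inspection.
#'
#' @param table A `PspTable`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writePspTable <- function(table, path) {
  df <- data.frame(weight = 0:100, unclass(table)[, , drop = FALSE])
  names(df)[-1] <- paste0("cycle", seq_len(ncol(table)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
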