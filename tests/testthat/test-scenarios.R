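test_that("scenario A reproduces the cued-reward timeline", {
  run <- scenarioARun()
  tr <- run$trace
  acts <- actionEvents(run)
  # reflex actions occur before cycle 100
  expect_gt(sum(acts < 100L), 3L)
  # reflex cessation around cycle 100
  cess <- reflexCessationCycle(tr)
  expect_lte(abs(cess - 100L), 15L)
  # the cue alone never drives the predictor in the first 100 cycles:
  # every early predictor spike follows a reward delivery closely
  preds <- tr$cycle[tr$spk_Predictor > 0 & tr$cycle < 100L]
  lights <- tr$cycle[tr$stim_light > 0]
  expect_gt(length(preds), 0L)
  for (pc in preds)
    expect_true(any(lights >= pc - 6L & lights < pc))
  # reward stops at the scheduled cycle, actions persist in expectation
  expect_lt(max(lights), 175L + 3L)
  expect_gt(sum(acts >= 175L), 0L)
  late <- classifyPhases(tr, run$protocol)
  expect_equal(late$classification[late$phase == "expectation"],
               "expectation")
})

test_that("the cue-to-predictor weight rises on the first reinforced pairing", {
  tr <- scenarioARun()$trace
  w <- tr[["w_Cue->Predictor"]]
  first_light <- tr$cycle[tr$stim_light > 0][1]
  expect_equal(w[1], 20L)
  # strictly increased within a chain latency of the first reward
  expect_gt(w[first_light + 10L], w[1])
})

test_that("scenario B acquires, expects, then reverses under punishment", {
  run <- scenarioBRun()
  tr <- run$trace
  acts <- actionEvents(run)
  expect_gt(sum(acts < 250L), 5L)                   # reward phase
  expect_gt(sum(acts >= 250L & acts < 500L), 5L)    # expectation window
  expect_equal(sum(acts >= 600L), 0L)               # after reversal
  heat <- tr$cycle[tr$stim_heat > 0]
  expect_gte(min(heat), 500L)                       # punishment onset
  # once reversed, the punishment predictor fires from the cue alone,
  # without further punishment delivery
  late_preds <- tr$cycle[tr$spk_PredictorP > 0 & tr$cycle >= 650L]
  expect_gt(length(late_preds), 5L)
  expect_equal(sum(heat >= 650L), 0L)
})

test_that("scenario C ends pressing red and avoiding green after the reversal", {
  run <- scenarioCRun()
  tr <- run$trace
  pr <- actionEvents(run)
  zones <- run$protocol$defaults$scenario_c$zones
  cpz <- run$protocol$defaults$scenario_c$cycles_per_zone
  expect_length(zones, 8L)
  # presses happen in the first (green, rewarded) zone
  expect_gt(sum(pr < cpz), 0L)
  # end state: no presses in the last green window, presses in the
  # final red zone
  expect_equal(sum(pr >= 650L & pr < 700L), 0L)
  expect_gt(sum(pr >= 700L), 0L)
})

test_that("without reinforcers pressing fades within a zone and recovers on color change", {
  p <- scenarioC(reinforced = FALSE)
  tr <- runScenario(p)
  pr <- actionCycles(tr, p)
  expect_equal(sum(tr$stim_light) + sum(tr$stim_heat), 0)
  per_zone <- vapply(1:8, function(z)
    sum(pr >= (z - 1L) * 100L & pr < z * 100L), integer(1))
  # every zone is re-sampled after the color change ...
  expect_true(all(per_zone > 0L))
  # ... but pressing always stops within the zone (fade under
  # adaptation + habituation: a press-free tail in every zone)
  last_in_zone <- vapply(1:8, function(z)
    max(pr[pr >= (z - 1L) * 100L & pr < z * 100L]), numeric(1))
  expect_true(all(last_in_zone <= (0:7) * 100L + 90L))
  # and the fade deepens as long-term habituation accumulates
  expect_true(all(per_zone[3:8] < per_zone[1]))
})

test_that("conveyor sorting ejects only the reinforced color at steady state", {
  for (s in 1:5) {
    p <- scenarioDSim(seed = s)
    tr <- runScenario(p, seed = s)
    perf <- sortingPerformance(tr)
    expect_equal(unname(perf$steady[["color-red"]]), 1.0)
    expect_equal(unname(perf$steady[["color-blue"]]), 0.0)
  }
})

test_that("without reinforcement the ejection reflex extinguishes for every color", {
  p <- scenarioDSim(seed = 1, reinforced_channel = NA)
  tr <- runScenario(p, seed = 1)
  perf <- sortingPerformance(tr)
  expect_equal(unname(perf$steady), c(0, 0))
  # early pieces were ejected by reflex
  expect_gt(sum(!is.na(attr(tr, "pieces")$ejected[1:10])), 5L)
})

test_that("a reinforcer latency beyond the STDP window produces no selective learning", {
  p <- scenarioDSim(seed = 1, touch_latency_range = c(20L, 20L),
                    base_interval = 40L)
  tr <- runScenario(p, seed = 1)
  wr <- tr[["w_CueRed->PredictorRRed"]]
  wb <- tr[["w_CueBlue->PredictorRBlue"]]
  expect_lte(max(abs(wr - 20L)), 5L)
  expect_lte(max(abs(wb - 20L)), 5L)
  perf <- sortingPerformance(tr)
  expect_equal(unname(perf$steady[["color-red"]]),
               unname(perf$steady[["color-blue"]]))
})

test_that("the trace classifier handles degenerate and default traces", {
  run <- scenarioARun()
  # an all-zero trace classifies every phase as quiet
  zero <- run$trace
  for (cl in setdiff(names(zero), "cycle")) zero[[cl]] <- 0L
  zero[["w_Cue->Predictor"]] <- 20L   # baseline weights, no history
  rep0 <- classifyPhases(zero, run$protocol)
  expect_true(all(rep0$classification == "habituated"))
  expect_true(all(rep0$n_actions == 0L))
  # classification is invariant to trace column order
  perm <- run$trace[, rev(seq_along(run$trace))]
  attr(perm, "phases") <- attr(run$trace, "phases")
  expect_equal(classifyPhases(perm, run$protocol),
               classifyPhases(run$trace, run$protocol))
  # protocol/trace mismatch is an error
  expect_error(classifyPhases(run$trace[, 1:3], run$protocol), "missing")
})

test_that("calibration reproduces the shipped defaults and rejects absurd targets", {
  cal <- calibrateDefaults()
  expect_identical(cal$defaults, ocDefaults())
  cal2 <- calibrateDefaults()
  expect_identical(cal, cal2)
  expect_error(
    calibrateDefaults(constraints = list(cessation_target = 1L,
                                         cessation_tol = 0L,
                                         acquisition_by = 175L,
                                         reversal_quiet_from = 600L),
                      grid = list(hab_mid = 6L, stdp_max = 10L,
                                  cue_action = 90L)),
    "cessation")
})
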