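test_that("an empty network produces an empty, spike-free trace", {
  net <- ocNetwork()
  w <- pulseWorld(10L)
  tr <- runNetwork(net, w)
  expect_equal(nrow(tr), 10L)
  expect_false(any(grepl("^spk_", names(tr))))
})

test_that("a strong relay drives the downstream neuron within 5 cycles", {
  net <- relayNet(weight = 95L)
  tr <- runNetwork(net, pulseWorld(20L))
  pre <- tr$cycle[tr$spk_Pre > 0][1]
  post <- tr$cycle[tr$spk_Post > 0][1]
  expect_false(is.na(pre))
  expect_false(is.na(post))
  expect_lte(post - pre, 5L)
})

test_that("an inhibitory synapse never lifts the target above rest", {
  net <- relayNet(weight = 95L, polarity = "inhibitory")
  tr <- runNetwork(net, pulseWorld(20L, period = 5L))
  rest <- neuronParams()$resting_potential
  expect_true(all(tr$pot_Post <= rest))
  expect_equal(sum(tr$spk_Post), 0L)
})

test_that("the engine matches the per-neuron oracle on a single neuron", {
  # dual route: the vectorized engine versus the exported per-neuron
  # integrate operation fed the same delta slices
  net <- ocNetwork()
  net <- addNeuron(net, "N")
  net <- addTransducer(net, "x", "N")
  tr <- runNetwork(net, pulseWorld(40L, period = 9L))
  tab <- net$psp_table
  curve <- pspCurve(tab, 100L)
  stream <- lapply(1:40, function(cy) {
    # pulses at cycles 0, 9, 18, ...: curve entry k arrives at pulse+k
    del <- integer(0)
    for (p0 in seq(0L, 39L, by = 9L)) {
      k <- cy - p0
      if (k >= 1 && k <= 5) del <- c(del, curve[k])
    }
    del
  })
  oracle <- oracleNeuronTrajectory(neuronParams(), stream)
  expect_equal(tr$pot_N[-1], oracle[-40])
})

test_that("runs are deterministic and prefix-consistent", {
  p <- scenarioA()
  t1 <- runScenario(p, seed = 3L)
  t2 <- runScenario(p, seed = 3L)
  expect_identical(t1, t2)
  short <- runScenario(p, cycles = 120L, seed = 3L)
  expect_identical(stripTrace(short),
                   stripTrace(t1[1:120, , drop = FALSE]))
})

test_that("all trace values are integral and in range", {
  run <- scenarioARun()
  tr <- run$trace
  expect_true(all(vapply(tr, function(v) all(v == as.integer(v)),
                         logical(1))))
  pots <- tr[grep("^pot_", names(tr))]
  expect_true(all(pots >= 0 & pots <= 100))
  ws <- tr[grep("^w_", names(tr))]
  expect_true(all(ws >= 0 & ws <= 100))
})

test_that("load-time validation names dangling identifiers", {
  net <- ocNetwork()
  net <- addNeuron(net, "A")
  net2 <- addSynapse(net, "A", "Ghost", 50L)
  expect_error(validateNetwork(net2), "Ghost")
  net3 <- addTransducer(net, "light", "Nobody")
  expect_error(validateNetwork(net3), "Nobody")
  expect_error(validateNetwork(addTransducer(net, "warp", "A"),
                               channels = "light"), "warp")
  expect_error(runNetwork(net2, pulseWorld(5L)), "Ghost")
})

test_that("contingent reinforcers always follow a trigger action", {
  run <- scenarioARun()
  tr <- run$trace
  lights <- tr$cycle[tr$stim_light > 0]
  acts <- actionEvents(run)
  lat <- run$protocol$world$contingencies$latency[1]
  for (lc in lights) expect_true((lc - lat) %in% acts)
  expect_error(ocWorld(channels = "x", cycles = 10L,
                       contingencies = data.frame(
                         action = "a", channel = "x", start = 0L,
                         end = 10L, latency = 0L, intensity = 100L)),
               "latency")
})
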