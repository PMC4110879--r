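# Heavier property suites over the composed system.

test_that("conditioning succeeds only with a strong cue-action and weak cue-predictor link", {
  # 5 x 5 x 5 grid of initial kernel weight triples; success must be
  # confined to the region where the cue alone can fire the Action
  # (strong cue_action) while the cue alone cannot fire the Predictor
  # (weak cue_predictor)
  vals <- c(10L, 30L, 50L, 70L, 90L)
  solo <- soloFiringWeight()
  n_success <- 0L
  for (ca in vals) for (pa_ in vals) for (cp in vals) {
    net <- buildKernel(weights = c(cue_action = ca,
                                   predictor_action = pa_,
                                   cue_predictor = cp),
                       validate = FALSE)
    p <- scenarioA()
    p$network <- net
    ok <- acquisitionExpectation(runScenario(p), p)
    if (ok) {
      n_success <- n_success + 1L
      expect_gte(ca, solo)
      expect_lt(cp, solo)
    }
  }
  # the shipped region is non-empty and a minority of the grid
  expect_gt(n_success, 0L)
  expect_lt(n_success, 25L)
})

test_that("no other placement of the two learning rules produces conditioning", {
  d <- ocDefaults()
  place <- function(ca_rule, cp_rule) {
    p <- scenarioA()
    net <- p$network
    k <- attr(net, "kernels")[[1]]
    w <- d$weights
    net$synapses[[k$cue_action]]$habituation <-
      if (ca_rule == "hab") spikeOC:::defaultHabituation(d)
    net$synapses[[k$cue_action]]$stdp <-
      if (ca_rule == "stdp") spikeOC:::defaultStdp(w[["cue_action"]], d)
    net$synapses[[k$cue_predictor]]$habituation <-
      if (cp_rule == "hab") spikeOC:::defaultHabituation(d)
    net$synapses[[k$cue_predictor]]$stdp <-
      if (cp_rule == "stdp") spikeOC:::defaultStdp(w[["cue_predictor"]], d)
    p$network <- net
    acquisitionExpectation(runScenario(p), p)
  }
  results <- c(hab_stdp = place("hab", "stdp"),   # the kernel's placement
               hab_hab = place("hab", "hab"),
               stdp_hab = place("stdp", "hab"),
               stdp_stdp = place("stdp", "stdp"))
  expect_identical(results,
                   c(hab_stdp = TRUE, hab_hab = FALSE,
                     stdp_hab = FALSE, stdp_stdp = FALSE))
})

test_that("traces are invariant to the declaration order of neurons", {
  # synchronous semantics: permuting the neuron declaration order must
  # not change any dynamics
  build <- function(order) {
    net <- ocNetwork()
    for (id in order) net <- addNeuron(net, id)
    net <- addSynapse(net, "A", "B", 95L)
    net <- addSynapse(net, "B", "C", 95L)
    net <- addTransducer(net, "x", "A")
    net
  }
  w <- pulseWorld(60L, period = 12L)
  t1 <- runNetwork(build(c("A", "B", "C")), w)
  t2 <- runNetwork(build(c("C", "B", "A")), w)
  cols <- sort(names(t1))
  expect_identical(as.data.frame(t1)[cols], as.data.frame(t2)[cols])
})

test_that("every spike schedules exactly one scaled 5-cycle curve per outgoing synapse", {
  # with habituation at 50% the delivered deltas are the rescaled curve
  hb <- habituationState(decay_steps = c(short = 0L, mid = 0L, long = 0L))
  hb$efficacy <- 50L
  net <- relayNet(weight = 70L, habituation = hb)
  tr <- runNetwork(net, pulseWorld(20L))
  pre <- tr$cycle[tr$spk_Pre > 0][1]
  expected <- cumsum(spikeOC:::scaledCurve(net$psp_table, 70L, 50L))
  got <- tr$pot_Post[(pre + 2):(pre + 6)] - tr$pot_Post[pre + 1]
  expect_equal(got, as.vector(expected))
})

test_that("after any stimulation history, silence restores every plasticity state", {
  # habituation, adaptation and STDP all recover to baseline given a
  # long enough silent tail (the extinction mechanism)
  set.seed(99)
  ad <- adaptationState(); hb <- habituationState(); sp <- stdpState()
  w <- 20L
  for (cy in 0:200) {
    stim <- runif(1) < 0.4
    pre <- runif(1) < 0.3
    post <- runif(1) < 0.3
    ad <- applyAdaptation(ad, stim)
    hb <- applyHabituation(hb, pre, cy)
    r <- applyStdp(sp, w, pre, post, cy)
    sp <- r$state; w <- r$weight
  }
  for (cy in 201:600) {
    ad <- applyAdaptation(ad, FALSE)
    hb <- applyHabituation(hb, FALSE, cy)
    r <- applyStdp(sp, w, FALSE, FALSE, cy)
    sp <- r$state; w <- r$weight
  }
  expect_equal(ad$efficacy, 100L)
  expect_equal(hb$efficacy, 100L)
  expect_equal(w, sp$baseline)
})
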