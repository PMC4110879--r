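test_that("sensory adaptation decays under stimulation and recovers fast", {
  st <- adaptationState()
  effs <- integer(30)
  for (i in 1:30) {
    st <- applyAdaptation(st, TRUE)
    effs[i] <- st$efficacy
  }
  expect_lt(effs[30], 100L)
  expect_true(all(diff(effs) <= 0))
  expect_gte(min(effs), st$floor)
  # removing the stimulus restores full efficacy within the recovery
  # horizon
  for (i in 1:15) st <- applyAdaptation(st, FALSE)
  expect_equal(st$efficacy, 100L)
})

test_that("sparse stimulation leaves adaptation roughly at rest", {
  # 1 stimulated cycle per 20 silent ones: fast recovery dominates
  st <- adaptationState()
  for (rep in 1:20) {
    st <- applyAdaptation(st, TRUE)
    for (i in 1:20) st <- applyAdaptation(st, FALSE)
  }
  expect_equal(st$efficacy, 100L)
})

test_that("habituation decreases with persistent input and is ISI-sensitive", {
  run_isi <- function(isi, n_spikes) {
    st <- habituationState()
    cy <- 0L
    for (k in 1:n_spikes) {
      st <- applyHabituation(st, TRUE, cy)
      for (i in 1:(isi - 1L)) {
        cy <- cy + 1L
        st <- applyHabituation(st, FALSE, cy)
      }
      cy <- cy + 1L
    }
    st
  }
  # periodic input: efficacy is non-increasing toward the floor
  st <- habituationState()
  effs <- integer(20)
  for (k in 1:20) {
    st <- applyHabituation(st, TRUE, (k - 1L) * 5L)
    for (j in 1:4) st <- applyHabituation(st, FALSE, (k - 1L) * 5L + j)
    effs[k] <- st$efficacy
  }
  expect_true(all(diff(effs) <= 0))
  expect_equal(min(effs), habituationState()$floor)
  # same spike count at shorter ISI habituates at least as much
  expect_lte(run_isi(2L, 8L)$efficacy, run_isi(10L, 8L)$efficacy)
  # bounded for arbitrary streams
  set.seed(7)
  st <- habituationState()
  for (i in 1:500) {
    st <- applyHabituation(st, runif(1) < 0.3, i)
    expect_true(st$efficacy >= st$floor && st$efficacy <= 100L)
  }
})

test_that("habituation recovers fully after sufficient silence", {
  st <- habituationState()
  for (k in 1:30) st <- applyHabituation(st, TRUE, k * 3L)
  expect_equal(st$efficacy, st$floor)
  horizon <- st$recovery_delay + (100L - st$floor) / st$recovery_step + 1L
  for (i in 1:horizon) st <- applyHabituation(st, FALSE, 100L + i)
  expect_equal(st$efficacy, 100L)
})

test_that("STDP increments have the correct sign and taper over the window", {
  st <- stdpState()
  for (dt in seq(-st$window - 5L, st$window + 5L)) {
    inc <- stdpIncrement(st, dt)
    if (dt == 0L || abs(dt) > st$window) {
      expect_identical(inc, 0L)
    } else if (dt > 0L) {
      expect_gt(inc, 0L)
    } else {
      expect_lt(inc, 0L)
    }
  }
  mags <- vapply(1:st$window, function(dt) stdpIncrement(st, dt), integer(1))
  expect_true(all(diff(mags) <= 0L))
  expect_lte(max(mags), 10L)
})

test_that("pair-based STDP potentiates, depresses, clamps and respects the window", {
  step_pair <- function(w, pre_cycle, post_cycle, horizon = 40L) {
    st <- stdpState()
    for (cy in 0:horizon) {
      r <- applyStdp(st, w, pre_cycle == cy, post_cycle == cy, cy)
      st <- r$state; w <- r$weight
    }
    w
  }
  expect_gt(step_pair(30L, 10L, 12L), 30L)
  expect_lt(step_pair(30L, 12L, 10L), 30L)
  expect_equal(step_pair(30L, 10L, 10L + stdpState()$window + 1L), 30L)
  expect_equal(step_pair(100L, 10L, 12L), 100L)
  expect_equal(step_pair(0L, 12L, 10L), 0L)
})

test_that("nearest-neighbor pairing never double-counts a spike", {
  # one pre followed by two posts inside the window: exactly one pairing
  st <- stdpState()
  w <- 50L
  for (cy in 0:20) {
    r <- applyStdp(st, w, cy == 5L, cy %in% c(7L, 9L), cy)
    st <- r$state; w <- r$weight
  }
  expect_equal(w, 50L + stdpIncrement(stdpState(), 2L))
  # two pres followed by one post: the nearer pre pairs, once
  st <- stdpState(); w <- 50L
  for (cy in 0:20) {
    r <- applyStdp(st, w, cy %in% c(3L, 8L), cy == 10L, cy)
    st <- r$state; w <- r$weight
  }
  expect_equal(w, 50L + stdpIncrement(stdpState(), 2L))
})

test_that("without pairings the weight drifts back to its baseline", {
  st <- stdpState(baseline = 20L)
  w <- 80L
  for (cy in 0:(st$forget_delay + 70L)) {
    r <- applyStdp(st, w, FALSE, FALSE, cy)
    st <- r$state; w <- r$weight
  }
  expect_equal(w, 20L)
})
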