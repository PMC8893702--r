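test_that("2-Context trial layout follows the target and input formulas", {
  cfg <- fixedOnsetConfig(dt = 0.01, onset = 0.5)
  trial <- makeTrial(cfg, "short")
  t <- seq_len(nrow(trial@inputs)) * 0.01

  expect_equal(trial@stimOnset, 0.5)
  expect_equal(trial@trialLength, 0.5 + 3 + 0.2)
  # linear ramp: halfway through the second half of the interval -> 0.5
  expect_equal(trial@target[t == 2.75], (2.25 - 1.5) / 1.5)
  expect_true(all(trial@target[t <= 2.0 + 1e-9] == 0))
  expect_true(all(trial@target[t > 3.5 + 1e-9] == 1))
  expect_true(all(trial@target >= 0 & trial@target <= 1))
  # hold window integrates to postInterval (target exactly 1 there)
  expect_equal(sum(trial@target[t > 3.5 + 1e-9]) * 0.01, 0.2,
               tolerance = 0.011)
  # Go channel: 1 exactly on (onset, onset + 0.5]
  expect_equal(trial@inputs[, 1],
               as.numeric(t > 0.5 + 1e-9 & t <= 1.0 + 1e-9))
  # context channel persistent at the short level
  expect_true(all(trial@inputs[t > 0.5 + 1e-9, 2] == 0.75))
  expect_true(all(trial@inputs[t <= 0.5 + 1e-9, 2] == 0))

  long <- makeTrial(cfg, "long")
  tl <- seq_len(nrow(long@inputs)) * 0.01
  expect_true(all(long@inputs[tl > 0.5 + 1e-9, 2] == 0.25))
  # short and long trials share the Go channel profile
  n <- nrow(trial@inputs)
  expect_equal(long@inputs[seq_len(n), 1], trial@inputs[, 1])
})

test_that("2-Stimulus channels carry the mixing weights on the stimulus window", {
  cfg <- fixedOnsetConfig("2stimulus", dt = 0.01, onset = 0.4)
  trial <- makeTrial(cfg, c(0.5, 0.5))
  t <- seq_len(nrow(trial@inputs)) * 0.01
  on <- t > 0.4 + 1e-9 & t <= 0.9 + 1e-9
  expect_true(all(trial@inputs[on, ] == 0.5))
  expect_true(all(trial@inputs[!on, ] == 0))
  # scalar condition is the long-channel weight
  tr2 <- makeTrial(cfg, 0.3)
  expect_equal(unique(tr2@inputs[, 2][tr2@inputs[, 2] > 0]), 0.3)

  expect_error(makeTrial(cfg, c(0.6, 0.6)), "sum to 1")
  expect_error(makeTrial(fixedOnsetConfig(), 1.5), "\\[0, 1\\]")
})

test_that("task variants: no-Go silences channel 1, transient context is brief", {
  cfg <- fixedOnsetConfig(dt = 0.01, onset = 0.5, goEnabled = FALSE)
  trial <- makeTrial(cfg, "short")
  expect_true(all(trial@inputs[, 1] == 0))

  cfg <- fixedOnsetConfig(dt = 0.01, onset = 0.5, contextMode = "transient")
  trial <- makeTrial(cfg, "long")
  t <- seq_len(nrow(trial@inputs)) * 0.01
  expect_true(all(trial@inputs[t > 1.0 + 1e-9, 2] == 0))
  expect_true(all(trial@inputs[t > 0.5 + 1e-9 & t <= 1.0 + 1e-9, 2] == 0.25))
})

test_that("stimulus onset is drawn on the dt grid within the baseline range", {
  cfg <- taskConfig("2context", dt = 0.02)
  onsets <- vapply(1:200, function(i) makeTrial(cfg, "short")@stimOnset,
                   numeric(1))
  expect_true(all(onsets >= 0.2 - 1e-9 & onsets <= 0.6 + 1e-9))
  expect_true(all(abs(onsets / 0.02 - round(onsets / 0.02)) < 1e-6))
  expect_gt(length(unique(onsets)), 5)
  # seeded draws are reproducible
  expect_equal(makeTrial(cfg, "short", seed = 7)@stimOnset,
               makeTrial(cfg, "short", seed = 7)@stimOnset)
})

test_that("mask covers the whole trial unless the baseline is excluded", {
  cfg <- fixedOnsetConfig(dt = 0.01, onset = 0.5)
  expect_true(all(makeTrial(cfg, "short")@mask == 1))
  cfg@maskBaseline <- TRUE
  trial <- makeTrial(cfg, "short")
  t <- seq_len(length(trial@mask)) * 0.01
  expect_true(all(trial@mask[t <= 0.5 + 1e-9] == 0))
  expect_true(all(trial@mask[t > 0.5 + 1e-9] == 1))
})

test_that("input weights are standard normal with the requested overlap", {
  cfg <- taskConfig("2stimulus", inputOverlap = 1)
  W <- makeInputWeights(cfg, 100, seed = 1)
  expect_equal(W[, 1], W[, 2])

  cfg0 <- taskConfig("2stimulus", inputOverlap = 0)
  # expected cosine similarity of independent columns is ~0
  cosines <- vapply(1:300, function(s) {
    W <- makeInputWeights(cfg0, 100, seed = s)
    sum(W[, 1] * W[, 2]) / sqrt(sum(W[, 1]^2) * sum(W[, 2]^2))
  }, numeric(1))
  expect_lt(mean(abs(cosines)), 0.1)

  cfgHalf <- taskConfig("2stimulus", inputOverlap = 0.5)
  W <- makeInputWeights(cfgHalf, 200, seed = 2)
  expect_equal(sum(W[, 1] == W[, 2]), 100)
})
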