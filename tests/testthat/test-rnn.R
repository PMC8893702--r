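test_that("initialization produces a sparse, signed, zero-diagonal matrix", {
  net <- initNetwork(N = 200, connectionProb = 0.2, seed = 3)
  W <- net@wRec
  off <- W[row(W) != col(W)]
  # binomial 99.9% interval for 200*199 Bernoulli(0.2) draws
  expect_gt(mean(off != 0), 0.17)
  expect_lt(mean(off != 0), 0.23)
  expect_true(all(W >= 0))
  expect_true(all(diag(W) == 0))
  expect_equal(sum(isExcitatory(net)), round(200 * 0.8))

  full <- initNetwork(N = 50, connectionProb = 1, seed = 4)
  offFull <- full@wRec[row(full@wRec) != col(full@wRec)]
  expect_true(all(offFull != 0))
})

test_that("inhibitory columns are boosted at initialization", {
  net <- initNetwork(N = 400, connectionProb = 1, inhibitoryBoost = 4,
                     seed = 5)
  e <- isExcitatory(net)
  W <- net@wRec
  mE <- mean(W[, e][W[, e] > 0])
  mI <- mean(W[, !e][W[, !e] > 0])
  # half-normal means scale with the boost factor
  expect_equal(mI / mE, 4, tolerance = 0.1)
})

test_that("effective weights respect Dale's law column-wise", {
  net <- initNetwork(N = 80, seed = 6)
  net@wRec[2, 1] <- -0.5  # a clipped (silent) raw weight
  W <- effectiveWeights(net)
  sgn <- net@signVector
  for (j in seq_len(80)) {
    nz <- W[, j][W[, j] != 0]
    if (length(nz)) expect_true(all(sign(nz) == sgn[j]))
  }
  expect_equal(W[2, 1], 0)
  expect_true(all(diag(W) == 0))
})

test_that("a single Euler step matches the hand-computed update", {
  net <- twoUnitNetwork(w12 = 0.5, w21 = 0.3, dt = 0.02)
  cfg <- fixedOnsetConfig(dt = 0.02, onset = 0.2)
  trial <- makeTrial(cfg, "short")
  sim <- simulateTrial(net, trial, noiseSigma = 0)
  alpha <- 0.02 / 0.1
  r0 <- rep(log(2), 2)
  Weff <- effectiveWeights(net)
  I1 <- trial@inputs[1, ]
  x1 <- (1 - alpha) * 0 + alpha * (Weff %*% r0 + net@wIn %*% I1)
  r1 <- pmin(log1p(exp(x1)), 20)
  expect_equal(sim$trajectory@rates[, 1], as.numeric(r1), tolerance = 1e-12)
  expect_equal(sim$output[1], sum(net@wOut * r1), tolerance = 1e-12)
})

test_that("with no recurrent or input drive the state stays at zero", {
  net <- initNetwork(N = 30, seed = 7)
  net@wRec <- matrix(0, 30, 30)
  net@wIn <- matrix(0, 30, 2)
  cfg <- fixedOnsetConfig(dt = 0.02, onset = 0.2)
  trial <- makeTrial(cfg, "short")
  sim <- simulateTrial(net, trial, noiseSigma = 0)
  # x stays 0, so every rate is softplus(0) = log 2 and o = log2 * sum(wOut)
  expect_true(all(abs(sim$trajectory@rates - log(2)) < 1e-12))
  expect_equal(sim$output,
               rep(log(2) * sum(net@wOut), length(sim$output)),
               tolerance = 1e-12)
})

test_that("rates are capped by the Softplus bound even under strong noise", {
  net <- initNetwork(N = 60, seed = 8)
  cfg <- taskConfig(dt = 0.02)
  trial <- makeTrial(cfg, "long", seed = 1)
  sim <- simulateTrial(net, trial, noiseSigma = 2, seed = 2)
  expect_true(all(sim$trajectory@rates >= 0))
  expect_true(all(sim$trajectory@rates <= 20))
  # the bound itself: softplus(50) would be 50 without the cap
  expect_equal(min(log1p(exp(20.0001)), 20), 20)
})

test_that("noiseless simulation is bit-identical across runs", {
  net <- initNetwork(N = 40, seed = 9)
  cfg <- fixedOnsetConfig(dt = 0.02, onset = 0.4)
  trial <- makeTrial(cfg, "short")
  a <- simulateTrial(net, trial, noiseSigma = 0)
  b <- simulateTrial(net, trial, noiseSigma = 0)
  expect_identical(a$trajectory@rates, b$trajectory@rates)
  expect_identical(a$output, b$output)
  # seeded noisy runs reproduce too
  c1 <- simulateTrial(net, trial, seed = 11)
  c2 <- simulateTrial(net, trial, seed = 11)
  expect_identical(c1$output, c2$output)
})

test_that("trial-averaged dynamics cover exactly the delay epoch", {
  net <- initNetwork(N = 20, seed = 10)
  cfg <- taskConfig(dt = 0.02)
  avg <- averageDynamics(net, cfg, "short", nTrials = 3, dt = 0.02,
                         seed = 12)
  expect_equal(ncol(avg@rates), 3 / 0.02)
  expect_equal(avg@nTrials, 3L)
  expect_identical(avg@rates,
                   averageDynamics(net, cfg, "short", nTrials = 3,
                                   dt = 0.02, seed = 12)@rates)
})
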