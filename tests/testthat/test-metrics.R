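test_that("reference vectors span pure scaling to pure absolute", {
  # tau = 1: starts at 1, increments by alpha, ends at Tlong
  v <- referenceVector(1, 3000, 6000)
  expect_equal(v[1], 1)
  expect_equal(diff(v)[-1], rep(5999 / 2999, 2998))
  expect_equal(v[3000], 6000)
  # tau = Tshort: the identity vector (pure absolute)
  expect_identical(referenceVector(3000, 3000, 6000), as.numeric(1:3000))
  # tau = Tshort/2: identity then linear to Tlong
  v <- referenceVector(150, 300, 600)
  expect_identical(v[1:150], as.numeric(1:150))
  expect_equal(v[300], 600)
  expect_equal(diff(v[151:300]), rep((600 - 150) / 150, 149))
})

test_that("population SSI matches the brute-force oracle on small prototypes", {
  for (regime in c("scaling", "absolute", "stimulus-specific")) {
    p <- makePrototype(regime, dt = 0.01, seed = 8)
    Xs <- rateMatrix(p, "short"); Xl <- rateMatrix(p, "long")
    fast <- computeSSIPop(Xs, Xl)
    slow <- oracleSSIPop(Xs, Xl)
    expect_identical(as.integer(fast@iMin), slow$iMin)
    expect_identical(fast@tauMin, slow$tauMin)
    expect_equal(fast@cTauMin, slow$cTauMin, tolerance = 1e-10)
    expect_equal(fast@ssiPop, slow$ssiPop, tolerance = 1e-10)
  }
})

test_that("pure regimes give SSI_pop = 0 and scaling gives tau_min = 1", {
  p <- smallPrototype("scaling")
  s <- computeSSIPop(rateMatrix(p, "short"), rateMatrix(p, "long"))
  expect_equal(s@ssiPop, 0, tolerance = 1e-10)
  expect_identical(s@tauMin, 1L)
  # the minimal index vector of pure scaling is the subsampling line
  expect_equal(s@iMin, seq(2, 600, by = 2))

  p <- smallPrototype("absolute")
  s <- computeSSIPop(rateMatrix(p, "short"), rateMatrix(p, "long"))
  expect_equal(s@ssiPop, 0, tolerance = 1e-10)
  expect_identical(s@tauMin, 300L)

  p <- smallPrototype("stimulus-specific", seed = 9)
  s <- computeSSIPop(rateMatrix(p, "short"), rateMatrix(p, "long"))
  expect_gt(s@ssiPop, 0.05)
})

test_that("unit warp indices agree with the approx-based oracle", {
  p <- makePrototype("stimulus-specific", dt = 0.01, seed = 10)
  Xs <- rateMatrix(p, "short"); Xl <- rateMatrix(p, "long")
  for (i in c(3, 25, 50, 77, 96)) {
    fast <- computeUnitIndices(Xs[i, ], Xl[i, ])
    slow <- oracleUnitIndices(Xs[i, ], Xl[i, ])
    expect_identical(fast$tauMin, slow$tauMin)
    expect_equal(fast$dist, slow$dist, tolerance = 1e-10)
    expect_equal(fast$ssiUnit, slow$ssiUnit, tolerance = 1e-10)
  }
})

test_that("unit indices behave analytically on canonical traces", {
  tt <- seq(0.01, 3, by = 0.01)
  # pure per-unit scaling: y(t) = x(t/2) exactly
  y <- exp(-(seq(0.01, 6, by = 0.01) - 2)^2 / (2 * 0.3^2))
  x <- y[seq(2, 600, by = 2)]
  ui <- computeUnitIndices(x, y)
  expect_equal(ui$tauMin, 0)
  expect_lt(ui$ssiUnit, 1e-10)
  expect_lte(ui$asi, 0.5)

  # absolute: y equals x on the short window, flat afterwards
  x2 <- exp(-(tt - 1)^2 / (2 * 0.3^2))
  y2 <- c(x2, rep(x2[300], 300))
  ui <- computeUnitIndices(x2, y2)
  expect_equal(ui$tauMin, 300)
  expect_equal(ui$dist, 0, tolerance = 1e-18)
  expect_equal(ui$asi, 1)  # AbsR = 1 and tau_min/Tshort = 1

  # disjoint bumps: no absolute-scaling warp aligns them
  x3 <- exp(-(tt - 1)^2 / (2 * 0.2^2))
  y3 <- exp(-(seq(0.01, 6, by = 0.01) - 5)^2 / (2 * 0.2^2))
  ui <- computeUnitIndices(x3, y3)
  expect_gt(ui$ssiUnit, 0.5)

  # silent unit: undefined indices
  ui <- computeUnitIndices(rep(0, 300), rep(0, 600))
  expect_true(is.na(ui$ssiUnit))
})

test_that("the coarse tau grid with refinement agrees with the exhaustive scan", {
  p <- makePrototype("stimulus-specific", dt = 0.01, seed = 12)
  Xs <- rateMatrix(p, "short"); Xl <- rateMatrix(p, "long")
  for (i in c(10, 40, 80)) {
    exact <- computeUnitIndices(Xs[i, ], Xl[i, ], tauStep = 1)
    coarse <- computeUnitIndices(Xs[i, ], Xl[i, ], tauStep = 10)
    expect_equal(coarse$ssiUnit, exact$ssiUnit, tolerance = 1e-6)
    expect_lte(abs(coarse$tauMin - exact$tauMin), 10)
  }
})

test_that("classification recovers the generating regime on prototypes", {
  cls <- classifyUnits(smallPrototype("scaling"), tauStep = 5)
  expect_true(all(classLabels(cls) == "scaling"))

  cls <- classifyUnits(smallPrototype("absolute"), tauStep = 5)
  lab <- classLabels(cls)
  # every active unit is absolute: short rows equal the long rows' onset
  expect_true(all(lab[cls@active] == "absolute"))

  cls <- classifyUnits(makePrototype("stimulus-specific", dt = 0.01,
                                     seed = 13), tauStep = 5)
  tab <- table(classLabels(cls))
  expect_gt(tab[["stimulus-specific"]] / sum(tab), 0.5)

  # threshold rule: SSI_unit > 0.5 wins regardless of ASI
  expect_identical(classLabels(cls)[cls@ssiUnit > 0.5],
                   rep("stimulus-specific", sum(cls@ssiUnit > 0.5,
                                                na.rm = TRUE)))
  # silent units are unclassifiable
  z <- matrix(0, 2, 300); zl <- matrix(0, 2, 600)
  expect_identical(classLabels(classifyUnits(z, zl)),
                   rep("unclassifiable", 2))
})

test_that("SSI values are invariant under a common positive rescaling", {
  p <- makePrototype("stimulus-specific", dt = 0.01, seed = 14)
  Xs <- rateMatrix(p, "short"); Xl <- rateMatrix(p, "long")
  a <- computeSSIPop(Xs, Xl)
  b <- computeSSIPop(3.7 * Xs, 3.7 * Xl)
  expect_identical(a@iMin, b@iMin)
  expect_equal(a@ssiPop, b@ssiPop, tolerance = 1e-12)
  u1 <- computeUnitIndices(Xs[20, ], Xl[20, ])
  u2 <- computeUnitIndices(5 * Xs[20, ], 5 * Xl[20, ])
  expect_equal(u1$ssiUnit, u2$ssiUnit, tolerance = 1e-12)
  expect_identical(u1$tauMin, u2$tauMin)
})

test_that("relaxing the shuffle toward identity never increases SSI_pop", {
  fracs <- c(1, 0.75, 0.5, 0.25, 0)
  vals <- vapply(fracs, function(f) {
    p <- makePrototype("stimulus-specific", dt = 0.01, permuteFraction = f,
                       seed = 15)
    computeSSIPop(rateMatrix(p, "short"), rateMatrix(p, "long"))@ssiPop
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-10))
  expect_equal(vals[length(vals)], 0, tolerance = 1e-10)
})
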