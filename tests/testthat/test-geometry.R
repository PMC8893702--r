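test_that("planar dynamics are fully captured by two components", {
  set.seed(51)
  # trajectories confined to a known 2-plane in 20-unit space
  b1 <- rnorm(20); b2 <- rnorm(20)
  t <- seq(0, 2 * pi, length.out = 100)
  Xs <- outer(b1, cos(t)) + outer(b2, sin(t))
  Xl <- outer(b1, cos(2 * t)) + outer(b2, sin(2 * t))
  expect_warning(proj <- fitSubspace(Xs, Xl, nComponents = 3),
                 "rank")
  expect_equal(sum(proj@varExplained[1:2]), 1, tolerance = 1e-10)
})

test_that("the component basis is orthonormal and variance sums to total", {
  net <- initNetwork(N = 30, dt = 0.02, seed = 52)
  cfg <- taskConfig(dt = 0.02)
  s <- averageDynamics(net, cfg, "short", nTrials = 2, dt = 0.02, seed = 53)
  l <- averageDynamics(net, cfg, "long", nTrials = 2, dt = 0.02, seed = 54)
  proj <- fitSubspace(s, l, params = net)
  B <- proj@basis
  expect_equal(unname(crossprod(B)), diag(3), tolerance = 1e-10)
  expect_equal(sum(proj@varExplained), 1, tolerance = 1e-10)
  expect_true(all(diff(proj@varExplained) <= 1e-12))
  # PCA identity: residual variance = total minus explained
  X <- cbind(rateMatrix(s), rateMatrix(l)) - proj@center
  total <- sum(X^2)
  recon <- B %*% (crossprod(B, X))
  expect_equal(sum((X - recon)^2) / total,
               1 - sum(proj@varExplained[1:3]), tolerance = 1e-8)
})

test_that("segment angles match a direct dot-product computation", {
  set.seed(55)
  for (k in 1:100) {
    u <- rnorm(3); v <- rnorm(3)
    ang <- tempocode:::vectorAngle(u, v)
    expect_equal(ang, acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi)
    expect_gte(ang, 0); expect_lte(ang, 180)
  }
  expect_equal(tempocode:::vectorAngle(c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(tempocode:::vectorAngle(c(1, 0, 0), c(0, 3, 0)), 90)
  expect_equal(tempocode:::vectorAngle(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_true(is.na(tempocode:::vectorAngle(c(0, 0, 0), c(1, 0, 0))))
})

test_that("segment angles are invariant under rotation of the basis", {
  net <- initNetwork(N = 25, dt = 0.02, seed = 56)
  cfg <- taskConfig(dt = 0.02)
  s <- averageDynamics(net, cfg, "short", nTrials = 1, dt = 0.02, seed = 57)
  l <- averageDynamics(net, cfg, "long", nTrials = 1, dt = 0.02, seed = 58)
  proj <- fitSubspace(s, l, params = net)
  ang <- segmentAngles(proj, binSeconds = 0.25)

  set.seed(59)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))  # random orthogonal rotation
  rot <- proj
  rot@projections <- lapply(proj@projections, function(P) Q %*% P)
  rot@projectedWeights <- Q %*% proj@projectedWeights
  ang2 <- segmentAngles(rot, binSeconds = 0.25)
  expect_equal(ang$angle, ang2$angle, tolerance = 1e-8)

  # sanity on the table layout: one row per condition x bin x weight
  expect_identical(names(ang), c("condition", "binStart", "weight", "angle"))
  expect_setequal(unique(ang$weight), c("input1", "input2", "output"))
  bsteps <- round(0.25 / 0.02)  # the bin is rounded to the grid
  nbinExpected <- floor(ncol(proj@projections$short) / bsteps) +
    floor(ncol(proj@projections$long) / bsteps)
  expect_equal(nrow(ang), 3 * nbinExpected)
})
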