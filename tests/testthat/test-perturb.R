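test_that("unit deletion zeroes exactly the touched rows and columns", {
  net <- initNetwork(N = 30, seed = 41)
  expect_identical(deleteUnits(net, integer(0))@wRec, net@wRec)

  del <- deleteUnits(net, c(3, 7))
  Weff <- effectiveWeights(del)
  expect_true(all(Weff[c(3, 7), ] == 0))
  expect_true(all(Weff[, c(3, 7)] == 0))
  untouched <- setdiff(seq_len(30), c(3, 7))
  expect_identical(del@wRec[untouched, untouched],
                   net@wRec[untouched, untouched])
  expect_identical(del@wIn, net@wIn)
  expect_identical(del@wOut, net@wOut)

  alldel <- deleteUnits(net, seq_len(30))
  expect_true(all(alldel@wRec == 0))
})

test_that("the four synapse groups partition the off-diagonal entries", {
  net <- initNetwork(N = 40, connectionProb = 1, seed = 42)
  masks <- lapply(c("EE", "EI", "IE", "II"),
                  function(g) tempocode:::groupMaskSrcDst(net, g))
  total <- Reduce(`+`, masks)
  expect_true(all(total == 1))  # disjoint cover

  p <- net
  for (g in c("EE", "EI", "IE", "II")) p <- deleteGroup(p, g)
  expect_true(all(p@wRec == 0))

  # deleting I->E removes inhibitory input to excitatory units only
  d <- deleteGroup(net, "IE")
  Weff <- effectiveWeights(d)
  e <- isExcitatory(net)
  expect_true(all(Weff[e, !e] == 0))
  expect_identical(Weff[!e, ], effectiveWeights(net)[!e, ])
})

test_that("unit deletion equals zeroing all groups restricted to the unit", {
  net <- initNetwork(N = 25, seed = 43)
  j <- 5L
  a <- deleteUnits(net, j)
  b <- net
  b@wRec[j, ] <- 0
  b@wRec[, j] <- 0
  expect_identical(a@wRec, b@wRec)
  # surviving weights keep their sign structure
  Weff <- effectiveWeights(a)
  sgn <- net@signVector
  nz <- which(Weff != 0, arr.ind = TRUE)
  expect_true(all(sign(Weff[nz]) == sgn[nz[, 2]]))
})

test_that("connectivity statistics reflect initialization and lesions", {
  net <- initNetwork(N = 200, connectionProb = 0.2, seed = 44)
  cs <- connectivityStats(net)
  expect_setequal(cs$group, c("EE", "EI", "IE", "II"))
  expect_true(all(abs(cs$probability - 0.2) < 0.04))
  # inhibitory columns were boosted at init
  expect_gt(cs$meanWeight[cs$group == "IE"],
            cs$meanWeight[cs$group == "EE"])

  csDel <- connectivityStats(deleteGroup(net, "EE"))
  expect_equal(csDel$probability[csDel$group == "EE"], 0)
  expect_equal(csDel$probability[csDel$group == "II"],
               cs$probability[cs$group == "II"])
})

test_that("deletion experiments skip oversized pools and reproduce under a seed", {
  net <- initNetwork(N = 30, dt = 0.02, seed = 45)
  cfg <- taskConfig("2context", dt = 0.02)
  cls <- new("TimingClassification",
             ssiUnit = rep(0.1, 30), asi = rep(0.1, 30),
             tauMin = rep(0, 30),
             classLabel = rep(c("scaling", "absolute", "stimulus-specific"),
                              each = 10),
             active = rep(TRUE, 30))
  expect_message(
    res <- runDeletionExperiment(net, cls, cfg, counts = c(2, 25),
                                 nSelections = 2, trialsPerInterval = 2,
                                 seed = 46),
    "skipping")
  expect_true(all(res$count == 2))
  res2 <- runDeletionExperiment(net, cls, cfg, counts = 2,
                                nSelections = 2, trialsPerInterval = 2,
                                seed = 46)
  expect_equal(res$performance, res2$performance)
  expect_equal(res$meanError, res2$meanError)
})

test_that("group deletion experiment includes the intact baseline", {
  net <- initNetwork(N = 20, dt = 0.02, seed = 47)
  cfg <- taskConfig("2context", dt = 0.02)
  res <- groupDeletionExperiment(net, cfg, trialsPerInterval = 2, seed = 48)
  expect_identical(res$condition, c("intact", "EE", "EI", "IE", "II"))
  expect_true(all(res$meanError >= 0))
})
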