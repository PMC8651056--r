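test_that("settings limits are enforced before any computation", {
  net16 <- makeNKNetwork(16, 2, seed = 3)
  ok <- simulationSettings(outputs = nodeNames(net16)[1:15], sampleCount = 20,
                           timePoints = 100, seed = 1)
  expect_s4_class(runEnsemble(net16, ok), "SimulationResult")
  expect_error(simulationSettings(outputs = nodeNames(net16)[1:16]),
               "limited to 15")
  expect_error(simulationSettings(timePoints = 101), "limited to 100")
  expect_error(simulationSettings(sampleCount = 0), "positive")
  expect_error(simulationSettings(maxTime = -1), "positive")
})

test_that("single-jump trajectories have Exponential(1) waiting times", {
  net <- makeToy("single_node", kUp = 1, kDown = 0)
  s <- simulationSettings(initial = fixedInitialState(c(S = 0)),
                          maxTime = 50, seed = 17)
  jumps <- vapply(1:4000, function(i) {
    tr <- simulateTrajectory(net, s, trajIndex = i)
    expect_length(tr$jumpTimes, 1L)   # exactly one 0 -> 1 flip, then absorbed
    tr$jumpTimes[1]
  }, numeric(1))
  expect_lt(abs(mean(jumps) - 1), 3 / sqrt(4000))  # Exp(1): mean 1, sd 1
})

test_that("zero-propensity states are held as fixed points", {
  tg <- makeToy("toggle_switch")
  tr <- simulateTrajectory(tg, simulationSettings(
    initial = fixedInitialState(c(A = 1, B = 0)), seed = 5))
  expect_length(tr$jumpTimes, 0L)
  expect_true(tr$fixedPoint)
})

test_that("invalid rates fail with the node and state named", {
  net <- buildNetwork(list(nodeDefinition("A", rateUp = "$k / 0", rateDown = "1")),
                      params = c(k = 1))
  expect_error(
    runEnsemble(net, simulationSettings(sampleCount = 5, seed = 1)),
    "division by zero")
  neg <- buildNetwork(list(nodeDefinition("A", rateUp = "0 - $k", rateDown = "1")),
                      params = c(k = 2))
  expect_error(
    runEnsemble(neg, simulationSettings(sampleCount = 5, seed = 1)),
    "node 'A'")
})

test_that("the ensemble recovers the two-state CTMC closed form", {
  net <- makeToy("single_node", kUp = 2, kDown = 1)
  res <- runEnsemble(net, simulationSettings(
    initial = fixedInitialState(c(S = 0)), sampleCount = 10000, seed = 2))
  pOn <- finalWindowDistribution(res)[["S"]]
  expect_lt(abs(pOn - 2 / 3), 0.02)
  ## node marginal agrees with the projected-state table exactly
  expect_equal(nodeProbabilities(res)[, "S"],
               unname(stateProbabilities(res)[, "S"]))
})

test_that("exact transient solver matches closed forms and the initial condition", {
  net <- makeToy("single_node", kUp = 2, kDown = 1)
  et <- exactTransient(net, fixedInitialState(c(S = 0)), times = c(0, 10))
  expect_equal(unname(et[1, ]), c(1, 0))              # t = 0: the initial law
  expect_equal(unname(et[2, "1"]), 2 / 3, tolerance = 1e-6)

  ## repressilator: no state has zero propensity, so no absorbing mass
  rep3 <- makeToy("repressilator", m = 3)
  expect_equal(nrow(fixedPointsExhaustive(rep3)), 0L)
  et3 <- exactTransient(rep3, initialStateDistribution(), times = 25)
  expect_equal(sum(et3), 1, tolerance = 1e-8)
  props <- sapply(rownames(t(et3)), function(s) {
    st <- stats::setNames(as.integer(strsplit(s, "")[[1]]), nodeNames(rep3))
    sum(nodePropensities(rep3, st))
  })
  expect_true(all(props > 0))
})

test_that("probability tables satisfy their exact identities", {
  nk <- makeNKNetwork(5, 2, seed = 9)
  res <- runEnsemble(nk, simulationSettings(sampleCount = 3000, seed = 4))
  expect_equal(unname(rowSums(stateProbabilities(res))),
               rep(1, 100), tolerance = 1e-9)
  expect_equal(sum(lastStateDistribution(res)), 1, tolerance = 1e-12)
  ## node marginal = sum of probabilities of states where the node is active
  sp <- stateProbabilities(res)
  for (nd in nodeNames(nk)) {
    active <- vapply(colnames(sp), function(l)
      nd %in% strsplit(l, " -- ", fixed = TRUE)[[1]], logical(1))
    expect_equal(unname(rowSums(sp[, active, drop = FALSE])),
                 unname(nodeProbabilities(res)[, nd]), tolerance = 1e-12)
  }
  ## fixed points reached by trajectories are confirmed by exhaustive search
  fp <- fixedPointTable(res)
  if (nrow(fp)) {
    exh <- apply(fixedPointsExhaustive(nk), 1, paste, collapse = "")
    expect_true(all(fp$state %in% exh))
  }
  expect_lte(sum(fp$share), 1)
})

test_that("results are bit-identical under a fixed seed and trajectories replay ensemble members", {
  nk <- makeNKNetwork(6, 2, seed = 2)
  s <- simulationSettings(sampleCount = 500, seed = 33)
  r1 <- runEnsemble(nk, s)
  r2 <- runEnsemble(nk, s)
  expect_identical(stateProbabilities(r1), stateProbabilities(r2))
  expect_identical(lastStateDistribution(r1), lastStateDistribution(r2))
  expect_identical(fixedPointTable(r1), fixedPointTable(r2))

  ## last-state distribution is reproduced by replaying per-trajectory streams
  finals <- vapply(1:500, function(i)
    projectState(simulateTrajectory(nk, s, trajIndex = i)$finalState,
                 outputNodes(nk)), character(1))
  replayed <- table(finals) / 500
  ls <- lastStateDistribution(r1)
  expect_equal(sort(names(ls)), sort(names(replayed)))
  expect_equal(unname(ls[sort(names(ls))]),
               unname(as.numeric(replayed[sort(names(ls))])))
})

test_that("simulated final-window distributions match the matrix-exponential oracle", {
  ## moderate-size spot check; the 5-network study-scale comparison lives in
  ## the acceptance suite
  nk <- makeNKNetwork(4, 2, seed = 7)
  res <- runEnsemble(nk, simulationSettings(sampleCount = 10000, seed = 8))
  ex <- exactTransient(nk, initialStateDistribution(),
                       times = windowMidpoints(res)[100])
  pe <- projectDistribution(ex[1, ], nodeNames(nk), outputNodes(nk))
  expect_lt(tvDistance(pe, finalWindowDistribution(res)), 0.02)
})
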