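test_that("a maxLevel-2 variable yields stepwise level transitions and 3 admissible combinations", {
  ## v targets level 2 whenever input I is on, 0 otherwise; I constant
  model <- multiValuedModel(list(
    multiValuedVariable("I", maxLevel = 1, constant = TRUE),
    multiValuedVariable("v", maxLevel = 2,
      terms = list(list(condition = list(op = "cmp", cmp = "geq",
                                         var = "I", level = 1L),
                        resultLevel = 2L)),
      defaultLevel = 0L)))
  conv <- booleanize(model)
  expect_setequal(nodeNames(conv$network), c("I", "v_b1", "v_b2"))

  ## admissibility: (v_b1, v_b2) = (0,1) excluded -> 3 of 4 combinations
  adm <- admissibleStates(conv$map)
  vComb <- unique(adm[, c("v_b1", "v_b2")])
  expect_equal(nrow(vComb), 3L)
  expect_false(any(vComb[, 1] == 0 & vComb[, 2] == 1))

  ## from (I=1, v=0) the only enabled move is v_b1 up, then v_b2 up: 0->1->2
  stg <- stateTransitionGraph(conv$network, adm)
  nm <- nodeNames(conv$network)
  lab <- function(I, v1, v2) paste(c(I, v1, v2)[match(nm, c("I", "v_b1", "v_b2"))],
                                   collapse = "")
  from0 <- stg[stg$from == lab(1, 0, 0), ]
  expect_equal(from0$node, "v_b1")
  expect_equal(from0$to, lab(1, 1, 0))
  from1 <- stg[stg$from == lab(1, 1, 0), ]
  expect_equal(from1$node, "v_b2")
  expect_equal(from1$to, lab(1, 1, 1))
})

test_that("all-Boolean models booleanize to an evaluation-identical network", {
  model <- readSBMLQual(sbmlQualBooleanDoc())
  conv <- booleanize(model)
  expect_equal(sort(nodeNames(conv$network)), sort(variableNames(model)))
  for (st in allAssignments(nodeNames(conv$network))) {
    lv <- projectToLevels(st, conv$map)
    for (v in variableNames(model)) {
      tgt <- targetLevel(model, v, lv)
      props <- nodePropensities(conv$network, st)
      ## component flips exactly when the Boolean target differs from state
      expect_equal(unname(props[v]) > 0, tgt != lv[[v]])
    }
  }
})

test_that("level projection counts components and rejects inadmissible states", {
  conv <- booleanize(makeToy("multivalued_toy"))
  map <- conv$map
  expect_equal(projectToLevels(c(I = 0, v_b1 = 1, v_b2 = 0), map)[["v"]], 1L)
  expect_equal(projectToLevels(c(I = 1, v_b1 = 1, v_b2 = 1), map)[["v"]], 2L)
  expect_error(projectToLevels(c(I = 0, v_b1 = 0, v_b2 = 1), map),
               "inadmissible")
})

test_that("the Booleanized STG restricted to admissible states is isomorphic to the multi-valued STG", {
  model <- makeToy("multivalued_toy")
  conv <- booleanize(model)
  adm <- admissibleStates(conv$map)

  ## project every admissible Boolean state to its level label
  levelLabel <- apply(adm, 1, function(st)
    paste(projectToLevels(st, conv$map)[variableNames(model)], collapse = ","))
  expect_false(anyDuplicated(levelLabel) > 0)  # projection is a bijection

  stg <- stateTransitionGraph(conv$network, adm)
  boolLab <- apply(adm, 1, paste, collapse = "")
  toLevel <- stats::setNames(levelLabel, boolLab)
  ## every reachable target of an admissible state is itself admissible
  expect_true(all(stg$to %in% boolLab))
  mapped <- data.frame(from = unname(toLevel[stg$from]),
                       to = unname(toLevel[stg$to]),
                       var = conv$map@table$variable[
                         match(stg$node, conv$map@table$component)])
  mv <- multiValuedTransitionGraph(model)
  expect_identical(edgeSet(mapped, labCol = "var"),
                   edgeSet(mv, labCol = "var"))
})

test_that("admissibility is invariant along simulated trajectories", {
  conv <- booleanize(makeToy("multivalued_toy"))
  init <- levelInitialDistribution(conv$map, c(I = 1, v = 0))
  s <- simulationSettings(initial = init, maxTime = 30, seed = 13)
  for (i in 1:25) {
    tr <- simulateTrajectory(conv$network, s, trajIndex = i)
    st <- tr$initialState
    expect_silent(projectToLevels(st, conv$map))
    for (nd in tr$flippedNode) {
      st[nd] <- 1L - st[nd]
      expect_silent(projectToLevels(st, conv$map))
    }
  }
})
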