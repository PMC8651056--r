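test_that("buildNetwork validates references and names", {
  net <- buildNetwork(list(nodeDefinition("A", logic = "!B"),
                           nodeDefinition("B", logic = "!A")))
  expect_s4_class(net, "BooleanNetwork")
  expect_equal(nodeNames(net), c("A", "B"))

  expect_error(buildNetwork(list(nodeDefinition("A", logic = "C"))),
               "undeclared node\\(s\\): C")
  expect_error(buildNetwork(list()), "non-empty")
  expect_error(buildNetwork(list(nodeDefinition("A", logic = "1"),
                                 nodeDefinition("A", logic = "0"))),
               "duplicate")
})

test_that("default rates implement the logic embedding with tunable constants", {
  net <- buildNetwork(list(nodeDefinition("A", logic = "B"),
                           nodeDefinition("B", logic = "B")))
  net1 <- defaultRatesFromLogic(net)
  expect_equal(unname(nodePropensities(net1, c(A = 0, B = 1))["A"]), 1)  # up
  expect_equal(unname(nodePropensities(net1, c(A = 1, B = 0))["A"]), 1)  # down
  expect_equal(unname(nodePropensities(net1, c(A = 1, B = 1))["A"]), 0)  # hold
  net2 <- defaultRatesFromLogic(net, kUp = 2, kDown = 5)
  expect_equal(unname(nodePropensities(net2, c(A = 0, B = 1))["A"]), 2)
  expect_equal(unname(nodePropensities(net2, c(A = 1, B = 0))["A"]), 5)
})

test_that("mutations clamp nodes and validate their specs", {
  tg <- makeToy("toggle_switch")
  ko <- applyMutation(tg, mutationSpec("A", "OFF"))
  ## A can never rise and is forced to 0 initially
  traj <- simulateTrajectory(ko, simulationSettings(maxTime = 20, seed = 11))
  expect_equal(unname(traj$initialState["A"]), 0L)
  expect_false("A" %in% traj$flippedNode)
  ki <- applyMutation(tg, mutationSpec("A", "ON"))
  traj2 <- simulateTrajectory(ki, simulationSettings(maxTime = 20, seed = 11))
  expect_equal(unname(traj2$initialState["A"]), 1L)
  expect_false("A" %in% traj2$flippedNode)
  ## original untouched
  expect_equal(unname(nodePropensities(tg, c(A = 0, B = 0))["A"]), 1)

  expect_error(mutationSpec(c("A", "A"), c("OFF", "ON")), "twice")
  expect_error(applyMutation(tg, mutationSpec("Z", "OFF")), "unknown node")
  ## idempotent per node-direction pair
  ko2 <- applyMutation(ko, mutationSpec("A", "OFF"))
  expect_equal(nodePropensities(ko2, c(A = 0, B = 0)),
               nodePropensities(ko, c(A = 0, B = 0)))
})

test_that("interaction graph reflects syntactic dependencies", {
  tg <- makeToy("toggle_switch")
  g <- interactionGraph(tg)
  expect_setequal(paste(g$from, g$to), c("B A", "A B"))

  const <- defaultRatesFromLogic(buildNetwork(list(
    nodeDefinition("A", logic = "1"), nodeDefinition("B", logic = "A | !A"))))
  g2 <- interactionGraph(const)
  expect_false("A" %in% g2$to)              # constant: no incoming edges
  expect_true(any(g2$from == "A" & g2$to == "B"))  # vacuous reference counts

  ## graph from rates of the logic embedding equals graph from logic alone
  raw <- buildNetwork(list(nodeDefinition("A", logic = "!B"),
                           nodeDefinition("B", logic = "!A")))
  expect_equal(interactionGraph(defaultRatesFromLogic(raw)),
               interactionGraph(raw))
})

test_that("state projection produces canonical labels", {
  expect_equal(projectState(c(A = 1, B = 0, C = 1), c("A", "C")), "A -- C")
  expect_equal(projectState(c(A = 0, B = 1, C = 0), c("A", "C")), "<nil>")
  expect_equal(projectState(c(A = 1, B = 0), "B"), "<nil>")
  expect_error(projectState(c(A = 1), c("A", "C")), "lacks output")
})

test_that("initial-state distributions validate and sample atomically", {
  expect_error(initialStateDistribution(list(list(
    nodes = c("A", "B"), probs = c(0.5, 0.4),
    assignments = rbind(c(1, 1), c(0, 0))))), "summing|sum")
  expect_error(initialStateDistribution(list(
    list(nodes = "A", probs = 1, assignments = matrix(1)),
    list(nodes = c("A", "B"), probs = 1, assignments = matrix(c(1, 1), 1)))),
    "more than one block")

  dist <- initialStateDistribution(list(list(
    nodes = c("A", "B"), probs = c(0.5, 0.5),
    assignments = rbind(c(1, 1), c(0, 0)))))
  set.seed(99)
  draws <- sampleInitialState(dist, c("A", "B", "C"), n = 4000)
  ## joint block is atomic: A and B always equal
  expect_true(all(draws[, "A"] == draws[, "B"]))
  expect_lt(abs(mean(draws[, "A"]) - 0.5), 3 * sqrt(0.25 / 4000))
  ## uncovered node ~ Bernoulli(0.5)
  expect_lt(abs(mean(draws[, "C"]) - 0.5), 3 * sqrt(0.25 / 4000))

  ## degenerate block is deterministic
  one <- sampleInitialState(fixedInitialState(c(A = 1, B = 0)), c("A", "B"), 50)
  expect_true(all(one[, "A"] == 1) && all(one[, "B"] == 0))
})
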