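## Simulation settings, the Gillespie ensemble driver, the exact
## matrix-exponential transient solver (small networks) and exhaustive
## fixed-point enumeration.

setClass("SimulationSettings",
  representation(initial = "InitialStateDistribution", outputs = "character",
                 sampleCount = "numeric", maxTime = "numeric",
                 timePoints = "numeric", seed = "numeric"))

setValidity("SimulationSettings", function(object) {
  msgs <- character(0)
  if (length(object@outputs) > 15)
    msgs <- c(msgs, "the number of outputs is limited to 15")
  if (object@timePoints > 100)
    msgs <- c(msgs, "the number of time points is limited to 100")
  if (object@timePoints < 1 || object@timePoints != round(object@timePoints))
    msgs <- c(msgs, "timePoints must be a positive integer")
  if (object@sampleCount < 1 || object@sampleCount != round(object@sampleCount))
    msgs <- c(msgs, "sampleCount must be a positive integer")
  if (!is.finite(object@maxTime) || object@maxTime <= 0)
    msgs <- c(msgs, "maxTime must be positive")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Simulation settings
#'
#' @param initial An [initialStateDistribution()] (default: every node
#'   Bernoulli(0.5)).
#' @param outputs Character vector of output nodes to project results onto
#'   (at most 15); if empty, the network's own output flags are used.
#' @param sampleCount Number of stochastic trajectories (default 10000).
#' @param maxTime Simulated time horizon in model time units (default 10).
#' @param timePoints Number of uniform time windows over `[0, maxTime]` for
#'   the probability trajectories (at most 100; default 100).
#' @param seed Master RNG seed; each trajectory uses a counter-based
#'   substream derived from it, so results are bit-reproducible and
#'   independent of execution order.
#' @return A `SimulationSettings` object.
#' @export
simulationSettings <- function(initial = initialStateDistribution(),
                               outputs = character(0),
                               sampleCount = 10000, maxTime = 10,
                               timePoints = 100, seed = 20250) {
  new("SimulationSettings", initial = initial, outputs = outputs,
      sampleCount = sampleCount, maxTime = maxTime, timePoints = timePoints,
      seed = seed)
}

setMethod("show", "SimulationSettings", function(object) {
  cat(sprintf(paste0("SimulationSettings: %d trajectories, maxTime = %g, ",
                     "%d windows, seed = %s\n"),
              as.integer(object@sampleCount), object@maxTime,
              as.integer(object@timePoints), format(object@seed)))
  if (length(object@outputs))
    cat("  outputs:", paste(object@outputs, collapse = ", "), "\n")
})

setClass("SimulationResult",
  representation(windowEdges = "numeric", stateProbs = "matrix",
                 nodeProbs = "matrix", lastState = "numeric",
                 fixedPoints = "data.frame", outputs = "character",
                 settings = "SimulationSettings", provenance = "character"))

setMethod("show", "SimulationResult", function(object) {
  W <- length(object@windowEdges) - 1L
  cat(sprintf("SimulationResult: %d windows over [0, %g], %d projected state(s)\n",
              W, max(object@windowEdges), ncol(object@stateProbs)))
  ls <- sort(object@lastState, decreasing = TRUE)
  cat("  last-state distribution:\n")
  for (i in seq_len(min(6L, length(ls))))
    cat(sprintf("    %-30s %.4f\n", names(ls)[i], ls[i]))
  if (length(ls) > 6L) cat("    ...\n")
  if (nrow(object@fixedPoints))
    cat(sprintf("  %d fixed point(s) reached (total share %.4f)\n",
                nrow(object@fixedPoints), sum(object@fixedPoints$share)))
})

#' @name result-accessors
#' @title Accessors for simulation results
#' @param x A `SimulationResult`.
#' @details
#' `stateProbabilities()` returns the windows-by-states matrix of projected
#' state probabilities (occupancy-time averages per window); only states
#' actually observed appear as columns, absent states have probability 0.
#' `nodeProbabilities()` returns the windows-by-nodes marginal matrix.
#' `lastStateDistribution()` is the named frequency vector of projected
#' states at `maxTime`. `fixedPointTable()` lists the fixed points reached by
#' trajectories with their full-state bit-vector and share.
#' `windowMidpoints()` / `windowEdges()` expose the time grid, and
#' `finalWindowDistribution()` the last window's projected distribution.
NULL

#' @rdname result-accessors
#' @export
stateProbabilities <- function(x) x@stateProbs

#' @rdname result-accessors
#' @export
nodeProbabilities <- function(x) x@nodeProbs

#' @rdname result-accessors
#' @export
lastStateDistribution <- function(x) x@lastState

#' @rdname result-accessors
#' @export
fixedPointTable <- function(x) x@fixedPoints

#' @rdname result-accessors
#' @export
windowEdges <- function(x) x@windowEdges

#' @rdname result-accessors
#' @export
windowMidpoints <- function(x) {
  e <- x@windowEdges
  (e[-1] + e[-length(e)]) / 2
}

#' @rdname result-accessors
#' @export
finalWindowDistribution <- function(x) {
  p <- x@stateProbs[nrow(x@stateProbs), ]
  stats::setNames(as.numeric(p), colnames(x@stateProbs))
}

## ---- bytecode compiler ------------------------------------------------------

.compileAst <- function(ast, nodeIdx, params) {
  ops <- integer(0); args <- integer(0); consts <- numeric(0)
  pushOp <- function(op, arg = 0L) {
    ops[[length(ops) + 1L]] <<- op
    args[[length(args) + 1L]] <<- arg
  }
  emitConst <- function(v) {
    consts[[length(consts) + 1L]] <<- v
    pushOp(1L, length(consts) - 1L)
  }
  emit <- function(a) {
    switch(a$op,
      const = emitConst(a$value),
      param = {
        if (is.na(match(a$name, names(params))))
          stop(sprintf("undefined parameter '$%s'", a$name), call. = FALSE)
        emitConst(params[[a$name]])
      },
      node = {
        i <- nodeIdx[[a$name]]
        if (is.null(i))
          stop(sprintf("undeclared node '%s'", a$name), call. = FALSE)
        pushOp(2L, i - 1L)
      },
      not = { emit(a$x); pushOp(3L) },
      neg = { emit(a$x); pushOp(4L) },
      and = { emit(a$lhs); emit(a$rhs); pushOp(5L) },
      or  = { emit(a$lhs); emit(a$rhs); pushOp(6L) },
      xor = { emit(a$lhs); emit(a$rhs); pushOp(7L) },
      add = { emit(a$lhs); emit(a$rhs); pushOp(8L) },
      sub = { emit(a$lhs); emit(a$rhs); pushOp(9L) },
      mul = { emit(a$lhs); emit(a$rhs); pushOp(10L) },
      div = { emit(a$lhs); emit(a$rhs); pushOp(11L) },
      ifelse = { emit(a$cond); emit(a$yes); emit(a$no); pushOp(12L) },
      stop(sprintf("unknown AST operator '%s'", a$op), call. = FALSE))
  }
  emit(ast)
  list(ops = ops, args = args, consts = consts)
}

.compileNetwork <- function(network) {
  nms <- nodeNames(network)
  nodeIdx <- stats::setNames(as.list(seq_along(nms)), nms)
  up <- lapply(network@nodes, function(nd)
    .compileAst(nd$rateUp, nodeIdx, network@params))
  down <- lapply(network@nodes, function(nd)
    .compileAst(nd$rateDown, nodeIdx, network@params))
  list(upOps = lapply(up, `[[`, "ops"), upArgs = lapply(up, `[[`, "args"),
       upConsts = lapply(up, `[[`, "consts"),
       downOps = lapply(down, `[[`, "ops"),
       downArgs = lapply(down, `[[`, "args"),
       downConsts = lapply(down, `[[`, "consts"),
       nodeNames = nms)
}

.distributionBlocks <- function(dist, nms) {
  unknown <- setdiff(unlist(lapply(dist@blocks, `[[`, "nodes")), nms)
  if (length(unknown))
    stop("initial-state distribution covers unknown node(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  list(nodes = lapply(dist@blocks, function(b) match(b$nodes, nms) - 1L),
       probs = lapply(dist@blocks, `[[`, "probs"),
       assign = lapply(dist@blocks, `[[`, "assignments"))
}

.forcedValues <- function(network) {
  idx <- integer(0); val <- integer(0)
  for (i in seq_along(network@nodes)) {
    fv <- network@nodes[[i]]$forcedValue
    if (!is.null(fv)) { idx <- c(idx, i - 1L); val <- c(val, as.integer(fv)) }
  }
  list(idx = idx, val = val)
}

.resolveOutputs <- function(network, settings) {
  out <- if (length(settings@outputs)) settings@outputs else outputNodes(network)
  unknown <- setdiff(out, nodeNames(network))
  if (length(unknown))
    stop("unknown output node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(out) == 0L)
    stop("the output set must be non-empty", call. = FALSE)
  if (length(out) > 15)
    stop("the number of outputs is limited to 15 (got ", length(out), ")",
         call. = FALSE)
  ## keep declaration order
  nodeNames(network)[sort(match(out, nodeNames(network)))]
}

.keyToLabel <- function(keys, outputs) {
  vapply(keys, function(k) {
    active <- outputs[bitwAnd(bitwShiftR(k, seq_along(outputs) - 1L), 1L) == 1L]
    if (length(active) == 0L) "<nil>" else paste(active, collapse = " -- ")
  }, character(1))
}

## ---- simulation -------------------------------------------------------------

#' Run a stochastic simulation ensemble
#'
#' Simulates `sampleCount` trajectories of the continuous-time Markov chain
#' defined by the network's rate expressions (Gillespie algorithm: at each
#' step the flip propensity of node i is `rateUp_i` if the node is 0 and
#' `rateDown_i` if it is 1; the waiting time is exponential with the total
#' propensity and the flipped node is chosen proportionally). States with
#' zero total propensity are fixed points and are held until `maxTime`.
#'
#' Probabilities per time window are occupancy-time averages: the probability
#' of projected state s in window w is the mean over trajectories of the
#' fraction of w spent in s.
#'
#' @param network A `BooleanNetwork`.
#' @param settings A [simulationSettings()] object.
#' @return A `SimulationResult` (see [stateProbabilities()] and friends).
#' @examples
#' net <- makeToy("single_node", kUp = 2, kDown = 1)
#' res <- runEnsemble(net, simulationSettings(
#'   initial = fixedInitialState(c(S = 0)), sampleCount = 2000, seed = 1))
#' finalWindowDistribution(res)   # ~ 1/3 "<nil>", ~ 2/3 "S"
#' @export
runEnsemble <- function(network, settings = simulationSettings()) {
  stopifnot(is(network, "BooleanNetwork"), is(settings, "SimulationSettings"))
  validObject(network); validObject(settings); validObject(settings@initial)
  outputs <- .resolveOutputs(network, settings)
  prog <- .compileNetwork(network)
  blocks <- .distributionBlocks(settings@initial, prog$nodeNames)
  forced <- .forcedValues(network)
  raw <- .ensembleCpp(prog$upOps, prog$upArgs, prog$upConsts,
                      prog$downOps, prog$downArgs, prog$downConsts,
                      prog$nodeNames,
                      blocks$nodes, blocks$probs, blocks$assign,
                      settings@initial@defaultProb,
                      forced$idx, forced$val,
                      match(outputs, prog$nodeNames) - 1L,
                      as.integer(settings@sampleCount), settings@maxTime,
                      as.integer(settings@timePoints), settings@seed)
  W <- as.integer(settings@timePoints)
  edges <- seq(0, settings@maxTime, length.out = W + 1L)

  ord <- order(raw$stateKeys)
  stateProbs <- raw$stateProbs[, ord, drop = FALSE]
  colnames(stateProbs) <- .keyToLabel(raw$stateKeys[ord], outputs)
  nodeProbs <- raw$nodeProbs
  colnames(nodeProbs) <- prog$nodeNames
  ordL <- order(raw$lastKeys)
  lastState <- stats::setNames(raw$lastFreq[ordL],
                               .keyToLabel(raw$lastKeys[ordL], outputs))
  ordF <- order(raw$fixedStates)
  fp <- data.frame(state = raw$fixedStates[ordF],
                   share = raw$fixedShare[ordF], stringsAsFactors = FALSE)
  fp$label <- vapply(fp$state, function(s) {
    bits <- as.integer(strsplit(s, "")[[1]])
    projectState(stats::setNames(bits, prog$nodeNames), outputs)
  }, character(1))
  fp <- fp[, c("label", "state", "share")]
  rownames(fp) <- NULL
  new("SimulationResult", windowEdges = edges, stateProbs = stateProbs,
      nodeProbs = nodeProbs, lastState = lastState, fixedPoints = fp,
      outputs = outputs, settings = settings, provenance = network@provenance)
}

#' Simulate a single trajectory
#'
#' Runs one Gillespie trajectory and records its jump chain. With the same
#' settings, trajectory `trajIndex` is exactly the corresponding member of
#' the [runEnsemble()] ensemble (identical RNG substream).
#'
#' @param network A `BooleanNetwork`.
#' @param settings A [simulationSettings()].
#' @param trajIndex 1-based trajectory index selecting the RNG substream.
#' @return A list with `initialState` (named 0/1 vector), `jumpTimes`
#'   (strictly increasing, all `< maxTime`), `flippedNode` (names, parallel
#'   to `jumpTimes`), `finalState` and `fixedPoint` (whether the trajectory
#'   ended in a zero-propensity state).
#' @export
simulateTrajectory <- function(network, settings = simulationSettings(),
                               trajIndex = 1L) {
  stopifnot(is(network, "BooleanNetwork"), is(settings, "SimulationSettings"))
  validObject(network); validObject(settings)
  prog <- .compileNetwork(network)
  blocks <- .distributionBlocks(settings@initial, prog$nodeNames)
  forced <- .forcedValues(network)
  raw <- .trajectoryCpp(prog$upOps, prog$upArgs, prog$upConsts,
                        prog$downOps, prog$downArgs, prog$downConsts,
                        prog$nodeNames,
                        blocks$nodes, blocks$probs, blocks$assign,
                        settings@initial@defaultProb,
                        forced$idx, forced$val,
                        settings@maxTime, settings@seed, as.integer(trajIndex))
  list(initialState = stats::setNames(raw$initialState, prog$nodeNames),
       jumpTimes = raw$jumpTimes,
       flippedNode = prog$nodeNames[raw$flippedNode],
       finalState = stats::setNames(raw$finalState, prog$nodeNames),
       fixedPoint = raw$fixedPoint)
}

## ---- exact transient oracle -------------------------------------------------

.initialProbabilityVector <- function(dist, nms) {
  n <- length(nms)
  states <- .allStates(n)
  p <- rep(1, nrow(states))
  covered <- character(0)
  for (b in dist@blocks) {
    cols <- match(b$nodes, nms)
    atomProb <- rep(0, nrow(states))
    for (k in seq_along(b$probs)) {
      hit <- rowSums(states[, cols, drop = FALSE] ==
                     matrix(b$assignments[k, ], nrow(states), length(cols),
                            byrow = TRUE)) == length(cols)
      atomProb[hit] <- atomProb[hit] + b$probs[k]
    }
    p <- p * atomProb
    covered <- c(covered, b$nodes)
  }
  for (j in which(!(nms %in% covered))) {
    p <- p * ifelse(states[, j] == 1, dist@defaultProb, 1 - dist@defaultProb)
  }
  p
}

.allStates <- function(n) {
  codes <- 0:(2^n - 1)
  m <- matrix(0L, length(codes), n)
  for (j in seq_len(n)) m[, j] <- bitwAnd(bitwShiftR(codes, j - 1L), 1L)
  m
}

#' Exact transient distribution of a small network
#'
#' Builds the full 2^n-state CTMC generator (off-diagonal entry from state S
#' to the state with node i flipped = the Gillespie propensity of i in S;
#' diagonal = minus the total propensity) and solves the transient
#' distribution at each requested time with the matrix exponential. This is
#' the exact counterpart of [runEnsemble()] for networks of up to 12 nodes
#' and is the package's independent oracle: it uses the pure-R expression
#' evaluator throughout.
#'
#' @param network A `BooleanNetwork` (at most 12 nodes).
#' @param initial An `InitialStateDistribution`.
#' @param times Numeric vector of times (>= 0).
#' @return A `length(times)` x 2^n matrix of probabilities; columns are named
#'   by full-state bit-vectors in node declaration order (e.g. `"10"` = first
#'   node on, second off).
#' @export
exactTransient <- function(network, initial = initialStateDistribution(),
                           times = c(0, 10)) {
  stopifnot(is(network, "BooleanNetwork"))
  validObject(network); validObject(initial)
  nms <- nodeNames(network)
  n <- length(nms)
  if (n > 12)
    stop("exactTransient is limited to 12 nodes (got ", n, ")", call. = FALSE)
  states <- .allStates(n)
  ns <- nrow(states)
  ## generator Q: rows = from-state
  triplets <- vector("list", ns)
  for (s in seq_len(ns)) {
    st <- stats::setNames(states[s, ], nms)
    props <- nodePropensities(network, st)
    to <- s + ifelse(states[s, ] == 0, 1L, -1L) * 2L^(seq_len(n) - 1L)
    keep <- props > 0
    triplets[[s]] <- cbind(from = rep(s, sum(keep) + 1L),
                           to = c(to[keep], s),
                           rate = c(props[keep], -sum(props)))
  }
  trip <- do.call(rbind, triplets)
  Q <- Matrix::sparseMatrix(i = trip[, "from"], j = trip[, "to"],
                            x = trip[, "rate"], dims = c(ns, ns))
  p0 <- .initialProbabilityVector(initial, nms)
  labels <- apply(states, 1, paste, collapse = "")
  out <- matrix(NA_real_, length(times), ns,
                dimnames = list(format(times, trim = TRUE), labels))
  for (k in seq_along(times)) {
    out[k, ] <- if (times[k] == 0) p0
                else as.numeric(p0 %*% Matrix::expm(Q * times[k]))
  }
  out
}

#' Project a full-state distribution onto output labels
#'
#' Aggregates a probability vector over full-state bit-vectors (as returned
#' by [exactTransient()]) into the projected-state labels used by
#' [runEnsemble()].
#'
#' @param p Named probability vector; names are full-state bit-vectors in
#'   node declaration order.
#' @param nodes All node names, declaration order.
#' @param outputs Output subset.
#' @return Named probability vector over projected-state labels.
#' @export
projectDistribution <- function(p, nodes, outputs) {
  labels <- vapply(names(p), function(s) {
    bits <- as.integer(strsplit(s, "")[[1]])
    projectState(stats::setNames(bits, nodes), outputs)
  }, character(1))
  out <- tapply(as.numeric(p), labels, sum)
  stats::setNames(as.numeric(out), names(out))
}

## ---- fixed points -----------------------------------------------------------

#' Exhaustive fixed-point enumeration
#'
#' Enumerates all 2^n full states (n <= 20, with early pruning at the first
#' positive propensity) and returns exactly those with zero total flip
#' propensity — the stable states of the continuous-time semantics.
#'
#' @param network A `BooleanNetwork` with at most 20 nodes.
#' @return An integer matrix, one row per fixed point, columns named by node.
#' @examples
#' fixedPointsExhaustive(makeToy("toggle_switch"))
#' @export
fixedPointsExhaustive <- function(network) {
  stopifnot(is(network, "BooleanNetwork"))
  validObject(network)
  if (length(network@nodes) > 20)
    stop("exhaustive fixed-point search is limited to 20 nodes (got ",
         length(network@nodes), ")", call. = FALSE)
  prog <- .compileNetwork(network)
  m <- .fixedPointsCpp(prog$upOps, prog$upArgs, prog$upConsts,
                       prog$downOps, prog$downArgs, prog$downConsts,
                       prog$nodeNames)
  colnames(m) <- prog$nodeNames
  m
}

#' Asynchronous state-transition graph of a network
#'
#' Lists every single-node flip with positive propensity between full states;
#' mainly a verification utility for small networks.
#'
#' @param network A `BooleanNetwork` (at most 12 nodes).
#' @param states Optional integer matrix of states to restrict to (columns =
#'   nodes in declaration order); defaults to all 2^n.
#' @return A `data.frame` with columns `from`, `to` (full-state bit-vector
#'   strings) and `node` (the flipped node).
#' @export
stateTransitionGraph <- function(network, states = NULL) {
  stopifnot(is(network, "BooleanNetwork"))
  nms <- nodeNames(network)
  n <- length(nms)
  if (is.null(states)) {
    if (n > 12) stop("full STG is limited to 12 nodes", call. = FALSE)
    states <- .allStates(n)
  }
  prog <- .compileNetwork(network)
  props <- .propensitiesCpp(prog$upOps, prog$upArgs, prog$upConsts,
                            prog$downOps, prog$downArgs, prog$downConsts,
                            prog$nodeNames, states)
  lab <- apply(states, 1, paste, collapse = "")
  rows <- list()
  for (s in seq_len(nrow(states))) {
    for (i in which(props[s, ] > 0)) {
      to <- states[s, ]
      to[i] <- 1L - to[i]
      rows[[length(rows) + 1L]] <- data.frame(
        from = lab[s], to = paste(to, collapse = ""), node = nms[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      node = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
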