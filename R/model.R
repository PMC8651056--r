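## Core model containers: BooleanNetwork, MutationSpec, InitialStateDistribution.
##
## A node definition is a plain list with fields
##   name     identifier, unique within the network
##   logic    boolean-context AST or NULL (nodes may be defined by rates alone)
##   rateUp   rate-context AST: propensity to switch 0 -> 1
##   rateDown rate-context AST: propensity to switch 1 -> 0
##   isOutput logical flag (is_internal is its complement)
## Node order is declaration order and is used everywhere (state encoding,
## projected-state labels), so results are reproducible across formats.

#' @import methods
NULL

setClass("BooleanNetwork",
  representation(nodes = "list", params = "numeric", provenance = "character"))

setValidity("BooleanNetwork", function(object) {
  msgs <- character(0)
  if (length(object@nodes) == 0L) return("network must contain at least one node")
  nms <- vapply(object@nodes, function(n) n$name %||% NA_character_, character(1))
  if (anyNA(nms)) msgs <- c(msgs, "every node needs a name")
  dup <- unique(nms[duplicated(nms)])
  if (length(dup))
    msgs <- c(msgs, paste0("duplicate node name(s): ", paste(dup, collapse = ", ")))
  for (nd in object@nodes) {
    if (is.null(nd$rateUp) || is.null(nd$rateDown))
      msgs <- c(msgs, paste0("node '", nd$name,
                             "' lacks rate expressions (and no logic to derive them from)"))
    refs <- unique(unlist(lapply(
      Filter(Negate(is.null), nd[c("logic", "rateUp", "rateDown")]), freeVariables)))
    undecl <- setdiff(refs, nms)
    if (length(undecl))
      msgs <- c(msgs, paste0("node '", nd$name, "' references undeclared node(s): ",
                             paste(undecl, collapse = ", ")))
    ## parameter values may arrive separately (e.g. from a settings file), so
    ## undefined parameters are only an error at evaluation/compile time
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

.freeParams <- function(ast) {
  acc <- character(0)
  walk <- function(a) {
    if (a$op == "param") acc <<- c(acc, a$name)
    else for (nm in setdiff(names(a), c("op", "name", "value"))) walk(a[[nm]])
  }
  walk(ast)
  unique(acc)
}

.asAst <- function(x, context) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) parseExpression(x, context) else x
}

#' Define a network node
#'
#' @param name Node identifier.
#' @param logic Boolean update rule (string or AST), or `NULL` if `rateUp` /
#'   `rateDown` are given directly.
#' @param rateUp,rateDown Rate expressions (string or AST); if `NULL` and
#'   `logic` is present they are derived later by [defaultRatesFromLogic()]
#'   or at [buildNetwork()] time.
#' @param isOutput Whether the node is an output (projected into result
#'   labels); internal nodes are the complement.
#' @return A node-definition list.
#' @export
nodeDefinition <- function(name, logic = NULL, rateUp = NULL, rateDown = NULL,
                           isOutput = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  list(name = name,
       logic = .asAst(logic, "boolean"),
       rateUp = .asAst(rateUp, "rate"),
       rateDown = .asAst(rateDown, "rate"),
       isOutput = isTRUE(isOutput))
}

#' Build a validated Boolean network
#'
#' Assembles node definitions into a `BooleanNetwork`. Nodes that carry logic
#' but no rates get default rates `logic ? 1 : 0` / `logic ? 0 : 1` (see
#' [defaultRatesFromLogic()]). All undeclared references and duplicate names
#' are reported together.
#'
#' @param nodes List of [nodeDefinition()] lists.
#' @param params Named numeric vector of `$parameter` values.
#' @param provenance Free-text origin note (source format or file).
#' @return A `BooleanNetwork`.
#' @examples
#' net <- buildNetwork(list(
#'   nodeDefinition("A", logic = "!B"),
#'   nodeDefinition("B", logic = "!A")))
#' nodeNames(net)
#' @export
buildNetwork <- function(nodes, params = numeric(0), provenance = "constructed") {
  if (!is.list(nodes) || length(nodes) == 0L)
    stop("'nodes' must be a non-empty list of node definitions", call. = FALSE)
  params <- unlist(params) %||% numeric(0)
  if (length(params) && is.null(names(params)))
    stop("'params' must be named", call. = FALSE)
  nodes <- lapply(nodes, function(nd) {
    if (!is.null(nd$logic) && (is.null(nd$rateUp) || is.null(nd$rateDown))) {
      if (is.null(nd$rateUp))
        nd$rateUp <- list(op = "ifelse", cond = nd$logic,
                          yes = list(op = "const", value = 1),
                          no = list(op = "const", value = 0))
      if (is.null(nd$rateDown))
        nd$rateDown <- list(op = "ifelse", cond = nd$logic,
                            yes = list(op = "const", value = 0),
                            no = list(op = "const", value = 1))
    }
    nd
  })
  new("BooleanNetwork", nodes = nodes, params = params, provenance = provenance)
}

#' @describeIn buildNetwork Node names in declaration order.
#' @param x,object A `BooleanNetwork`.
#' @export
nodeNames <- function(x) vapply(x@nodes, `[[`, character(1), "name")

#' Network parameters
#' @param x A `BooleanNetwork`.
#' @return Named numeric vector.
#' @export
networkParameters <- function(x) x@params

#' Output nodes of a network
#' @param x A `BooleanNetwork`.
#' @return Character vector of output-node names, in declaration order.
#' @export
outputNodes <- function(x) nodeNames(x)[vapply(x@nodes, `[[`, logical(1), "isOutput")]

#' Set the output nodes of a network
#' @param x A `BooleanNetwork`.
#' @param value Character vector of node names to flag as outputs; all other
#'   nodes become internal.
#' @export
`outputNodes<-` <- function(x, value) {
  unknown <- setdiff(value, nodeNames(x))
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  x@nodes <- lapply(x@nodes, function(nd) {
    nd$isOutput <- nd$name %in% value
    nd
  })
  x
}

setMethod("show", "BooleanNetwork", function(object) {
  cat(sprintf("BooleanNetwork with %d node(s) [%s]\n",
              length(object@nodes), object@provenance))
  for (nd in object@nodes) {
    cat(sprintf("  %s%s: ", nd$name, if (nd$isOutput) "" else " (internal)"))
    if (!is.null(nd$logic)) cat(serializeExpression(nd$logic))
    else cat(sprintf("up = %s, down = %s",
                     serializeExpression(nd$rateUp),
                     serializeExpression(nd$rateDown)))
    cat("\n")
  }
  if (length(object@params))
    cat("  params:", paste0("$", names(object@params), " = ", object@params,
                            collapse = ", "), "\n")
})

#' Derive transition rates from logic
#'
#' For every node with an update rule, sets
#' `rateUp = logic ? kUp : 0` and `rateDown = logic ? 0 : kDown`; this is the
#' standard embedding of a pure-logic (e.g. BoolNet) model into the
#' continuous-time semantics, with a single time scale unless `kUp`/`kDown`
#' are changed.
#'
#' @param network A `BooleanNetwork` in which every node has logic.
#' @param kUp,kDown Activation / inactivation rate constants (default 1).
#' @return A new `BooleanNetwork` with rates filled in.
#' @export
defaultRatesFromLogic <- function(network, kUp = 1, kDown = 1) {
  stopifnot(is(network, "BooleanNetwork"), kUp >= 0, kDown >= 0)
  network@nodes <- lapply(network@nodes, function(nd) {
    if (is.null(nd$logic))
      stop(sprintf("node '%s' has no logic to derive rates from", nd$name),
           call. = FALSE)
    nd$rateUp <- list(op = "ifelse", cond = nd$logic,
                      yes = list(op = "const", value = kUp),
                      no = list(op = "const", value = 0))
    nd$rateDown <- list(op = "ifelse", cond = nd$logic,
                        yes = list(op = "const", value = 0),
                        no = list(op = "const", value = kDown))
    nd
  })
  validObject(network)
  network
}

## ---- Mutations --------------------------------------------------------------

setClass("MutationSpec",
  representation(node = "character", direction = "character"))

setValidity("MutationSpec", function(object) {
  if (length(object@node) != length(object@direction))
    return("node and direction must have equal length")
  if (!all(object@direction %in% c("OFF", "ON")))
    return("directions must be 'OFF' or 'ON'")
  if (anyDuplicated(object@node))
    return(paste0("node(s) listed twice: ",
                  paste(unique(object@node[duplicated(object@node)]), collapse = ", ")))
  TRUE
})

#' Specify a mutation (knock-out / knock-in)
#'
#' `OFF` clamps a node to 0 (knock-out), `ON` clamps it to 1
#' (overexpression). A spec may combine several nodes (single or double
#' mutants in practice) but never the same node twice.
#'
#' @param node Character vector of node names.
#' @param direction Matching vector of `"OFF"` / `"ON"`.
#' @return A `MutationSpec`.
#' @examples
#' mutationSpec(c("SMAD2", "NFAT2A"), c("OFF", "ON"))
#' @export
mutationSpec <- function(node = character(0), direction = character(0)) {
  new("MutationSpec", node = as.character(node), direction = as.character(direction))
}

#' Human-readable mutant label, e.g. "SMAD2:OFF + NFAT2A:ON" ("WT" if empty)
#' @param spec A `MutationSpec`.
#' @export
mutationLabel <- function(spec) {
  if (length(spec@node) == 0L) return("WT")
  paste(paste0(spec@node, ":", spec@direction), collapse = " + ")
}

setMethod("show", "MutationSpec", function(object) {
  cat("MutationSpec:", mutationLabel(object), "\n")
})

#' Apply a mutation to a network
#'
#' Clamping semantics: for `OFF` the node's `rateUp` is replaced by the
#' constant 0 and `rateDown` by 1 (and the initial value is forced to 0 at
#' simulation time); for `ON` symmetrically. The node therefore never leaves
#' its forced value on any trajectory. The input network is unchanged.
#'
#' @param network A `BooleanNetwork`.
#' @param mutation A `MutationSpec`.
#' @return A mutated copy of the network.
#' @export
applyMutation <- function(network, mutation) {
  stopifnot(is(network, "BooleanNetwork"), is(mutation, "MutationSpec"))
  validObject(mutation)
  unknown <- setdiff(mutation@node, nodeNames(network))
  if (length(unknown))
    stop("unknown node(s) in mutation: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  zero <- list(op = "const", value = 0)
  one <- list(op = "const", value = 1)
  for (i in seq_along(mutation@node)) {
    j <- match(mutation@node[i], nodeNames(network))
    if (mutation@direction[i] == "OFF") {
      network@nodes[[j]]$rateUp <- zero
      network@nodes[[j]]$rateDown <- one
      network@nodes[[j]]$forcedValue <- 0L
    } else {
      network@nodes[[j]]$rateUp <- one
      network@nodes[[j]]$rateDown <- zero
      network@nodes[[j]]$forcedValue <- 1L
    }
  }
  network
}

## ---- Interaction graph ------------------------------------------------------

#' Regulator -> target interaction graph
#'
#' An edge regulator -> target exists when the regulator appears among the
#' free variables of the target's logic (or of its rate expressions, for
#' nodes defined by rates alone). Dependency is syntactic: a vacuous
#' reference such as `A | !A` still counts. Self-loops are allowed.
#'
#' @param network A `BooleanNetwork`.
#' @return A `data.frame` with character columns `from` and `to`, one row per
#'   directed edge, ordered by target declaration order.
#' @export
interactionGraph <- function(network) {
  stopifnot(is(network, "BooleanNetwork"))
  rows <- lapply(network@nodes, function(nd) {
    regs <- if (!is.null(nd$logic)) freeVariables(nd$logic)
            else unique(c(freeVariables(nd$rateUp), freeVariables(nd$rateDown)))
    if (length(regs)) data.frame(from = regs, to = nd$name,
                                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(from = character(0), to = character(0))
  rownames(out) <- NULL
  out
}

## ---- State projection -------------------------------------------------------

#' Project a full state onto the output nodes
#'
#' The canonical label is the names of the active output nodes in network
#' declaration order joined by `" -- "`; a projection with no active output
#' is labelled `"<nil>"`.
#'
#' @param state Named 0/1 vector over (at least) the output nodes.
#' @param outputs Character vector of output-node names, in declaration order.
#' @return The state label string.
#' @examples
#' projectState(c(A = 1, B = 0, C = 1), c("A", "C"))
#' @export
projectState <- function(state, outputs) {
  state <- unlist(state)
  missing <- setdiff(outputs, names(state))
  if (length(missing))
    stop("state lacks output node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  active <- outputs[state[outputs] != 0]
  if (length(active) == 0L) "<nil>" else paste(active, collapse = " -- ")
}

#' Per-node flip propensities in a given state
#'
#' For node i, the propensity is `rateUp_i(state)` when the node is 0 and
#' `rateDown_i(state)` when it is 1 — the Gillespie propensity vector.
#' This is the pure-R reference path, used by the exact transient solver.
#'
#' @param network A `BooleanNetwork`.
#' @param state Named 0/1 vector over all nodes.
#' @return Named numeric vector of propensities.
#' @export
nodePropensities <- function(network, state) {
  nms <- nodeNames(network)
  state <- unlist(state)[nms]
  vapply(seq_along(nms), function(i) {
    nd <- network@nodes[[i]]
    ast <- if (state[i] == 0) nd$rateUp else nd$rateDown
    evaluateExpression(ast, state, network@params, context = "rate")
  }, numeric(1)) |> stats::setNames(nms)
}

## ---- Initial-state distributions -------------------------------------------

setClass("InitialStateDistribution",
  representation(blocks = "list", defaultProb = "numeric"))

setValidity("InitialStateDistribution", function(object) {
  msgs <- character(0)
  if (length(object@defaultProb) != 1L || object@defaultProb < 0 ||
      object@defaultProb > 1)
    msgs <- c(msgs, "defaultProb must be a single probability")
  seen <- character(0)
  for (b in object@blocks) {
    if (!all(c("nodes", "probs", "assignments") %in% names(b))) {
      msgs <- c(msgs, "each block needs nodes, probs, assignments")
      next
    }
    if (any(b$nodes %in% seen))
      msgs <- c(msgs, paste0("node(s) covered by more than one block: ",
                             paste(intersect(b$nodes, seen), collapse = ", ")))
    seen <- c(seen, b$nodes)
    if (!is.matrix(b$assignments) || ncol(b$assignments) != length(b$nodes) ||
        nrow(b$assignments) != length(b$probs))
      msgs <- c(msgs, "assignment matrix shape must be (atoms x nodes)")
    if (any(b$probs < 0) || abs(sum(b$probs) - 1) > 1e-9)
      msgs <- c(msgs, paste0("block over (", paste(b$nodes, collapse = ","),
                             ") has probabilities not summing to 1"))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Initial-state distribution
#'
#' Joint blocks assign probabilities to joint 0/1 assignments over disjoint
#' node subsets (sampled atomically, so linked nodes stay linked); any node
#' not covered by a block starts at 1 with independent probability
#' `defaultProb` (0.5 = "random").
#'
#' @param blocks List of blocks, each a list with `nodes` (character vector),
#'   `probs` (numeric, sums to 1) and `assignments` (0/1 matrix, one row per
#'   atom, one column per node).
#' @param defaultProb Bernoulli probability for uncovered nodes.
#' @return An `InitialStateDistribution`.
#' @examples
#' ## A and B start together: both on or both off, 50/50
#' initialStateDistribution(list(list(
#'   nodes = c("A", "B"), probs = c(0.5, 0.5),
#'   assignments = rbind(c(1, 1), c(0, 0)))))
#' @export
initialStateDistribution <- function(blocks = list(), defaultProb = 0.5) {
  blocks <- lapply(blocks, function(b) {
    b$assignments <- matrix(as.integer(b$assignments),
                            nrow = length(b$probs), ncol = length(b$nodes))
    b$probs <- as.numeric(b$probs)
    b
  })
  new("InitialStateDistribution", blocks = blocks, defaultProb = defaultProb)
}

#' Convenience: a degenerate distribution fixing the given nodes
#'
#' @param values Named 0/1 vector; listed nodes start exactly there, others
#'   follow `defaultProb`.
#' @param defaultProb Bernoulli probability for the remaining nodes.
#' @return An `InitialStateDistribution`.
#' @export
fixedInitialState <- function(values, defaultProb = 0.5) {
  values <- unlist(values)
  if (length(values) == 0L) return(initialStateDistribution(defaultProb = defaultProb))
  initialStateDistribution(list(list(
    nodes = names(values), probs = 1,
    assignments = matrix(as.integer(values), nrow = 1))), defaultProb)
}

setMethod("show", "InitialStateDistribution", function(object) {
  cat(sprintf("InitialStateDistribution: %d joint block(s), default P(on) = %g\n",
              length(object@blocks), object@defaultProb))
  for (b in object@blocks)
    cat("  [", paste(b$nodes, collapse = ","), "]: ",
        paste(sprintf("%g [%s]", b$probs,
                      apply(b$assignments, 1, paste, collapse = ",")),
              collapse = ", "), "\n", sep = "")
})

#' Sample full initial states
#'
#' Draws complete 0/1 states: each joint block is sampled atomically from its
#' atom probabilities; uncovered nodes are independent Bernoulli draws. Uses
#' R's RNG (set a seed with [set.seed()] for reproducibility); the simulation
#' engine has its own per-trajectory streams and does not go through this
#' function.
#'
#' @param dist An `InitialStateDistribution`.
#' @param nodes Character vector of all node names (declaration order).
#' @param n Number of states to draw.
#' @return An `n` x `length(nodes)` integer matrix with column names.
#' @export
sampleInitialState <- function(dist, nodes, n = 1L) {
  validObject(dist)
  unknown <- setdiff(unlist(lapply(dist@blocks, `[[`, "nodes")), nodes)
  if (length(unknown))
    stop("distribution covers unknown node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- matrix(0L, nrow = n, ncol = length(nodes),
                dimnames = list(NULL, nodes))
  covered <- character(0)
  for (b in dist@blocks) {
    idx <- sample.int(length(b$probs), n, replace = TRUE, prob = b$probs)
    out[, b$nodes] <- b$assignments[idx, , drop = FALSE]
    covered <- c(covered, b$nodes)
  }
  free <- setdiff(nodes, covered)
  if (length(free))
    out[, free] <- matrix(as.integer(stats::runif(n * length(free)) < dist@defaultProb),
                          nrow = n)
  out
}
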