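## Conversion of multi-valued logical models into purely Boolean networks by
## level-component duplication: a variable v with maxLevel m becomes ordered
## components v_b1 .. v_bm, with level(v) = number of active components.
## Admissibility (v_bj active only if v_b(j-1) is) is preserved by the
## stepwise (+/-1 level) asynchronous semantics: component j can switch on
## only when component j-1 is on, and off only when component j+1 is off.

setClass("BooleanizationMap", representation(table = "data.frame"))

setValidity("BooleanizationMap", function(object) {
  need <- c("component", "variable", "level")
  if (!all(need %in% names(object@table)))
    return("map table needs columns component, variable, level")
  if (anyDuplicated(object@table$component))
    return("duplicate component names")
  TRUE
})

setMethod("show", "BooleanizationMap", function(object) {
  nv <- length(unique(object@table$variable))
  cat(sprintf("BooleanizationMap: %d component(s) for %d variable(s)\n",
              nrow(object@table), nv))
})

#' Components of a Booleanization map
#' @param map A `BooleanizationMap`.
#' @return A `data.frame` with columns `component`, `variable`, `level`.
#' @export
componentTable <- function(map) map@table

.componentName <- function(var, level, maxLevel) {
  if (maxLevel == 1) var else paste0(var, "_b", level)
}

## Translate "level(var) >= k" into a Boolean AST over components.
.geqAst <- function(var, k, maxLevel) {
  if (k <= 0) return(list(op = "const", value = 1))
  if (k > maxLevel) return(list(op = "const", value = 0))
  list(op = "node", name = .componentName(var, k, maxLevel))
}

.conditionToBoolean <- function(cond, maxLevels) {
  geq <- function(var, k) .geqAst(var, k, maxLevels[[var]])
  conv <- function(a) {
    switch(a$op,
      const = a,
      node = geq(a$name, 1L),
      cmp = switch(a$cmp,
        geq = geq(a$var, a$level),
        gt = geq(a$var, a$level + 1L),
        leq = list(op = "not", x = geq(a$var, a$level + 1L)),
        lt = list(op = "not", x = geq(a$var, a$level)),
        eq = list(op = "and", lhs = geq(a$var, a$level),
                  rhs = list(op = "not", x = geq(a$var, a$level + 1L))),
        neq = list(op = "not",
                   x = list(op = "and", lhs = geq(a$var, a$level),
                            rhs = list(op = "not",
                                       x = geq(a$var, a$level + 1L))))),
      not = list(op = "not", x = conv(a$x)),
      and = list(op = "and", lhs = conv(a$lhs), rhs = conv(a$rhs)),
      or = list(op = "or", lhs = conv(a$lhs), rhs = conv(a$rhs)),
      xor = list(op = "xor", lhs = conv(a$lhs), rhs = conv(a$rhs)),
      stop(sprintf("unknown condition operator '%s'", a$op), call. = FALSE))
  }
  conv(cond)
}

.andAll <- function(xs) {
  if (length(xs) == 0L) return(list(op = "const", value = 1))
  Reduce(function(l, r) list(op = "and", lhs = l, rhs = r), xs)
}

.orAll <- function(xs) {
  if (length(xs) == 0L) return(list(op = "const", value = 0))
  Reduce(function(l, r) list(op = "or", lhs = l, rhs = r), xs)
}

## Boolean expression for "target level of v >= j", honoring first-match
## term semantics: term t fires iff its condition holds and no earlier one does.
.targetGeqAst <- function(v, j, maxLevels) {
  conds <- lapply(v$terms, function(tm)
    .conditionToBoolean(tm$condition, maxLevels))
  resultLevels <- vapply(v$terms, `[[`, numeric(1), "resultLevel")
  pieces <- list()
  for (t in seq_along(conds)) {
    if (resultLevels[t] >= j) {
      notPrev <- lapply(conds[seq_len(t - 1L)], function(c)
        list(op = "not", x = c))
      pieces[[length(pieces) + 1L]] <- .andAll(c(notPrev, conds[t]))
    }
  }
  if (v$defaultLevel >= j)
    pieces[[length(pieces) + 1L]] <-
      .andAll(lapply(conds, function(c) list(op = "not", x = c)))
  .simplifyAst(.orAll(pieces))
}

#' Convert a multi-valued model into a purely Boolean network
#'
#' Each variable v with maxLevel m becomes components `v_b1 .. v_bm` (a
#' Boolean variable keeps its own name); level(v) = number of active
#' components. Component j is driven by the logic
#' `(F_v >= j & v_b(j-1)) | (v_bj & (F_v >= j | v_b(j+1)))`
#' (boundary components drop the absent neighbour), so with the default rate
#' embedding the component switches on only when the target level reaches j
#' and the level below is already on, and switches off only when the target
#' falls below j and the level above is already off: levels move stepwise
#' and admissibility is invariant. Constant variables keep their level.
#'
#' @param model A `MultiValuedModel`.
#' @return A list with `network` (a `BooleanNetwork`, rates filled with the
#'   default logic embedding at rate 1) and `map` (a `BooleanizationMap`).
#' @examples
#' conv <- booleanize(makeToy("multivalued_toy"))
#' nodeNames(conv$network)
#' @export
booleanize <- function(model) {
  stopifnot(is(model, "MultiValuedModel"))
  validObject(model)
  nms <- variableNames(model)
  maxLevels <- stats::setNames(
    lapply(model@variables, `[[`, "maxLevel"), nms)
  nodes <- list()
  rows <- list()
  for (v in model@variables) {
    m <- v$maxLevel
    for (j in seq_len(m)) {
      comp <- .componentName(v$name, j, m)
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp, variable = v$name, level = j,
        stringsAsFactors = FALSE)
      if (v$constant) {
        logic <- list(op = "node", name = comp)
      } else {
        Fgeq <- .targetGeqAst(v, j, maxLevels)
        self <- list(op = "node", name = comp)
        up <- if (j == 1L) Fgeq
              else list(op = "and", lhs = Fgeq,
                        rhs = list(op = "node",
                                   name = .componentName(v$name, j - 1L, m)))
        holdOn <- if (j == m) Fgeq
                  else list(op = "or", lhs = Fgeq,
                            rhs = list(op = "node",
                                       name = .componentName(v$name, j + 1L, m)))
        logic <- .simplifyAst(list(op = "or", lhs = up,
                                   rhs = list(op = "and", lhs = self,
                                              rhs = holdOn)))
      }
      nodes[[length(nodes) + 1L]] <- nodeDefinition(comp, logic = logic)
    }
  }
  net <- defaultRatesFromLogic(
    buildNetwork(nodes, provenance = "booleanized multi-valued model"))
  map <- new("BooleanizationMap", table = do.call(rbind, rows))
  list(network = net, map = map)
}

#' Project a Boolean component state back to levels
#'
#' @param state Named 0/1 vector over the Booleanized components.
#' @param map The `BooleanizationMap` from [booleanize()].
#' @return Named integer vector of levels (count of active components per
#'   variable). Errors on an inadmissible state (a level-j component active
#'   above an inactive level-(j-1) one).
#' @export
projectToLevels <- function(state, map) {
  state <- unlist(state)
  tab <- map@table
  missing <- setdiff(tab$component, names(state))
  if (length(missing))
    stop("state lacks component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  vars <- unique(tab$variable)
  out <- stats::setNames(integer(length(vars)), vars)
  for (v in vars) {
    comps <- tab$component[tab$variable == v][order(tab$level[tab$variable == v])]
    bits <- as.integer(state[comps] != 0)
    if (any(diff(bits) > 0))
      stop(sprintf("inadmissible state for variable '%s': components (%s)",
                   v, paste(bits, collapse = ",")), call. = FALSE)
    out[[v]] <- sum(bits)
  }
  out
}

#' Admissible component states of a Booleanized model
#'
#' @param map A `BooleanizationMap`.
#' @return Integer matrix of all admissible full component states (columns in
#'   component order of the map).
#' @export
admissibleStates <- function(map) {
  tab <- map@table
  vars <- unique(tab$variable)
  perVar <- lapply(vars, function(v) {
    m <- max(tab$level[tab$variable == v])
    ## level k  =>  first k components on
    do.call(rbind, lapply(0:m, function(k) as.integer(seq_len(m) <= k)))
  })
  grid <- expand.grid(lapply(perVar, function(x) seq_len(nrow(x))))
  out <- do.call(cbind, lapply(seq_along(vars), function(i)
    perVar[[i]][grid[[i]], , drop = FALSE]))
  colnames(out) <- unlist(lapply(vars, function(v)
    tab$component[tab$variable == v][order(tab$level[tab$variable == v])]))
  out[, tab$component, drop = FALSE]
}

#' Initial levels as an initial-state distribution over components
#'
#' Level k of a variable maps to its first k components on and the rest off,
#' emitted as one joint degenerate block per variable.
#'
#' @param map A `BooleanizationMap`.
#' @param levels Named integer vector of initial levels (missing variables
#'   are left to the default Bernoulli).
#' @param defaultProb Bernoulli probability for unlisted components.
#' @return An `InitialStateDistribution`.
#' @export
levelInitialDistribution <- function(map, levels, defaultProb = 0.5) {
  tab <- map@table
  blocks <- list()
  for (v in names(levels)) {
    comps <- tab$component[tab$variable == v][order(tab$level[tab$variable == v])]
    if (length(comps) == 0L)
      stop("unknown variable '", v, "' in levels", call. = FALSE)
    k <- as.integer(levels[[v]])
    if (k < 0 || k > length(comps))
      stop(sprintf("initial level %d of '%s' outside 0..%d", k, v,
                   length(comps)), call. = FALSE)
    blocks[[length(blocks) + 1L]] <- list(
      nodes = comps, probs = 1,
      assignments = matrix(as.integer(seq_along(comps) <= k), nrow = 1))
  }
  initialStateDistribution(blocks, defaultProb)
}
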