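## Multi-valued logical models: variables with levels 0..maxLevel and
## target-level functions given as ordered (condition, resultLevel) terms
## plus a default level — the structure of an SBML-qual transition.
##
## Conditions are small ASTs over variable LEVELS:
##   list(op = "cmp", cmp = "geq"|"gt"|"leq"|"lt"|"eq"|"neq",
##        var = <name>, level = <int>)
##   list(op = "node", name = <name>)   -- Boolean variable used directly (>= 1)
##   list(op = "const", value = 0|1)
##   and / or / not / xor combinators as in the Boolean expression AST.

setClass("MultiValuedModel", representation(variables = "list"))

setValidity("MultiValuedModel", function(object) {
  msgs <- character(0)
  if (length(object@variables) == 0L) return("model must contain at least one variable")
  nms <- vapply(object@variables, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    msgs <- c(msgs, "duplicate variable names")
  for (v in object@variables) {
    if (v$maxLevel < 1)
      msgs <- c(msgs, paste0("variable '", v$name, "' must have maxLevel >= 1"))
    if (v$defaultLevel < 0 || v$defaultLevel > v$maxLevel)
      msgs <- c(msgs, paste0("default level of '", v$name, "' outside 0..maxLevel"))
    for (tm in v$terms) {
      if (tm$resultLevel < 0 || tm$resultLevel > v$maxLevel)
        msgs <- c(msgs, paste0("result level ", tm$resultLevel, " of '", v$name,
                               "' exceeds its maxLevel ", v$maxLevel))
      refs <- .conditionVars(tm$condition)
      unknown <- setdiff(refs, nms)
      if (length(unknown))
        msgs <- c(msgs, paste0("condition of '", v$name,
                               "' references undeclared variable(s): ",
                               paste(unknown, collapse = ", ")))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

.conditionVars <- function(cond) {
  acc <- character(0)
  walk <- function(a) {
    if (a$op == "cmp") acc <<- c(acc, a$var)
    else if (a$op == "node") acc <<- c(acc, a$name)
    else for (nm in setdiff(names(a), c("op", "name", "value", "cmp", "var", "level")))
      walk(a[[nm]])
  }
  walk(cond)
  unique(acc)
}

#' Define a multi-valued variable
#'
#' @param name Variable identifier.
#' @param maxLevel Highest activity level (>= 1; 1 = Boolean).
#' @param terms Ordered list of `list(condition =, resultLevel =)` pairs;
#'   the first condition that holds determines the target level.
#' @param defaultLevel Target level when no condition holds.
#' @param initialLevel Optional initial level (used when exporting settings).
#' @param constant If `TRUE` the variable never changes (no transition).
#' @return A variable-definition list for [multiValuedModel()].
#' @export
multiValuedVariable <- function(name, maxLevel = 1, terms = list(),
                                defaultLevel = 0, initialLevel = NULL,
                                constant = FALSE) {
  list(name = name, maxLevel = as.integer(maxLevel), terms = terms,
       defaultLevel = as.integer(defaultLevel), initialLevel = initialLevel,
       constant = isTRUE(constant))
}

#' Build a multi-valued logical model
#'
#' @param variables List of [multiValuedVariable()] definitions.
#' @return A `MultiValuedModel`.
#' @export
multiValuedModel <- function(variables) {
  new("MultiValuedModel", variables = variables)
}

setMethod("show", "MultiValuedModel", function(object) {
  cat(sprintf("MultiValuedModel with %d variable(s)\n", length(object@variables)))
  for (v in object@variables)
    cat(sprintf("  %s: levels 0..%d, %d term(s), default %d%s\n", v$name,
                v$maxLevel, length(v$terms), v$defaultLevel,
                if (v$constant) " (constant)" else ""))
})

#' Variable names of a multi-valued model
#' @param model A `MultiValuedModel`.
#' @export
variableNames <- function(model) {
  vapply(model@variables, `[[`, character(1), "name")
}

.evalCondition <- function(cond, levels) {
  ev <- function(a) {
    switch(a$op,
      const = a$value != 0,
      node = levels[[a$name]] >= 1,
      cmp = {
        l <- levels[[a$var]]
        switch(a$cmp,
          geq = l >= a$level, gt = l > a$level,
          leq = l <= a$level, lt = l < a$level,
          eq = l == a$level, neq = l != a$level)
      },
      not = !ev(a$x),
      and = ev(a$lhs) && ev(a$rhs),
      or = ev(a$lhs) || ev(a$rhs),
      xor = ev(a$lhs) != ev(a$rhs),
      stop(sprintf("unknown condition operator '%s'", a$op), call. = FALSE))
  }
  ev(cond)
}

#' Target level of a variable in a given level state
#'
#' First-match semantics over the variable's ordered function terms; the
#' default level applies when no condition holds. Constant variables target
#' their current level.
#'
#' @param model A `MultiValuedModel`.
#' @param var Variable name.
#' @param levels Named integer vector of current levels.
#' @return The target level (integer).
#' @export
targetLevel <- function(model, var, levels) {
  v <- model@variables[[match(var, variableNames(model))]]
  if (is.null(v)) stop("unknown variable '", var, "'", call. = FALSE)
  if (v$constant) return(as.integer(levels[[var]]))
  for (tm in v$terms)
    if (.evalCondition(tm$condition, levels)) return(as.integer(tm$resultLevel))
  v$defaultLevel
}

#' Asynchronous transition graph of a multi-valued model
#'
#' Stepwise (+/-1 level) asynchronous semantics: from a level state L,
#' variable v can move one level toward its target `F_v(L)` whenever
#' `F_v(L) != L_v`. Enumerates the full level grid; meant for desk-scale
#' verification.
#'
#' @param model A `MultiValuedModel` (product of (maxLevel+1) up to 4096).
#' @return A `data.frame` with columns `from`, `to` (comma-separated level
#'   strings in variable order) and `var`.
#' @export
multiValuedTransitionGraph <- function(model) {
  validObject(model)
  nms <- variableNames(model)
  maxes <- vapply(model@variables, `[[`, integer(1), "maxLevel")
  if (prod(maxes + 1) > 4096)
    stop("level grid too large for exhaustive enumeration", call. = FALSE)
  grid <- expand.grid(lapply(maxes, function(m) 0:m))
  names(grid) <- nms
  lab <- apply(grid, 1, paste, collapse = ",")
  rows <- list()
  for (s in seq_len(nrow(grid))) {
    levels <- stats::setNames(as.integer(grid[s, ]), nms)
    for (v in nms) {
      tgt <- targetLevel(model, v, levels)
      if (tgt != levels[[v]]) {
        nxt <- levels
        nxt[[v]] <- levels[[v]] + sign(tgt - levels[[v]])
        rows[[length(rows) + 1L]] <- data.frame(
          from = lab[s], to = paste(nxt, collapse = ","), var = v,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(from = character(0), to = character(0), var = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
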