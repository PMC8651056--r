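## Built-in toy models with known analytic behaviour, and seeded random
## N-K (Kauffman) networks, so every simulation path is testable without
## external model files.

#' Built-in toy models
#'
#' Available toys and their documented analytic facts:
#' \describe{
#'   \item{`single_node`}{One node `S` with constant rates `rate_up = kUp`,
#'     `rate_down = kDown` (exposed as parameters `$ku`, `$kd`). Two-state
#'     CTMC: started at 0, `P(S=1 at t) = kUp/(kUp+kDown) * (1 - exp(-(kUp+kDown) t))`;
#'     stationary `P(on) = kUp/(kUp+kDown)` (2/3 for the default 2, 1).}
#'   \item{`toggle_switch`}{`A = !B`, `B = !A`; fixed points exactly
#'     `(1,0)` and `(0,1)`. Started from `(0,0)` the first flip decides the
#'     branch, so the last-state split is 0.5/0.5 by symmetry.}
#'   \item{`repressilator`}{Cyclic repression `G_i = !G_(i-1)` over `m`
#'     nodes; for odd `m` (e.g. 3) there is no fixed point and the chain
#'     cycles forever.}
#'   \item{`multivalued_toy`}{A `MultiValuedModel`: Boolean input `I`
#'     (target 1 while `v < 2`, else 0) and `v` with levels 0..2 (target 2
#'     while `I >= 1`, else 0) — a negative feedback across levels that
#'     exercises stepwise Booleanization.}
#' }
#'
#' @param name One of `"single_node"`, `"toggle_switch"`, `"repressilator"`,
#'   `"multivalued_toy"`.
#' @param kUp,kDown Rates for `single_node` (defaults 2 and 1).
#' @param m Cycle length for `repressilator` (default 3).
#' @return A `BooleanNetwork`, or a `MultiValuedModel` for
#'   `"multivalued_toy"`.
#' @examples
#' makeToy("toggle_switch")
#' @export
makeToy <- function(name, kUp = 2, kDown = 1, m = 3) {
  switch(name,
    single_node = buildNetwork(
      list(nodeDefinition("S", rateUp = "$ku", rateDown = "$kd")),
      params = c(ku = kUp, kd = kDown),
      provenance = "toy: single_node"),
    toggle_switch = defaultRatesFromLogic(buildNetwork(
      list(nodeDefinition("A", logic = "!B"),
           nodeDefinition("B", logic = "!A")),
      provenance = "toy: toggle_switch")),
    repressilator = {
      stopifnot(m >= 2)
      nms <- paste0("G", seq_len(m))
      nodes <- lapply(seq_len(m), function(i)
        nodeDefinition(nms[i], logic = paste0("!", nms[if (i == 1) m else i - 1])))
      defaultRatesFromLogic(buildNetwork(
        nodes, provenance = sprintf("toy: repressilator(%d)", m)))
    },
    multivalued_toy = multiValuedModel(list(
      multiValuedVariable("I", maxLevel = 1,
        terms = list(list(
          condition = list(op = "and",
                           lhs = list(op = "node", name = "I"),
                           rhs = list(op = "cmp", cmp = "lt",
                                      var = "v", level = 2L)),
          resultLevel = 1L)),
        defaultLevel = 0L, initialLevel = 1L),
      multiValuedVariable("v", maxLevel = 2,
        terms = list(list(
          condition = list(op = "cmp", cmp = "geq", var = "I", level = 1L),
          resultLevel = 2L)),
        defaultLevel = 0L, initialLevel = 0L))),
    stop("unknown toy model '", name, "'", call. = FALSE))
}

#' Random N-K (Kauffman) Boolean network
#'
#' Each node receives `k` distinct regulators drawn uniformly (possibly
#' including itself) and a uniformly random truth table over them, emitted as
#' logic in disjunctive normal form; rates follow the default logic embedding
#' at rate 1. Generation is fully determined by `seed`.
#'
#' @param n Number of nodes.
#' @param k Regulators per node (`1 <= k <= n`).
#' @param seed Integer seed for the generator.
#' @return A `BooleanNetwork` with nodes `N1 .. Nn`, all flagged output.
#' @examples
#' net <- makeNKNetwork(6, 2, seed = 42)
#' @export
makeNKNetwork <- function(n, k, seed = 1L) {
  if (k > n) stop("k must not exceed n", call. = FALSE)
  stopifnot(n >= 1, k >= 1)
  nms <- paste0("N", seq_len(n))
  rng <- .lcgStream(seed)
  nodes <- vector("list", n)
  for (i in seq_len(n)) {
    regs <- nms[.sampleDistinct(rng, n, k)]
    truth <- vapply(seq_len(2^k), function(j) rng() < 0.5, logical(1))
    logic <- .dnfFromTruthTable(regs, truth)
    nodes[[i]] <- nodeDefinition(nms[i], logic = logic)
  }
  defaultRatesFromLogic(buildNetwork(
    nodes, provenance = sprintf("random N-K network (n=%d, k=%d, seed=%d)",
                                n, k, as.integer(seed))))
}

## Minimal deterministic uniform stream (Lehmer / Park-Miller), independent
## of R's global RNG state so generated fixtures never perturb user code.
.lcgStream <- function(seed) {
  state <- (as.numeric(seed) %% 2147483646) + 1
  function() {
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
}

.sampleDistinct <- function(rng, n, k) {
  pool <- seq_len(n)
  out <- integer(k)
  for (j in seq_len(k)) {
    pick <- floor(rng() * length(pool)) + 1
    out[j] <- pool[pick]
    pool <- pool[-pick]
  }
  sort(out)
}

## DNF over the rows of a truth table: one conjunction per TRUE row;
## all-FALSE tables collapse to the literal 0 and all-TRUE to 1.
.dnfFromTruthTable <- function(regs, truth) {
  k <- length(regs)
  if (!any(truth)) return(parseExpression("0", "boolean"))
  if (all(truth)) return(parseExpression("1", "boolean"))
  terms <- vapply(which(truth), function(row) {
    bits <- bitwAnd(bitwShiftR(row - 1L, seq_len(k) - 1L), 1L)
    lits <- ifelse(bits == 1L, regs, paste0("!", regs))
    paste0("(", paste(lits, collapse = " & "), ")")
  }, character(1))
  parseExpression(paste(terms, collapse = " | "), "boolean")
}
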