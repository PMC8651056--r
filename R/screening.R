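## Automatic mutant screening: enumerate single/double knock-out/knock-in
## perturbations over candidate nodes, simulate each under identical
## settings, and filter the resulting last-state distributions for a
## phenotype of interest.

setClass("ScreenResult",
  representation(mutants = "list", results = "list", errors = "character",
                 settings = "SimulationSettings", provenance = "character"))

setValidity("ScreenResult", function(object) {
  if (length(object@mutants) != length(object@results) ||
      length(object@mutants) != length(object@errors))
    return("mutants, results and errors must be parallel")
  TRUE
})

setMethod("show", "ScreenResult", function(object) {
  ok <- sum(is.na(object@errors))
  cat(sprintf("ScreenResult: %d entr%s (%d simulated, %d failed) [%s]\n",
              length(object@mutants), if (length(object@mutants) == 1) "y" else "ies",
              ok, sum(!is.na(object@errors)), object@provenance))
})

#' @name screen-accessors
#' @title Accessors for screen results
#' @param x A `ScreenResult`.
#' @details `screenMutants()` lists the `MutationSpec`s (the unperturbed
#'   wild type first), `screenResults()` the parallel `SimulationResult`s
#'   (`NULL` where that mutant's simulation failed) and `screenErrors()` the
#'   parallel error messages (`NA` on success).
NULL

#' @rdname screen-accessors
#' @export
screenMutants <- function(x) x@mutants

#' @rdname screen-accessors
#' @export
screenResults <- function(x) x@results

#' @rdname screen-accessors
#' @export
screenErrors <- function(x) x@errors

#' Enumerate mutation specifications
#'
#' Generates all single mutants (every candidate crossed with every
#' direction) and, for `maxOrder = 2`, all unordered candidate pairs crossed
#' with direction pairs. Order is deterministic: candidate order, then
#' direction order `OFF < ON`. `minOrder = 2` restricts to doubles only.
#'
#' @param candidates Character vector of distinct node names.
#' @param maxOrder 1 (singles) or 2 (add doubles).
#' @param directions Subset of `c("OFF", "ON")`.
#' @param minOrder Lowest order to include (1 or 2).
#' @return A list of `MutationSpec`s.
#' @examples
#' length(enumerateMutants(c("A", "B", "C"), maxOrder = 2))  # 6 + 12
#' @export
enumerateMutants <- function(candidates, maxOrder = 1,
                             directions = c("OFF", "ON"), minOrder = 1) {
  if (length(candidates) == 0L)
    stop("candidate list must be non-empty", call. = FALSE)
  if (anyDuplicated(candidates))
    stop("duplicate candidate(s): ",
         paste(unique(candidates[duplicated(candidates)]), collapse = ", "),
         call. = FALSE)
  stopifnot(maxOrder %in% 1:2, minOrder %in% 1:2, minOrder <= maxOrder)
  directions <- match.arg(directions, c("OFF", "ON"), several.ok = TRUE)
  directions <- c("OFF", "ON")[c("OFF", "ON") %in% directions]
  out <- list()
  if (minOrder <= 1)
    for (nd in candidates)
      for (d in directions)
        out[[length(out) + 1L]] <- mutationSpec(nd, d)
  if (maxOrder >= 2 && length(candidates) >= 2)
    for (i in seq_len(length(candidates) - 1L))
      for (j in (i + 1L):length(candidates))
        for (d1 in directions)
          for (d2 in directions)
            out[[length(out) + 1L]] <- mutationSpec(
              c(candidates[i], candidates[j]), c(d1, d2))
  out
}

#' Run a mutant screen
#'
#' Simulates the unperturbed network ("wild type") and every mutant under
#' identical settings; mutant i uses a seed derived deterministically from
#' the master seed and i, so the screen is reproducible and individual
#' entries can be recomputed in isolation. A failing mutant is recorded as
#' an error without aborting the rest of the screen.
#'
#' @param network A `BooleanNetwork`.
#' @param settings A `SimulationSettings` shared by all entries.
#' @param mutants List of `MutationSpec`s (e.g. from [enumerateMutants()]).
#' @return A `ScreenResult`; the first entry is always the wild type.
#' @export
runScreen <- function(network, settings = simulationSettings(),
                      mutants = list()) {
  stopifnot(is(network, "BooleanNetwork"), is(settings, "SimulationSettings"))
  specs <- c(list(mutationSpec()), mutants)
  results <- vector("list", length(specs))
  errors <- rep(NA_character_, length(specs))
  for (i in seq_along(specs)) {
    entrySettings <- settings
    entrySettings@seed <- .childSeed(settings@seed, i - 1L)
    results[[i]] <- tryCatch({
      mutated <- if (length(specs[[i]]@node)) applyMutation(network, specs[[i]])
                 else network
      runEnsemble(mutated, entrySettings)
    }, error = function(e) {
      errors[i] <<- conditionMessage(e)
      NULL
    })
  }
  new("ScreenResult", mutants = specs, results = results, errors = errors,
      settings = settings, provenance = network@provenance)
}

.childSeed <- function(seed, index) {
  (seed + 104729 * index) %% 2147483647
}

setClass("PhenotypeQuery",
  representation(constraints = "numeric", threshold = "numeric"))

setValidity("PhenotypeQuery", function(object) {
  msgs <- character(0)
  if (is.null(names(object@constraints)) || length(object@constraints) == 0L)
    msgs <- c(msgs, "constraints must be a named vector of required 0/1 values")
  if (!all(object@constraints %in% c(0, 1)))
    msgs <- c(msgs, "required values must be 0 or 1")
  if (length(object@threshold) != 1L || object@threshold < 0 ||
      object@threshold > 1)
    msgs <- c(msgs, "threshold must be a probability")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Define a phenotype query
#'
#' A phenotype is a conjunction of required output values; its statistic for
#' a mutant is the last-state probability mass of projected states
#' satisfying every constraint.
#'
#' @param constraints Named vector of required values, e.g.
#'   `c(IL17F = 1, IL17A = 0)`.
#' @param threshold Probability threshold; [filterPhenotype()] keeps mutants
#'   with statistic strictly greater.
#' @return A `PhenotypeQuery`.
#' @export
phenotypeQuery <- function(constraints, threshold = 0) {
  new("PhenotypeQuery", constraints = unlist(constraints),
      threshold = threshold)
}

.labelActiveSet <- function(label) {
  if (label == "<nil>") character(0) else strsplit(label, " -- ", fixed = TRUE)[[1]]
}

#' Phenotype statistic of one simulation result
#'
#' @param result A `SimulationResult`.
#' @param query A `PhenotypeQuery` whose constraint nodes are all outputs of
#'   the result.
#' @return The last-state probability mass satisfying the constraints.
#' @export
phenotypeStatistic <- function(result, query) {
  validObject(query)
  nonOut <- setdiff(names(query@constraints), result@outputs)
  if (length(nonOut))
    stop("constraint on non-output node(s): ", paste(nonOut, collapse = ", "),
         call. = FALSE)
  ls <- lastStateDistribution(result)
  sat <- vapply(names(ls), function(label) {
    active <- .labelActiveSet(label)
    all((names(query@constraints) %in% active) == (query@constraints == 1))
  }, logical(1))
  sum(ls[sat])
}

#' Filter a screen for a phenotype
#'
#' Keeps entries (wild type included) whose phenotype statistic is strictly
#' greater than the query threshold, sorted by statistic descending.
#'
#' @param screen A `ScreenResult`.
#' @param query A `PhenotypeQuery`.
#' @return A `data.frame` with columns `mutant` (label, `"WT"` for the wild
#'   type), `statistic`, and the constraint description as attribute
#'   `phenotype`.
#' @export
filterPhenotype <- function(screen, query) {
  stopifnot(is(screen, "ScreenResult"), is(query, "PhenotypeQuery"))
  rows <- list()
  for (i in seq_along(screen@mutants)) {
    if (is.null(screen@results[[i]])) next
    stat <- phenotypeStatistic(screen@results[[i]], query)
    if (stat > query@threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        mutant = mutationLabel(screen@mutants[[i]]), statistic = stat,
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(mutant = character(0), statistic = numeric(0))
  out <- out[order(-out$statistic), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "phenotype") <- paste0(names(query@constraints), "=",
                                   query@constraints, collapse = " & ")
  out
}
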