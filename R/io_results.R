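## Result export: probability-trajectory CSV (one row per time window),
## node-probability CSV, last-state and fixed-point TSV, and a complete
## JSON serialization of a SimulationResult.

#' Export a simulation result to files
#'
#' Writes five files under `dir` (created if needed):
#' `<prefix>_state_probs.csv` (columns: time = window midpoint, then one
#' column per observed projected state), `<prefix>_node_probs.csv`,
#' `<prefix>_last_state.tsv` (state label, frequency),
#' `<prefix>_fixed_points.tsv` (label, full-state bit-vector, share) and
#' `<prefix>_result.json` (the complete result).
#'
#' @param result A `SimulationResult`.
#' @param dir Output directory.
#' @param prefix File-name prefix (default `"result"`).
#' @return Invisibly, the vector of paths written.
#' @export
writeResultFiles <- function(result, dir, prefix = "result") {
  stopifnot(is(result, "SimulationResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("_state_probs.csv",
                                           "_node_probs.csv",
                                           "_last_state.tsv",
                                           "_fixed_points.tsv",
                                           "_result.json")))
  mids <- windowMidpoints(result)
  stateDf <- data.frame(time = mids, stateProbabilities(result),
                        check.names = FALSE)
  utils::write.csv(stateDf, paths[1], row.names = FALSE)
  nodeDf <- data.frame(time = mids, nodeProbabilities(result),
                       check.names = FALSE)
  utils::write.csv(nodeDf, paths[2], row.names = FALSE)
  ls <- lastStateDistribution(result)
  utils::write.table(data.frame(state = names(ls), frequency = as.numeric(ls)),
                     paths[3], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(fixedPointTable(result), paths[4], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(resultToList(result), paths[5], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Convert a simulation result to a plain list (JSON-ready)
#'
#' @param result A `SimulationResult`.
#' @return A nested list mirroring all result components plus the resolved
#'   settings (seed included), sufficient to reproduce the run.
#' @export
resultToList <- function(result) {
  s <- result@settings
  list(
    settings = list(sampleCount = as.integer(s@sampleCount),
                    maxTime = s@maxTime,
                    timePoints = as.integer(s@timePoints),
                    seed = s@seed,
                    defaultInitialProb = s@initial@defaultProb),
    outputs = result@outputs,
    provenance = result@provenance,
    windowEdges = result@windowEdges,
    stateProbabilities = apply(stateProbabilities(result), 2, identity,
                               simplify = FALSE),
    nodeProbabilities = apply(nodeProbabilities(result), 2, identity,
                              simplify = FALSE),
    lastStateDistribution = as.list(lastStateDistribution(result)),
    fixedPoints = fixedPointTable(result))
}

#' Export a screen to a directory tree
#'
#' Writes one subdirectory per entry (wild type first, named `WT`; mutants
#' named after their label with `:` replaced by `-`) containing that entry's
#' result files, plus `screen_summary.tsv` listing each entry's label,
#' status and error message if any.
#'
#' @param screen A `ScreenResult`.
#' @param dir Output directory.
#' @return Invisibly, the summary data frame.
#' @export
writeScreenFiles <- function(screen, dir) {
  stopifnot(is(screen, "ScreenResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- vapply(screen@mutants, mutationLabel, character(1))
  safe <- gsub("[^A-Za-z0-9_+-]+", "-", gsub(":", "-", labels))
  for (i in seq_along(labels)) {
    if (is.null(screen@results[[i]])) next
    writeResultFiles(screen@results[[i]], file.path(dir, safe[i]))
  }
  summary <- data.frame(
    mutant = labels,
    status = ifelse(is.na(screen@errors), "ok", "error"),
    error = ifelse(is.na(screen@errors), "", screen@errors),
    stringsAsFactors = FALSE)
  utils::write.table(summary, file.path(dir, "screen_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(summary)
}

#' Serialize a Booleanization map as JSON
#'
#' @param map A `BooleanizationMap`.
#' @param path Optional output path; when `NULL` the JSON text is returned.
#' @return JSON text (invisibly when written).
#' @export
booleanizationMapJson <- function(map, path = NULL) {
  stopifnot(is(map, "BooleanizationMap"))
  json <- jsonlite::toJSON(componentTable(map), dataframe = "rows",
                           auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
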