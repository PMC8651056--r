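## MaBoSS-style model description (.bnd) and simulation settings (.cfg)
## files. The dialect implemented here:
##
##   .bnd:  node NAME {
##            logic = <boolean expr>;       // optional if both rates given
##            rate_up = <rate expr>;        // optional if logic given
##            rate_down = <rate expr>;
##          }
##   .cfg:  $param = <value>;
##          NAME.istate = <p> [1] , <q> [0];
##          [A,B].istate = <p> [1,1] , <q> [0,0];     // joint (linked) nodes
##          NAME.is_internal = TRUE;                  // FALSE = output
##          sample_count = <int>; max_time = <num>;
##          time_tick = <num>;                        // window width
##          seed = <int>;
##
## "//" comments are ignored; statements end with ";". Round-trip fidelity
## (write -> read gives an equivalent model/settings) is the contract; no
## bit-compatibility with any particular MaBoSS release is claimed.

#' Read a MaBoSS-style model description (.bnd)
#'
#' @param x Path to a `.bnd` file, or its text.
#' @return A `BooleanNetwork` (parameters referenced as `$name` are expected
#'   from the paired settings file; all nodes default to output until
#'   `is_internal` statements say otherwise).
#' @export
readBnd <- function(x) {
  text <- paste(.readLinesFlexible(x), collapse = "\n")
  text <- gsub("//[^\n]*", "", text)
  nodes <- list()
  pos <- 1L
  n <- nchar(text)
  pat <- "node\\s+([A-Za-z_][A-Za-z0-9_.]*)\\s*\\{([^}]*)\\}"
  while (pos <= n) {
    rest <- substring(text, pos)
    if (!nzchar(trimws(rest))) break
    m <- regexpr(pat, rest, perl = TRUE)
    if (m < 0)
      stop(sprintf("malformed .bnd near position %d: expected 'node NAME { ... }'",
                   pos), call. = FALSE)
    before <- substr(rest, 1, m - 1)
    if (nzchar(trimws(before)))
      stop(sprintf("malformed .bnd near position %d: unexpected text '%s'",
                   pos, trimws(before)), call. = FALSE)
    starts <- attr(m, "capture.start")
    lens <- attr(m, "capture.length")
    name <- substr(rest, starts[1], starts[1] + lens[1] - 1)
    body <- substr(rest, starts[2], starts[2] + lens[2] - 1)
    fields <- .parseBndBody(body, name)
    nodes[[length(nodes) + 1L]] <- nodeDefinition(
      name, logic = fields$logic, rateUp = fields$rate_up,
      rateDown = fields$rate_down)
    pos <- pos + m + attr(m, "match.length") - 1L
  }
  if (length(nodes) == 0L)
    stop("no node blocks found in .bnd input", call. = FALSE)
  buildNetwork(nodes, provenance = "MaBoSS bnd")
}

.parseBndBody <- function(body, name) {
  stmts <- strsplit(body, ";", fixed = TRUE)[[1]]
  out <- list(logic = NULL, rate_up = NULL, rate_down = NULL)
  for (s in stmts) {
    s <- trimws(s)
    if (!nzchar(s)) next
    eq <- regexpr("=", s, fixed = TRUE)
    if (eq < 0)
      stop(sprintf("malformed statement in node '%s': '%s'", name, s),
           call. = FALSE)
    key <- trimws(substr(s, 1, eq - 1))
    val <- trimws(substring(s, eq + 1))
    if (!key %in% c("logic", "rate_up", "rate_down"))
      stop(sprintf("unknown field '%s' in node '%s'", key, name), call. = FALSE)
    ctx <- if (key == "logic") "boolean" else "rate"
    out[[key]] <- tryCatch(parseExpression(val, ctx),
      error = function(e) stop(sprintf("node '%s', field '%s': %s", name, key,
                                       conditionMessage(e)), call. = FALSE))
  }
  if (is.null(out$logic) && (is.null(out$rate_up) || is.null(out$rate_down)))
    stop(sprintf("node '%s' needs either logic or both rate_up and rate_down",
                 name), call. = FALSE)
  out
}

#' Read MaBoSS-style simulation settings (.cfg)
#'
#' Parameter assignments (`$p = v;`) are attached to the returned settings
#' as the `params` attribute and merged into the network by [readBndCfg()];
#' `is_internal` statements define the output set (nodes not marked
#' internal).
#'
#' @param x Path to a `.cfg` file, or its text.
#' @param network The `BooleanNetwork` the settings refer to.
#' @return A `SimulationSettings`; attribute `params` carries the parameter
#'   assignments.
#' @export
readCfg <- function(x, network) {
  stopifnot(is(network, "BooleanNetwork"))
  text <- paste(.readLinesFlexible(x), collapse = "\n")
  text <- gsub("//[^\n]*", "", text)
  stmts <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  stmts <- stmts[nzchar(stmts)]
  nms <- nodeNames(network)
  params <- numeric(0)
  blocks <- list()
  internal <- character(0)
  external <- character(0)
  opts <- list(sample_count = 10000, max_time = 10, time_tick = 0.1,
               seed = 20250)
  for (s in stmts) {
    eq <- regexpr("=", s, fixed = TRUE)
    if (eq < 0) stop("malformed .cfg statement: '", s, "'", call. = FALSE)
    key <- trimws(substr(s, 1, eq - 1))
    val <- trimws(substring(s, eq + 1))
    if (startsWith(key, "$")) {
      params[substring(key, 2)] <- .cfgNumber(val, s)
    } else if (grepl("\\.istate$", key)) {
      spec <- sub("\\.istate$", "", key)
      nodesIn <- if (startsWith(spec, "[")) {
        trimws(strsplit(gsub("^\\[|\\]$", "", spec), ",")[[1]])
      } else spec
      unknown <- setdiff(nodesIn, nms)
      if (length(unknown))
        stop("unknown node(s) in istate statement: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      blocks[[length(blocks) + 1L]] <- .parseIstate(val, nodesIn, s)
    } else if (grepl("\\.is_internal$", key)) {
      node <- sub("\\.is_internal$", "", key)
      if (!(node %in% nms))
        stop("unknown node in is_internal statement: ", node, call. = FALSE)
      if (toupper(val) %in% c("TRUE", "1")) internal <- c(internal, node)
      else external <- c(external, node)
    } else if (key %in% names(opts)) {
      opts[[key]] <- .cfgNumber(val, s)
    } else {
      stop("unknown .cfg statement: '", s, "'", call. = FALSE)
    }
  }
  outputs <- if (length(internal) || length(external)) setdiff(nms, internal)
             else character(0)
  timePoints <- max(1, round(opts$max_time / opts$time_tick))
  settings <- simulationSettings(
    initial = initialStateDistribution(blocks),
    outputs = outputs,
    sampleCount = opts$sample_count, maxTime = opts$max_time,
    timePoints = timePoints, seed = opts$seed)
  attr(settings, "params") <- params
  settings
}

.cfgNumber <- function(val, stmt) {
  v <- suppressWarnings(as.numeric(val))
  if (is.na(v)) stop("expected a number in .cfg statement: '", stmt, "'",
                     call. = FALSE)
  v
}

## "0.5 [1,1], 0.5 [0,0]" over the given nodes -> distribution block
.parseIstate <- function(val, nodesIn, stmt) {
  atoms <- trimws(strsplit(val, ",(?![^\\[]*\\])", perl = TRUE)[[1]])
  probs <- numeric(0)
  assign <- NULL
  for (a in atoms) {
    m <- regmatches(a, regexec("^([0-9.eE+-]+)\\s*\\[([^]]*)\\]$", a))[[1]]
    if (length(m) != 3)
      stop("malformed istate atom '", a, "' in: '", stmt, "'", call. = FALSE)
    probs <- c(probs, as.numeric(m[2]))
    vals <- as.integer(trimws(strsplit(m[3], ",")[[1]]))
    if (length(vals) != length(nodesIn) || any(is.na(vals)) ||
        any(!vals %in% 0:1))
      stop("istate assignment '[", m[3], "]' does not match nodes (",
           paste(nodesIn, collapse = ","), ")", call. = FALSE)
    assign <- rbind(assign, vals)
  }
  if (abs(sum(probs) - 1) > 1e-9)
    stop("istate probabilities for (", paste(nodesIn, collapse = ","),
         ") sum to ", sum(probs), ", not 1", call. = FALSE)
  list(nodes = nodesIn, probs = probs,
       assignments = matrix(assign, ncol = length(nodesIn)))
}

#' Read a paired .bnd/.cfg model
#'
#' @param bnd,cfg Paths or texts of the model description and settings files.
#' @return A list with `network` (parameters from the .cfg merged in) and
#'   `settings`.
#' @export
readBndCfg <- function(bnd, cfg) {
  network <- readBnd(bnd)
  settings <- readCfg(cfg, network)
  params <- attr(settings, "params")
  if (length(params)) network@params[names(params)] <- params
  if (length(settings@outputs)) outputNodes(network) <- settings@outputs
  list(network = network, settings = settings)
}

#' Write a network and settings as .bnd/.cfg texts
#'
#' @param network A `BooleanNetwork`.
#' @param settings A `SimulationSettings` (parameters are taken from the
#'   network).
#' @param bndPath,cfgPath Optional output paths.
#' @return A list with `bnd` and `cfg` texts (invisibly when paths given).
#' @export
writeBndCfg <- function(network, settings = simulationSettings(),
                        bndPath = NULL, cfgPath = NULL) {
  stopifnot(is(network, "BooleanNetwork"), is(settings, "SimulationSettings"))
  bnd <- vapply(network@nodes, function(nd) {
    lines <- character(0)
    if (!is.null(nd$logic))
      lines <- c(lines, paste0("  logic = ", serializeExpression(nd$logic), ";"))
    lines <- c(lines,
               paste0("  rate_up = ", serializeExpression(nd$rateUp), ";"),
               paste0("  rate_down = ", serializeExpression(nd$rateDown), ";"))
    paste0("node ", nd$name, " {\n", paste(lines, collapse = "\n"), "\n}")
  }, character(1))
  bndText <- paste(c(bnd, ""), collapse = "\n")

  cfg <- character(0)
  if (length(network@params))
    cfg <- c(cfg, paste0("$", names(network@params), " = ",
                         format(network@params, scientific = FALSE, trim = TRUE), ";"))
  for (b in settings@initial@blocks) {
    atoms <- vapply(seq_along(b$probs), function(k)
      sprintf("%s [%s]", format(b$probs[k], scientific = FALSE, trim = TRUE),
              paste(b$assignments[k, ], collapse = ",")), character(1))
    lhs <- if (length(b$nodes) == 1L) b$nodes
           else paste0("[", paste(b$nodes, collapse = ","), "]")
    cfg <- c(cfg, paste0(lhs, ".istate = ", paste(atoms, collapse = " , "), ";"))
  }
  outs <- if (length(settings@outputs)) settings@outputs else outputNodes(network)
  for (nm in nodeNames(network))
    cfg <- c(cfg, paste0(nm, ".is_internal = ",
                         if (nm %in% outs) "FALSE" else "TRUE", ";"))
  cfg <- c(cfg,
           paste0("sample_count = ", as.integer(settings@sampleCount), ";"),
           paste0("max_time = ",
                  format(settings@maxTime, scientific = FALSE, trim = TRUE), ";"),
           paste0("time_tick = ",
                  format(settings@maxTime / settings@timePoints,
                         scientific = FALSE, trim = TRUE), ";"),
           paste0("seed = ", format(settings@seed, scientific = FALSE), ";"))
  cfgText <- paste(c(cfg, ""), collapse = "\n")

  if (!is.null(bndPath)) writeLines(bndText, bndPath, sep = "")
  if (!is.null(cfgPath)) writeLines(cfgText, cfgPath, sep = "")
  out <- list(bnd = bndText, cfg = cfgText)
  if (!is.null(bndPath) || !is.null(cfgPath)) invisible(out) else out
}
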