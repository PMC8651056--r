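## BoolNet text format: a "targets, factors" header then one
## "target, expression" line per node. Comments start with "#". Rules are
## pure logic (the literals 0/1 are accepted as constant rules); the
## probabilistic and temporal BoolNet extensions are outside the
## continuous-time semantics implemented here and are rejected.

#' Read a BoolNet model
#'
#' @param x Path to a `.bnet` file, or the file's text (anything containing a
#'   newline is treated as text).
#' @return A `BooleanNetwork` with logic rules, rates filled by the default
#'   logic embedding at rate 1, and every node flagged as output.
#' @examples
#' net <- readBNet("targets, factors\nA, !B\nB, !A")
#' @export
readBNet <- function(x) {
  lines <- .readLinesFlexible(x)
  lines <- sub("#.*$", "", lines)
  keep <- nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0L)
    stop("empty BoolNet file", call. = FALSE)
  if (!grepl("^targets\\s*,\\s*factors$", lines[1], ignore.case = TRUE))
    stop(sprintf("line %d: missing BoolNet header 'targets, factors'",
                 lineNo[1]), call. = FALSE)
  if (length(lines) < 2L)
    stop("BoolNet file has no rules", call. = FALSE)
  nodes <- list()
  seen <- character(0)
  for (i in 2:length(lines)) {
    ln <- lines[i]
    if (grepl("probabilities|temporal", ln, ignore.case = TRUE))
      stop(sprintf("line %d: probabilistic/temporal BoolNet extensions are not supported",
                   lineNo[i]), call. = FALSE)
    comma <- regexpr(",", ln, fixed = TRUE)
    if (comma < 0)
      stop(sprintf("line %d: expected 'target, expression'", lineNo[i]),
           call. = FALSE)
    target <- trimws(substr(ln, 1, comma - 1))
    exprTxt <- trimws(substring(ln, comma + 1))
    if (!grepl("^[A-Za-z_][A-Za-z0-9_.]*$", target))
      stop(sprintf("line %d: invalid target name '%s'", lineNo[i], target),
           call. = FALSE)
    if (target %in% seen)
      stop(sprintf("line %d: duplicate target '%s'", lineNo[i], target),
           call. = FALSE)
    seen <- c(seen, target)
    logic <- tryCatch(parseExpression(exprTxt, "boolean"),
      error = function(e) stop(sprintf("line %d: %s", lineNo[i],
                                       conditionMessage(e)), call. = FALSE))
    nodes[[length(nodes) + 1L]] <- nodeDefinition(target, logic = logic)
  }
  defaultRatesFromLogic(buildNetwork(nodes, provenance = "BoolNet"))
}

#' Write a BoolNet model
#'
#' @param network A `BooleanNetwork` in which every node has logic.
#' @param path Optional output path; when `NULL` the text is returned.
#' @return The file text, invisibly when written to `path`.
#' @export
writeBNet <- function(network, path = NULL) {
  stopifnot(is(network, "BooleanNetwork"))
  for (nd in network@nodes)
    if (is.null(nd$logic))
      stop(sprintf("node '%s' has no logic; BoolNet requires logic rules",
                   nd$name), call. = FALSE)
  body <- vapply(network@nodes, function(nd)
    paste0(nd$name, ", ", serializeExpression(nd$logic)), character(1))
  text <- paste(c("targets, factors", body, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(c("targets, factors", body), path)
    return(invisible(text))
  }
  text
}

.readLinesFlexible <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  if (length(x) > 1L) return(x)
  if (!grepl("[\n;{]", x)) {   # a path, not inline model/settings text
    if (!file.exists(x))
      stop("file not found: ", x, call. = FALSE)
    return(readLines(x, warn = FALSE, encoding = "UTF-8"))
  }
  strsplit(gsub("\r\n?", "\n", x), "\n", fixed = TRUE)[[1]]
}
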