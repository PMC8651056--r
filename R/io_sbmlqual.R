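## SBML-qual import (read-only): qualitativeSpecies + transitions with
## functionTerms become a MultiValuedModel. The supported MathML subset is
## and/or/not/xor over comparisons (eq, neq, geq, gt, leq, lt) between a
## species and an integer level, bare species references (Boolean use),
## and the constants true/false. Sign/threshold attributes on transition
## inputs are ignored: the math is authoritative.

#' Read an SBML-qual document
#'
#' @param x Path to an SBML file, or its XML text.
#' @return A `MultiValuedModel`. Boolean-only documents (all `maxLevel` 1)
#'   convert losslessly; species without a transition are treated as
#'   constant inputs held at their initial level.
#' @export
readSBMLQual <- function(x) {
  doc <- if (grepl("<", x, fixed = TRUE)) xml2::read_xml(x)
         else xml2::read_xml(paste(readLines(x, warn = FALSE), collapse = "\n"))
  ns <- c(q = "http://www.sbml.org/sbml/level3/version1/qual/version1",
          m = "http://www.w3.org/1998/Math/MathML")
  species <- xml2::xml_find_all(doc, "//q:qualitativeSpecies", ns)
  if (length(species) == 0L)
    stop("no qualitativeSpecies found: not an SBML-qual document?",
         call. = FALSE)
  vars <- list()
  for (sp in species) {
    id <- xml2::xml_attr(sp, "id")
    maxLevel <- xml2::xml_attr(sp, "maxLevel")
    maxLevel <- if (is.na(maxLevel)) 1L else as.integer(maxLevel)
    initial <- xml2::xml_attr(sp, "initialLevel")
    vars[[id]] <- multiValuedVariable(
      id, maxLevel = max(1L, maxLevel),
      initialLevel = if (is.na(initial)) NULL else as.integer(initial),
      constant = TRUE)  # until a transition targets it
  }
  transitions <- xml2::xml_find_all(doc, "//q:transition", ns)
  for (tr in transitions) {
    outs <- xml2::xml_find_all(tr, ".//q:output", ns)
    targets <- xml2::xml_attr(outs, "qualitativeSpecies")
    terms <- xml2::xml_find_all(tr, ".//q:functionTerm", ns)
    default <- xml2::xml_find_first(tr, ".//q:defaultTerm", ns)
    if (inherits(default, "xml_missing"))
      stop(sprintf("transition '%s' lacks a defaultTerm",
                   xml2::xml_attr(tr, "id") %||% "?"), call. = FALSE)
    defaultLevel <- as.integer(xml2::xml_attr(default, "resultLevel"))
    termList <- lapply(terms, function(tm) {
      math <- xml2::xml_find_first(tm, ".//m:math", ns)
      if (inherits(math, "xml_missing"))
        stop("functionTerm without math element", call. = FALSE)
      list(condition = .mathmlToCondition(xml2::xml_children(math)[[1]]),
           resultLevel = as.integer(xml2::xml_attr(tm, "resultLevel")))
    })
    for (target in targets) {
      if (is.null(vars[[target]]))
        stop("transition output references unknown species '", target, "'",
             call. = FALSE)
      for (tm in termList)
        if (tm$resultLevel > vars[[target]]$maxLevel)
          stop(sprintf("resultLevel %d exceeds maxLevel %d of species '%s'",
                       tm$resultLevel, vars[[target]]$maxLevel, target),
               call. = FALSE)
      if (defaultLevel > vars[[target]]$maxLevel)
        stop(sprintf("default resultLevel %d exceeds maxLevel %d of species '%s'",
                     defaultLevel, vars[[target]]$maxLevel, target),
             call. = FALSE)
      vars[[target]]$terms <- termList
      vars[[target]]$defaultLevel <- defaultLevel
      vars[[target]]$constant <- FALSE
    }
  }
  multiValuedModel(unname(vars))
}

.mathmlToCondition <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "ci")
    return(list(op = "node", name = trimws(xml2::xml_text(node))))
  if (name == "true") return(list(op = "const", value = 1))
  if (name == "false") return(list(op = "const", value = 0))
  if (name != "apply")
    stop("unsupported MathML element '", name, "'", call. = FALSE)
  children <- xml2::xml_children(node)
  opName <- xml2::xml_name(children[[1]])
  args <- children[-1]
  if (opName %in% c("eq", "neq", "geq", "gt", "leq", "lt")) {
    if (length(args) != 2)
      stop("comparison must have exactly two operands", call. = FALSE)
    kinds <- vapply(args, xml2::xml_name, character(1))
    if (identical(kinds, c("ci", "cn"))) {
      var <- trimws(xml2::xml_text(args[[1]]))
      lev <- as.integer(as.numeric(trimws(xml2::xml_text(args[[2]]))))
      cmp <- opName
    } else if (identical(kinds, c("cn", "ci"))) {
      ## mirror "2 <= v" into "v >= 2"
      var <- trimws(xml2::xml_text(args[[2]]))
      lev <- as.integer(as.numeric(trimws(xml2::xml_text(args[[1]]))))
      cmp <- c(eq = "eq", neq = "neq", geq = "leq", gt = "lt",
               leq = "geq", lt = "gt")[[opName]]
    } else {
      stop("comparisons must be between a species and an integer level",
           call. = FALSE)
    }
    return(list(op = "cmp", cmp = cmp, var = var, level = lev))
  }
  if (opName == "not") {
    if (length(args) != 1) stop("'not' takes one operand", call. = FALSE)
    return(list(op = "not", x = .mathmlToCondition(args[[1]])))
  }
  if (opName %in% c("and", "or", "xor")) {
    if (length(args) < 2)
      stop("'", opName, "' needs at least two operands", call. = FALSE)
    parts <- lapply(args, .mathmlToCondition)
    return(Reduce(function(l, r) list(op = opName, lhs = l, rhs = r), parts))
  }
  stop("unsupported MathML operator '", opName,
       "' (supported: and, or, not, xor, eq, neq, geq, gt, leq, lt)",
       call. = FALSE)
}

#' Import an SBML-qual document as a Boolean network
#'
#' Reads the document with [readSBMLQual()] and converts it with
#' [booleanize()]; the initial levels recorded in the document become a
#' degenerate initial-state distribution over the components.
#'
#' @param x Path to an SBML file, or its XML text.
#' @return A list with `network`, `map` and `initial` (an
#'   `InitialStateDistribution`, or `NULL` when the document records no
#'   initial levels).
#' @export
importSBMLQual <- function(x) {
  model <- readSBMLQual(x)
  conv <- booleanize(model)
  init <- NULL
  levels <- Filter(Negate(is.null),
                   stats::setNames(lapply(model@variables, `[[`, "initialLevel"),
                                   variableNames(model)))
  if (length(levels))
    init <- levelInitialDistribution(conv$map, unlist(levels))
  c(conv, list(initial = init, model = model))
}
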