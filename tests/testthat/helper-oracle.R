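# Independent oracles and small utilities shared across tests.

# Brute-force expression oracle: translate symbolic logic text to an R
# expression (xor spelled as an infix operator) and eval() it with base R.
# Deliberately shares no code with the package's parser/evaluator.
oracleEvalLogic <- function(text, state) {
  `%xor%` <- function(a, b) xor(as.logical(a), as.logical(b))
  txt <- gsub("^", "%xor%", text, fixed = TRUE)
  env <- list2env(lapply(as.list(state), function(v) v != 0))
  env$`%xor%` <- `%xor%`
  as.numeric(isTRUE(as.logical(eval(parse(text = txt), env))))
}

# Random symbolic boolean expression over the given variables.
randomLogicText <- function(vars, depth = 3) {
  if (depth == 0 || runif(1) < 0.3) {
    v <- sample(vars, 1)
    return(if (runif(1) < 0.3) paste0("!", v) else v)
  }
  op <- sample(c("&", "|", "^"), 1)
  lhs <- randomLogicText(vars, depth - 1)
  rhs <- randomLogicText(vars, depth - 1)
  paste0("(", lhs, " ", op, " ", rhs, ")")
}

# All 0/1 assignments over variable names, as a list of named vectors.
allAssignments <- function(vars) {
  grid <- expand.grid(rep(list(0:1), length(vars)))
  names(grid) <- vars
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, , drop = FALSE]))
}

tvDistance <- function(p, q) {
  keys <- union(names(p), names(q))
  pv <- ifelse(is.na(p[keys]), 0, p[keys])
  qv <- ifelse(is.na(q[keys]), 0, q[keys])
  0.5 * sum(abs(pv - qv))
}

# Canonical edge-set representation of a labelled transition graph.
edgeSet <- function(df, fromCol = "from", toCol = "to", labCol = NULL) {
  lab <- if (is.null(labCol)) "" else df[[labCol]]
  sort(paste(df[[fromCol]], df[[toCol]], lab, sep = " => "))
}

# A two-node model whose SBML-qual serialization is built in code: species R
# (constant Boolean input at level 1) activating S.
sbmlQualBooleanDoc <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"\n',
    '      xmlns:qual="http://www.sbml.org/sbml/level3/version1/qual/version1" qual:required="true">\n',
    '<model id="toy">\n',
    '<qual:listOfQualitativeSpecies>\n',
    '<qual:qualitativeSpecies qual:id="R" qual:maxLevel="1" qual:initialLevel="1"/>\n',
    '<qual:qualitativeSpecies qual:id="S" qual:maxLevel="1" qual:initialLevel="0"/>\n',
    '</qual:listOfQualitativeSpecies>\n',
    '<qual:listOfTransitions>\n',
    '<qual:transition qual:id="tr_S">\n',
    '<qual:listOfInputs><qual:input qual:qualitativeSpecies="R" qual:sign="positive"/></qual:listOfInputs>\n',
    '<qual:listOfOutputs><qual:output qual:qualitativeSpecies="S"/></qual:listOfOutputs>\n',
    '<qual:listOfFunctionTerms>\n',
    '<qual:functionTerm qual:resultLevel="1">\n',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">\n',
    '<apply><geq/><ci>R</ci><cn type="integer">1</cn></apply>\n',
    '</math>\n',
    '</qual:functionTerm>\n',
    '<qual:defaultTerm qual:resultLevel="0"/>\n',
    '</qual:listOfFunctionTerms>\n',
    '</qual:transition>\n',
    '</qual:listOfTransitions>\n',
    '</model>\n</sbml>\n')
}

# Multi-valued document: M (levels 0..2) driven up by A, with two function
# terms; A Boolean with a default-only transition (so not constant).
sbmlQualMultiDoc <- function(withDefault = TRUE) {
  defaultTerm <- if (withDefault) '<qual:defaultTerm qual:resultLevel="0"/>\n' else ''
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"\n',
    '      xmlns:qual="http://www.sbml.org/sbml/level3/version1/qual/version1" qual:required="true">\n',
    '<model id="toy2">\n',
    '<qual:listOfQualitativeSpecies>\n',
    '<qual:qualitativeSpecies qual:id="A" qual:maxLevel="1" qual:initialLevel="1"/>\n',
    '<qual:qualitativeSpecies qual:id="M" qual:maxLevel="2" qual:initialLevel="0"/>\n',
    '</qual:listOfQualitativeSpecies>\n',
    '<qual:listOfTransitions>\n',
    '<qual:transition qual:id="tr_M">\n',
    '<qual:listOfOutputs><qual:output qual:qualitativeSpecies="M"/></qual:listOfOutputs>\n',
    '<qual:listOfFunctionTerms>\n',
    '<qual:functionTerm qual:resultLevel="2">\n',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">\n',
    '<apply><and/><apply><geq/><ci>A</ci><cn type="integer">1</cn></apply>',
    '<apply><geq/><ci>M</ci><cn type="integer">1</cn></apply></apply>\n',
    '</math>\n',
    '</qual:functionTerm>\n',
    '<qual:functionTerm qual:resultLevel="1">\n',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">\n',
    '<apply><geq/><ci>A</ci><cn type="integer">1</cn></apply>\n',
    '</math>\n',
    '</qual:functionTerm>\n',
    defaultTerm,
    '</qual:listOfFunctionTerms>\n',
    '</qual:transition>\n',
    '</qual:listOfTransitions>\n',
    '</model>\n</sbml>\n')
}
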