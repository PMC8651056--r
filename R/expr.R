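## Boolean / rate expression grammar, parser and evaluator.
##
## An expression AST is a plain list tree. Leaves:
##   list(op = "node",  name = <chr>)            -- reference to a network node
##   list(op = "param", name = <chr>)            -- "$name" parameter reference
##   list(op = "const", value = <dbl>)           -- numeric literal
## Internal nodes:
##   not, neg (unary: x); and, or, xor, add, sub, mul, div (binary: lhs, rhs);
##   ifelse (cond, yes, no).
##
## Precedence (loosest to tightest): ?: < | < ^ < & < +- < */ < ! - < atom.
## Both symbolic (!, &, |, ^) and word (NOT, AND, OR, XOR, case-insensitive)
## operators are accepted on input; serialization is always symbolic.
##
## Boolean context is pure logic plus the bare literals 0 and 1 (the BoolNet
## constant-rule dialect); any other literal, arithmetic or ternary is a
## rate-only construct and rejected.

.TOKEN_RE <- paste0(
  "(?<ws>\\s+)",
  "|(?<num>[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?|\\.[0-9]+([eE][+-]?[0-9]+)?)",
  "|(?<param>\\$[A-Za-z_][A-Za-z0-9_.]*)",
  "|(?<ident>[A-Za-z_][A-Za-z0-9_.]*)",
  "|(?<op>[!&|^?:+*/()-])"
)

.tokenize <- function(text) {
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    m <- regexpr(.TOKEN_RE, substr(text, pos, n), perl = TRUE)
    if (m != 1L)
      stop(sprintf("syntax error at position %d: unexpected character '%s'",
                   pos, substr(text, pos, pos)), call. = FALSE)
    len <- attr(m, "match.length")
    tok <- substr(text, pos, pos + len - 1L)
    if (!grepl("^\\s", tok)) {
      type <-
        if (grepl("^[0-9.]", tok)) "num"
        else if (startsWith(tok, "$")) "param"
        else if (grepl("^[A-Za-z_]", tok)) {
          up <- toupper(tok)
          if (up %in% c("NOT", "AND", "OR", "XOR")) up else "ident"
        } else tok
      tokens[[length(tokens) + 1L]] <- list(type = type, text = tok, pos = pos)
    }
    pos <- pos + len
  }
  tokens
}

## Recursive-descent parser over a token stream held in a mutable environment.
.parserState <- function(tokens, text) {
  e <- new.env(parent = emptyenv())
  e$tokens <- tokens
  e$i <- 1L
  e$text <- text
  e
}

.peek <- function(ps) if (ps$i <= length(ps$tokens)) ps$tokens[[ps$i]] else NULL

.advance <- function(ps) {
  tok <- .peek(ps)
  ps$i <- ps$i + 1L
  tok
}

.expect <- function(ps, type) {
  tok <- .peek(ps)
  if (is.null(tok))
    stop(sprintf("syntax error at position %d: expected '%s', got end of input",
                 nchar(ps$text) + 1L, type), call. = FALSE)
  if (tok$type != type)
    stop(sprintf("syntax error at position %d: expected '%s', got '%s'",
                 tok$pos, type, tok$text), call. = FALSE)
  .advance(ps)
}

.parseTernary <- function(ps) {
  cond <- .parseOr(ps)
  tok <- .peek(ps)
  if (!is.null(tok) && tok$type == "?") {
    .advance(ps)
    yes <- .parseTernary(ps)
    .expect(ps, ":")
    no <- .parseTernary(ps)
    return(list(op = "ifelse", cond = cond, yes = yes, no = no))
  }
  cond
}

.binaryLoop <- function(ps, nextFn, opMap) {
  lhs <- nextFn(ps)
  repeat {
    tok <- .peek(ps)
    if (is.null(tok) || is.null(opMap[[tok$type]])) return(lhs)
    .advance(ps)
    rhs <- nextFn(ps)
    lhs <- list(op = opMap[[tok$type]], lhs = lhs, rhs = rhs)
  }
}

.parseOr  <- function(ps) .binaryLoop(ps, .parseXor, list("|" = "or", "OR" = "or"))
.parseXor <- function(ps) .binaryLoop(ps, .parseAnd, list("^" = "xor", "XOR" = "xor"))
.parseAnd <- function(ps) .binaryLoop(ps, .parseAdd, list("&" = "and", "AND" = "and"))
.parseAdd <- function(ps) .binaryLoop(ps, .parseMul, list("+" = "add", "-" = "sub"))
.parseMul <- function(ps) .binaryLoop(ps, .parseUnary, list("*" = "mul", "/" = "div"))

.parseUnary <- function(ps) {
  tok <- .peek(ps)
  if (!is.null(tok) && (tok$type == "!" || tok$type == "NOT")) {
    .advance(ps)
    return(list(op = "not", x = .parseUnary(ps)))
  }
  if (!is.null(tok) && tok$type == "-") {
    .advance(ps)
    return(list(op = "neg", x = .parseUnary(ps)))
  }
  .parseAtom(ps)
}

.parseAtom <- function(ps) {
  tok <- .peek(ps)
  if (is.null(tok))
    stop(sprintf("syntax error at position %d: unexpected end of input",
                 nchar(ps$text) + 1L), call. = FALSE)
  if (tok$type == "num") {
    .advance(ps)
    return(list(op = "const", value = as.numeric(tok$text)))
  }
  if (tok$type == "param") {
    .advance(ps)
    return(list(op = "param", name = substring(tok$text, 2L)))
  }
  if (tok$type == "ident") {
    .advance(ps)
    return(list(op = "node", name = tok$text))
  }
  if (tok$type == "(") {
    .advance(ps)
    inner <- .parseTernary(ps)
    .expect(ps, ")")
    return(inner)
  }
  stop(sprintf("syntax error at position %d: unexpected '%s'",
               tok$pos, tok$text), call. = FALSE)
}

.checkBooleanContext <- function(ast, text) {
  walk <- function(a) {
    if (a$op == "const") {
      if (!(a$value %in% c(0, 1)))
        stop(sprintf("numeric literal %s is not allowed in a boolean expression: '%s'",
                     format(a$value), text), call. = FALSE)
    } else if (a$op %in% c("add", "sub", "mul", "div", "neg", "ifelse")) {
      stop(sprintf("operator '%s' is only allowed in rate expressions: '%s'",
                   a$op, text), call. = FALSE)
    } else if (a$op %in% c("not", "and", "or", "xor")) {
      for (nm in setdiff(names(a), "op")) walk(a[[nm]])
    }
    invisible(NULL)
  }
  walk(ast)
  invisible(ast)
}

#' Parse a Boolean or rate expression
#'
#' Parses the expression dialect used in node definitions: node names,
#' `$param` references, `! & | ^` (or word forms `NOT AND OR XOR`), and — in
#' rate context only — numeric literals, `+ - * /` and the ternary
#' `cond ? a : b`. Precedence is `NOT > */ > +- > AND > XOR > OR > ?:`, with
#' parentheses overriding.
#'
#' @param text Expression string (non-empty).
#' @param context Either `"boolean"` (pure logic; the literals `0` and `1`
#'   are also accepted, matching BoolNet constant rules) or `"rate"`
#'   (arithmetic, literals and ternary allowed).
#' @return An expression AST (a nested list; see [freeVariables()],
#'   [evaluateExpression()], [serializeExpression()]).
#' @examples
#' parseExpression("A & !B", "boolean")
#' parseExpression("$ku * (C | D)", "rate")
#' @export
parseExpression <- function(text, context = c("boolean", "rate")) {
  context <- match.arg(context)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("expression text must be a non-empty string", call. = FALSE)
  ps <- .parserState(.tokenize(text), text)
  ast <- .parseTernary(ps)
  tok <- .peek(ps)
  if (!is.null(tok))
    stop(sprintf("syntax error at position %d: unexpected '%s'",
                 tok$pos, tok$text), call. = FALSE)
  if (context == "boolean") .checkBooleanContext(ast, text)
  ast
}

#' Evaluate an expression AST
#'
#' @param ast Expression AST from [parseExpression()].
#' @param state Named vector/list mapping node names to 0/1.
#' @param params Named vector/list mapping parameter names to numeric values.
#' @param context `"boolean"` coerces the result to 0/1; `"rate"` returns the
#'   numeric value and requires it to be finite and non-negative.
#' @return A numeric scalar.
#' @export
evaluateExpression <- function(ast, state = list(), params = list(),
                               context = c("boolean", "rate")) {
  context <- match.arg(context)
  state <- unlist(state)
  params <- unlist(params)
  ev <- function(a) {
    switch(a$op,
      const = a$value,
      node = {
        if (is.null(state) || is.na(match(a$name, names(state))))
          stop(sprintf("unknown node '%s' in expression", a$name), call. = FALSE)
        as.numeric(state[[a$name]])
      },
      param = {
        if (is.null(params) || is.na(match(a$name, names(params))))
          stop(sprintf("unknown parameter '$%s' in expression", a$name), call. = FALSE)
        as.numeric(params[[a$name]])
      },
      not = as.numeric(ev(a$x) == 0),
      neg = -ev(a$x),
      and = as.numeric(ev(a$lhs) != 0 && ev(a$rhs) != 0),
      or  = as.numeric(ev(a$lhs) != 0 || ev(a$rhs) != 0),
      xor = as.numeric((ev(a$lhs) != 0) != (ev(a$rhs) != 0)),
      add = ev(a$lhs) + ev(a$rhs),
      sub = ev(a$lhs) - ev(a$rhs),
      mul = ev(a$lhs) * ev(a$rhs),
      div = {
        d <- ev(a$rhs)
        if (d == 0) stop("division by zero in rate expression", call. = FALSE)
        ev(a$lhs) / d
      },
      ifelse = if (ev(a$cond) != 0) ev(a$yes) else ev(a$no),
      stop(sprintf("unknown AST operator '%s'", a$op), call. = FALSE))
  }
  v <- ev(ast)
  if (context == "boolean") return(as.numeric(v != 0))
  if (!is.finite(v) || v < 0)
    stop(sprintf("rate expression evaluated to a non-finite or negative value (%s)",
                 format(v)), call. = FALSE)
  v
}

#' Node names referenced by an expression
#'
#' @param ast Expression AST.
#' @return Character vector of distinct node names (parameters excluded).
#' @export
freeVariables <- function(ast) {
  acc <- character(0)
  walk <- function(a) {
    if (a$op == "node") acc <<- c(acc, a$name)
    else for (nm in setdiff(names(a), c("op", "name", "value"))) walk(a[[nm]])
  }
  walk(ast)
  unique(acc)
}

.PRECEDENCE <- c(ifelse = 1, or = 2, xor = 3, and = 4, add = 5, sub = 5,
                 mul = 6, div = 6, not = 7, neg = 7, node = 9, param = 9,
                 const = 9)

#' Serialize an expression AST to canonical text
#'
#' Writes the symbolic-operator form accepted by [parseExpression()];
#' parse -> serialize -> parse yields an evaluation-identical tree.
#'
#' @param ast Expression AST.
#' @return A single string.
#' @export
serializeExpression <- function(ast) {
  wrap <- function(child, parentPrec, strict = FALSE) {
    s <- ser(child)
    cp <- .PRECEDENCE[[child$op]]
    if (cp < parentPrec || (strict && cp == parentPrec)) paste0("(", s, ")") else s
  }
  ser <- function(a) {
    p <- .PRECEDENCE[[a$op]]
    switch(a$op,
      node = a$name,
      param = paste0("$", a$name),
      const = format(a$value, scientific = FALSE, trim = TRUE),
      not = paste0("!", wrap(a$x, p)),
      neg = paste0("-", wrap(a$x, p)),
      and = paste(wrap(a$lhs, p), "&", wrap(a$rhs, p, strict = TRUE)),
      or  = paste(wrap(a$lhs, p), "|", wrap(a$rhs, p, strict = TRUE)),
      xor = paste(wrap(a$lhs, p), "^", wrap(a$rhs, p, strict = TRUE)),
      add = paste(wrap(a$lhs, p), "+", wrap(a$rhs, p, strict = TRUE)),
      sub = paste(wrap(a$lhs, p), "-", wrap(a$rhs, p, strict = TRUE)),
      mul = paste(wrap(a$lhs, p), "*", wrap(a$rhs, p, strict = TRUE)),
      div = paste(wrap(a$lhs, p), "/", wrap(a$rhs, p, strict = TRUE)),
      ifelse = paste0(wrap(a$cond, 2), " ? ", ser(a$yes), " : ", ser(a$no)))
  }
  ser(ast)
}

## Constant-fold an AST where possible; used by the Booleanizer to keep
## generated logic readable. Only folds pure-constant subtrees and trivial
## identities (x & 1, x | 0, !1, ...).
.simplifyAst <- function(a) {
  isConst <- function(x) x$op == "const"
  cv <- function(x) x$value
  switch(a$op,
    node = , param = , const = a,
    not = {
      x <- .simplifyAst(a$x)
      if (isConst(x)) list(op = "const", value = as.numeric(cv(x) == 0))
      else list(op = "not", x = x)
    },
    and = {
      l <- .simplifyAst(a$lhs); r <- .simplifyAst(a$rhs)
      if (isConst(l)) { if (cv(l) == 0) list(op = "const", value = 0) else r }
      else if (isConst(r)) { if (cv(r) == 0) list(op = "const", value = 0) else l }
      else list(op = "and", lhs = l, rhs = r)
    },
    or = {
      l <- .simplifyAst(a$lhs); r <- .simplifyAst(a$rhs)
      if (isConst(l)) { if (cv(l) != 0) list(op = "const", value = 1) else r }
      else if (isConst(r)) { if (cv(r) != 0) list(op = "const", value = 1) else l }
      else list(op = "or", lhs = l, rhs = r)
    },
    {
      out <- a
      for (nm in setdiff(names(a), c("op", "name", "value")))
        out[[nm]] <- .simplifyAst(a[[nm]])
      out
    })
}
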