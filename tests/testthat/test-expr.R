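test_that("parser builds the expected trees with documented precedence", {
  ast <- parseExpression("A & !B", "boolean")
  expect_equal(ast$op, "and")
  expect_equal(ast$lhs, list(op = "node", name = "A"))
  expect_equal(ast$rhs, list(op = "not", x = list(op = "node", name = "B")))

  rate <- parseExpression("$ku * (C | D)", "rate")
  expect_equal(rate$op, "mul")
  expect_equal(rate$lhs, list(op = "param", name = "ku"))
  expect_equal(rate$rhs$op, "or")

  ## NOT > AND > XOR > OR, ternary lowest
  st <- c(A = 1, B = 1, C = 0, D = 1)
  expect_equal(evaluateExpression(parseExpression("A | B ^ C & !D"), st), 1)
  expect_equal(evaluateExpression(parseExpression("(A | B) ^ (C & !D)"), st), 1)
  expect_equal(
    evaluateExpression(parseExpression("A | B ? 2 : 3", "rate"), st, context = "rate"),
    2)

  ## word operators are case-insensitive aliases
  expect_equal(
    evaluateExpression(parseExpression("A AND not B or C Xor D"), st),
    evaluateExpression(parseExpression("A & !B | C ^ D"), st))
})

test_that("malformed input and context violations are rejected", {
  expect_error(parseExpression("A &", "boolean"), "syntax error")
  expect_error(parseExpression("", "boolean"), "non-empty")
  expect_error(parseExpression("A @ B", "boolean"), "position 3")
  expect_error(parseExpression("(A | B", "boolean"), "expected '\\)'")

  ## rate-only constructs in boolean context
  expect_error(parseExpression("A + B", "boolean"), "rate expressions")
  expect_error(parseExpression("A ? 1 : 0", "boolean"), "rate expressions")
  expect_error(parseExpression("2.5", "boolean"), "literal")
  ## but the BoolNet constant literals pass
  expect_equal(evaluateExpression(parseExpression("1", "boolean")), 1)
  expect_equal(evaluateExpression(parseExpression("0", "boolean")), 0)
})

test_that("evaluation handles references, ternary, arithmetic and errors", {
  expect_equal(evaluateExpression(parseExpression("!A"), c(A = 0)), 1)
  expect_equal(
    evaluateExpression(parseExpression("A ? 2.0 : 0.5", "rate"), c(A = 1),
                       context = "rate"), 2.0)
  expect_equal(
    evaluateExpression(parseExpression("$k * B", "rate"), c(B = 1),
                       c(k = 3), context = "rate"), 3)
  expect_error(evaluateExpression(parseExpression("X"), c(A = 1)), "unknown node 'X'")
  expect_error(
    evaluateExpression(parseExpression("$z", "rate"), c(A = 1), context = "rate"),
    "unknown parameter")
  expect_error(
    evaluateExpression(parseExpression("$k / 0", "rate"), params = c(k = 1),
                       context = "rate"), "division by zero")
  expect_error(
    evaluateExpression(parseExpression("0 - $k", "rate"), params = c(k = 1),
                       context = "rate"), "negative")
})

test_that("freeVariables returns exactly the node references", {
  expect_setequal(freeVariables(parseExpression("A & (B | A)")), c("A", "B"))
  expect_length(freeVariables(parseExpression("$k", "rate")), 0)
  expect_setequal(freeVariables(parseExpression("(A ? 1 : 0) * !C", "rate")),
                  c("A", "C"))
})

test_that("parse -> serialize -> parse is an evaluation fixpoint and the evaluator matches a brute-force oracle", {
  set.seed(421)
  vars <- c("A", "B", "C", "D", "E", "F")
  for (rep in 1:40) {
    text <- randomLogicText(vars, depth = 3)
    ast <- parseExpression(text, "boolean")
    ast2 <- parseExpression(serializeExpression(ast), "boolean")
    used <- freeVariables(ast)
    if (length(used) == 0) used <- vars[1]
    for (st in allAssignments(used)) {
      v <- evaluateExpression(ast, st)
      expect_identical(v, evaluateExpression(ast2, st))
      expect_identical(v, oracleEvalLogic(text, st))
    }
  }
})
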