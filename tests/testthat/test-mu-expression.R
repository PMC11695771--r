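test_that("parsing, formatting and evaluation round-trip at many mu", {
  cases <- c("-mu/65.0", "3.5", "mu", "1e-3*mu + 2", "(1 - mu/2)/(3 + mu)",
             "-(mu*mu)/10")
  grid <- c(0, 0.01, 0.1, 0.5, 1, 2)
  for (txt in cases) {
    e <- parse_mu_expression(txt)
    e2 <- parse_mu_expression(format(e))
    expect_equal(eval_mu(e, grid), eval_mu(e2, grid), info = txt)
  }
  expect_equal(eval_mu(parse_mu_expression("-mu/65.0"), 65), -1)
  expect_equal(eval_mu(parse_mu_expression("3.5"), c(0, 1)), c(3.5, 3.5))
})

test_that("invalid expressions are rejected with informative errors", {
  expect_error(parse_mu_expression("nu + 1"), "unknown symbol")
  expect_error(parse_mu_expression("sin(mu)"), "not allowed")
  expect_error(parse_mu_expression("mu/0"), "literal zero")
  expect_error(parse_mu_expression("mu +"), "cannot parse")
})

test_that("pole detection flags denominators crossing zero on the interval", {
  expect_false(mu_expr_finite_on(parse_mu_expression("mu/(mu - 0.5)"), 1))
  expect_true(mu_expr_finite_on(parse_mu_expression("mu/(mu + 0.5)"), 1))
  expect_true(mu_expr_finite_on(parse_mu_expression("-mu/65"), 2))
  expect_true(mu_expr_finite_on(2.5, 2))
})

test_that("constant expressions collapse to numerics on deserialization", {
  expect_identical(forespore:::coef_from_json("2 + 1"), 3)
  e <- forespore:::coef_from_json("-mu/10")
  expect_s3_class(e, "mu_expr")
  expect_identical(forespore:::coef_to_json(e), "-mu/10")
})
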