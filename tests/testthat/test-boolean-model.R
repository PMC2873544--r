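test_that("expression tabulation matches brute-force evaluation", {
  # (A || C) && ~(B || C): true only at (1,0,0)
  e <- parse_boolean_expression("(A || C) && ~(B || C)")
  r <- expression_to_rule(e, c("A", "B", "C"))
  expect_equal(which(r$table == 1L), 5L)  # corner (1,0,0) -> index 4+1

  # brute force over random trees
  set.seed(7)
  for (rep in 1:50) {
    vars <- c("A", "B", "C")
    expr <- random_expression(vars)
    r <- expression_to_rule(expr, vars)
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      expect_identical(r$table[[a * 4 + b * 2 + cc + 1]],
                       eval_expression(expr, c(A = a, B = b, C = cc)))
    }
  }

  # OR of two variables: single 0 at (0,0)
  r_or <- expression_to_rule(parse_boolean_expression("A || B"), c("A", "B"))
  expect_equal(r_or$table, c(0L, 1L, 1L, 1L))
  # constant, d = 0
  expect_equal(expression_to_rule(bool_const(1))$table, 1L)
  # errors
  expect_error(expression_to_rule(parse_boolean_expression("A && B"), "A"),
               "missing")
})

test_that("expression -> rule -> sum-of-products round trip is exact", {
  set.seed(11)
  for (rep in 1:200) {
    d <- sample(0:4, 1)
    r <- random_rule(d)
    r2 <- expression_to_rule(rule_to_expression(r), r$inputs, target = r$target)
    expect_identical(r2$table, r$table)
  }
})

test_that("generic logic reproduces 'at least one activator and no inhibitor'", {
  # Fig-style example: shared activator/inhibitor kept in both lists
  e <- build_generic_rule(c("A", "C"), c("B", "C"))
  expect_equal(format(e), "(A || C) && ~(B || C)")

  expect_equal(format(build_generic_rule("A", character(0))), "A")
  e_and <- build_generic_rule(c("A", "B"), "I",
                              logic_operators(activators = "and"))
  r <- expression_to_rule(e_and, c("A", "B", "I"))
  expect_equal(which(r$table == 1L), 7L)  # only (1,1,0)

  expect_error(build_generic_rule(character(0), character(0)), "at least one")

  # default semantics, exhaustively for all set sizes <= 3
  for (m in 0:3) for (n in 0:3) {
    if (m + n == 0) next
    acts <- if (m) paste0("A", 1:m) else character(0)
    inhs <- if (n) paste0("I", 1:n) else character(0)
    e <- build_generic_rule(acts, inhs)
    vars <- c(acts, inhs)
    r <- expression_to_rule(e, vars)
    cm <- boolcube:::corner_matrix(m + n)
    for (row in seq_len(nrow(cm))) {
      a_on <- if (m) any(cm[row, 1:m] == 1L) else FALSE
      i_on <- if (n) any(cm[row, m + 1:n] == 1L) else FALSE
      want <- if (m && n) a_on && !i_on else if (m) a_on else !i_on
      expect_identical(r$table[[row]], as.integer(want))
    }
  }
})

test_that("GraphML import handles plain graphs, hypergraphs and errors", {
  tmp <- withr::local_tempfile(fileext = ".graphml")

  # hypergraph: E = (A && ~B) || C || ~D
  write_test_graphml(
    nodes = c("A", "B", "&", "E", "C", "D"),
    edges = rbind(c(1, 3, "+"), c(2, 3, "-"), c(3, 4, "+"),
                  c(5, 4, "+"), c(6, 4, "-")),
    tmp)
  m <- import_interaction_graph(tmp)
  ref <- parse_boolean_equations("E = (A && ~B) || C || ~D")$rules$E
  got <- expression_to_rule(rule_to_expression(m$rules$E), ref$inputs, "E")
  expect_identical(got$table, ref$table)
  expect_setequal(m$species, c("A", "B", "C", "D", "E"))
  expect_equal(sort(boolcube:::input_species(m)), c("A", "B", "C", "D"))

  # single activating edge: B = A
  write_test_graphml(c("A", "B"), rbind(c(1, 2, "+")), tmp)
  m2 <- import_interaction_graph(tmp)
  expect_equal(m2$rules$B$table, c(0L, 1L))

  # plain graph with defaults: E = (A || C) && ~(B || C)
  write_test_graphml(
    nodes = c("A", "B", "C", "E"),
    edges = rbind(c(1, 4, "+"), c(3, 4, "+"), c(2, 4, "-"), c(3, 4, "-")),
    tmp)
  m3 <- import_interaction_graph(tmp)
  ref3 <- expression_to_rule(build_generic_rule(c("A", "C"), c("B", "C")),
                             c("A", "C", "B"), "E")
  got3 <- expression_to_rule(rule_to_expression(m3$rules$E),
                             c("A", "C", "B"), "E")
  expect_identical(got3$table, ref3$table)

  # '&' node with no output
  write_test_graphml(c("A", "&"), rbind(c(1, 2, "+")), tmp)
  expect_error(import_interaction_graph(tmp), "no outgoing")
  # '&' node with no input
  write_test_graphml(c("A", "&"), rbind(c(2, 1, "+")), tmp)
  expect_error(import_interaction_graph(tmp), "no incoming")
  # cyclic chain of '&' nodes
  write_test_graphml(c("A", "&", "&", "B"),
                     rbind(c(1, 2, "+"), c(2, 3, "+"), c(3, 2, "+"),
                           c(3, 4, "+")),
                     tmp)
  expect_error(import_interaction_graph(tmp), "cyclic")
})

test_that("random models are reproducible and respect their contract", {
  m1 <- random_boolean_model(5, 3, seed = 99)
  m2 <- random_boolean_model(5, 3, seed = 99)
  expect_identical(m1, m2)

  m0 <- random_boolean_model(5, 0, seed = 1)
  expect_true(all(vapply(m0$rules, function(r) length(r$inputs), integer(1)) == 0L))

  expect_error(random_boolean_model(0, 0), "n_species")
  expect_error(random_boolean_model(3, 5), "max_indegree")

  # fraction of constant-valued rules matches the analytic probability:
  # P(constant table | d) = 2/2^(2^d); d uniform on 0..2
  draws <- 1000
  p_const <- mean(c(2 / 2, 2 / 4, 2 / 16))
  set.seed(123)
  n_const <- 0L
  n_rules <- 0L
  for (i in seq_len(draws)) {
    m <- random_boolean_model(4, 2)
    for (r in m$rules) {
      n_rules <- n_rules + 1L
      if (all(r$table == r$table[[1L]])) n_const <- n_const + 1L
    }
  }
  se <- sqrt(p_const * (1 - p_const) / n_rules)
  expect_lt(abs(n_const / n_rules - p_const), 3 * se)
})

test_that("model validation rejects malformed rules", {
  expect_error(update_rule("X", c("A", "A"), c(0L, 1L, 0L, 1L)), "duplicate")
  expect_error(update_rule("X", "A", c(0L, 1L, 1L)), "expected 2\\^1")
  expect_error(update_rule("X", "A", c(0L, 2L)), "0 or 1")
  expect_error(boolean_model("A", list(update_rule("B", character(0), 1L))),
               "not a declared species")
  expect_error(
    boolean_model(c("A", "B"),
                  list(update_rule("A", "B", c(0L, 1L)),
                       update_rule("A", "B", c(1L, 0L)))),
    "duplicate rule")
  big <- paste0("V", 1:20)
  expect_error(
    boolean_model(big, list(update_rule("V1", big[1:17],
                                        rep(0L, 2^17))), max_indegree = 16L),
    "in-degree")
})
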