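or2 <- function() expression_to_rule(parse_boolean_expression("A || B"), c("A", "B"))
id1 <- function() update_rule("Y", "X", c(0L, 1L))  # B(x) = x

test_that("hill function: half-maximality, endpoints, hand values", {
  for (n in 1:16) for (k in seq(0.1, 0.9, by = 0.1)) {
    expect_equal(hill(k, n = n, k = k), 0.5)
    expect_equal(hill(0, n = n, k = k), 0)
  }
  expect_equal(hill(1, n = 2, k = 0.5), 0.8)
  expect_error(hill(1.2, n = 2, k = 0.5), "\\[0,1\\]")
  expect_error(hill_parameters(n = 0.5), ">= 1")
  expect_error(hill_parameters(k = 1), "\\(0,1\\)")
})

test_that("boolecube: corner exactness and interior interpolation", {
  r <- or2()
  expect_equal(boolecube(r, c(1, 0)), 1)
  expect_equal(boolecube(r, c(0, 0)), 0)
  expect_equal(boolecube(r, c(0.5, 0.5)), 0.75)  # corner sum 0/4+1/4+1/4+1/4
  expect_equal(boolecube(update_rule("C", character(0), 1L), numeric(0)), 1)
  expect_error(boolecube(r, c(0.5)), "inputs")
  expect_error(boolecube(r, c(0.5, 1.5)), "\\[0,1\\]")
})

test_that("hillcube composes the interpolation with Hill transforms", {
  cr <- continuous_rule(id1(), hill_parameters(n = 4, k = 0.5), "hillcube")
  expect_equal(hillcube(cr, 0.25), 0.25^4 / (0.25^4 + 0.5^4))
  # cross-check against the explicit corner-sum oracle
  x <- 0.37
  h <- hill(x, n = 4, k = 0.5)
  expect_equal(hillcube(cr, x), 0 * (1 - h) + 1 * h)

  # at xbar_j = k_j every Hill term is 0.5: equals boolecube at (0.5, ...)
  set.seed(3)
  for (rep in 1:20) {
    d <- sample(1:4, 1)
    r <- random_rule(d)
    ks <- runif(d, 0.2, 0.8)
    ps <- lapply(ks, function(k) hill_parameters(n = sample(1:8, 1), k = k))
    cr <- continuous_rule(r, ps, "hillcube")
    expect_equal(hillcube(cr, ks), boolecube(r, rep(0.5, d)))
  }
  # d = 0 constant rule
  cr0 <- continuous_rule(update_rule("C", character(0), 1L), list(), "hillcube")
  expect_equal(hillcube(cr0, numeric(0)), 1)
})

test_that("normalized hillcube is exact at corners and scales Hill terms", {
  cr <- continuous_rule(id1(), hill_parameters(n = 2, k = 0.5), "hillcubenorm")
  expect_equal(normalized_hillcube(cr, 0.5), 0.5 / 0.8)  # hill(0.5)/hill(1)
  or_cr <- continuous_rule(or2(), hill_parameters(), "hillcubenorm")
  expect_equal(normalized_hillcube(or_cr, c(1, 1)), 1)

  set.seed(23)
  for (rep in 1:200) {
    d <- sample(0:4, 1)
    r <- random_rule(d)
    ps <- replicate(d, hill_parameters(n = runif(1, 1, 10), k = runif(1, 0.1, 0.9)),
                    simplify = FALSE)
    cr <- continuous_rule(r, ps, "hillcubenorm")
    cm <- boolcube:::corner_matrix(d)
    for (row in seq_len(nrow(cm))) {
      corner <- as.numeric(cm[row, ])
      expect_equal(normalized_hillcube(cr, corner), r$table[[row]])
      expect_equal(boolecube(r, corner), r$table[[row]])
    }
  }
})

test_that("boolecube is multilinear: zero second differences in each coordinate", {
  set.seed(31)
  for (rep in 1:30) {
    d <- sample(1:4, 1)
    r <- random_rule(d)
    x <- runif(d)
    for (j in seq_len(d)) {
      f <- function(v) { y <- x; y[j] <- v; boolecube(r, y) }
      expect_equal(f(0.2) - 2 * f(0.5) + f(0.8), 0, tolerance = 1e-12)
    }
  }
})

test_that("all three transforms map [0,1]^d into [0,1]", {
  set.seed(37)
  for (rep in 1:50) {
    d <- sample(0:4, 1)
    r <- random_rule(d)
    ps <- replicate(d, hill_parameters(n = runif(1, 1, 12), k = runif(1, 0.1, 0.9)),
                    simplify = FALSE)
    x <- runif(d)
    vals <- c(boolecube(r, x),
              hillcube(continuous_rule(r, ps, "hillcube"), x),
              normalized_hillcube(continuous_rule(r, ps, "hillcubenorm"), x))
    expect_true(all(vals >= 0 & vals <= 1))
    # hillcube never reaches 1 unless the table is identically 1
    if (d > 0 && any(r$table == 0L)) expect_lt(vals[[2]], 1)
  }
})

test_that("monotone Boolean inputs give monotone cube responses", {
  set.seed(43)
  grid <- seq(0, 1, by = 0.2)
  tried <- 0L
  while (tried < 15L) {
    d <- sample(1:3, 1)
    r <- random_rule(d)
    cm <- boolcube:::corner_matrix(d)
    for (j in seq_len(d)) {
      lo <- which(cm[, j] == 0L)
      hi <- which(cm[, j] == 1L)
      if (!all(r$table[hi] >= r$table[lo])) next  # not nondecreasing in j
      tried <- tried + 1L
      ps <- replicate(d, hill_parameters(n = 3, k = 0.5), simplify = FALSE)
      others <- runif(d)
      for (method in c("boolecube", "hillcube", "hillcubenorm")) {
        vals <- vapply(grid, function(v) {
          x <- others; x[j] <- v
          switch(method,
                 boolecube = boolecube(r, x),
                 hillcube = hillcube(continuous_rule(r, ps, "hillcube"), x),
                 hillcubenorm = normalized_hillcube(continuous_rule(r, ps, "hillcubenorm"), x))
        }, numeric(1))
        expect_true(all(diff(vals) >= -1e-12))
      }
    }
  }
})

test_that("steep normalized hillcube approaches the Boolean step function", {
  set.seed(47)
  for (rep in 1:20) {
    d <- sample(1:3, 1)
    r <- random_rule(d)
    ps <- replicate(d, hill_parameters(n = 200, k = 0.5), simplify = FALSE)
    cr <- continuous_rule(r, ps, "hillcubenorm")
    pts <- boolcube:::corner_matrix(d)
    for (row in seq_len(nrow(pts))) {
      x <- ifelse(pts[row, ] == 1L, 0.9, 0.1)
      expect_equal(normalized_hillcube(cr, x), r$table[[row]],
                   tolerance = 0.01)
    }
  }
})
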