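test_that("integration matches the closed-form solution of a linear rule", {
  m <- parse_boolean_equations("X = 1")
  vf <- build_vector_field(m, "boolecube")
  tr <- integrate_field(vf, 0, t_end = 1)
  expect_equal(tr$time[[1L]], 0)
  expect_equal(tr$time[[length(tr$time)]], 1)
  expect_equal(unname(tr$states[nrow(tr$states), ]), 1 - exp(-1),
               tolerance = 1e-5)
  # x(t) = 1 - e^-t along the whole trajectory
  expect_equal(unname(tr$states[, 1L]), 1 - exp(-tr$time), tolerance = 1e-5)

  # constant model stays put
  m_in <- parse_boolean_equations("B = A")
  vf_in <- build_vector_field(m_in, "hillcubenorm")
  tr2 <- integrate_field(vf_in, c(0.4, 0.4), t_end = 5)
  expect_equal(unname(tr2$states[nrow(tr2$states), "A"]), 0.4)

  expect_error(integrate_field(vf, 2, t_end = 1), "\\[0,1\\]")
  expect_error(integrate_field(vf, 0, t_end = -1), "t_end")
})

test_that("chaining two half-interval integrations reproduces the endpoint", {
  vf <- build_vector_field(or_switch(), "hillcubenorm")
  x0 <- c(0.35, 0.65)
  full <- integrate_field(vf, x0, 10, times = c(0, 10))$states[2L, ]
  half <- integrate_field(vf, x0, 5, times = c(0, 5))$states[2L, ]
  again <- integrate_field(vf, half, 5, times = c(0, 5))$states[2L, ]
  expect_equal(again, full, tolerance = 1e-6)
})

test_that("toggle-switch basins behave as expected", {
  vf <- build_vector_field(or_switch(), "hillcubenorm")
  # starting clearly in the X-dominant basin
  tr <- integrate_field(vf, c(0.9, 0.1), t_end = 50, times = c(0, 50))
  expect_lt(max(abs(tr$states[2L, ] - c(1, 0))), 1e-3)

  sss <- find_stable_states(vf, phase_grid(11))
  expect_equal(nrow(stable_states(sss)), 3L)
  # representatives are equilibria to high accuracy
  for (r in seq_len(nrow(sss$representatives))) {
    expect_lt(max(abs(vf$f(sss$representatives[r, ]))), 1e-5)
  }
  # basin symmetry under coordinate swap (model is swap-symmetric)
  grid <- phase_grid(11)
  labs <- sss$labels
  reps <- sss$representatives
  for (i in seq_len(nrow(grid))) {
    j <- which(grid[, 1] == grid[i, 2] & grid[, 2] == grid[i, 1])
    expect_equal(unname(reps[labs[[i]], c(2, 1)]), unname(reps[labs[[j]], ]),
                 tolerance = 1e-6)
  }
  # basins partition the grid
  expect_true(all(!is.na(labs)))
})

test_that("every point of a neutral field is its own equilibrium", {
  m <- parse_boolean_equations("X = X")
  vf <- build_vector_field(m, "boolecube")
  initials <- matrix(seq(0.1, 0.9, by = 0.2), ncol = 1)
  sss <- find_stable_states(vf, initials, t_end = 5)
  expect_equal(nrow(sss$representatives), nrow(initials))
  expect_true(all(sss$stable))  # neutral directions count as stable
  expect_equal(unname(sss$representatives[, 1L]), as.numeric(initials),
               tolerance = 1e-6)
})

test_that("activity patterns threshold strictly", {
  expect_equal(unname(activity_pattern(c(0.9, 0.1), 0.5)), c(1L, 0L))
  expect_equal(unname(activity_pattern(c(0.5, 0.5), 0.5)), c(0L, 0L))
  expect_error(activity_pattern(c(0.2, 0.4), 0), "\\(0,1\\)")

  # per-species thresholds from mean incoming k reduce to the global 0.5
  m <- or_switch()
  p <- default_parameters(m)
  th <- species_thresholds(m, p)
  expect_equal(unname(th), c(0.5, 0.5))
  x <- c(0.63, 0.41)
  expect_equal(activity_pattern(x, th), activity_pattern(x, 0.5))
  # heterogeneous k moves the thresholds
  p2 <- set_hill(p, "X", "X", k = 0.1)
  expect_equal(unname(species_thresholds(m, p2)["X"]), mean(c(0.1, 0.5)))
})

test_that("pattern maintenance distinguishes stabilizing from contradicting models", {
  # rules that fix the pattern: corner-stable under normalized conversion
  m_fix <- parse_boolean_equations("A = A && ~B\nB = B && ~A")
  expect_true(pattern_is_maintained(m_fix, c(1, 0)))
  expect_true(pattern_is_maintained(m_fix, c(0, 1)))
  # a rule forcing the opposite value breaks maintenance
  m_bad <- parse_boolean_equations("A = 0\nB = B && ~A")
  expect_false(pattern_is_maintained(m_bad, c(1, 0)))
  expect_error(pattern_is_maintained(m_fix, c(1, 0, 1)), "species")
})

test_that("the six-compartment boundary pattern is maintained by curated networks only", {
  pattern <- mhb_pattern()
  spec <- mhb_spec(6)
  verdicts <- screen_models(mhb_valid_models(), pattern, spec = spec)
  expect_true(all(verdicts))

  # the boundary pattern is a Boolean fixed point of the expanded model
  ex <- expand_multicompartment(mhb_model(), spec)
  flat <- as.vector(t(pattern))
  expect_equal(unname(synchronous_update(ex, flat)), as.integer(flat))

  # an ensemble of random 4-species networks essentially never keeps it
  models <- lapply(1:60, function(i) {
    random_boolean_model(4, 3, seed = 1000 + i,
                         species = colnames(pattern))
  })
  rand_verdicts <- screen_models(models, pattern, spec = spec)
  expect_lt(mean(rand_verdicts), 0.1)
})

test_that("csv exports write the documented tables", {
  vf <- build_vector_field(or_switch(), "hillcubenorm")
  tr <- integrate_field(vf, c(0.9, 0.1), 5)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp), add = TRUE)
  trajectory_to_csv(tr, tmp)
  df <- utils::read.csv(tmp)
  expect_equal(names(df), c("time", "X", "Y"))
  expect_equal(nrow(df), length(tr$time))

  grid <- phase_grid(5)
  sss <- find_stable_states(vf, grid)
  tmp2 <- tempfile(fileext = ".csv")
  tmp3 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tmp2, tmp3)), add = TRUE)
  stable_states_to_csv(sss, tmp2, initials = grid, basins_path = tmp3)
  reps <- utils::read.csv(tmp2)
  expect_equal(nrow(reps), nrow(sss$representatives))
  basins <- utils::read.csv(tmp3)
  expect_equal(nrow(basins), nrow(grid))
  ss_mat <- boolean_steady_states(or_switch())
  tmp4 <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp4), add = TRUE)
  states_to_csv(ss_mat, tmp4)
  expect_equal(unname(as.matrix(utils::read.csv(tmp4))), unname(ss_mat))
})
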