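test_that("baseline parameters validate with no violations and the expected
           reduced coefficients", {
  rep <- validate_parameters(baseline_parameters(), strict = TRUE)
  expect_true(rep$valid)
  expect_length(rep$violations, 0)
  # a = U1-U2+P2-P1+S1-S2, b = U2+S2-P2, c = R1-R2+P1-S1p+C2-C1,
  # d = R2+S1p-C2, each frozen from hand arithmetic on the baseline values
  expect_equal(unname(rep$coefficients),
               c(0.37, -0.2, 0.63, -0.2), tolerance = 1e-12)
})

test_that("strict validation names each violated ordering", {
  p <- baseline_with(U1 = 1.3)  # now U1 > U2
  expect_error(validate_parameters(p, strict = TRUE), "U2 > U1")
  rep <- validate_parameters(p, strict = FALSE)
  expect_false(rep$valid)
  expect_identical(rep$violations, "U2 > U1")
  # multiple violations are all reported
  p2 <- baseline_with(U1 = 1.3, S1 = 1.7)
  expect_error(validate_parameters(p2), "U2 > U1.*S2 > S1")
})

test_that("constructor and coercion enforce the type invariants", {
  expect_error(game_parameters(U1 = -1, U2 = 1.2, P1 = 2.23, P2 = 3,
                               R1 = 2.2, R2 = 2.42, C1 = 4, C2 = 4.21,
                               S1 = 1.4, S2 = 1.6, S1p = 1.59),
               "nonnegative.*U1")
  expect_error(as_game_parameters(list(U1 = 1)), "missing parameter")
  full <- unclass(baseline_parameters())
  expect_error(as_game_parameters(c(full, list(bogus = 1))),
               "unknown parameter")
})

test_that("payoff matrix matches the four strategy-profile cells", {
  pt <- payoff_matrix(baseline_parameters())
  # frozen by substituting the baseline into the cell formulas
  expect_equal(unname(pt$social["participation", ]), c(0.17, -0.2),
               tolerance = 1e-12)
  expect_equal(unname(pt$social["nonparticipation", ]), c(0, 0))
  expect_equal(unname(pt$health["participation", ]), c(0.43, 0),
               tolerance = 1e-12)
  expect_equal(unname(pt$health["nonparticipation", ]), c(-0.2, 0),
               tolerance = 1e-12)

  zero <- game_parameters(U1 = 0, U2 = 0, P1 = 0, P2 = 0, R1 = 0, R2 = 0,
                          C1 = 0, C2 = 0, S1 = 0, S2 = 0, S1p = 0)
  ptz <- payoff_matrix(zero)
  expect_true(all(ptz$social == 0) && all(ptz$health == 0))

  # the mutual nonparticipation cell is (0, 0) for any parameters
  set.seed(11)
  for (i in 1:20) {
    pt <- payoff_matrix(random_strict_params())
    expect_identical(unname(pt$social["nonparticipation",
                                      "nonparticipation"]), 0)
    expect_identical(unname(pt$health["nonparticipation",
                                      "nonparticipation"]), 0)
  }
})

test_that("expected payoffs follow the convex-combination forms", {
  p <- baseline_parameters()
  e <- expected_payoffs(p, 0.5, 0.5)
  expect_equal(e$E11, -0.015, tolerance = 1e-12)
  expect_equal(e$E21, 0.115, tolerance = 1e-12)
  expect_identical(e$E12, 0)
  expect_identical(e$E22, 0)
  expect_equal(e$Ebar1, 0.5 * e$E11)
  expect_equal(e$Ebar2, 0.5 * e$E21)

  # endpoint: y = 1 collapses E11 to the bilateral cell payoff
  set.seed(12)
  for (i in 1:20) {
    q <- random_strict_params()
    e1 <- expected_payoffs(q, runif(1), 1)
    expect_equal(e1$E11, q$U1 + q$S1 - q$P1, tolerance = 1e-12)
  }
  expect_error(expected_payoffs(p, 1.2, 0.5), "unit square")
})

test_that("replicator field examples and corner stationarity", {
  p <- baseline_parameters()
  expect_equal(unname(replicator_field(p, 0.5, 0.5)),
               c(-0.00375, 0.02875), tolerance = 1e-12)
  # interior root of both bracket terms
  f <- replicator_field(p, 0.2 / 0.63, 0.2 / 0.37)
  expect_lt(max(abs(f)), 1e-12)
  set.seed(13)
  for (i in 1:20) {
    q <- random_strict_params()
    for (corner in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
      expect_identical(unname(replicator_field(q, corner[1], corner[2])),
                       c(0, 0))
  }
  expect_error(replicator_field(p, -0.1, 0.5), "unit square")
})

test_that("reduced-coefficient and payoff-difference forms of the field
           agree at 1000 random draws", {
  set.seed(14)
  for (i in 1:1000) {
    q <- random_strict_params()
    x <- runif(1); y <- runif(1)
    f <- replicator_field(q, x, y)
    e <- expected_payoffs(q, x, y)
    expect_equal(unname(f),
                 c(x * (1 - x) * (e$E11 - e$E12),
                   y * (1 - y) * (e$E21 - e$E22)),
                 tolerance = 1e-12)
  }
})

test_that("field sign structure follows the bracket terms", {
  set.seed(15)
  for (i in 1:200) {
    q <- random_strict_params()
    co <- reduced_coefficients(q)
    x <- runif(1, 0.01, 0.99); y <- runif(1, 0.01, 0.99)
    f <- replicator_field(q, x, y)
    bx <- co[["a"]] * y + co[["b"]]
    by <- co[["c"]] * x + co[["d"]]
    if (abs(bx) > 1e-12) expect_identical(f[["dxdt"]] > 0, bx > 0)
    if (abs(by) > 1e-12) expect_identical(f[["dydt"]] > 0, by > 0)
  }
})

test_that("equal reduced coefficients imply identical fields", {
  # the published sweeps are pairwise consistent under this identity
  pairs <- list(
    list(baseline_with(U1 = 0.85), baseline_with(S1 = 1.25)),
    list(baseline_with(U1 = 0.90), baseline_with(S1 = 1.30)),
    list(baseline_with(R1 = 2.0), baseline_with(C1 = 4.2)),
    list(baseline_with(R1 = 2.1), baseline_with(C1 = 4.1)))
  set.seed(16)
  for (pr in pairs) {
    expect_equal(reduced_coefficients(pr[[1]]),
                 reduced_coefficients(pr[[2]]), tolerance = 1e-12)
    for (i in 1:25) {
      x <- runif(1); y <- runif(1)
      expect_equal(replicator_field(pr[[1]], x, y),
                   replicator_field(pr[[2]], x, y), tolerance = 1e-12)
    }
  }
})
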