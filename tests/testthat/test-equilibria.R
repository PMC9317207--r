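test_that("interior equilibrium at the baseline: coordinates, residual,
           trace", {
  p <- baseline_parameters()
  eq <- interior_equilibrium(p)
  expect_true(eq$exists)
  expect_equal(unname(eq$point), c(0.2 / 0.63, 0.2 / 0.37),
               tolerance = 1e-12)
  # the field residual at the fixed point vanishes by construction
  f <- replicator_field(p, eq$point[["x"]], eq$point[["y"]])
  expect_lt(sqrt(sum(f^2)), 1e-10)
  expect_identical(eq$tr, 0)
  expect_equal(eq$det, -0.2 * 0.2 * 0.17 * 0.43 / (0.37 * 0.63),
               tolerance = 1e-10)
  expect_identical(eq$stability, "saddle")
})

test_that("a boundary interior point is reported as non-existent", {
  # C2 - R2 - S1p = 0 puts x* on the boundary of the square
  p <- baseline_with(S1p = 4.21 - 2.42)
  expect_equal(p$C2 - p$R2 - p$S1p, 0)
  eq <- interior_equilibrium(p)
  expect_false(eq$exists)
  expect_identical(eq$stability, "indeterminate")
})

test_that("jacobian closed form: corners and finite-difference oracle", {
  p <- baseline_parameters()
  expect_equal(replicator_jacobian(p, 0, 0), diag(c(-0.2, -0.2)),
               tolerance = 1e-12)
  # the (1-2x), (1-2y) factors kill the diagonal at the midpoint
  set.seed(21)
  for (i in 1:10) {
    q <- random_strict_params()
    expect_equal(diag(replicator_jacobian(q, 0.5, 0.5)), c(0, 0))
  }
  # central finite differences of the field, step 1e-6
  h <- 1e-6
  for (i in 1:50) {
    q <- random_strict_params()
    x <- runif(1, 0.1, 0.9); y <- runif(1, 0.1, 0.9)
    J <- replicator_jacobian(q, x, y)
    fd <- cbind((replicator_field(q, x + h, y) -
                 replicator_field(q, x - h, y)) / (2 * h),
                (replicator_field(q, x, y + h) -
                 replicator_field(q, x, y - h)) / (2 * h))
    expect_equal(J, unname(fd), tolerance = 1e-6)
  }
})

test_that("closed-form det/trace agree with the Jacobian at 1000 random
           parameter sets", {
  set.seed(22)
  corners <- list(O = c(0, 0), A = c(0, 1), B = c(1, 0), C = c(1, 1))
  for (i in 1:1000) {
    q <- random_strict_params()
    nm <- sample(names(corners), 1)
    J <- replicator_jacobian(q, corners[[nm]][1], corners[[nm]][2])
    dt <- det_trace_at(q, nm)
    expect_equal(dt[["det"]], det(J), tolerance = 1e-10)
    expect_equal(dt[["tr"]], sum(diag(J)), tolerance = 1e-10)
  }
})

test_that("closed-form det/trace at E agree with the Jacobian when E
           exists, and tr is exactly 0", {
  set.seed(23)
  for (i in 1:200) {
    q <- random_scenario1_params()
    eq <- interior_equilibrium(q)
    expect_true(eq$exists)  # scenario 1 implies an interior saddle
    J <- replicator_jacobian(q, eq$point[["x"]], eq$point[["y"]])
    dt <- det_trace_at(q, "E")
    expect_equal(dt[["det"]], det(J), tolerance = 1e-10)
    expect_identical(dt[["tr"]], 0)
    expect_lt(abs(sum(diag(J))), 1e-10)
  }
})

test_that("det_trace_at baseline examples and E existence error", {
  p <- baseline_parameters()
  expect_equal(det_trace_at(p, "C"), c(det = 0.0731, tr = -0.6),
               tolerance = 1e-12)
  expect_equal(det_trace_at(p, "O"), c(det = 0.04, tr = -0.4),
               tolerance = 1e-12)
  # U1 + S1 = P1 makes the C determinant vanish
  pz <- baseline_with(P1 = 2.4)
  expect_equal(det_trace_at(pz, "C")[["det"]], 0, tolerance = 1e-12)
  # E must exist to be queried
  p4 <- random_scenario_params(4)
  expect_false(interior_equilibrium(p4)$exists)
  expect_error(det_trace_at(p4, "E"), "does not exist")
})

test_that("classify_point implements the sign rules", {
  expect_identical(classify_point(0.0731, -0.6), "ESS")
  expect_identical(classify_point(-0.05, 0), "saddle")
  expect_identical(classify_point(0.04, 0.4), "unstable")
  expect_identical(classify_point(0, 0.3), "indeterminate")
  expect_identical(classify_point(0.05, 0), "indeterminate")
  expect_identical(classify_point(1e-14, -1), "indeterminate")
})

test_that("baseline regime: scenario 1 with the published stability
           pattern", {
  reg <- classify_regime(baseline_parameters())
  expect_identical(reg$scenario, 1L)
  expect_setequal(reg$ess_points, c("O", "C"))
  expect_identical(reg$care_model_types, "bilateral")
  stab <- vapply(reg$equilibria, `[[`, character(1), "stability")
  expect_identical(unname(stab[c("O", "A", "B", "C", "E")]),
                   c("ESS", "unstable", "unstable", "ESS", "saddle"))
})

test_that("every scenario reproduces its published stability column", {
  patterns <- list(
    `1` = c(O = "ESS", A = "unstable", B = "unstable", C = "ESS",
            E = "saddle"),
    `2` = c(O = "saddle", A = "saddle", B = "unstable", C = "ESS"),
    `3` = c(O = "saddle", A = "unstable", B = "saddle", C = "ESS"),
    `4` = c(O = "unstable", A = "saddle", B = "saddle", C = "ESS"))
  set.seed(24)
  for (s in 1:4) {
    for (i in 1:50) {
      q <- random_scenario_params(s)
      reg <- classify_regime(q)
      expect_identical(reg$scenario, as.integer(s))
      stab <- vapply(reg$equilibria, `[[`, character(1), "stability")
      expect_identical(stab[names(patterns[[as.character(s)]])],
                       patterns[[as.character(s)]])
      if (s > 1) expect_false(reg$equilibria$E$exists)
    }
  }
})

test_that("regime bullets: one-sided ESS name the led care models", {
  set.seed(25)
  # U1+S1 < P1 and R2+S1p > C2: health-care-led (A is the ESS)
  for (i in 1:20) {
    repeat {
      q <- random_strict_params()
      if (q$U1 + q$S1 < q$P1 && q$R2 + q$S1p > q$C2) break
    }
    expect_true("health-led" %in% classify_regime(q)$care_model_types)
  }
  # U2+S2 > P2 and R1+P1 < C1: social-care-led (B is the ESS)
  for (i in 1:20) {
    repeat {
      q <- random_strict_params()
      if (q$U2 + q$S2 > q$P2 && q$R1 + q$P1 < q$C1) break
    }
    expect_true("social-led" %in% classify_regime(q)$care_model_types)
  }
})

test_that("corner classification depends only on the corner closed forms", {
  # trading R1 against C1 leaves R1+P1-C1 (and every other corner
  # expression) fixed, so no classification may move
  p <- baseline_parameters()
  q <- baseline_with(R1 = 2.3, C1 = 4.1)  # R1 + P1 - C1 unchanged
  for (nm in c("O", "A", "B", "C")) {
    dtp <- det_trace_at(p, nm); dtq <- det_trace_at(q, nm)
    expect_equal(dtp, dtq, tolerance = 1e-12)
    expect_identical(classify_point(dtp[["det"]], dtp[["tr"]]),
                     classify_point(dtq[["det"]], dtq[["tr"]]))
  }
})
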