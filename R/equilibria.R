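#' Interior equilibrium of the replicator system
#'
#' The interior fixed point has coordinates
#' \deqn{x^* = (C_2 - R_2 - S_1') / c, \qquad
#'       y^* = (P_2 - (U_2 + S_2)) / a,}
#' where `a` and `c` are [reduced_coefficients()]. It exists as an interior
#' equilibrium only when both denominators exceed `eps` in magnitude and
#' `(x*, y*)` lies strictly inside the open unit square; otherwise
#' `exists = FALSE` and the stability is `"indeterminate"`. When it exists
#' its Jacobian trace is exactly 0 (non-hyperbolic) and the determinant has
#' the closed form reported by [det_trace_at()].
#'
#' @param params A `game_parameters` object.
#' @param eps Sign tolerance for denominators and strict interiority.
#' @return An object of class `equilibrium`: list with `point` (named
#'   numeric `c(x, y)`), `det`, `tr`, `stability`, `exists`.
#' @export
interior_equilibrium <- function(params, eps = .eps_default) {
  p <- as_game_parameters(params)
  co <- reduced_coefficients(p)
  a <- co[["a"]]; cc <- co[["c"]]
  xs <- if (abs(cc) > eps) (p$C2 - p$R2 - p$S1p) / cc else NA_real_
  ys <- if (abs(a) > eps) (p$P2 - (p$U2 + p$S2)) / a else NA_real_
  exists <- !is.na(xs) && !is.na(ys) &&
    xs > eps && xs < 1 - eps && ys > eps && ys < 1 - eps
  if (exists) {
    dt <- .det_tr_closed(p, "E")
    stab <- classify_point(dt[["det"]], dt[["tr"]], eps)
    structure(list(point = c(x = xs, y = ys), det = dt[["det"]],
                   tr = dt[["tr"]], stability = stab, exists = TRUE),
              class = "equilibrium")
  } else {
    structure(list(point = c(x = xs, y = ys), det = NA_real_, tr = NA_real_,
                   stability = "indeterminate", exists = FALSE),
              class = "equilibrium")
  }
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium (%s, %s): det = %s, tr = %s, %s%s\n",
              format(x$point[["x"]]), format(x$point[["y"]]),
              format(x$det), format(x$tr), x$stability,
              if (isFALSE(x$exists)) " (does not exist as interior point)"
              else ""))
  invisible(x)
}

#' Jacobian of the replicator field
#'
#' \deqn{J = \begin{pmatrix} (1-2x)(ay+b) & x(1-x)a \\
#'            y(1-y)c & (1-2y)(cx+d) \end{pmatrix}}
#'
#' @inheritParams expected_payoffs
#' @return A 2x2 numeric matrix.
#' @export
replicator_jacobian <- function(params, x, y) {
  co <- reduced_coefficients(params)
  .check_state(x, y)
  a <- co[["a"]]; b <- co[["b"]]; cc <- co[["c"]]; d <- co[["d"]]
  matrix(c((1 - 2 * x) * (a * y + b), x * (1 - x) * a,
           y * (1 - y) * cc,          (1 - 2 * y) * (cc * x + d)),
         nrow = 2, byrow = TRUE)
}

# Corner coordinates of the unit square, in the conventional labelling.
.corners <- list(O = c(0, 0), A = c(0, 1), B = c(1, 0), C = c(1, 1))

# Closed-form determinant and trace at the five candidate equilibria.
.det_tr_closed <- function(p, which) {
  f_O1 <- p$U2 + p$S2 - p$P2      # social side payoff advantage at O
  f_O2 <- p$R2 + p$S1p - p$C2     # health side payoff advantage at O
  f_C1 <- p$U1 + p$S1 - p$P1
  f_C2 <- p$R1 + p$P1 - p$C1
  switch(which,
    O = c(det = f_O1 * f_O2, tr = f_O1 + f_O2),
    A = c(det = f_C1 * (-f_O2), tr = f_C1 - f_O2),
    B = c(det = (-f_O1) * f_C2, tr = -f_O1 + f_C2),
    C = c(det = f_C1 * f_C2, tr = -f_C1 - f_C2),
    E = {
      co <- reduced_coefficients(p)
      c(det = -((-f_O1) * (-f_O2) * f_C1 * f_C2) /
          (co[["a"]] * co[["c"]]),
        tr = 0)
    },
    stop("unknown equilibrium label: ", which))
}

#' Determinant and trace at a candidate equilibrium
#'
#' Closed forms for the Jacobian determinant and trace at the corner points
#' `O(0,0)`, `A(0,1)`, `B(1,0)`, `C(1,1)` and at the interior point `E`.
#' For example at `O`: `det = (U2+S2-P2)(R2+S1p-C2)` and
#' `tr = (U2+S2-P2)+(R2+S1p-C2)`; at `C`: `det = (U1+S1-P1)(R1+P1-C1)`,
#' `tr = C1-R1-U1-S1`. At `E` the trace is exactly 0. These agree with the
#' determinant and trace of [replicator_jacobian()] evaluated at the point.
#'
#' @param params A `game_parameters` object.
#' @param which One of `"O"`, `"A"`, `"B"`, `"C"`, `"E"`.
#' @param eps Sign tolerance (used for the existence check at `E`).
#' @return Named numeric vector `c(det, tr)`.
#' @export
det_trace_at <- function(params, which = c("O", "A", "B", "C", "E"),
                         eps = .eps_default) {
  which <- match.arg(which)
  p <- as_game_parameters(params)
  if (which == "E") {
    eq <- interior_equilibrium(p, eps)
    if (!eq$exists)
      stop("interior equilibrium E does not exist for these parameters")
  }
  .det_tr_closed(p, which)
}

#' Classify a fixed point from its Jacobian determinant and trace
#'
#' A point is an evolutionary stable strategy (ESS, locally attracting) iff
#' `det J > 0` and `tr J < 0`; unstable iff both are positive; a saddle iff
#' `det J < 0` (including the non-hyperbolic `tr = 0` interior case); any
#' other sign pattern — `det` within `eps` of 0, or `det > 0` with
#' `|tr| <= eps` — is reported `"indeterminate"` because linearization is
#' inconclusive there.
#'
#' @param det,tr Jacobian determinant and trace at the point.
#' @param eps Sign tolerance.
#' @return One of `"ESS"`, `"unstable"`, `"saddle"`, `"indeterminate"`.
#' @export
classify_point <- function(det, tr, eps = .eps_default) {
  if (det < -eps) return("saddle")
  if (det > eps && tr < -eps) return("ESS")
  if (det > eps && tr > eps) return("unstable")
  "indeterminate"
}

#' Classify all five candidate equilibria
#'
#' @param params A `game_parameters` object.
#' @param eps Sign tolerance.
#' @return Named list (`O`, `A`, `B`, `C`, `E`) of `equilibrium` objects.
#' @export
classify_equilibria <- function(params, eps = .eps_default) {
  p <- as_game_parameters(params)
  out <- lapply(names(.corners), function(nm) {
    dt <- .det_tr_closed(p, nm)
    structure(list(point = setNames(.corners[[nm]], c("x", "y")),
                   det = dt[["det"]], tr = dt[["tr"]],
                   stability = classify_point(dt[["det"]], dt[["tr"]], eps),
                   exists = TRUE),
              class = "equilibrium")
  })
  names(out) <- names(.corners)
  out$E <- interior_equilibrium(p, eps)
  out
}

#' Regime and scenario classification of a parameter set
#'
#' Classifies all five candidate equilibria and names the care-model types
#' implied by ESS membership: `A(0,1)` ESS means the health-care-led model,
#' `B(1,0)` the social-care-led model, `C(1,1)` bilateral cooperation
#' (`O(0,0)` ESS is reported in `ess_points` but names no care model — it is
#' the no-integrated-service outcome). When `C` is an ESS (requires
#' `U1+S1 > P1` and `R1+P1 > C1`), a scenario 1--4 is assigned from the sign
#' pair `(U2+S2-P2, R2+S1p-C2)`:
#' `(-,-) -> 1`, `(-,+) -> 2`, `(+,-) -> 3`, `(+,+) -> 4`.
#'
#' @param params A `game_parameters` object.
#' @param eps Sign tolerance.
#' @return Object of class `regime_report`: list with `equilibria` (the five
#'   classified points), `ess_points` (character), `care_model_types`
#'   (character subset of health-led / social-led / bilateral / none) and
#'   `scenario` (integer 1--4 or `NA`).
#' @export
classify_regime <- function(params, eps = .eps_default) {
  p <- as_game_parameters(params)
  eqs <- classify_equilibria(p, eps)
  ess <- names(eqs)[vapply(eqs, function(e) e$stability == "ESS",
                           logical(1))]
  types <- c(if ("A" %in% ess) "health-led",
             if ("B" %in% ess) "social-led",
             if ("C" %in% ess) "bilateral")
  if (is.null(types)) types <- "none"
  scenario <- NA_integer_
  if ("bilateral" %in% types) {
    s1 <- p$U2 + p$S2 - p$P2
    s2 <- p$R2 + p$S1p - p$C2
    if (abs(s1) > eps && abs(s2) > eps) {
      scenario <- if (s1 < 0 && s2 < 0) 1L else if (s1 < 0) 2L
                  else if (s2 < 0) 3L else 4L
    }
  }
  structure(list(equilibria = eqs, ess_points = ess,
                 care_model_types = types, scenario = scenario),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat("Equilibrium classification:\n")
  for (nm in names(x$equilibria)) {
    e <- x$equilibria[[nm]]
    cat(sprintf("  %s (%.4g, %.4g): det = %.6g, tr = %.6g -> %s%s\n",
                nm, e$point[["x"]], e$point[["y"]],
                e$det, e$tr, e$stability,
                if (isFALSE(e$exists)) " [absent]" else ""))
  }
  cat("ESS points:", if (length(x$ess_points))
    paste(x$ess_points, collapse = ", ") else "none", "\n")
  cat("Care model types:", paste(x$care_model_types, collapse = ", "), "\n")
  cat("Scenario:", if (is.na(x$scenario)) "not applicable" else x$scenario,
      "\n")
  invisible(x)
}
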