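# Scenario-1 preconditions: C(1,1) and O(0,0) are both ESS, the interior
# saddle E exists, and its stable manifold splits the square into the two
# basins. Returns the character vector of failed conditions (empty if ok).
.scenario1_failures <- function(p, eps = .eps_default) {
  fails <- character(0)
  if (!(p$U1 + p$S1 - p$P1 > eps)) fails <- c(fails, "U1 + S1 > P1")
  if (!(p$R1 + p$P1 - p$C1 > eps)) fails <- c(fails, "R1 + P1 > C1")
  if (!(p$P2 - (p$U2 + p$S2) > eps)) fails <- c(fails, "U2 + S2 < P2")
  if (!(p$C2 - (p$R2 + p$S1p) > eps)) fails <- c(fails, "R2 + S1p < C2")
  fails
}

.check_scenario1 <- function(p, eps = .eps_default) {
  fails <- .scenario1_failures(p, eps)
  if (length(fails))
    stop("scenario-1 precondition violated: ",
         paste(fails, collapse = "; "))
  invisible(NULL)
}

#' Area of the bilateral-cooperation basin (region ACBE)
#'
#' Under scenario 1 the interior saddle `E(x*, y*)` splits the unit square
#' of initial conditions into a basin of `O(0,0)` (region AOBE) and a basin
#' of `C(1,1)` (region ACBE). The area of region ACBE, measured as the two
#' triangles A-C-E and C-B-E,
#' \deqn{S_{ACBE} = \tfrac12 (1 - x^*) + \tfrac12 (1 - y^*)
#'       = 1 - (x^* + y^*)/2,}
#' is the probability mass (under uniform initial conditions) of evolving to
#' bilateral cooperation.
#'
#' @param params A `game_parameters` object satisfying the scenario-1
#'   conditions `U1+S1 > P1`, `R1+P1 > C1`, `U2+S2 < P2`, `R2+S1p < C2`.
#' @param eps Sign tolerance for the precondition checks.
#' @return A number in (0, 1).
#' @export
basin_area <- function(params, eps = .eps_default) {
  p <- as_game_parameters(params)
  .check_scenario1(p, eps)
  eq <- interior_equilibrium(p, eps)
  if (!eq$exists)
    stop("interior equilibrium does not exist; basin area undefined")
  1 - (eq$point[["x"]] + eq$point[["y"]]) / 2
}

# Closed-form partials of x* = Nx/c and y* = Ny/a with Nx = C2-R2-S1p,
# Ny = P2-U2-S2, then dS/dtheta = -(dx* + dy*)/2.
.basin_partial <- function(p, name) {
  co <- reduced_coefficients(p)
  a <- co[["a"]]; cc <- co[["c"]]
  Nx <- p$C2 - p$R2 - p$S1p
  Ny <- p$P2 - p$U2 - p$S2
  dxs <- switch(name,
    R1 = -Nx / cc^2, P1 = -Nx / cc^2,
    R2 = (Nx - cc) / cc^2, S1p = (Nx - cc) / cc^2,
    C1 = Nx / cc^2, C2 = (cc - Nx) / cc^2, 0)
  dys <- switch(name,
    U1 = -Ny / a^2, S1 = -Ny / a^2,
    U2 = (Ny - a) / a^2, S2 = (Ny - a) / a^2,
    P1 = Ny / a^2, P2 = (a - Ny) / a^2, 0)
  -(dxs + dys) / 2
}

#' Sensitivity of the basin area to one parameter
#'
#' Partial derivative of [basin_area()] with respect to a single parameter,
#' either from the hand-derived closed form (the area depends on each
#' parameter only through the simple quotients `x*` and `y*`) or by central
#' finite differences with relative step `h = 1e-6 * max(1, |value|)`. The
#' two methods agree to about 1e-5 relative. `P1` is additionally annotated
#' as globally indeterminate: it enters both quotients with opposite effect,
#' so its sign depends on where in the scenario-1 region it is evaluated.
#'
#' @inheritParams basin_area
#' @param name One of the eleven parameter names.
#' @param method `"closed_form"` (default) or `"finite_difference"`.
#' @return Object of class `sensitivity_row`: list with `parameter`,
#'   `derivative`, `sign` (`"+"`, `"-"` or `"indeterminate"`), `method` and
#'   `annotation` (`"+-"` for the globally indeterminate `P1`, `""`
#'   otherwise).
#' @export
area_sensitivity <- function(params, name,
                             method = c("closed_form", "finite_difference"),
                             eps = .eps_default) {
  method <- match.arg(method)
  p <- as_game_parameters(params)
  .check_scenario1(p, eps)
  if (!name %in% param_names)
    stop("unknown parameter name: ", name)
  if (method == "closed_form") {
    deriv <- .basin_partial(p, name)
  } else {
    h <- 1e-6 * max(1, abs(p[[name]]))
    up <- p; up[[name]] <- p[[name]] + h
    dn <- p; dn[[name]] <- p[[name]] - h
    for (q in list(up, dn)) {
      fails <- .scenario1_failures(q, eps)
      if (length(fails))
        stop("perturbed parameters leave the scenario-1 region (",
             paste(fails, collapse = "; "), ")")
      if (q[[name]] < 0)
        stop("perturbed parameter ", name, " becomes negative")
    }
    deriv <- (basin_area(up, eps) - basin_area(dn, eps)) / (2 * h)
  }
  sgn <- if (deriv > eps) "+" else if (deriv < -eps) "-" else "indeterminate"
  structure(list(parameter = name, derivative = deriv, sign = sgn,
                 method = method,
                 annotation = if (name == "P1") "+-" else ""),
            class = "sensitivity_row")
}

#' @export
print.sensitivity_row <- function(x, ...) {
  cat(sprintf("dS_ACBE/d%s = %.6g (%s)%s [%s]\n", x$parameter, x$derivative,
              x$sign,
              if (nzchar(x$annotation)) " globally indeterminate" else "",
              x$method))
  invisible(x)
}

#' Sign table of all eleven basin-area sensitivities
#'
#' One row per parameter, ordered `R1, R2, P1, P2, C1, C2, U1, U2, S1, S1p,
#' S2`. Inside the scenario-1 region with an interior saddle, increasing any
#' benefit or subsidy enlarges the bilateral-cooperation basin and
#' increasing any of the costs `P2`, `C1`, `C2` shrinks it; the effect of
#' `P1` is globally indeterminate (its row is annotated `"+-"` regardless of
#' the local numeric sign).
#'
#' @inheritParams basin_area
#' @param method Sensitivity method, as in [area_sensitivity()].
#' @return A data.frame with columns `parameter`, `derivative`, `sign`,
#'   `annotation`, `method`.
#' @export
sensitivity_sign_table <- function(params, method = "closed_form",
                                   eps = .eps_default) {
  order <- c("R1", "R2", "P1", "P2", "C1", "C2",
             "U1", "U2", "S1", "S1p", "S2")
  rows <- lapply(order, function(nm)
    area_sensitivity(params, nm, method, eps))
  data.frame(parameter = order,
             derivative = vapply(rows, `[[`, numeric(1), "derivative"),
             sign = vapply(rows, `[[`, character(1), "sign"),
             annotation = vapply(rows, `[[`, character(1), "annotation"),
             method = method,
             stringsAsFactors = FALSE)
}
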