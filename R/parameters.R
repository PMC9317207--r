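#' Names of the eleven model parameters
#'
#' `U1`, `U2`: additional benefit to the elderly social care organization in
#' the bilateral-cooperation resp. social-care-led model; `P1`, `P2`: its
#' purchase/negotiation cost resp. own-provision cost; `R1`, `R2`: additional
#' income of the health care organization in the bilateral resp. health-led
#' model; `C1`, `C2`: its additional operating costs; `S1`, `S2`: government
#' subsidy to the social care organization (bilateral resp. social-led);
#' `S1p`: government subsidy to the health care organization (health-led).
#'
#' @format Character vector of length 11.
#' @export
param_names <- c("U1", "U2", "P1", "P2", "R1", "R2",
                 "C1", "C2", "S1", "S2", "S1p")

#' Construct a set of game parameters
#'
#' Bundles the eleven nonnegative scalars that determine the evolutionary
#' game between a health care organization and an elderly social care
#' organization. All values are dimensionless currency-scale reals; no unit
#' system is imposed. Negative or non-finite values are rejected here; the
#' ordering assumptions (`U2 > U1` etc.) are checked by
#' [validate_parameters()].
#'
#' @param U1,U2 Additional benefit to the social care organization
#'   (bilateral resp. social-care-led model).
#' @param P1,P2 Social care organization's purchase/negotiation cost resp.
#'   own-provision cost.
#' @param R1,R2 Additional income to the health care organization (bilateral
#'   resp. health-care-led model).
#' @param C1,C2 Health care organization's additional operating costs.
#' @param S1,S2 Government subsidy to the social care organization
#'   (bilateral resp. social-care-led model).
#' @param S1p Government subsidy to the health care organization
#'   (health-care-led model).
#' @return An object of class `game_parameters`: a named list of the eleven
#'   scalars.
#' @seealso [baseline_parameters()], [validate_parameters()],
#'   [reduced_coefficients()]
#' @examples
#' p <- game_parameters(U1 = 1, U2 = 1.2, P1 = 2.23, P2 = 3, R1 = 2.2,
#'                      R2 = 2.42, C1 = 4, C2 = 4.21, S1 = 1.4, S2 = 1.6,
#'                      S1p = 1.59)
#' reduced_coefficients(p)
#' @export
game_parameters <- function(U1, U2, P1, P2, R1, R2, C1, C2, S1, S2, S1p) {
  vals <- list(U1 = U1, U2 = U2, P1 = P1, P2 = P2, R1 = R1, R2 = R2,
               C1 = C1, C2 = C2, S1 = S1, S2 = S2, S1p = S1p)
  bad <- names(vals)[!vapply(vals, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))]
  if (length(bad))
    stop("parameters must be finite numeric scalars: ",
         paste(bad, collapse = ", "))
  neg <- names(vals)[vapply(vals, function(v) v < 0, logical(1))]
  if (length(neg))
    stop("parameters must be nonnegative: ", paste(neg, collapse = ", "))
  structure(lapply(vals, as.numeric), class = "game_parameters")
}

#' Coerce a named list or vector to game parameters
#'
#' Accepts exactly the eleven parameter names in [param_names]; unknown or
#' missing names are an error (no silent defaults).
#'
#' @param x Named list or named numeric vector.
#' @return A `game_parameters` object.
#' @export
as_game_parameters <- function(x) {
  if (inherits(x, "game_parameters")) return(x)
  x <- as.list(x)
  unknown <- setdiff(names(x), param_names)
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(param_names, names(x))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  do.call(game_parameters, x[param_names])
}

#' The printed baseline parameter set
#'
#' The scenario-1 parameter set used by all the sweep experiments:
#' `U1 = 1`, `U2 = 1.2`, `R1 = 2.2`, `R2 = 2.42`, `S1 = 1.4`, `S1p = 1.59`,
#' `S2 = 1.6`, `C1 = 4`, `C2 = 4.21`, `P1 = 2.23`, `P2 = 3`.
#'
#' @return A `game_parameters` object.
#' @export
baseline_parameters <- function() {
  game_parameters(U1 = 1, U2 = 1.2, P1 = 2.23, P2 = 3, R1 = 2.2, R2 = 2.42,
                  C1 = 4, C2 = 4.21, S1 = 1.4, S2 = 1.6, S1p = 1.59)
}

#' Reduced coefficients of the dynamics
#'
#' The eleven raw parameters enter the replicator field only through four
#' combinations:
#' \deqn{a = U_1 - U_2 + P_2 - P_1 + S_1 - S_2, \quad b = U_2 + S_2 - P_2,}
#' \deqn{c = R_1 - R_2 + P_1 - S_1' + C_2 - C_1, \quad d = R_2 + S_1' - C_2,}
#' so two parameter sets with equal `(a, b, c, d)` generate identical
#' dynamics.
#'
#' @param params A `game_parameters` object.
#' @return Named numeric vector `c(a, b, c, d)`.
#' @export
reduced_coefficients <- function(params) {
  p <- as_game_parameters(params)
  c(a = p$U1 - p$U2 + p$P2 - p$P1 + p$S1 - p$S2,
    b = p$U2 + p$S2 - p$P2,
    c = p$R1 - p$R2 + p$P1 - p$S1p + p$C2 - p$C1,
    d = p$R2 + p$S1p - p$C2)
}

# Ordering assumptions of the model, checked by validate_parameters().
.orderings <- list(
  c("U2", "U1"), c("P2", "P1"), c("R2", "R1"), c("C2", "C1"), c("S2", "S1"))

#' Validate a parameter set against the model assumptions
#'
#' Checks nonnegativity of every field and the ordering assumptions
#' `U2 > U1`, `P2 > P1`, `R2 > R1`, `C2 > C1`, `S2 > S1`. With
#' `strict = TRUE` (the default) any violation is an error naming each
#' violated inequality; otherwise violations are collected as warnings in
#' the returned report. The report also echoes the reduced coefficients.
#'
#' @param params A `game_parameters` object (or coercible named list).
#' @param strict Logical; raise an error on any violation?
#' @return An object of class `validation_report`: list with elements
#'   `valid`, `violations` (character), `negative` (character) and
#'   `coefficients` (the reduced coefficients).
#' @export
validate_parameters <- function(params, strict = TRUE) {
  p <- as_game_parameters(params)
  neg <- param_names[vapply(param_names, function(n) p[[n]] < 0, logical(1))]
  viol <- character(0)
  for (o in .orderings) {
    if (!(p[[o[1]]] > p[[o[2]]]))
      viol <- c(viol, paste(o[1], ">", o[2]))
  }
  all_viol <- c(viol, if (length(neg)) paste(neg, ">= 0"))
  report <- structure(
    list(valid = length(all_viol) == 0L, violations = all_viol,
         negative = neg, coefficients = reduced_coefficients(p)),
    class = "validation_report")
  if (strict && !report$valid)
    stop("parameter validation failed: ",
         paste(all_viol, collapse = "; "))
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Parameter validation:", if (x$valid) "valid" else "INVALID", "\n")
  if (length(x$violations))
    cat("  violated:", paste(x$violations, collapse = "; "), "\n")
  co <- x$coefficients
  cat(sprintf("  reduced coefficients: a = %.6g, b = %.6g, c = %.6g, d = %.6g\n",
              co["a"], co["b"], co["c"], co["d"]))
  invisible(x)
}

#' @export
print.game_parameters <- function(x, ...) {
  cat("Game parameters:\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 4), " = ", format(v)),
      sep = "\n")
  invisible(x)
}
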