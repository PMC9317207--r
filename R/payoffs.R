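.check_state <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != 1L || length(y) != 1L ||
      !is.finite(x) || !is.finite(y) || x < 0 || x > 1 || y < 0 || y > 1)
    stop("state (x, y) must lie in the unit square [0,1]^2")
  invisible(NULL)
}

#' Payoff matrix of the game
#'
#' The four strategy-profile cells of the bimatrix game. Rows index the
#' social care organization's strategy (participation / nonparticipation),
#' columns the health care organization's. In the bilateral cell the social
#' care organization earns `U1 + S1 - P1` and the health care organization
#' `R1 + P1 - C1`; if only the social care organization participates it
#' earns `U2 + S2 - P2` (health side 0); if only the health care
#' organization participates it earns `R2 + S1p - C2` (social side 0); the
#' mutual nonparticipation cell is (0, 0).
#'
#' @param params A `game_parameters` object.
#' @return Object of class `payoff_table`: list of two 2x2 matrices,
#'   `social` and `health`, with dimnames
#'   `participation`/`nonparticipation`.
#' @export
payoff_matrix <- function(params) {
  p <- as_game_parameters(params)
  dn <- list(social = c("participation", "nonparticipation"),
             health = c("participation", "nonparticipation"))
  social <- matrix(c(p$U1 + p$S1 - p$P1, p$U2 + p$S2 - p$P2,
                     0,                  0),
                   nrow = 2, byrow = TRUE, dimnames = dn)
  health <- matrix(c(p$R1 + p$P1 - p$C1, 0,
                     p$R2 + p$S1p - p$C2, 0),
                   nrow = 2, byrow = TRUE, dimnames = dn)
  structure(list(social = social, health = health), class = "payoff_table")
}

#' @export
print.payoff_table <- function(x, ...) {
  cat("Social care organization payoffs:\n"); print(x$social)
  cat("Health care organization payoffs:\n"); print(x$health)
  invisible(x)
}

#' Expected payoffs at a mixed-strategy state
#'
#' `E11` is the social care organization's expected payoff from
#' participation (a convex combination in the opponent's probability `y`),
#' `E21` the health care organization's from participation (combination in
#' `x`); the nonparticipation payoffs `E12`, `E22` are identically zero, and
#' the population averages are `Ebar1 = x E11`, `Ebar2 = y E21`.
#'
#' @param params A `game_parameters` object.
#' @param x,y Participation probabilities of the social care resp. health
#'   care organization, each in \[0, 1\].
#' @return Named list with `E11`, `E12`, `E21`, `E22`, `Ebar1`, `Ebar2`.
#' @export
expected_payoffs <- function(params, x, y) {
  p <- as_game_parameters(params)
  .check_state(x, y)
  E11 <- y * (p$U1 + p$S1 - p$P1) + (1 - y) * (p$U2 + p$S2 - p$P2)
  E21 <- x * (p$R1 + p$P1 - p$C1) + (1 - x) * (p$R2 + p$S1p - p$C2)
  list(E11 = E11, E12 = 0, E21 = E21, E22 = 0,
       Ebar1 = x * E11, Ebar2 = y * E21)
}

#' Replicator vector field
#'
#' The replicator dynamics of the two participation probabilities:
#' \deqn{\dot x = x(1-x)(a y + b), \qquad \dot y = y(1-y)(c x + d),}
#' with `(a, b, c, d)` the [reduced_coefficients()]. This equals
#' `x(1-x)(E11 - E12)` and `y(1-y)(E21 - E22)` exactly.
#'
#' @inheritParams expected_payoffs
#' @return Named numeric vector `c(dxdt, dydt)`.
#' @export
replicator_field <- function(params, x, y) {
  co <- reduced_coefficients(params)
  .check_state(x, y)
  c(dxdt = x * (1 - x) * (co[["a"]] * y + co[["b"]]),
    dydt = y * (1 - y) * (co[["c"]] * x + co[["d"]]))
}
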