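# Random parameter generators used by the property-style tests.

# A parameter set satisfying the strict ordering assumptions
# (U2 > U1, P2 > P1, R2 > R1, C2 > C1, S2 > S1), nothing more.
random_strict_params <- function() {
  U1 <- runif(1, 0.5, 2);  U2 <- U1 + runif(1, 0.05, 1)
  P1 <- runif(1, 0.5, 2.5); P2 <- P1 + runif(1, 0.05, 1)
  R1 <- runif(1, 0.5, 3);  R2 <- R1 + runif(1, 0.05, 1)
  C1 <- runif(1, 0.5, 4);  C2 <- C1 + runif(1, 0.05, 1)
  S1 <- runif(1, 0.2, 2);  S2 <- S1 + runif(1, 0.05, 1)
  game_parameters(U1 = U1, U2 = U2, P1 = P1, P2 = P2, R1 = R1, R2 = R2,
                  C1 = C1, C2 = C2, S1 = S1, S2 = S2,
                  S1p = runif(1, 0.2, 2))
}

# A strict-valid parameter set in which C(1,1) is an ESS, with the sign pair
# (U2+S2-P2, R2+S1p-C2) chosen to place it in the requested scenario:
# scenario 1 = (-,-), 2 = (-,+), 3 = (+,-), 4 = (+,+).
random_scenario_params <- function(scenario = 1) {
  stopifnot(scenario %in% 1:4)
  for (i in 1:10000) {
    S1 <- runif(1, 0.5, 2);  S2 <- S1 + runif(1, 0.05, 0.6)
    U1 <- runif(1, 0.5, 2);  U2 <- U1 + runif(1, 0.05, 0.6)
    S1p <- runif(1, 0.5, 2)
    P1 <- U1 + S1 - runif(1, 0.05, 0.5)          # U1 + S1 > P1
    b_sign <- if (scenario %in% c(3, 4)) -1 else 1
    P2 <- U2 + S2 + b_sign * runif(1, 0.05, 0.5) # sign of U2+S2-P2
    R1 <- runif(1, 1, 3);  R2 <- R1 + runif(1, 0.05, 0.6)
    C1 <- R1 + P1 - runif(1, 0.05, 0.5)          # R1 + P1 > C1
    d_sign <- if (scenario %in% c(2, 4)) -1 else 1
    C2 <- R2 + S1p + d_sign * runif(1, 0.05, 0.5)
    if (P2 > P1 && C2 > C1 && C1 >= 0 && C2 >= 0 && P1 >= 0)
      return(game_parameters(U1 = U1, U2 = U2, P1 = P1, P2 = P2, R1 = R1,
                             R2 = R2, C1 = C1, C2 = C2, S1 = S1, S2 = S2,
                             S1p = S1p))
  }
  stop("failed to draw a scenario-", scenario, " parameter set")
}

random_scenario1_params <- function() random_scenario_params(1)

# Baseline with one field overridden.
baseline_with <- function(...) {
  p <- baseline_parameters()
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}
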