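#' Integrator settings for the replicator system
#'
#' The adaptive Dormand-Prince 5(4) pair is the default, with tolerances
#' tight enough (rtol 1e-8, atol 1e-10) that outcome labels are
#' integrator-independent; fixed-step classical RK4 and explicit Euler are
#' available as cross-checking oracles. Time is continuous replicator time
#' in arbitrary units; `t_max = 500` is far beyond all observed convergence
#' times at the baseline parameters. Convergence to a corner is declared
#' when the state is within `delta` of the corner *and* the field magnitude
#' is below `delta^2`, which prevents misclassifying slow transits near
#' saddles.
#'
#' @param method `"adaptive"` (Dormand-Prince 5(4), default), `"rk4"` or
#'   `"euler"`.
#' @param dt Fixed step size for `"rk4"` and `"euler"`.
#' @param rtol,atol Relative and absolute error tolerances for
#'   `"adaptive"`.
#' @param t_max Integration horizon (time units).
#' @param delta Convergence tolerance (distance to corner), in (0, 0.5).
#' @param clamp Clamp the state to the unit square after every step?
#' @param record_interval Approximate spacing of recorded trajectory
#'   points.
#' @return Object of class `integrator_settings`.
#' @export
integrator_settings <- function(method = c("adaptive", "rk4", "euler"),
                                dt = 1e-3, rtol = 1e-8, atol = 1e-10,
                                t_max = 500, delta = 1e-4, clamp = TRUE,
                                record_interval = 0.5) {
  method <- match.arg(method)
  stopifnot(dt > 0, rtol > 0, atol > 0, t_max > 0,
            delta > 0, delta < 0.5, record_interval > 0)
  structure(list(method = method, dt = dt, rtol = rtol, atol = atol,
                 t_max = t_max, delta = delta, clamp = clamp,
                 record_interval = record_interval),
            class = "integrator_settings")
}

.corner_labels <- c("O", "A", "B", "C")

#' Integrate the replicator system
#'
#' Solves \eqn{\dot x = x(1-x)(ay+b)}, \eqn{\dot y = y(1-y)(cx+d)} forward
#' from `(x0, y0)` until corner convergence (see [integrator_settings()])
#' or `t_max`. States are clamped to the unit square after each step when
#' clamping is on (the exact dynamics are forward-invariant; clamping only
#' suppresses infinitesimal numerical excursions). A trajectory that passes
#' within 1e-9 of the interior saddle is reported `"nonconvergent"` rather
#' than forced to a corner, since it is numerically on the separatrix.
#'
#' @param params A `game_parameters` object.
#' @param x0,y0 Initial participation probabilities, in \[0, 1\].
#' @param settings An [integrator_settings()] object.
#' @return Object of class `replicator_trajectory`: list with `times`,
#'   `states` (two-column matrix `x`, `y`), `outcome` (one of `"O"`, `"A"`,
#'   `"B"`, `"C"`, `"interior"`, `"nonconvergent"`), `convergence_time`
#'   (`NA` if non-convergent), `max_excursion`, `params`, `settings`.
#' @examples
#' traj <- integrate_replicator(baseline_parameters(), 0.6, 0.95)
#' traj$outcome            # "C": bilateral cooperation
#' @export
integrate_replicator <- function(params, x0, y0,
                                 settings = integrator_settings()) {
  p <- as_game_parameters(params)
  stopifnot(inherits(settings, "integrator_settings"))
  if (!is.finite(x0) || !is.finite(y0) ||
      x0 < 0 || x0 > 1 || y0 < 0 || y0 > 1)
    stop("initial state (x0, y0) must lie in the unit square")
  co <- reduced_coefficients(p)
  eq <- interior_equilibrium(p)
  method_code <- match(settings$method, c("adaptive", "rk4", "euler")) - 1L
  res <- integrate_core(co[["a"]], co[["b"]], co[["c"]], co[["d"]],
                        x0, y0, method_code, settings$dt, settings$rtol,
                        settings$atol, settings$t_max, settings$delta,
                        settings$clamp, settings$record_interval,
                        eq$exists,
                        if (eq$exists) eq$point[["x"]] else 0,
                        if (eq$exists) eq$point[["y"]] else 0)
  if (isTRUE(res$nonfinite))
    stop("integrator failure: non-finite state encountered")
  states <- cbind(x = res$x, y = res$y)
  corner <- res$corner
  outcome <- if (corner >= 0) .corner_labels[corner + 1L] else NULL
  conv <- res$convergence_time
  # Separatrix rule: a grazing pass of the saddle voids a corner label,
  # unless the trajectory starts (and thus stays) at the saddle itself.
  if (!is.null(outcome) && eq$exists && res$min_saddle_dist < 1e-9) {
    outcome <- "nonconvergent"
    conv <- NA_real_
  }
  traj <- structure(
    list(times = res$times, states = states, outcome = "nonconvergent",
         convergence_time = conv, max_excursion = res$max_excursion,
         params = p, settings = settings),
    class = "replicator_trajectory")
  traj$outcome <- if (is.null(outcome)) classify_outcome(traj) else outcome
  traj
}

#' Classify the outcome of a trajectory
#'
#' Returns the corner label whose distance to the final state is below
#' `delta` and where the field test passes; `"interior"` if the final state
#' is within `delta` of an existing interior equilibrium; `"nonconvergent"`
#' otherwise.
#'
#' @param traj A `replicator_trajectory`.
#' @param delta Convergence tolerance; defaults to the trajectory's own.
#' @return One of `"O"`, `"A"`, `"B"`, `"C"`, `"interior"`,
#'   `"nonconvergent"`.
#' @export
classify_outcome <- function(traj, delta = traj$settings$delta) {
  stopifnot(inherits(traj, "replicator_trajectory"),
            nrow(traj$states) >= 1L)
  fin <- traj$states[nrow(traj$states), ]
  corners <- list(O = c(0, 0), A = c(0, 1), B = c(1, 0), C = c(1, 1))
  f <- replicator_field(traj$params, fin[["x"]], fin[["y"]])
  for (nm in names(corners)) {
    if (sqrt(sum((fin - corners[[nm]])^2)) < delta &&
        sqrt(sum(f^2)) < delta^2)
      return(nm)
  }
  eq <- interior_equilibrium(traj$params)
  if (eq$exists && sqrt(sum((fin - eq$point)^2)) < delta)
    return("interior")
  "nonconvergent"
}

#' @export
print.replicator_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf(
    "Replicator trajectory: %d recorded states over t = [0, %.4g]\n",
    n, x$times[n]))
  cat(sprintf("  start (%.4g, %.4g) -> final (%.6g, %.6g)\n",
              x$states[1, "x"], x$states[1, "y"],
              x$states[n, "x"], x$states[n, "y"]))
  cat(sprintf("  outcome: %s%s\n", x$outcome,
              if (!is.na(x$convergence_time))
                sprintf(" (convergence time %.4g)", x$convergence_time)
              else ""))
  invisible(x)
}
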