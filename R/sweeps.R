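#' Specify a one-dimensional sweep
#'
#' A sweep varies one quantity — a model parameter or one of the initial
#' probabilities `x0`, `y0` — over a strictly increasing grid, holding
#' everything else fixed, and integrates one trajectory per grid value.
#'
#' @param quantity A parameter name from [param_names], `"x0"` or `"y0"`.
#' @param grid Strictly increasing numeric vector of swept values.
#' @param params Fixed parameter set (default [baseline_parameters()]).
#' @param x0,y0 Fixed initial condition (overridden when swept).
#' @param settings [integrator_settings()] used for every grid point.
#' @param require_scenario1 Assert the scenario-1 sign conditions at every
#'   grid point before running?
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(quantity, grid, params = baseline_parameters(),
                       x0 = 0.5, y0 = 0.5,
                       settings = integrator_settings(),
                       require_scenario1 = FALSE) {
  if (!quantity %in% c(param_names, "x0", "y0"))
    stop("unknown swept quantity: ", quantity)
  if (!length(grid) || any(diff(grid) <= 0))
    stop("grid must be nonempty and strictly increasing")
  p <- as_game_parameters(params)
  structure(list(quantity = quantity, grid = as.numeric(grid), params = p,
                 x0 = x0, y0 = y0, settings = settings,
                 require_scenario1 = require_scenario1),
            class = "sweep_spec")
}

# Parameter set / initial condition at one grid point of a sweep.
.sweep_point <- function(spec, value) {
  p <- spec$params; x0 <- spec$x0; y0 <- spec$y0
  if (spec$quantity == "x0") x0 <- value
  else if (spec$quantity == "y0") y0 <- value
  else p[[spec$quantity]] <- value
  list(params = p, x0 = x0, y0 = y0)
}

#' Run a sweep
#'
#' Integrates one trajectory per grid value and records the outcome label
#' and convergence time. `flip_threshold` is the smallest grid value whose
#' outcome differs from the first grid point's outcome (`NA` when all
#' outcomes agree); because outcome sequences need not be monotone near the
#' separatrix, *all* change points along the grid are also reported. A grid
#' point that fails to converge is flagged, never dropped.
#'
#' @param spec A [sweep_spec()].
#' @return Object of class `sweep_result`: list with `table` (data.frame of
#'   `swept_name`, `swept_value`, `outcome`, `convergence_time`),
#'   `flip_threshold`, `change_points` (swept values at which the outcome
#'   differs from the previous grid point), `any_nonconvergent` and `spec`.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (spec$require_scenario1) {
    for (v in spec$grid)
      .check_scenario1(.sweep_point(spec, v)$params)
  }
  outcomes <- character(length(spec$grid))
  times <- numeric(length(spec$grid))
  for (i in seq_along(spec$grid)) {
    pt <- .sweep_point(spec, spec$grid[i])
    traj <- integrate_replicator(pt$params, pt$x0, pt$y0, spec$settings)
    outcomes[i] <- traj$outcome
    times[i] <- if (is.null(traj$convergence_time) ||
                    is.na(traj$convergence_time)) NA_real_
                else traj$convergence_time
  }
  changes <- which(outcomes[-1] != outcomes[-length(outcomes)]) + 1L
  structure(list(
    table = data.frame(swept_name = spec$quantity,
                       swept_value = spec$grid, outcome = outcomes,
                       convergence_time = times,
                       stringsAsFactors = FALSE),
    flip_threshold = if (length(changes)) spec$grid[changes[1]] else
      NA_real_,
    change_points = spec$grid[changes],
    any_nonconvergent = any(outcomes == "nonconvergent"),
    spec = spec), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  print(x$table)
  cat("flip_threshold:",
      if (is.na(x$flip_threshold)) "absent" else x$flip_threshold, "\n")
  invisible(x)
}

# The published sweep setups. Each entry: swept quantity, grid, fixed
# initial condition; fixed parameters are always the printed baseline.
.figure_setups <- list(
  `2a` = list(quantity = "x0", grid = seq(0.05, 0.95, by = 0.1), y0 = 0.4),
  `2b` = list(quantity = "x0", grid = seq(0.05, 0.95, by = 0.1), y0 = 0.6),
  `3a` = list(quantity = "y0", grid = seq(0.05, 0.95, by = 0.1), x0 = 0.5),
  `3b` = list(quantity = "y0", grid = seq(0.05, 0.95, by = 0.1), x0 = 0.6),
  `4a` = list(quantity = "U1", grid = c(0.85, 0.90, 0.95, 1.00, 1.05)),
  `4b` = list(quantity = "R1", grid = c(2.0, 2.1, 2.2, 2.3, 2.4)),
  `5ab` = list(quantity = "P1", grid = c(1.81, 1.91, 2.01, 2.11, 2.21)),
  `5c` = list(quantity = "C1", grid = c(3.8, 3.9, 4.0, 4.1, 4.2)),
  `6a` = list(quantity = "S1", grid = c(1.25, 1.30, 1.35, 1.40, 1.45)),
  `6b` = list(quantity = "S1p", grid = c(1.3, 1.4, 1.5, 1.6, 1.7)))

#' IDs of the published figure experiments
#' @return Character vector of valid `figure_id` values.
#' @export
figure_ids <- function() names(.figure_setups)

#' Reproduce a published sweep experiment
#'
#' Builds the exact sweep printed for the given figure — the baseline
#' parameter set with the figure's grid and initial condition (default
#' `x0 = y0 = 0.5` for parameter sweeps) — asserts that every grid point
#' satisfies the scenario-1 sign conditions, and delegates to
#' [run_sweep()].
#'
#' @param figure_id One of `"2a"`, `"2b"`, `"3a"`, `"3b"` (initial-condition
#'   sweeps), `"4a"` (U1), `"4b"` (R1), `"5ab"` (P1), `"5c"` (C1), `"6a"`
#'   (S1), `"6b"` (S1p).
#' @param settings [integrator_settings()] to use.
#' @return A `sweep_result`.
#' @examples
#' res <- run_figure_experiment("4b")
#' res$flip_threshold   # 2.1: participation of the health side from R1 = 2.1
#' @export
run_figure_experiment <- function(figure_id,
                                  settings = integrator_settings()) {
  if (!figure_id %in% names(.figure_setups))
    stop("unknown figure_id: ", figure_id, " (see figure_ids())")
  setup <- .figure_setups[[figure_id]]
  spec <- sweep_spec(setup$quantity, setup$grid,
                     params = baseline_parameters(),
                     x0 = if (is.null(setup$x0)) 0.5 else setup$x0,
                     y0 = if (is.null(setup$y0)) 0.5 else setup$y0,
                     settings = settings, require_scenario1 = TRUE)
  run_sweep(spec)
}

#' Convergence-time ordering along a sweep
#'
#' For grid points sharing an outcome label, reports whether the
#' convergence time is monotone in the swept value. This is how the
#' qualitative speed claims (higher initial participation or larger
#' benefits/subsidies reach bilateral cooperation faster) are checked — as
#' orderings of continuous convergence time, not of discrete step counts.
#'
#' @param result A `sweep_result`.
#' @return A data.frame with one row per outcome label having at least two
#'   converged grid points: columns `outcome`, `n`, `direction` (one of
#'   `"decreasing"`, `"increasing"`, `"tie"`, `"nonmonotone"`).
#' @export
convergence_time_ordering <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  tab <- result$table[!is.na(result$table$convergence_time), ]
  groups <- split(tab, tab$outcome)
  groups <- groups[vapply(groups, nrow, integer(1)) >= 2L]
  if (!length(groups))
    stop("fewer than 2 grid points share an outcome with a convergence time")
  out <- lapply(groups, function(g) {
    g <- g[order(g$swept_value), ]
    d <- diff(g$convergence_time)
    direction <- if (all(d < 0)) "decreasing" else if (all(d > 0))
      "increasing" else if (all(d == 0)) "tie" else if (all(d <= 0) ||
      all(d >= 0)) "tie" else "nonmonotone"
    data.frame(outcome = g$outcome[1], n = nrow(g), direction = direction,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
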