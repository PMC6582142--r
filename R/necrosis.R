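#' Threshold-driven necrosis feedback iteration
#'
#' Implements the supply/demand feedback that turns a flow dip into a
#' sharply margined necrosis: solve the perfusion field, mark every active
#' cell whose terminal flow `j_omega` falls below the viability threshold
#' `theta`, collapse the conductivity of the newly necrotic cells to the
#' residual retrograde value `omega_necrotic` (synchronous update), and
#' re-solve — until no new cell dies (a fixed point) or a round cap of
#' `nx * ny` is hit. The necrotic set can only grow, so termination is
#' guaranteed. Because the dead core sheds its collateral supply back to
#' the rim, the rim's flow rises, which is what arrests the spread:
#' the lesion is self-limiting purely through Kirchhoff's laws.
#'
#' @param scenario A `mucoflow_scenario` (typically
#'   `scenario_necrosis("pre")`).
#' @param theta Positive viability threshold on `j_omega`.
#' @param omega_necrotic Conductivity assigned to necrotic cells; must be
#'   below the minimum `omega` over the active mask. Default 0.05 (the
#'   surviving retrograde muscle supply).
#' @param active_mask Logical grid of cells allowed to necrose; defaults
#'   to the whole grid.
#' @param opts [solver_options()].
#' @return A `mucoflow_necrosis_trace`: list with `rounds` (each holding
#'   `necrotic` mask and `solution`), `theta`, `omega_necrotic`,
#'   `terminated`, `fixed_point_reached` and the final `fields`.
#' @examples
#' \donttest{
#' tr <- run_necrosis_iteration(scenario_necrosis("pre"), theta = 0.06)
#' tr$fixed_point_reached
#' }
#' @export
run_necrosis_iteration <- function(scenario, theta, omega_necrotic = 0.05,
                                   active_mask = NULL,
                                   opts = solver_options()) {
  grid <- scenario$grid
  if (is.null(active_mask)) active_mask <- matrix(TRUE, grid$nx, grid$ny)
  stopifnot(identical(dim(active_mask), c(grid$nx, grid$ny)))
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0)
    stop("`theta` must be a positive scalar", call. = FALSE)
  fields <- scenario$fields
  if (omega_necrotic >= min(fields$omega[active_mask]))
    stop("`omega_necrotic` must be below the minimum omega over the active mask",
         call. = FALSE)
  necrotic <- matrix(FALSE, grid$nx, grid$ny)
  rounds <- list()
  fixed_point <- FALSE
  cap <- grid$nx * grid$ny
  for (k in seq_len(cap)) {
    sol <- solve_gauss_seidel(fields, grid, opts)
    fresh <- active_mask & !necrotic & (sol$j_omega < theta)
    rounds[[k]] <- list(necrotic = necrotic, solution = sol,
                        new_necrosis = sum(fresh))
    if (!any(fresh)) { fixed_point <- TRUE; break }
    necrotic <- necrotic | fresh
    fields$omega[fresh] <- omega_necrotic
  }
  structure(
    list(rounds = rounds, theta = theta, omega_necrotic = omega_necrotic,
         active_mask = active_mask, necrotic = necrotic,
         terminated = TRUE, fixed_point_reached = fixed_point,
         fields = fields),
    class = "mucoflow_necrosis_trace"
  )
}

#' @export
print.mucoflow_necrosis_trace <- function(x, ...) {
  cat(sprintf("<mucoflow_necrosis_trace> theta = %g, %d round(s)\n",
              x$theta, length(x$rounds)))
  cat(sprintf("  necrotic cells: %d, fixed point: %s\n",
              sum(x$necrotic), x$fixed_point_reached))
  invisible(x)
}

#' Round-by-round summary of a necrosis trace
#'
#' @param trace A `mucoflow_necrosis_trace`.
#' @return A tibble with one row per round: cumulative necrotic cells at
#'   the start of the round, new necroses marked from that round's
#'   solution, and the minimum `j_omega` over the active mask.
#' @export
trace_summary <- function(trace) {
  tibble::tibble(
    round = seq_along(trace$rounds),
    necrotic_cells = vapply(trace$rounds, function(r) sum(r$necrotic), double(1)),
    new_necrosis = vapply(trace$rounds, function(r) r$new_necrosis, double(1)),
    min_j_omega = vapply(trace$rounds, function(r)
      min(r$solution$j_omega[trace$active_mask]), double(1))
  )
}

#' Search for a self-limiting viability threshold
#'
#' Scans `n` candidate thresholds between the minimum and maximum observed
#' terminal flow over `active_mask` in the initial solve, and returns the
#' first whose fixed-point necrotic set is non-empty and strictly
#' contained in `within_mask` (default: the scenario's `watershed_centre`
#' mask, or the active mask). This exhibits the self-limiting regime of
#' the feedback without fixing a physiological value for the threshold,
#' which the model does not supply.
#'
#' @inheritParams run_necrosis_iteration
#' @param n Number of candidate thresholds.
#' @param within_mask Mask the fixed-point necrotic set must stay strictly
#'   inside.
#' @return List with `theta` and the corresponding `trace`, or `NULL` if
#'   no candidate qualifies.
#' @export
find_self_limiting_theta <- function(scenario, n = 12, omega_necrotic = 0.05,
                                     active_mask = NULL, within_mask = NULL,
                                     opts = solver_options()) {
  grid <- scenario$grid
  if (is.null(active_mask)) active_mask <- matrix(TRUE, grid$nx, grid$ny)
  if (is.null(within_mask))
    within_mask <- scenario$masks$watershed_centre %||% active_mask
  sol0 <- solve_gauss_seidel(scenario$fields, grid, opts)
  jw <- sol0$j_omega[active_mask]
  candidates <- seq(min(jw), max(jw), length.out = n + 2L)[2:(n + 1L)]
  for (theta in candidates) {
    tr <- run_necrosis_iteration(scenario, theta, omega_necrotic,
                                 active_mask, opts)
    nn <- sum(tr$necrotic)
    if (tr$fixed_point_reached && nn > 0 && nn < sum(within_mask) &&
        all(within_mask[tr$necrotic]))
      return(list(theta = theta, trace = tr, baseline = sol0))
  }
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a
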