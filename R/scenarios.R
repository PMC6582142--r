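new_scenario <- function(name, grid, fields, masks, metadata) {
  stopifnot(all(vapply(masks, function(m)
    is.logical(m) && identical(dim(m), c(grid$nx, grid$ny)), logical(1))))
  structure(list(name = name, grid = grid, fields = fields, masks = masks,
                 metadata = metadata),
            class = "mucoflow_scenario")
}

#' @export
print.mucoflow_scenario <- function(x, ...) {
  cat(sprintf("<mucoflow_scenario> '%s' on a %d x %d grid\n",
              x$name, x$grid$nx, x$grid$ny))
  cat("  masks:", paste(names(x$masks), collapse = ", "), "\n")
  cat("  constants:",
      paste(names(x$metadata), unlist(lapply(x$metadata, format)),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

apply_overrides <- function(constants, overrides) {
  if (is.null(overrides)) return(constants)
  unknown <- setdiff(names(overrides), names(constants))
  if (length(unknown) > 0L)
    stop("unknown scenario constant(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  constants[names(overrides)] <- overrides
  constants
}

col_mask <- function(grid, cols) {
  m <- matrix(FALSE, grid$nx, grid$ny); m[cols, ] <- TRUE; m
}
row_mask <- function(grid, rows) {
  m <- matrix(FALSE, grid$nx, grid$ny); m[, rows] <- TRUE; m
}

#' Antrum/corpus borderline scenario (gastric ulcer)
#'
#' The model's reference configuration for the typical gastric ulcer at
#' the antrum/corpus mucosal border: a 50 x 50 wall patch with limited
#' transmural influx everywhere (`alpha = 0.1`), a high-demand
#' acid-secreting corpus (`omega = 5.0`, axial cells 1-30) against the
#' passive antrum (`omega = 1.0`, cells 31-50). The lesser curvature
#' (circumferential rows 1-20) carries axially oriented submucosal
#' arteries (`lambda_x = 3.82e-1`, `lambda_y = 3.82e3`); the parietal wall
#' (rows 21-50) the circumferential pattern (`lambda_x = 3.82e3`,
#' `lambda_y = 3.82e-1`). Solving it produces the asymmetric terminal-flow
#' trough on the antral side of the border, confined to the lesser
#' curvature — the Reibungsform pattern.
#'
#' @param overrides Named list of constants to change; allowed names are
#'   those in the scenario `metadata` (`alpha`, `omega_corpus`,
#'   `omega_antrum`, `lambda_low`, `lambda_high`, `delta_p0`).
#' @return A `mucoflow_scenario` with masks `corpus`, `antrum`,
#'   `lesser_curvature`, `parietal_wall`.
#' @examples
#' sc <- scenario_antrum_borderline()
#' sum(sc$fields$omega == 5.0)  # 1500 corpus cells
#' @export
scenario_antrum_borderline <- function(overrides = NULL) {
  k <- apply_overrides(list(alpha = 0.1, omega_corpus = 5.0,
                            omega_antrum = 1.0, lambda_low = 3.82e-1,
                            lambda_high = 3.82e3, delta_p0 = 1),
                       overrides)
  grid <- grid_spec(50, 50)
  corpus <- col_mask(grid, 1:30)
  antrum <- col_mask(grid, 31:50)
  lesser <- row_mask(grid, 1:20)
  parietal <- row_mask(grid, 21:50)
  omega <- matrix(k$omega_antrum, 50, 50); omega[corpus] <- k$omega_corpus
  lx <- matrix(k$lambda_high, 50, 50); lx[lesser] <- k$lambda_low
  ly <- matrix(k$lambda_low, 50, 50); ly[lesser] <- k$lambda_high
  fields <- param_fields(grid, alpha = k$alpha, omega = omega,
                         lambda_x = lx, lambda_y = ly, delta_p0 = k$delta_p0)
  new_scenario("antrum-borderline", grid, fields,
               list(corpus = corpus, antrum = antrum,
                    lesser_curvature = lesser, parietal_wall = parietal),
               k)
}

#' Cardia scenario: the borderline mirrored
#'
#' The rare ulcer at the cardia sits at the cranial (proximal) edge of the
#' acid-secreting mucosa; its morphology is the lateral mirror image of the
#' typical antral ulcer. The scenario is [scenario_antrum_borderline()]
#' with every field (and mask) mirrored in x, so the corpus occupies the
#' high-x side.
#'
#' @inheritParams scenario_antrum_borderline
#' @return A `mucoflow_scenario`.
#' @export
scenario_cardia <- function(overrides = NULL) {
  base <- scenario_antrum_borderline(overrides)
  mir <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  f <- base$fields
  fields <- param_fields(base$grid, alpha = mir(f$alpha), omega = mir(f$omega),
                         lambda_x = mir(f$lambda_x), lambda_y = mir(f$lambda_y),
                         delta_p0 = f$delta_p0)
  new_scenario("cardia", base$grid, fields, lapply(base$masks, mir),
               base$metadata)
}

#' Linear (circumferential) ulcer scenario
#'
#' In the distal antrum the submucous plexus loses its circumferential
#' anisotropy: the mesh is star-shaped and the lateral resistance is the
#' same in both directions. The borderline flow trough is then no longer
#' confined to one part of the circumference but forms a ring — the linear
#' ulcer. Identical to [scenario_antrum_borderline()] except that
#' `lambda_x = lambda_y = 3.82e-1` everywhere.
#'
#' @inheritParams scenario_antrum_borderline
#' @return A `mucoflow_scenario`.
#' @export
scenario_linear_ulcer <- function(overrides = NULL) {
  base <- scenario_antrum_borderline(overrides)
  k <- base$metadata
  fields <- param_fields(base$grid, alpha = base$fields$alpha,
                         omega = base$fields$omega,
                         lambda_x = k$lambda_low, lambda_y = k$lambda_low,
                         delta_p0 = k$delta_p0)
  new_scenario("linear-ulcer", base$grid, fields, base$masks, k)
}

#' Watershed demand-ramp scenario (duodenal bulb)
#'
#' A collaterally supplied watershed area under rising mucosal demand: the
#' central 30 x 30 block (cells 11-40 in both directions) has essentially
#' no direct transmural influx (`alpha = 0.001`) while the surround has
#' free influx (`alpha = 1`); the submucosal mesh is isotropic
#' (`lambda = 3.82e-1`). Terminal conductivity `omega` is uniform at
#' `omega_level`; solving at `omega_level` 1, 10 and 100 reproduces the
#' demand ramp in which the central dip of mucosal blood flow deepens and
#' rounds off as demand rises.
#'
#' @param omega_level Positive uniform terminal conductivity.
#' @return A `mucoflow_scenario` with masks `watershed_centre` (900 cells)
#'   and `surround` (1600 cells).
#' @export
scenario_watershed <- function(omega_level = 10) {
  if (!is.numeric(omega_level) || length(omega_level) != 1L || omega_level <= 0)
    stop("`omega_level` must be a positive scalar", call. = FALSE)
  grid <- grid_spec(50, 50)
  centre <- matrix(FALSE, 50, 50); centre[11:40, 11:40] <- TRUE
  alpha <- matrix(1, 50, 50); alpha[centre] <- 0.001
  fields <- param_fields(grid, alpha = alpha, omega = omega_level,
                         lambda_x = 3.82e-1, lambda_y = 3.82e-1, delta_p0 = 1)
  new_scenario("watershed", grid, fields,
               list(watershed_centre = centre, surround = !centre),
               list(alpha_centre = 0.001, alpha_surround = 1,
                    lambda = 3.82e-1, omega_level = omega_level, delta_p0 = 1))
}

disc_mask <- function(grid, diameter) {
  cx <- (grid$nx + 1) / 2; cy <- (grid$ny + 1) / 2
  d <- outer(seq_len(grid$nx) - cx, seq_len(grid$ny) - cy,
             function(a, b) sqrt(a^2 + b^2))
  d <= diameter / 2 # ties on the rim count as inside
}

#' Necrosis scenario (duodenal ulcer, pre/post mucosal death)
#'
#' A circular watershed of diameter 18 cells centred on a 50 x 50 patch:
#' limited transmural influx inside (`alpha = 0.05`) against the surround
#' (`alpha = 0.1`), isotropic submucosa (`lambda = 3.82e-1`), vital
#' mucosal conductivity `omega = 10`. In stage `"post"` the mucosa of the
#' inner disc of diameter 15 is dead: its conductivity collapses to the
#' residual retrograde muscle supply, `omega = 0.05`. Comparing the two
#' stages shows the collateral-flow reversal and the contrast-enhanced,
#' sharply margined flow defect. The threshold-driven route to the same
#' state is [run_necrosis_iteration()].
#'
#' @param stage `"pre"` (vital mucosa) or `"post"` (necrotic core).
#' @return A `mucoflow_scenario` with masks `watershed_centre` (disc 18),
#'   `necrotic_core` (disc 15) and `surround`.
#' @export
scenario_necrosis <- function(stage = c("pre", "post")) {
  stage <- match.arg(stage)
  grid <- grid_spec(50, 50)
  watershed <- disc_mask(grid, 18)
  core <- disc_mask(grid, 15)
  alpha <- matrix(0.1, 50, 50); alpha[watershed] <- 0.05
  omega <- matrix(10, 50, 50)
  if (stage == "post") omega[core] <- 0.05
  fields <- param_fields(grid, alpha = alpha, omega = omega,
                         lambda_x = 3.82e-1, lambda_y = 3.82e-1, delta_p0 = 1)
  new_scenario(paste0("necrosis-", stage), grid, fields,
               list(watershed_centre = watershed, necrotic_core = core,
                    surround = !watershed),
               list(stage = stage, d_watershed = 18, d_core = 15,
                    alpha_centre = 0.05, alpha_surround = 0.1,
                    omega_vital = 10, omega_necrotic = 0.05,
                    lambda = 3.82e-1, delta_p0 = 1))
}

#' Homogeneous scenario
#'
#' Uniform fields on a 50 x 50 grid; the solved pressure is the cellwise
#' closed form `alpha * delta_p0 / (alpha + omega)` everywhere. Useful as a
#' null configuration.
#'
#' @param alpha,omega,lambda,delta_p0 Uniform constants.
#' @return A `mucoflow_scenario`.
#' @export
scenario_homogeneous <- function(alpha = 0.1, omega = 1, lambda = 3.82e-1,
                                 delta_p0 = 1) {
  grid <- grid_spec(50, 50)
  fields <- param_fields(grid, alpha, omega, lambda, lambda, delta_p0)
  new_scenario("homogeneous", grid, fields,
               list(all = matrix(TRUE, 50, 50)),
               list(alpha = alpha, omega = omega, lambda = lambda,
                    delta_p0 = delta_p0))
}

#' Seeded random test fixture
#'
#' Reproducible random parameter fields for oracle testing: log-uniform
#' `alpha` in \[1e-3, 1\], `omega` in \[1e-2, 1e2\], `lambda` in
#' \[1e-1, 1e4\], `delta_p0 = 1`. The same `(seed, nx, ny)` always yields
#' bit-identical fields; the caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param nx,ny Grid size (keep `nx * ny <= 10000`).
#' @return A `mucoflow_scenario`.
#' @export
random_fixture <- function(seed, nx = 10, ny = 10) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  grid <- grid_spec(nx, ny)
  logu <- function(lo, hi) matrix(10^stats::runif(nx * ny, log10(lo), log10(hi)),
                                  nx, ny)
  fields <- param_fields(grid, alpha = logu(1e-3, 1), omega = logu(1e-2, 1e2),
                         lambda_x = logu(1e-1, 1e4),
                         lambda_y = logu(1e-1, 1e4), delta_p0 = 1)
  new_scenario(sprintf("fixture-%d", seed), grid, fields,
               list(all = matrix(TRUE, nx, ny)),
               list(seed = seed, nx = nx, ny = ny))
}

#' Solve a scenario
#'
#' Runs [solve_gauss_seidel()] (or [solve_exact()]) on a scenario's fields.
#'
#' @param scenario A `mucoflow_scenario`.
#' @param opts A [solver_options()] object.
#' @param method `"gauss_seidel"` or `"direct"`.
#' @return A `mucoflow_solution`.
#' @examples
#' \donttest{
#' sol <- solve_scenario(scenario_antrum_borderline())
#' sol$converged
#' }
#' @export
solve_scenario <- function(scenario, opts = solver_options(),
                           method = c("gauss_seidel", "direct")) {
  method <- match.arg(method)
  if (method == "gauss_seidel")
    solve_gauss_seidel(scenario$fields, scenario$grid, opts)
  else
    solve_exact(scenario$fields, scenario$grid, opts)
}
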