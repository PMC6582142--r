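#' Options for the iterative solver
#'
#' @param tolerance Convergence tolerance on the maximum absolute per-sweep
#'   pressure update. `NULL` (the default) means `1e-10 * delta_p0`,
#'   resolved when the solve runs.
#' @param max_iterations Sweep cap, default 200000.
#' @param relaxation SOR relaxation factor in (0, 2); 1 is plain
#'   Gauss-Seidel, values above 1 over-relax.
#' @param face_convention How a face conductance is built from the two
#'   adjacent cells' lateral resistance: `"lower_index"` uses the
#'   lower-index cell alone (the model's finite-difference convention, in
#'   which the pressure drop to the next cell is carried by the resistance
#'   at the current cell), `"harmonic_mean"` the standard finite-volume
#'   harmonic average.
#' @return A `mucoflow_options` object.
#' @export
solver_options <- function(tolerance = NULL, max_iterations = 200000L,
                           relaxation = 1,
                           face_convention = c("lower_index", "harmonic_mean")) {
  face_convention <- match.arg(face_convention)
  if (!is.null(tolerance) && (!is.numeric(tolerance) || tolerance <= 0))
    stop("`tolerance` must be positive or NULL", call. = FALSE)
  if (max_iterations < 1) stop("`max_iterations` must be >= 1", call. = FALSE)
  if (relaxation <= 0 || relaxation >= 2)
    stop("`relaxation` must lie in (0, 2)", call. = FALSE)
  structure(
    list(tolerance = tolerance, max_iterations = as.integer(max_iterations),
         relaxation = as.numeric(relaxation), face_convention = face_convention),
    class = "mucoflow_options"
  )
}

resolve_tolerance <- function(opts, fields) {
  if (is.null(opts$tolerance)) 1e-10 * fields$delta_p0 else opts$tolerance
}

#' Assemble the finite-volume linear system
#'
#' Discretises the stationary perfusion balance
#' \eqn{\alpha(\Delta p_0 - p) - \omega p + \nabla\cdot(\lambda^{-1}\nabla p) = 0}
#' on the grid. Each cell's equation is
#' \eqn{(\alpha + \omega + \sum g)\,p - \sum g\,p_{nb} = \alpha \Delta p_0},
#' with face conductance `g = 1/(lambda * h^2)` taken from the lower-index
#' cell (default) or as the harmonic mean of the two adjacent cells. The
#' resulting matrix is diagonally dominant (an M-matrix), which is what
#' guarantees both Gauss-Seidel convergence and the maximum principle.
#'
#' @param fields A [param_fields()] object (must pass [validate_fields()]).
#' @param grid Grid; defaults to the one in `fields`.
#' @param opts A [solver_options()] object.
#' @return A `mucoflow_system`: list with `diagonal` (nx x ny),
#'   `face_conductance_x` ((nx+1) x ny), `face_conductance_y`
#'   (nx x (ny+1)), `source` (nx x ny), plus the grid and `delta_p0`.
#'   Boundary no-flux faces have conductance exactly 0; under
#'   `periodic_y` the first and last y-face columns carry the wrap face.
#' @export
assemble_system <- function(fields, grid = fields$grid, opts = solver_options()) {
  v <- validate_fields(fields, grid)
  if (nrow(v) > 0L)
    stop("invalid parameter fields: ", paste(v$message, collapse = "; "),
         call. = FALSE)
  nx <- grid$nx; ny <- grid$ny; h2 <- grid$h^2
  lx <- fields$lambda_x; ly <- fields$lambda_y

  gx <- matrix(0, nx + 1L, ny)
  if (nx > 1L) {
    if (opts$face_convention == "lower_index") {
      gx[2:nx, ] <- 1 / (lx[1:(nx - 1L), , drop = FALSE] * h2)
    } else {
      gx[2:nx, ] <- 2 / ((lx[1:(nx - 1L), , drop = FALSE] +
                            lx[2:nx, , drop = FALSE]) * h2)
    }
  }
  gy <- matrix(0, nx, ny + 1L)
  if (ny > 1L) {
    if (opts$face_convention == "lower_index") {
      gy[, 2:ny] <- 1 / (ly[, 1:(ny - 1L), drop = FALSE] * h2)
    } else {
      gy[, 2:ny] <- 2 / ((ly[, 1:(ny - 1L), drop = FALSE] +
                            ly[, 2:ny, drop = FALSE]) * h2)
    }
    if (grid$boundary == "periodic_y") {
      wrap <- if (opts$face_convention == "lower_index")
        1 / (ly[, ny] * h2)
      else
        2 / ((ly[, ny] + ly[, 1L]) * h2)
      gy[, 1L] <- wrap
      gy[, ny + 1L] <- wrap
    }
  }
  diagonal <- fields$alpha + fields$omega +
    gx[1:nx, , drop = FALSE] + gx[2:(nx + 1L), , drop = FALSE] +
    gy[, 1:ny, drop = FALSE] + gy[, 2:(ny + 1L), drop = FALSE]
  structure(
    list(diagonal = diagonal, face_conductance_x = gx, face_conductance_y = gy,
         source = fields$alpha * fields$delta_p0, grid = grid,
         delta_p0 = fields$delta_p0),
    class = "mucoflow_system"
  )
}

cell_index <- function(i, j, nx) i + (j - 1L) * nx

# laterally connected components over faces with positive conductance;
# returns an integer label per cell
lateral_components <- function(system) {
  nx <- system$grid$nx; ny <- system$grid$ny
  n <- nx * ny
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  gx <- system$face_conductance_x; gy <- system$face_conductance_y
  if (nx > 1L) for (j in seq_len(ny)) for (i in seq_len(nx - 1L))
    if (gx[i + 1L, j] > 0) union_(cell_index(i, j, nx), cell_index(i + 1L, j, nx))
  if (ny > 1L) {
    for (j in seq_len(ny - 1L)) for (i in seq_len(nx))
      if (gy[i, j + 1L] > 0) union_(cell_index(i, j, nx), cell_index(i, j + 1L, nx))
    if (system$grid$boundary == "periodic_y")
      for (i in seq_len(nx))
        if (gy[i, 1L] > 0) union_(cell_index(i, ny, nx), cell_index(i, 1L, nx))
  }
  vapply(seq_len(n), find, integer(1))
}

#' Solve the assembled system by a sparse direct method
#'
#' Ground-truth companion to [solve_gauss_seidel()]: builds the sparse
#' system matrix and solves it exactly (up to floating point) with a sparse
#' Cholesky/LU factorisation. A laterally connected component whose cells
#' all have `alpha + omega = 0` makes the matrix singular; this is reported
#' with a cell of the offending component.
#'
#' @param system A `mucoflow_system` from [assemble_system()].
#' @return The pressure grid `p` (nx x ny matrix).
#' @export
solve_direct <- function(system) {
  stopifnot(inherits(system, "mucoflow_system"))
  nx <- system$grid$nx; ny <- system$grid$ny
  n <- nx * ny
  rowsum_cond <- system$diagonal - (system$face_conductance_x[1:nx, , drop = FALSE] +
    system$face_conductance_x[2:(nx + 1L), , drop = FALSE] +
    system$face_conductance_y[, 1:ny, drop = FALSE] +
    system$face_conductance_y[, 2:(ny + 1L), drop = FALSE])
  # rowsum_cond == alpha + omega; singular component check
  comp <- lateral_components(system)
  anchored <- tapply(as.vector(rowsum_cond) > 0, comp, any)
  if (!all(anchored)) {
    bad <- names(anchored)[!anchored][1L]
    cell <- which(comp == as.integer(bad))[1L]
    i <- ((cell - 1L) %% nx) + 1L; j <- ((cell - 1L) %/% nx) + 1L
    stop(sprintf(paste("singular system: the laterally connected component",
                       "containing cell (%d,%d) has no inflow or outflow",
                       "(alpha + omega = 0 throughout)"), i, j), call. = FALSE)
  }
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  push <- function(a, b, v) {
    keep <- v != 0
    ii <<- c(ii, a[keep]); jj <<- c(jj, b[keep]); vv <<- c(vv, -v[keep])
  }
  gx <- system$face_conductance_x; gy <- system$face_conductance_y
  if (nx > 1L) {
    for (j in seq_len(ny)) {
      i <- seq_len(nx - 1L)
      a <- cell_index(i, j, nx); b <- cell_index(i + 1L, j, nx)
      g <- gx[i + 1L, j]
      push(a, b, g); push(b, a, g)
    }
  }
  if (ny > 1L) {
    for (j in seq_len(ny - 1L)) {
      i <- seq_len(nx)
      a <- cell_index(i, j, nx); b <- cell_index(i, j + 1L, nx)
      g <- gy[i, j + 1L]
      push(a, b, g); push(b, a, g)
    }
    if (system$grid$boundary == "periodic_y") {
      i <- seq_len(nx)
      a <- cell_index(i, ny, nx); b <- cell_index(i, 1L, nx)
      g <- gy[i, 1L]
      push(a, b, g); push(b, a, g)
    }
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                            x = c(as.vector(system$diagonal), vv),
                            dims = c(n, n))
  p <- Matrix::solve(A, as.vector(system$source))
  matrix(as.numeric(p), nx, ny)
}

#' Solve the perfusion equation by Gauss-Seidel (SOR) iteration
#'
#' Sweeps the cells in a fixed order (ascending x within ascending y),
#' applying the relaxed update
#' \eqn{p \leftarrow (1-w)p + w(\alpha\Delta p_0 + \sum g\,p_{nb}) /
#' (\alpha+\omega+\sum g)} until the largest absolute update in a sweep
#' falls below the tolerance. The initial guess is the cellwise closed form
#' \eqn{p = \alpha\Delta p_0/(\alpha+\omega)} (0/0 treated as 0), which is
#' already exact for laterally decoupled or homogeneous fields. The system
#' is diagonally dominant, so the sweep never diverges; if the sweep cap is
#' reached first the fields are still returned with `converged = FALSE`.
#'
#' @inheritParams assemble_system
#' @return A `mucoflow_solution`: pressure `p`, flow densities `j_alpha`,
#'   `j_omega`, face flows `j_lambda_x`, `j_lambda_y`, plus `iterations`,
#'   `converged`, `max_update`, `max_residual`, `global_imbalance`, the
#'   grid, fields and resolved options.
#' @examples
#' g <- grid_spec(10, 10)
#' f <- param_fields(g, alpha = 0.1, omega = 1, lambda_x = 1, lambda_y = 1)
#' sol <- solve_gauss_seidel(f)
#' range(sol$p)  # uniform 0.1/1.1
#' @export
solve_gauss_seidel <- function(fields, grid = fields$grid,
                               opts = solver_options()) {
  system <- assemble_system(fields, grid, opts)
  tol <- resolve_tolerance(opts, fields)
  denom <- fields$alpha + fields$omega
  p0 <- ifelse(denom > 0, fields$alpha * fields$delta_p0 / denom, 0)
  p0 <- matrix(p0, grid$nx, grid$ny)
  # gs_iterate updates its first argument in place; force a fresh copy
  p <- p0 + 0
  res <- gs_iterate(p, system$source, system$diagonal,
                    system$face_conductance_x, system$face_conductance_y,
                    grid$boundary == "periodic_y",
                    tol, opts$max_iterations, opts$relaxation)
  build_solution(p, fields, grid, opts,
                 iterations = res$iterations, converged = res$converged,
                 max_update = res$max_update)
}

build_solution <- function(p, fields, grid, opts, iterations, converged,
                           max_update) {
  flows <- compute_flows(p, fields, grid, opts)
  sol <- structure(
    c(list(p = p), flows,
      list(iterations = as.integer(iterations), converged = converged,
           max_update = max_update, grid = grid, fields = fields,
           opts = opts)),
    class = "mucoflow_solution"
  )
  bal <- balance_residuals(sol, fields, grid)
  sol$max_residual <- max(abs(bal$residuals))
  sol$global_imbalance <- bal$global_imbalance
  sol
}

#' Exact solve wrapped as a solution object
#'
#' Convenience: [assemble_system()] + [solve_direct()] + [compute_flows()],
#' returning the same `mucoflow_solution` structure as
#' [solve_gauss_seidel()] (with `iterations = 0`).
#'
#' @inheritParams assemble_system
#' @return A `mucoflow_solution`.
#' @export
solve_exact <- function(fields, grid = fields$grid, opts = solver_options()) {
  system <- assemble_system(fields, grid, opts)
  p <- solve_direct(system)
  build_solution(p, fields, grid, opts,
                 iterations = 0L, converged = TRUE, max_update = 0)
}

#' @export
print.mucoflow_solution <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<mucoflow_solution> %d x %d grid\n", g$nx, g$ny))
  cat(sprintf("  p in [%.6g, %.6g] (delta_p0 = %g)\n",
              min(x$p), max(x$p), x$fields$delta_p0))
  cat(sprintf("  j_omega in [%.6g, %.6g]\n", min(x$j_omega), max(x$j_omega)))
  cat(sprintf("  iterations = %d, converged = %s, max residual = %.3g\n",
              x$iterations, x$converged, x$max_residual))
  invisible(x)
}

#' Derive all flow fields from a pressure grid
#'
#' Flow densities `j_alpha = alpha * (delta_p0 - p)` (transmural influx)
#' and `j_omega = omega * p` (terminal outflow), plus face-centred lateral
#' flows `j_lambda = g * (p_lower - p_upper)`, positive in the +x / +y
#' direction. No-flux boundary faces are exactly zero.
#'
#' @param p Pressure matrix of grid shape.
#' @inheritParams assemble_system
#' @return List with `j_alpha`, `j_omega` (nx x ny), `j_lambda_x`
#'   ((nx+1) x ny) and `j_lambda_y` (nx x (ny+1); under `periodic_y` the
#'   first and last columns both hold the wrap-face flow).
#' @export
compute_flows <- function(p, fields, grid = fields$grid,
                          opts = solver_options()) {
  stopifnot(identical(dim(p), c(grid$nx, grid$ny)))
  system <- assemble_system(fields, grid, opts)
  nx <- grid$nx; ny <- grid$ny
  gx <- system$face_conductance_x; gy <- system$face_conductance_y
  jx <- matrix(0, nx + 1L, ny)
  if (nx > 1L)
    jx[2:nx, ] <- gx[2:nx, , drop = FALSE] *
      (p[1:(nx - 1L), , drop = FALSE] - p[2:nx, , drop = FALSE])
  jy <- matrix(0, nx, ny + 1L)
  if (ny > 1L) {
    jy[, 2:ny] <- gy[, 2:ny, drop = FALSE] *
      (p[, 1:(ny - 1L), drop = FALSE] - p[, 2:ny, drop = FALSE])
    if (grid$boundary == "periodic_y") {
      wrap <- gy[, 1L] * (p[, ny] - p[, 1L])
      jy[, 1L] <- wrap
      jy[, ny + 1L] <- wrap
    }
  }
  list(j_alpha = fields$alpha * (fields$delta_p0 - p),
       j_omega = fields$omega * p,
       j_lambda_x = jx, j_lambda_y = jy)
}

#' Audit Kirchhoff balance of a solution
#'
#' Recomputes the stationary flow balance cell by cell: influx minus
#' outflow minus net lateral outflow. At a converged solution every
#' residual is at (10x) tolerance scale; the global imbalance
#' `|sum(j_alpha) - sum(j_omega)| * h^2` checks total conservation (under
#' no-flux boundaries the lateral flows telescope away).
#'
#' @param sol A `mucoflow_solution`.
#' @inheritParams assemble_system
#' @return List with `residuals` (nx x ny matrix) and `global_imbalance`
#'   (scalar).
#' @export
balance_residuals <- function(sol, fields = sol$fields, grid = sol$grid) {
  nx <- grid$nx; ny <- grid$ny
  jx <- sol$j_lambda_x; jy <- sol$j_lambda_y
  net_lateral <- (jx[2:(nx + 1L), , drop = FALSE] - jx[1:nx, , drop = FALSE]) +
    (jy[, 2:(ny + 1L), drop = FALSE] - jy[, 1:ny, drop = FALSE])
  residuals <- sol$j_alpha - sol$j_omega - net_lateral
  list(residuals = residuals,
       global_imbalance = abs(sum(sol$j_alpha) - sum(sol$j_omega)) * grid$h^2)
}

#' Net lateral flow across a region boundary
#'
#' Sums the face flows crossing the boundary of `mask`, oriented so a
#' positive value means net collateral flow *into* the region. This is the
#' quantity whose sign flips when a watershed centre turns necrotic: the
#' vital dip attracts collateral flow, the necrotic core sheds it.
#'
#' @param sol A `mucoflow_solution`.
#' @param mask Logical matrix of grid shape selecting the region.
#' @return Signed scalar net inflow.
#' @export
net_boundary_flow <- function(sol, mask) {
  grid <- sol$grid
  stopifnot(identical(dim(mask), c(grid$nx, grid$ny)))
  nx <- grid$nx; ny <- grid$ny
  jx <- sol$j_lambda_x; jy <- sol$j_lambda_y
  total <- 0
  if (nx > 1L) {
    left <- mask[1:(nx - 1L), , drop = FALSE]; right <- mask[2:nx, , drop = FALSE]
    f <- jx[2:nx, , drop = FALSE]
    total <- total + sum(f[!left & right]) - sum(f[left & !right])
  }
  if (ny > 1L) {
    low <- mask[, 1:(ny - 1L), drop = FALSE]; up <- mask[, 2:ny, drop = FALSE]
    f <- jy[, 2:ny, drop = FALSE]
    total <- total + sum(f[!low & up]) - sum(f[low & !up])
    if (grid$boundary == "periodic_y") {
      f <- jy[, 1L]
      lowc <- mask[, ny]; upc <- mask[, 1L]
      total <- total + sum(f[!lowc & upc]) - sum(f[lowc & !upc])
    }
  }
  total
}
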