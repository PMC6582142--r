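#' Define the computational grid of the wall model
#'
#' The intestinal wall is discretised into `nx` axial by `ny` circumferential
#' cells of edge length `h`. The x direction runs oral to aboral (corpus
#' towards antrum/duodenum), y runs around the organ circumference. Axial
#' (x) edges are always no-flux; the circumference can optionally be closed
#' (`boundary = "periodic_y"`) to represent a full organ ring.
#'
#' @param nx,ny Positive integers, number of cells in x (axial) and y
#'   (circumferential).
#' @param h Positive cell edge length in dimensionless model units.
#' @param boundary Either `"no_flux"` (isolated tissue patch, the default)
#'   or `"periodic_y"` (circumference wrapped).
#' @return A `mucoflow_grid` object.
#' @examples
#' grid_spec(50, 50)
#' @export
grid_spec <- function(nx, ny, h = 1, boundary = c("no_flux", "periodic_y")) {
  boundary <- match.arg(boundary)
  if (!is.numeric(nx) || length(nx) != 1L || nx < 1 || nx != round(nx))
    stop("`nx` must be a positive integer", call. = FALSE)
  if (!is.numeric(ny) || length(ny) != 1L || ny < 1 || ny != round(ny))
    stop("`ny` must be a positive integer", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("`h` must be a positive number", call. = FALSE)
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), h = as.numeric(h),
         boundary = boundary),
    class = "mucoflow_grid"
  )
}

#' @export
print.mucoflow_grid <- function(x, ...) {
  cat(sprintf("<mucoflow_grid> %d x %d cells, h = %g, boundary = %s\n",
              x$nx, x$ny, x$h, x$boundary))
  invisible(x)
}

# recycle a scalar to the grid shape, or check a matrix against it
as_field_matrix <- function(value, grid, name) {
  if (is.null(value)) stop("field `", name, "` is missing", call. = FALSE)
  if (length(value) == 1L) {
    matrix(as.numeric(value), grid$nx, grid$ny)
  } else {
    if (!is.matrix(value) || !identical(dim(value), c(grid$nx, grid$ny)))
      stop("field `", name, "` must be a scalar or a ", grid$nx, " x ",
           grid$ny, " matrix", call. = FALSE)
    storage.mode(value) <- "double"
    value
  }
}

#' Bundle the model's parameter fields
#'
#' The four conductivity/resistance fields of the wall model plus the
#' systemic perfusion-pressure gradient:
#' * `alpha` — transmural influx conductivity per area (muscle-perforating
#'   arteries); falls with wall stress.
#' * `omega` — terminal outflow conductivity per area (mucosal vascular bed
#'   plus retrogradely supplied muscle); rises with metabolic demand.
#' * `lambda_x`, `lambda_y` — lateral haemodynamic resistance of the
#'   submucous plexus in the axial and circumferential direction.
#' * `delta_p0` — systemic arterial perfusion-pressure gradient over the
#'   wall as a whole.
#'
#' Scalars are recycled to the full grid. All quantities are dimensionless.
#'
#' @param grid A [grid_spec()] object.
#' @param alpha,omega Non-negative scalar or `nx` x `ny` matrix.
#' @param lambda_x,lambda_y Positive scalar or `nx` x `ny` matrix.
#' @param delta_p0 Positive scalar.
#' @return A `mucoflow_fields` object (list of matrices plus the grid).
#' @seealso [validate_fields()]
#' @examples
#' g <- grid_spec(10, 10)
#' param_fields(g, alpha = 0.1, omega = 1, lambda_x = 0.382, lambda_y = 0.382)
#' @export
param_fields <- function(grid, alpha, omega, lambda_x, lambda_y,
                         delta_p0 = 1) {
  stopifnot(inherits(grid, "mucoflow_grid"))
  f <- structure(
    list(
      alpha    = as_field_matrix(alpha, grid, "alpha"),
      omega    = as_field_matrix(omega, grid, "omega"),
      lambda_x = as_field_matrix(lambda_x, grid, "lambda_x"),
      lambda_y = as_field_matrix(lambda_y, grid, "lambda_y"),
      delta_p0 = as.numeric(delta_p0),
      grid     = grid
    ),
    class = "mucoflow_fields"
  )
  f
}

#' @export
print.mucoflow_fields <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<mucoflow_fields> %d x %d grid, delta_p0 = %g\n",
              g$nx, g$ny, x$delta_p0))
  for (nm in c("alpha", "omega", "lambda_x", "lambda_y")) {
    v <- x[[nm]]
    cat(sprintf("  %-9s in [%g, %g]\n", nm, min(v), max(v)))
  }
  invisible(x)
}

#' Validate parameter fields against the model invariants
#'
#' Checks shapes, sign constraints (`alpha >= 0`, `omega >= 0`,
#' `lambda_x > 0`, `lambda_y > 0`, `delta_p0 > 0`) and the presence of at
#' least one pressure source (`alpha > 0` somewhere). Violations are
#' returned as data, one row each, never raised as conditions.
#'
#' @param fields A [param_fields()] object.
#' @param grid Grid to check against; defaults to the grid stored in
#'   `fields`.
#' @return A tibble with columns `check`, `cell` (a "(i,j)" label or `NA`
#'   for global checks) and `message`. Zero rows means the fields are valid.
#' @examples
#' g <- grid_spec(5, 5)
#' f <- param_fields(g, 0.1, 1, 0.382, 0.382)
#' validate_fields(f)  # 0 rows
#' @export
validate_fields <- function(fields, grid = fields$grid) {
  stopifnot(inherits(fields, "mucoflow_fields"), inherits(grid, "mucoflow_grid"))
  bad <- list()
  add <- function(check, cell, message) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(
      check = check, cell = cell, message = message)
  }
  shape <- c(grid$nx, grid$ny)
  first_cell <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)[1L, , drop = TRUE]
    sprintf("(%d,%d)", idx[[1L]], idx[[2L]])
  }
  for (nm in c("alpha", "omega", "lambda_x", "lambda_y")) {
    m <- fields[[nm]]
    if (!is.matrix(m) || !identical(dim(m), as.integer(shape))) {
      add("shape", NA_character_,
          sprintf("%s does not have grid shape %d x %d", nm, shape[1], shape[2]))
      next
    }
    if (anyNA(m) || any(!is.finite(m))) {
      add("finite", first_cell(!is.finite(m)),
          sprintf("%s contains non-finite values", nm))
      next
    }
    if (nm %in% c("alpha", "omega") && any(m < 0))
      add("negative_conductivity", first_cell(m < 0),
          sprintf("%s must be >= 0", nm))
    if (nm %in% c("lambda_x", "lambda_y") && any(m <= 0))
      add("non_positive_resistance", first_cell(m <= 0),
          sprintf("%s must be > 0", nm))
  }
  if (!is.numeric(fields$delta_p0) || length(fields$delta_p0) != 1L ||
      !is.finite(fields$delta_p0) || fields$delta_p0 <= 0)
    add("delta_p0", NA_character_, "delta_p0 must be a positive scalar")
  if (is.matrix(fields$alpha) && identical(dim(fields$alpha), as.integer(shape)) &&
      all(is.finite(fields$alpha)) && all(fields$alpha <= 0))
    add("no_pressure_source", NA_character_,
        "alpha is zero everywhere: the system has no pressure source")
  if (length(bad) == 0L)
    tibble::tibble(check = character(), cell = character(), message = character())
  else
    do.call(rbind, bad)
}
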