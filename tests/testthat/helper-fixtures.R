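# shared helpers for building tiny instances in code

tiny_fields <- function(nx = 2, ny = 1, alpha = 1, omega = 1,
                        lambda = 1, delta_p0 = 1, boundary = "no_flux") {
  g <- grid_spec(nx, ny, boundary = boundary)
  param_fields(g, alpha = alpha, omega = omega,
               lambda_x = lambda, lambda_y = lambda, delta_p0 = delta_p0)
}

# rasterized disc centred on an nx x ny grid, ties-inside convention
helper_disc_mask <- function(nx, ny, diameter) {
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  d <- outer(seq_len(nx) - cx, seq_len(ny) - cy, function(a, b) sqrt(a^2 + b^2))
  d <= diameter / 2
}

# wrap a bare pressure grid into enough of a solution for the metric and
# balance functions
wrap_solution <- function(p, fields, grid = fields$grid,
                          opts = solver_options()) {
  flows <- compute_flows(p, fields, grid, opts)
  structure(c(list(p = p), flows,
              list(grid = grid, fields = fields, opts = opts)),
            class = "mucoflow_solution")
}

# piecewise-linear trough profile: plateaus at 1, minimum 0 at `imin`,
# linear rise over `left` cells proximally and `right` cells distally,
# so the 50%-recovery half-widths are left/2 and right/2 exactly
synthetic_trough <- function(n = 30, imin = 10, left = 4, right = 12) {
  v <- rep(1, n)
  for (k in 0:left) v[imin - k] <- k / left
  for (k in 0:right) v[imin + k] <- k / right
  v
}
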