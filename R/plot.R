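#' Tidy a solution into a long tibble
#'
#' One row per grid cell with the pressure and flow densities — the
#' natural input for ggplot2 raster plots or further dplyr work.
#'
#' @param sol A `mucoflow_solution`.
#' @return Tibble with columns `x`, `y`, `p`, `j_alpha`, `j_omega`.
#' @export
solution_tibble <- function(sol) {
  nx <- sol$grid$nx; ny <- sol$grid$ny
  tibble::tibble(
    x = rep(seq_len(nx), times = ny),
    y = rep(seq_len(ny), each = nx),
    p = as.vector(sol$p),
    j_alpha = as.vector(sol$j_alpha),
    j_omega = as.vector(sol$j_omega)
  )
}

#' Plot a solved flow field
#'
#' Raster view of a solution field, oriented like the model's surface
#' plots (x axial left to right, y circumferential). Requires ggplot2.
#'
#' @param sol A `mucoflow_solution`.
#' @param field One of `"j_omega"`, `"j_alpha"`, `"p"`.
#' @return A ggplot object.
#' @export
plot_field <- function(sol, field = c("j_omega", "j_alpha", "p")) {
  field <- match.arg(field)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- solution_tibble(sol)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data[[field]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = field) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (axial)", y = "y (circumferential)") +
    ggplot2::theme_minimal()
}

#' Plot an axial terminal-flow profile
#'
#' @param sol A `mucoflow_solution`.
#' @param row Circumferential row index.
#' @return A ggplot object.
#' @export
plot_profile <- function(sol, row) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- axial_profile(sol, row)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$j_omega)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x (axial)", y = "terminal flow j_omega") +
    ggplot2::theme_minimal()
}
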