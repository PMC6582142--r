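undefined_metric <- function(msg) {
  stop(structure(class = c("mucoflow_undefined_metric", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Terminal-flow profile along one circumferential row
#'
#' @param sol A `mucoflow_solution`.
#' @param row Circumferential index `y` (1-based).
#' @return Tibble with columns `x` and `j_omega`, ascending x (oral to
#'   aboral).
#' @export
axial_profile <- function(sol, row) {
  ny <- sol$grid$ny
  if (!is.numeric(row) || length(row) != 1L || row < 1 || row > ny)
    stop("`row` must lie in [1, ", ny, "]", call. = FALSE)
  tibble::tibble(x = seq_len(sol$grid$nx), j_omega = sol$j_omega[, row])
}

# median of the last `k` profile values = the distal plateau reference
distal_plateau <- function(values, k = 10) {
  n <- length(values)
  stats::median(values[max(1L, n - k + 1L):n])
}

# linearly interpolated distance from the minimum to the first crossing of
# `level` walking in direction `dir` (+1 distal, -1 proximal)
halfwidth <- function(values, imin, level, dir) {
  n <- length(values)
  i <- imin
  repeat {
    nxt <- i + dir
    if (nxt < 1L || nxt > n) return(NA_real_)
    if (values[nxt] >= level) {
      frac <- (level - values[i]) / (values[nxt] - values[i])
      return(abs(i - imin) + frac)
    }
    i <- nxt
  }
}

#' Asymmetry ratio of a flow trough (Reibungsform orientation)
#'
#' Quantifies the staircase asymmetry of the borderline flow trough: the
#' profile minimum is located and, on each side, the distance from the
#' minimum to the point where the flow recovers to 50% of that side's
#' plateau (median of the 10 outermost cells on that side) is measured,
#' linearly interpolated between cells. The ratio distal/proximal
#' half-width exceeds 1 when the trough has the classic gastric-ulcer
#' orientation — steep edge toward the corpus, shallow tail running
#' distally. Because each side is referenced to its own plateau, the
#' metric of a mirrored profile is exactly the reciprocal.
#'
#' @param profile A tibble from [axial_profile()] or a numeric vector of
#'   `j_omega` values in ascending x.
#' @param boundary_x Optional mucosal-border position; only recorded, the
#'   trough is located from the profile itself.
#' @return Positive scalar `distal_half_width / proximal_half_width`.
#' @export
reibungsform_asymmetry <- function(profile, boundary_x = NULL) {
  v <- if (is.data.frame(profile)) profile$j_omega else as.numeric(profile)
  n <- length(v)
  imin <- which.min(v)
  if (imin == 1L || imin == n || !any(v > v[imin]))
    undefined_metric("profile has no interior minimum")
  ref_distal <- distal_plateau(v)
  ref_proximal <- distal_plateau(rev(v))
  if (ref_distal <= v[imin] || ref_proximal <= v[imin])
    undefined_metric("plateau does not rise above the minimum")
  dw <- halfwidth(v, imin, v[imin] + 0.5 * (ref_distal - v[imin]), +1L)
  pw <- halfwidth(v, imin, v[imin] + 0.5 * (ref_proximal - v[imin]), -1L)
  if (is.na(dw) || is.na(pw))
    undefined_metric("profile does not recover to the 50% level on both sides")
  dw / pw
}

#' Regional steal index
#'
#' Relative change of mean terminal flow over a region between a test and
#' a baseline solution:
#' `(mean j_omega test - mean j_omega baseline) / mean j_omega baseline`.
#' Negative over the antral border zone when corpus demand rises — the
#' submucosal steal.
#'
#' @param sol_test,sol_baseline Solutions on the same grid.
#' @param region Non-empty logical grid mask.
#' @return Signed scalar.
#' @export
steal_index <- function(sol_test, sol_baseline, region) {
  stopifnot(identical(dim(sol_test$j_omega), dim(sol_baseline$j_omega)),
            identical(dim(region), dim(sol_test$j_omega)))
  if (!any(region)) stop("`region` is empty", call. = FALSE)
  base <- mean(sol_baseline$j_omega[region])
  if (base == 0) undefined_metric("baseline mean j_omega over region is zero")
  (mean(sol_test$j_omega[region]) - base) / base
}

#' Central dip depth of terminal flow
#'
#' `1 - min(j_omega over centre) / mean(j_omega over reference)`, clipped
#' to \[0, 1\]. Zero for a flat field, approaching 1 when flow at the
#' centre of a watershed collapses relative to the periphery.
#'
#' @param sol A `mucoflow_solution`.
#' @param centre_mask,reference_mask Non-empty, disjoint logical masks.
#' @return Scalar in \[0, 1\].
#' @export
dip_depth <- function(sol, centre_mask, reference_mask) {
  stopifnot(any(centre_mask), any(reference_mask),
            !any(centre_mask & reference_mask))
  ref <- mean(sol$j_omega[reference_mask])
  if (ref == 0) undefined_metric("reference mean j_omega is zero")
  min(max(1 - min(sol$j_omega[centre_mask]) / ref, 0), 1)
}

# largest 4-connected component of a logical mask; returns logical matrix
largest_component <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  current <- 0L
  best <- NULL; best_size <- 0L
  for (j0 in seq_len(ny)) for (i0 in seq_len(nx)) {
    if (!mask[i0, j0] || lab[i0, j0] != 0L) next
    current <- current + 1L
    stack <- list(c(i0, j0)); lab[i0, j0] <- current
    cells <- matrix(c(i0, j0), 1L)
    while (length(stack) > 0L) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- cur[1L]; j <- cur[2L]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        a <- i + d[1L]; b <- j + d[2L]
        if (a >= 1L && a <= nx && b >= 1L && b <= ny &&
            mask[a, b] && lab[a, b] == 0L) {
          lab[a, b] <- current
          stack[[length(stack) + 1L]] <- c(a, b)
          cells <- rbind(cells, c(a, b))
        }
      }
    }
    if (nrow(cells) > best_size) { best_size <- nrow(cells); best <- current }
  }
  lab == best
}

# boundary edge count of a mask (4-neighbour; grid border counts)
perimeter_edges <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  pad <- matrix(FALSE, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- mask
  inner <- pad[2:(nx + 1L), 2:(ny + 1L)]
  sum(inner & !pad[1:nx, 2:(ny + 1L)]) +
    sum(inner & !pad[3:(nx + 2L), 2:(ny + 1L)]) +
    sum(inner & !pad[2:(nx + 1L), 1:ny]) +
    sum(inner & !pad[2:(nx + 1L), 3:(ny + 2L)])
}

#' Shape circularity of a mask
#'
#' `4 * pi * A / P^2` with `A` the cell count and `P` the 4-neighbour
#' boundary edge count. A single cell scores `4*pi/16`; note that with an
#' edge-count (taxicab) perimeter the index is maximised by squares, so
#' comparisons are meaningful between rasterized shapes scored the same
#' way, not against the Euclidean ideal of 1.
#'
#' @param mask Non-empty logical matrix.
#' @return Scalar in (0, 1\].
#' @export
mask_circularity <- function(mask) {
  if (!any(mask)) undefined_metric("mask is empty")
  comp <- largest_component(mask)
  4 * pi * sum(comp) / perimeter_edges(comp)^2
}

#' Circularity of a flow sublevel set
#'
#' Thresholds the terminal flow within `search_mask` at
#' `min + level_fraction * (reference - min)` (reference = median of
#' `j_omega` over the search mask, a robust plateau level), takes the
#' largest 4-connected sublevel component and returns its
#' [mask_circularity()]. Used to show that the flow dip over a square
#' watershed rounds off toward a disc.
#'
#' @param sol A `mucoflow_solution`.
#' @param level_fraction Threshold position in (0, 1).
#' @param search_mask Logical mask to search in; defaults to the whole
#'   grid.
#' @return List with `circularity`, the sublevel `mask`, and the
#'   `threshold` used.
#' @export
circularity <- function(sol, level_fraction = 0.2, search_mask = NULL) {
  if (level_fraction <= 0 || level_fraction >= 1)
    stop("`level_fraction` must lie in (0, 1)", call. = FALSE)
  jw <- sol$j_omega
  if (is.null(search_mask)) search_mask <- matrix(TRUE, nrow(jw), ncol(jw))
  vals <- jw[search_mask]
  lo <- min(vals)
  ref <- stats::median(vals)
  threshold <- lo + level_fraction * (ref - lo)
  mask <- search_mask & (jw <= threshold)
  if (!any(mask)) undefined_metric("sublevel set is empty")
  comp <- largest_component(mask)
  list(circularity = 4 * pi * sum(comp) / perimeter_edges(comp)^2,
       mask = comp, threshold = threshold)
}

# relative interior trough depth of one row profile, against its distal
# plateau; 0 when no interior minimum exists
row_trough_depth <- function(v) {
  n <- length(v)
  imin <- which.min(v)
  if (imin == 1L || imin == n) return(0)
  ref <- distal_plateau(v)
  if (ref <= 0) return(0)
  max(0, (ref - v[imin]) / ref)
}

#' Circumferential extent of the flow trough
#'
#' Fraction of circumferential rows whose axial profile contains an
#' interior minimum deeper than `depth_threshold` (relative to that row's
#' distal plateau, the median of its last 10 cells). 1 means the trough
#' rings the whole circumference (linear ulcer); the anisotropic
#' borderline scenario confines it to the lesser curvature and scores
#' below 1.
#'
#' @param sol A `mucoflow_solution`.
#' @param depth_threshold Relative depth in (0, 1); default 0.05.
#' @return Scalar in \[0, 1\].
#' @export
circumferential_extent <- function(sol, depth_threshold = 0.05) {
  depths <- apply(sol$j_omega, 2L, row_trough_depth)
  mean(depths > depth_threshold)
}

# per-cell gradient magnitude of a field by central differences
# (one-sided at the grid border)
gradient_magnitude <- function(f, h = 1) {
  nx <- nrow(f); ny <- ncol(f)
  gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
  if (nx > 1L) {
    gx[2:(nx - 1L), ] <- (f[3:nx, , drop = FALSE] -
                            f[1:(nx - 2L), , drop = FALSE]) / (2 * h)
    gx[1L, ] <- (f[2L, ] - f[1L, ]) / h
    gx[nx, ] <- (f[nx, ] - f[nx - 1L, ]) / h
  }
  if (ny > 1L) {
    gy[, 2:(ny - 1L)] <- (f[, 3:ny, drop = FALSE] -
                            f[, 1:(ny - 2L), drop = FALSE]) / (2 * h)
    gy[, 1L] <- (f[, 2L] - f[, 1L]) / h
    gy[, ny] <- (f[, ny] - f[, ny - 1L]) / h
  }
  sqrt(gx^2 + gy^2)
}

#' Margin contrast enhancement across a necrotic boundary
#'
#' Ratio of the maximum terminal-flow gradient magnitude over the boundary
#' cells after mucosal death to the same quantity before: above 1 means
#' the margin of the flow defect has sharpened — the contrast enhancement
#' that turns a soft dip into a demarcated lesion.
#'
#' @param sol_pre,sol_post Solutions on the same grid.
#' @param boundary_cells Non-empty logical mask of the cells straddling
#'   the necrotic border.
#' @return Positive scalar.
#' @export
contrast_enhancement <- function(sol_pre, sol_post, boundary_cells) {
  stopifnot(identical(dim(sol_pre$j_omega), dim(sol_post$j_omega)),
            any(boundary_cells))
  h <- sol_pre$grid$h
  pre <- max(gradient_magnitude(sol_pre$j_omega, h)[boundary_cells])
  if (pre == 0) undefined_metric("pre-necrosis boundary gradient is zero")
  max(gradient_magnitude(sol_post$j_omega, h)[boundary_cells]) / pre
}

#' Boundary ring of a mask
#'
#' Cells of `mask` adjacent (4-neighbour) to a cell outside it, together
#' with the outside cells adjacent to the mask — the one-cell-wide ring
#' straddling the region border.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the ring.
#' @export
boundary_ring <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  pad <- matrix(FALSE, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- mask
  nb_any <- pad[1:nx, 2:(ny + 1L)] | pad[3:(nx + 2L), 2:(ny + 1L)] |
    pad[2:(nx + 1L), 1:ny] | pad[2:(nx + 1L), 3:(ny + 2L)]
  padT <- matrix(TRUE, nx + 2L, ny + 2L)
  padT[2:(nx + 1L), 2:(ny + 1L)] <- mask
  nb_all <- padT[1:nx, 2:(ny + 1L)] & padT[3:(nx + 2L), 2:(ny + 1L)] &
    padT[2:(nx + 1L), 1:ny] & padT[2:(nx + 1L), 3:(ny + 2L)]
  (mask & !nb_all) | (!mask & nb_any)
}

#' Collected lesion metrics of a solved scenario
#'
#' Convenience wrapper computing the metrics that make sense for a given
#' scenario/solution pair, returned as a one-row tibble.
#'
#' @param sol A `mucoflow_solution`.
#' @param scenario The `mucoflow_scenario` it came from.
#' @param row Row for the asymmetry profile (default 10, a
#'   lesser-curvature row on the borderline grids).
#' @return One-row tibble of metric values (`NA` where undefined).
#' @export
lesion_metrics <- function(sol, scenario, row = 10) {
  safe <- function(expr) tryCatch(expr, mucoflow_undefined_metric = function(e) NA_real_)
  asym <- safe(reibungsform_asymmetry(axial_profile(sol, row)))
  ext <- circumferential_extent(sol)
  dip <- if (!is.null(scenario$masks$watershed_centre))
    safe(dip_depth(sol, scenario$masks$watershed_centre,
                   scenario$masks$surround))
  else NA_real_
  circ <- safe(circularity(sol)$circularity)
  tibble::tibble(scenario = scenario$name, asymmetry_ratio = asym,
                 circumferential_extent = ext, dip_depth = dip,
                 circularity = circ)
}
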