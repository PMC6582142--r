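test_that("assembly matches hand-computed stencils", {
  # isolated cell: diagonal alpha + omega, no faces
  f1 <- tiny_fields(1, 1, alpha = 1, omega = 1)
  s1 <- assemble_system(f1)
  expect_equal(s1$diagonal[1, 1], 2)
  expect_equal(s1$source[1, 1], 1)
  expect_true(all(s1$face_conductance_x == 0))
  expect_true(all(s1$face_conductance_y == 0))

  # 2x1, lambda = 1, h = 1, lower-index: single interior face g = 1
  f2 <- tiny_fields(2, 1)
  s2 <- assemble_system(f2)
  expect_equal(s2$face_conductance_x[2, 1], 1)
  expect_equal(s2$face_conductance_x[c(1, 3), 1], c(0, 0))

  # harmonic mean of lambda {1, 3}: g = 2/(1+3)
  f3 <- tiny_fields(2, 1)
  f3$lambda_x <- matrix(c(1, 3), 2, 1)
  s3 <- assemble_system(f3, opts = solver_options(face_convention = "harmonic_mean"))
  expect_equal(s3$face_conductance_x[2, 1], 0.5)

  # diagonal dominance: diagonal - sum of face conductances = alpha + omega
  sc <- random_fixture(11, 9, 7)
  s <- assemble_system(sc$fields)
  nx <- 9L; ny <- 7L
  facesum <- s$face_conductance_x[1:nx, ] + s$face_conductance_x[2:(nx + 1), ] +
    s$face_conductance_y[, 1:ny] + s$face_conductance_y[, 2:(ny + 1)]
  expect_equal(s$diagonal - facesum, sc$fields$alpha + sc$fields$omega)
})

test_that("direct solve reproduces hand-eliminated and closed-form solutions", {
  # 1x1: p = alpha dp0 / (alpha + omega)
  expect_equal(solve_direct(assemble_system(tiny_fields(1, 1)))[1, 1], 0.5)

  # 2x1 with omega {0, 2}, face g = 1: 2pA - pB = 1, -pA + 4pB = 1
  f <- tiny_fields(2, 1, alpha = 1)
  f$omega <- matrix(c(0, 2), 2, 1)
  p <- solve_direct(assemble_system(f))
  expect_equal(as.vector(p), c(5 / 7, 3 / 7), tolerance = 1e-12)

  # uniform fields: uniform closed form regardless of lateral coupling
  fu <- tiny_fields(6, 5, alpha = 0.3, omega = 1.7, lambda = 0.2)
  pu <- solve_direct(assemble_system(fu))
  expect_equal(pu, matrix(0.3 / 2, 6, 5), tolerance = 1e-12)
})

test_that("a component with neither inflow nor outflow is reported singular", {
  # a pure-omega component is well-posed (p = 0), not singular
  g <- grid_spec(2, 1)
  f2 <- param_fields(g, alpha = matrix(c(1, 0), 2, 1),
                     omega = matrix(c(0, 1), 2, 1),
                     lambda_x = 1, lambda_y = 1)
  expect_silent(p <- solve_direct(assemble_system(f2)))
  # truly dead component: needs a disconnected degenerate cell, which
  # validate_fields permits (alpha = omega = 0 is a lateral conductor) but
  # only lateral isolation makes singular; emulate via a 1x1 grid
  f3 <- param_fields(grid_spec(1, 1), alpha = 1e-300, omega = 0,
                     lambda_x = 1, lambda_y = 1)
  f3$alpha[1, 1] <- 0
  expect_error(solve_direct(structure(list(
    diagonal = matrix(0, 1, 1), face_conductance_x = matrix(0, 2, 1),
    face_conductance_y = matrix(0, 1, 2), source = matrix(0, 1, 1),
    grid = grid_spec(1, 1), delta_p0 = 1), class = "mucoflow_system")),
    "singular")
})

test_that("Gauss-Seidel agrees with the direct oracle on seeded fixtures", {
  worst <- 0
  for (seed in 1:12) {
    sc <- random_fixture(seed, nx = 5 + (seed %% 4) * 5, ny = 5 + (seed %% 3) * 5)
    sol <- solve_gauss_seidel(sc$fields)
    p_ref <- solve_direct(assemble_system(sc$fields))
    expect_true(sol$converged, info = paste("seed", seed))
    worst <- max(worst, max(abs(sol$p - p_ref)))
  }
  expect_lt(worst, 1e-6)
})

test_that("homogeneous fields solve to the closed form on a 50x50 grid", {
  f <- tiny_fields(50, 50, alpha = 0.1, omega = 1.0, lambda = 0.382)
  sol <- solve_gauss_seidel(f)
  expect_true(sol$converged)
  expect_equal(sol$p, matrix(1 / 11, 50, 50), tolerance = 1e-9)
})

test_that("omega = 0 everywhere gives p = delta_p0 and no terminal flow", {
  f <- tiny_fields(8, 8, alpha = 0.5, omega = 0, lambda = 1, delta_p0 = 2)
  sol <- solve_gauss_seidel(f)
  expect_equal(sol$p, matrix(2, 8, 8), tolerance = 1e-9)
  expect_true(all(sol$j_omega == 0))
})

test_that("maximum principle and conservation hold across scenarios", {
  scenarios <- list(scenario_antrum_borderline(), scenario_watershed(100),
                    scenario_necrosis("post"), random_fixture(3, 12, 12))
  for (sc in scenarios) {
    sol <- solve_scenario(sc)
    expect_true(all(sol$p >= -1e-12), info = sc$name)
    expect_true(all(sol$p <= sc$fields$delta_p0 + 1e-12), info = sc$name)
    expect_lt(sol$global_imbalance, 1e-8 * sum(sol$j_alpha))
  }
})

test_that("flows follow their defining relations and boundary faces are zero", {
  sc <- random_fixture(5, 7, 9)
  sol <- solve_gauss_seidel(sc$fields)
  f <- sc$fields
  expect_equal(sol$j_alpha, f$alpha * (f$delta_p0 - sol$p), tolerance = 1e-14)
  expect_equal(sol$j_omega, f$omega * sol$p, tolerance = 1e-14)
  expect_true(all(sol$j_lambda_x[c(1, 8), ] == 0))
  expect_true(all(sol$j_lambda_y[, c(1, 10)] == 0))

  # uniform pressure: no lateral flow at all
  fu <- tiny_fields(4, 4)
  flows <- compute_flows(matrix(0.25, 4, 4), fu)
  expect_true(all(flows$j_lambda_x == 0) && all(flows$j_lambda_y == 0))

  # hand-solved 2x1 system: face flow 2/7 from the high- to low-pressure cell
  f2 <- tiny_fields(2, 1, alpha = 1)
  f2$omega <- matrix(c(0, 2), 2, 1)
  flows2 <- compute_flows(matrix(c(5 / 7, 3 / 7), 2, 1), f2)
  expect_equal(flows2$j_lambda_x[2, 1], 2 / 7, tolerance = 1e-12)
})

test_that("balance residuals vanish at solutions and localise perturbations", {
  sc <- scenario_watershed(10)
  sol <- solve_scenario(sc)
  tol <- 1e-10 * sc$fields$delta_p0
  expect_lt(sol$max_residual, 10 * tol * max(assemble_system(sc$fields)$diagonal))

  exact <- solve_scenario(sc, method = "direct")
  expect_lt(exact$max_residual, 1e-10)

  # perturb one interior cell: residual appears only there and at neighbours
  p <- exact$p
  p[25, 25] <- p[25, 25] + 0.1
  pert <- wrap_solution(p, sc$fields)
  res <- balance_residuals(pert, sc$fields, sc$grid)$residuals
  touched <- abs(res) > 1e-9
  expected <- matrix(FALSE, 50, 50)
  expected[cbind(c(25, 24, 26, 25, 25), c(25, 25, 25, 24, 26))] <- TRUE
  expect_identical(touched, expected)
})

test_that("raising omega in one cell lowers pressure everywhere (steal direction)", {
  sc <- random_fixture(21, 6, 6)
  p1 <- solve_direct(assemble_system(sc$fields))
  bumped <- sc$fields
  bumped$omega[3, 4] <- bumped$omega[3, 4] + 5
  p2 <- solve_direct(assemble_system(bumped))
  expect_true(all(p2 < p1)) # strict on the fully connected grid
})

test_that("mirroring the parameter fields mirrors the solution", {
  sc <- random_fixture(9, 8, 5)
  mir <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  f <- sc$fields
  # under the lower-index face convention the face resistance travels with
  # its cell only if lambda is also shifted; use harmonic mean, which is
  # mirror-symmetric by construction
  opts <- solver_options(face_convention = "harmonic_mean")
  fm <- param_fields(sc$grid, mir(f$alpha), mir(f$omega), mir(f$lambda_x),
                     mir(f$lambda_y), f$delta_p0)
  p <- solve_direct(assemble_system(f, opts = opts))
  pm <- solve_direct(assemble_system(fm, opts = opts))
  expect_equal(pm, mir(p), tolerance = 1e-12)

  # the cardia scenario is the mirrored borderline: solved patterns mirror
  sol <- solve_gauss_seidel(scenario_antrum_borderline()$fields)
  solm <- solve_gauss_seidel(scenario_cardia()$fields)
  expect_equal(solm$j_omega, mir(sol$j_omega), tolerance = 1e-6)
})

test_that("SOR converges to the Gauss-Seidel fixed point", {
  sc <- random_fixture(14, 10, 10)
  gs <- solve_gauss_seidel(sc$fields)
  sor <- solve_gauss_seidel(sc$fields, opts = solver_options(relaxation = 1.5))
  expect_true(sor$converged)
  expect_equal(sor$p, gs$p, tolerance = 1e-7)
  expect_error(solver_options(relaxation = 2), "relaxation")
})

test_that("periodic_y wraps the circumference consistently", {
  # y-invariant inputs: periodic and no-flux give the same y-invariant field
  g_per <- grid_spec(12, 8, boundary = "periodic_y")
  f_per <- param_fields(g_per, alpha = matrix(rep(seq(0.1, 1, length.out = 12), 8), 12, 8),
                        omega = 1, lambda_x = 0.5, lambda_y = 0.5)
  g_nf <- grid_spec(12, 8)
  f_nf <- param_fields(g_nf, f_per$alpha, 1, 0.5, 0.5)
  p_per <- solve_direct(assemble_system(f_per))
  p_nf <- solve_direct(assemble_system(f_nf))
  expect_equal(p_per, p_nf, tolerance = 1e-12)
  expect_equal(max(apply(p_per, 1, stats::sd)), 0, tolerance = 1e-13)

  # GS matches direct under periodicity with y-varying fields too
  f_var <- param_fields(g_per, alpha = 0.2,
                        omega = matrix(rep(c(1, 5), each = 48), 12, 8),
                        lambda_x = 0.5, lambda_y = 0.5)
  sol <- solve_gauss_seidel(f_var)
  expect_equal(sol$p, solve_direct(assemble_system(f_var)), tolerance = 1e-8)
  # wrap faces carry flow
  expect_true(any(sol$j_lambda_y[, 1] != 0))
  expect_equal(sol$j_lambda_y[, 1], sol$j_lambda_y[, 9])
  expect_lt(sol$global_imbalance, 1e-8 * sum(sol$j_alpha))
})
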