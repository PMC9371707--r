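test_that("uniform equilibrium is preserved exactly", {
  m <- tiny_mesh(0.2)
  p <- model_params()
  st <- stepper_spec(t_end = 0.3)
  tr <- simulate_monolayer(m, p, rep(1, nrow(m$nodes)), st,
                           output_times = seq(0, 0.3, 0.05))
  expect_lt(max(abs(tr$u)), 10 * st$newton_tol)
  expect_lt(max(abs(tr$c - 1)), 10 * st$newton_tol)
})

test_that("boundary displacement is exactly zero at every snapshot", {
  m <- tiny_mesh(0.2)
  p <- model_params(alpha_hat = 2)
  ci <- seed_concentration(m, seeding_spec(prefactor = 1, rng_seed = 5))
  tr <- simulate_monolayer(m, p, ci, stepper_spec(t_end = 0.2),
                           output_times = seq(0, 0.2, 0.05))
  expect_true(all(tr$u[m$boundary_mask, , ] == 0))
  expect_true(all(is.finite(tr$u)), all(is.finite(tr$c)))
})

test_that("identical inputs give identical trajectories", {
  m <- tiny_mesh(0.2)
  p <- model_params(alpha_hat = 5)
  sp <- seeding_spec(prefactor = 1, rng_seed = 11)
  st <- stepper_spec(t_end = 0.2)
  t1 <- quiescence_run(m, p, sp, st, output_times = seq(0, 0.2, 0.05))
  t2 <- quiescence_run(m, p, sp, st, output_times = seq(0, 0.2, 0.05))
  expect_identical(t1$u, t2$u)
  expect_identical(t1$c, t2$c)
})

test_that("axisymmetric collapse matches an independent 1D radial solver", {
  # a smooth centred actinomyosin bump, moderate contractility; the 2D
  # P1 solution is compared against a 1D radial finite-difference oracle
  # run on the same backward-Euler time grid
  m <- disc_mesh(0.05)
  p <- model_params(alpha_hat = 2)
  st <- stepper_spec(t_end = 0.1)
  r2d <- sqrt(rowSums(m$nodes^2))
  bump <- function(r) 1 + 0.3 * exp(-(r / 0.35)^2)
  tr <- simulate_monolayer(m, p, bump(r2d), st, output_times = c(0, 0.1),
                           c_boundary = "fixed")
  u_r2d <- rowSums(tr$u[, , 2] * m$nodes / pmax(r2d, 1e-12))
  u_r2d[r2d < 1e-12] <- 0

  ora <- radial_oracle(p, bump, stepper_dts(st), nr = 401,
                       c_boundary = "fixed")
  u_ref <- stats::approx(ora$r, ora$u, xout = r2d)$y
  w <- m$node_areas / sum(m$node_areas)
  rel_l2 <- sqrt(sum(w * (u_r2d - u_ref)^2)) / sqrt(sum(w * u_ref^2))
  expect_lt(rel_l2, 0.02)
})

test_that("mesh refinement changes the subcritical response by < 5%", {
  # solver-convergence check in the smooth, deterministic regime
  p <- model_params(alpha_hat = 2)
  st <- stepper_spec(t_end = 0.15)
  val <- vapply(c(0.1, 0.05), function(h) {
    m <- disc_mesh(h)
    r <- sqrt(rowSums(m$nodes^2))
    tr <- simulate_monolayer(m, p, 1 + 0.3 * exp(-(r / 0.35)^2), st,
                             output_times = c(0, 0.15))
    w <- m$node_areas / sum(m$node_areas)
    ur <- rowSums(tr$u[, , 2] * m$nodes / pmax(r, 1e-12))
    sum(w * ur)
  }, numeric(1))
  expect_lt(abs(val[2] - val[1]) / abs(val[2]), 0.05)
})

test_that("concentration boundary flux is numerically closed (no-flux run)", {
  m <- tiny_mesh(0.2)
  p <- model_params(alpha_hat = 0, D = 1e-9)   # pure diffusion-relaxation
  r <- sqrt(rowSums(m$nodes^2))
  ci <- 1 + 0.3 * exp(-(r / 0.4)^2)
  tr <- simulate_monolayer(m, p, ci, stepper_spec(t_end = 0.05),
                           output_times = c(0, 0.05), c_boundary = "noflux")
  # with alpha = 0 and no flux, total excess decays exactly like the
  # relaxation integral: d/dt int(c-1) = -int(c-1)/tauc
  g <- nondim_groups(p)
  w <- m$node_areas
  exc0 <- sum(w * (tr$c[, 1] - 1))
  exc1 <- sum(w * (tr$c[, 2] - 1))
  expect_equal(exc1 / exc0, exp(-0.05 / g$tauc_hat), tolerance = 2e-3)
})

test_that("traction frames obey the friction law on constructed motion", {
  m <- tiny_mesh(0.2)
  p <- model_params()
  g <- nondim_groups(p)
  n <- nrow(m$nodes)
  # u growing linearly at nondimensional rate v at every node
  v <- 0.01
  times <- seq(0, 1, 0.25)
  frames <- lapply(times, function(t) matrix(v * t, n, 2))
  tr <- manual_trajectory(m, times, frames, params = p)
  ts <- traction_series(tr)
  expected <- p$Gamma * (v * sqrt(2)) * (p$R / g$tau_L)
  expect_equal(ts$mean_traction_Pa, rep(expected, length(times)),
               tolerance = 1e-12)

  static <- manual_trajectory(m, times, lapply(times, function(t) matrix(0, n, 2)),
                              params = p)
  expect_true(all(traction_series(static)$mean_traction_Pa == 0))
  one <- manual_trajectory(m, 0, list(matrix(0, n, 2)), params = p)
  expect_error(traction_series(one), "2 snapshots")
})

test_that("flattening: subcritical runs relax back to uniform equilibrium", {
  m <- tiny_mesh(0.2)
  p <- model_params(alpha_hat = 2)
  ci <- seed_concentration(m, seeding_spec(prefactor = 1, rng_seed = 9))
  tr <- simulate_monolayer(m, p, ci, stepper_spec(t_end = 1.5),
                           output_times = c(0, 1.5))
  expect_lt(max(abs(tr$c[, 2] - 1)), 0.05)
})
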