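test_that("radial velocity of a uniform contraction matches the disc average", {
  # u(x, t) = -x v t: radial speed v r inward; area-weighted mean radius
  # of the unit disc is 2/3
  m <- tiny_mesh(0.2)
  p <- model_params()
  v <- 0.05
  times <- c(0, 0.5, 1)
  frames <- lapply(times, function(t) -m$nodes * v * t)
  tr <- manual_trajectory(m, times, frames, params = p)
  rs <- radial_velocity_series(tr)
  g <- nondim_groups(p)
  w <- m$node_areas / sum(m$node_areas)
  mean_r <- sum(w * sqrt(rowSums(m$nodes^2)))   # ~2/3 up to mesh quadrature
  expect_equal(mean_r, 2 / 3, tolerance = 0.01)
  expect_equal(rs$mean_radial_velocity,
               rep(v * mean_r * g$vel_scale_um_h, 2), tolerance = 1e-10)
  expect_true(all(rs$outward_fraction == 0))
})

test_that("static and mirror-symmetric fields give the expected statistics", {
  m <- tiny_mesh(0.2)
  n <- nrow(m$nodes)
  times <- c(0, 1)
  still <- manual_trajectory(m, times, list(matrix(0, n, 2), matrix(0, n, 2)))
  rs <- radial_velocity_series(still)
  expect_true(all(rs$mean_radial_velocity == 0))
  expect_true(all(rs$outward_fraction == 0))

  # right half moves outward, left half inward, by the same radial rate
  mirror <- sign(m$nodes[, 1]) * 0.01
  fr2 <- cbind(mirror * m$nodes[, 1] / pmax(sqrt(rowSums(m$nodes^2)), 1e-12), 0)
  # radial component: (du . rhat); build u = s * rhat with s = +-0.01
  rhat <- m$nodes / pmax(sqrt(rowSums(m$nodes^2)), 1e-12)
  u2 <- rhat * 0.01 * sign(m$nodes[, 1])
  u2[sqrt(rowSums(m$nodes^2)) < 1e-12, ] <- 0
  tr2 <- manual_trajectory(m, times, list(matrix(0, n, 2), u2))
  rs2 <- radial_velocity_series(tr2)
  expect_equal(rs2$outward_fraction, 0.5, tolerance = 0.05)
})

test_that("the 1%/20% window reproduces a hand-computed average", {
  # outward fraction drops below 1% at frame 5; velocity 10 um/h there,
  # decaying linearly to 0 at frame 25 -> window closes at the first
  # frame below 2 um/h
  nfr <- 30
  v <- numeric(nfr)
  v[5:25] <- seq(10, 0, length.out = 21)
  outf <- c(rep(0.5, 4), rep(0, 26))
  ser <- data.frame(time = seq_len(nfr), time_h = seq_len(nfr),
                    mean_radial_velocity = v, outward_fraction = outf)
  class(ser) <- c("radial_velocity_series", "data.frame")
  # v(frame k) = 10 - 0.5 (k - 5); first frame with v < 2: k = 22
  expect_equal(averaged_radial_velocity(ser), mean(v[5:22]))

  const <- data.frame(time = 1:5, time_h = 1:5,
                      mean_radial_velocity = rep(7, 5),
                      outward_fraction = rep(0, 5))
  expect_equal(averaged_radial_velocity(const), 7)

  never <- data.frame(time = 1:5, time_h = 1:5,
                      mean_radial_velocity = rep(7, 5),
                      outward_fraction = rep(0.5, 5))
  expect_error(averaged_radial_velocity(never), class = "activegel_window_error")
})

test_that("windowed average is stable under time resampling", {
  f <- function(t) 10 * exp(-(t - 3)^2 / 4)
  mk <- function(dt) {
    t <- seq(0, 10, by = dt)
    d <- data.frame(time = t, time_h = t, mean_radial_velocity = f(t),
                    outward_fraction = ifelse(t < 1, 0.5, 0))
    class(d) <- c("radial_velocity_series", "data.frame")
    d
  }
  v1 <- averaged_radial_velocity(mk(0.1))
  v2 <- averaged_radial_velocity(mk(0.05))
  expect_lt(abs(v1 - v2) / v1, 0.02)
})

test_that("sigmoid fit recovers exact coefficients and rejects degeneracy", {
  x <- c(0.002, 0.02, 0.1, 0.2, 0.4, 0.6)
  truth <- c(a0 = 28, a1 = 17.1, a2 = 0.19)
  v <- truth["a0"] / (1 + exp(-truth["a1"] * (x - truth["a2"])))
  fit <- fit_sigmoid(x, v)
  expect_equal(fit$a0, 28, tolerance = 1e-6)
  expect_equal(fit$a1, 17.1, tolerance = 1e-6)
  expect_equal(fit$a2, 0.19, tolerance = 1e-6)

  # invariance to shuffling
  idx <- c(4, 1, 6, 2, 5, 3)
  fit2 <- fit_sigmoid(x[idx], v[idx])
  expect_equal(fit2$a0, fit$a0, tolerance = 1e-9)

  expect_error(fit_sigmoid(x, rep(5, 6)), "degenerate")
  expect_error(fit_sigmoid(x[1:3], v[1:3]), "4 distinct")
})

test_that("sigmoid fit is robust to noise (Monte-Carlo self-consistency)", {
  x <- c(0.002, 0.02, 0.1, 0.2, 0.4, 0.6)
  v0 <- 28 / (1 + exp(-17.1 * (x - 0.19)))
  set.seed(1)
  err <- replicate(100, {
    v <- v0 * (1 + stats::rnorm(length(x), 0, 0.05))
    abs(fit_sigmoid(x, v)$a0 - 28) / 28
  })
  expect_lt(stats::median(err), 0.10)
})

test_that("a zero-prefactor sweep is immobile and deterministic", {
  m <- tiny_mesh(0.2)
  p <- model_params()
  st <- stepper_spec(t_end = 0.1)
  sw1 <- prestress_sweep(m, p, st, prefactors = 0, n_seeds = 2,
                         output_times = seq(0, 0.1, 0.02))
  expect_true(all(sw1$runs$v_avg == 0))
  sw2 <- prestress_sweep(m, p, st, prefactors = 0, n_seeds = 2,
                         output_times = seq(0, 0.1, 0.02))
  expect_identical(sw1$runs, sw2$runs)
  expect_true(all(sw1$summary$v_min <= sw1$summary$v_mean &
                  sw1$summary$v_mean <= sw1$summary$v_max))
})
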