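test_that("point-force Boussinesq displacement decays like 1/r", {
  n <- 48
  Tx <- matrix(0, n, n); Tx[n / 2, n / 2] <- 100
  tr <- list(x = seq_len(n), y = seq_len(n), Tx = Tx,
             Ty = matrix(0, n, n), grid_spacing = 4)
  u <- boussinesq_forward(tr, substrate_spec(), method = "direct")
  # sample along +x from the force over one decade of r
  js <- (n / 2 + 2):(n / 2 + 20)
  r <- (js - n / 2) * 4
  ux <- u$ux[n / 2, js]
  slope <- stats::coef(stats::lm(log(ux) ~ log(r)))[2]
  expect_lt(abs(slope + 1), 0.05)
  # zero traction -> zero displacement
  u0 <- boussinesq_forward(list(x = 1:8, y = 1:8, Tx = matrix(0, 8, 8),
                                Ty = matrix(0, 8, 8), grid_spacing = 4),
                           substrate_spec(), method = "direct")
  expect_true(all(u0$ux == 0) && all(u0$uy == 0))
})

test_that("real-space and Fourier Green convolutions agree", {
  set.seed(13)
  n <- 32
  kx <- c(0:(n / 2), -(n / 2 - 1):-1)[1:n]
  K2 <- outer(kx^2, kx^2, "+")
  sm <- function(z) {
    w <- Re(ifft2(fft2(z) * exp(-K2 / 8)))
    w - mean(w)      # zero net force, as monolayer force balance requires
  }
  tr <- list(x = seq_len(n), y = seq_len(n),
             Tx = sm(matrix(stats::rnorm(n * n), n, n)) * 30,
             Ty = sm(matrix(stats::rnorm(n * n), n, n)) * 30,
             grid_spacing = 4)
  sub <- substrate_spec()
  ud <- boussinesq_forward(tr, sub, method = "direct")
  uf <- boussinesq_forward(tr, sub, method = "fourier")
  rel <- sqrt(sum((ud$ux - uf$ux)^2 + (ud$uy - uf$uy)^2) /
              sum(ud$ux^2 + ud$uy^2))
  expect_lt(rel, 0.01)
})

test_that("bead pairs are reproducible and honour zero displacement", {
  spec <- bead_image_spec(size = 96, density = 0.03, rng_seed = 21)
  p1 <- render_bead_pair(spec)
  p2 <- render_bead_pair(spec)
  expect_identical(p1$reference, p2$reference)
  expect_identical(p1$deformed, p2$deformed)
  expect_equal(p1$reference, p1$deformed, tolerance = 1e-12)

  noisy <- render_bead_pair(bead_image_spec(size = 96, density = 0.03,
                                            noise = 50, rng_seed = 21))
  expect_false(identical(noisy$reference, noisy$deformed))
})

test_that("uniform-shift bead pair closes the displacement round trip", {
  n <- 16
  disp <- structure(list(x = seq(0, 127, length.out = n),
                         y = seq(0, 127, length.out = n),
                         ux = matrix(2, n, n), uy = matrix(0, n, n),
                         mask = matrix(TRUE, n, n), grid_spacing = 127 / (n - 1)),
                    class = "displacement_grid")
  pair <- render_bead_pair(bead_image_spec(size = 128, density = 0.04,
                                           rng_seed = 6), disp)
  d <- bead_displacement(pair$reference, pair$deformed, window = 32)
  expect_equal(mean(d$ux[d$mask]), 2, tolerance = 0.1)
})

test_that("flow movies carry their ground truth", {
  still <- render_flow_movie(flow_movie_spec(frames = 3, flow = "none",
                                             rng_seed = 2))
  expect_identical(still$frames[[1]], still$frames[[3]])

  mv <- render_flow_movie(flow_movie_spec(frames = 2, flow = "uniform",
                                          speed = 10, dt_min = 16,
                                          size = 256, n_nuclei = 400,
                                          sigma = 3, rng_seed = 14))
  v <- piv_velocity(mv$frames[[1]], mv$frames[[2]], dt_min = 16, window = 48)
  expect_equal(mean_speed(v), 10, tolerance = 1)

  rad <- render_flow_movie(flow_movie_spec(frames = 2, flow = "radial",
                                           speed = 15, dt_min = 16,
                                           size = 256, n_nuclei = 400,
                                           sigma = 3, rng_seed = 15))
  vr <- piv_velocity(rad$frames[[1]], rad$frames[[2]], dt_min = 16, window = 48)
  ctr <- 128
  dx <- outer(rep(1, length(vr$y)), vr$x - ctr)
  dy <- outer(vr$y - ctr, rep(1, length(vr$x)))
  rr <- pmax(sqrt(dx^2 + dy^2), 1e-9)
  vrad <- (vr$vx * dx + vr$vy * dy) / rr
  ok <- vr$mask & rr > 20
  expect_gt(mean(vrad[ok] < 0), 0.95)

  # radial PIV directions agree with ground truth within 10 degrees
  tru <- rad$truth(dx[ok] + ctr, dy[ok] + ctr)
  ang <- acos(pmin(1, pmax(-1,
    (vr$vx[ok] * tru[, 1] + vr$vy[ok] * tru[, 2]) /
      (sqrt(vr$vx[ok]^2 + vr$vy[ok]^2) * sqrt(rowSums(tru^2))))))
  expect_lt(mean(ang) * 180 / pi, 10)
})
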