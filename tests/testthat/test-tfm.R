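make_bead_field <- function(seed = 1, size = 128, density = 0.03) {
  render_bead_pair(bead_image_spec(size = size, density = density,
                                   sigma = 1.5, rng_seed = seed))
}

test_that("rigid registration recovers constructed shifts", {
  img <- make_bead_field(seed = 2)$reference
  shifted_int <- fourier_shift(img, 3, -2)
  reg <- register_rigid(list(img, shifted_int))
  expect_equal(unname(reg$offsets[2, ]), c(3, -2), tolerance = 0.1)

  reg0 <- register_rigid(list(img, img, img))
  expect_true(all(abs(reg0$offsets) < 1e-6))

  sub <- fourier_shift(img, 0.4, 0)
  regs <- register_rigid(list(img, sub))
  expect_equal(unname(regs$offsets[2, 1]), 0.4, tolerance = 0.05)

  expect_error(register_rigid(list(matrix(1, 32, 32), img)), "featureless")
  expect_error(register_rigid(list(img)), "2 frames")
})

test_that("bead displacement recovers shifts and flags empty windows", {
  pair <- make_bead_field(seed = 3)
  shifted <- fourier_shift(pair$reference, 2, 0)
  d <- bead_displacement(pair$reference, shifted, window = 32, overlap = 0.5,
                         pixel_size = 0.5)
  expect_equal(mean(d$ux[d$mask]), 2 * 0.5, tolerance = 0.05)
  expect_lt(max(abs(d$uy[d$mask])), 0.1)

  d0 <- bead_displacement(pair$reference, pair$reference, window = 32)
  expect_lt(max(abs(c(d0$ux[d0$mask], d0$uy[d0$mask]))), 1e-6)

  empty <- matrix(0, 64, 64)
  de <- bead_displacement(empty, empty, window = 32)
  expect_true(all(!de$mask))
  expect_error(bead_displacement(pair$reference, shifted, window = 8), ">= 16")
})

test_that("PIV-style recovery of a smooth warp is subpixel accurate", {
  # smooth displacement field with ~2 px amplitude applied to beads
  n <- 24
  xs <- seq(0, 127, length.out = n)
  gx <- outer(rep(1, n), sin(2 * pi * xs / 128)) * 2
  gy <- outer(cos(2 * pi * xs / 128), rep(1, n)) * 1.5
  disp <- structure(list(x = xs, y = xs, ux = gx, uy = gy,
                         mask = matrix(TRUE, n, n),
                         grid_spacing = diff(xs)[1]),
                    class = "displacement_grid")
  pair <- render_bead_pair(bead_image_spec(size = 128, density = 0.04,
                                           sigma = 1.5, rng_seed = 5), disp)
  d <- bead_displacement(pair$reference, pair$deformed, window = 32,
                         overlap = 0.75)
  # window correlation estimates the window-mean displacement: compare
  # against the box-filtered field (sinc attenuation of the harmonic)
  att <- sin(pi * 32 / 128) / (pi * 32 / 128)
  truth_x <- att * matrix(2 * sin(2 * pi * d$x / 128), nrow = length(d$y),
                          ncol = length(d$x), byrow = TRUE)
  truth_y <- att * matrix(1.5 * cos(2 * pi * d$y / 128), nrow = length(d$y),
                          ncol = length(d$x))
  err <- sqrt((d$ux - truth_x)^2 + (d$uy - truth_y)^2)
  expect_lt(sqrt(mean(err[d$mask]^2)), 0.25)
})

test_that("FTTC is linear and inverts the forward operator", {
  # band-limited traction island (zero net force by antisymmetry) well
  # inside the field of view; the displacement tail lost outside the
  # field is then negligible and the padded inversion closes the loop
  n <- 48
  xs <- (0:(n - 1)) - (n - 1) / 2
  g <- exp(-(xs / 6)^2)
  bump <- outer(g, g)
  Tx <- bump * outer(rep(1, n), sin(2 * pi * xs / 24)) * 50
  Ty <- bump * outer(sin(2 * pi * xs / 24), rep(1, n)) * 50
  tr <- list(x = seq_len(n), y = seq_len(n), Tx = Tx, Ty = Ty, grid_spacing = 4)
  sub <- substrate_spec(youngs_modulus = 4000, poisson_ratio = 0.49)
  u <- boussinesq_forward(tr, sub, method = "fourier")
  rec <- fttc_traction(u, sub)
  ii <- 3:(n - 2)
  relerr <- sqrt(sum((rec$Tx[ii, ii] - Tx[ii, ii])^2 +
                     (rec$Ty[ii, ii] - Ty[ii, ii])^2) /
                 sum(Tx[ii, ii]^2 + Ty[ii, ii]^2))
  expect_lt(relerr, 0.02)

  # linearity to machine precision
  u2 <- u; u2$ux <- 3 * u$ux; u2$uy <- 3 * u$uy
  rec3 <- fttc_traction(u2, sub)
  expect_equal(rec3$Tx, 3 * rec$Tx, tolerance = 1e-12)

  # zero displacement -> zero traction
  u0 <- u; u0$ux[] <- 0; u0$uy[] <- 0
  r0 <- fttc_traction(u0, sub)
  expect_true(all(r0$Tx == 0) && all(r0$Ty == 0))
})

test_that("round-trip error decreases under grid refinement", {
  # the same physical traction island sampled at two resolutions
  sub <- substrate_spec()
  err_at <- function(n) {
    xs <- ((0:(n - 1)) - (n - 1) / 2) * 32 / n   # fixed physical frame
    g <- exp(-(xs / 4)^2)
    bump <- outer(g, g)
    Tx <- bump * outer(rep(1, n), sin(2 * pi * xs / 16)) * 50
    Ty <- bump * outer(sin(2 * pi * xs / 16), rep(1, n)) * 50
    tr <- list(x = seq_len(n), y = seq_len(n), Tx = Tx, Ty = Ty,
               grid_spacing = 128 / n)
    u <- boussinesq_forward(tr, sub, method = "fourier")
    rec <- fttc_traction(u, sub)
    ii <- ceiling(n / 16):(n - ceiling(n / 16) + 1)
    sqrt(sum((rec$Tx[ii, ii] - Tx[ii, ii])^2 +
             (rec$Ty[ii, ii] - Ty[ii, ii])^2) /
         sum(Tx[ii, ii]^2 + Ty[ii, ii]^2))
  }
  expect_lt(err_at(64), err_at(32))
})

test_that("a tangential point force is recovered against the real-space oracle", {
  # point-like force: a narrow Gaussian patch carrying 1.5 nN; forward
  # displacements from the real-space quadrature, inversion by FTTC;
  # the recovered blob integrates back to the applied force
  n <- 48
  xs <- (0:(n - 1)) - (n - 1) / 2
  gg <- exp(-(xs / 1.2)^2)
  patch <- outer(gg, gg)
  d <- 2e-6; dA <- d^2
  Tx <- patch / (sum(patch) * dA) * 1.5e-9
  tr <- list(x = seq_len(n), y = seq_len(n), Tx = Tx,
             Ty = matrix(0, n, n), grid_spacing = 2)
  sub <- substrate_spec()
  u <- boussinesq_forward(tr, sub, method = "direct")
  rec <- fttc_traction(u, sub)
  ctr <- (n / 2 - 5):(n / 2 + 6)
  expect_equal(sum(rec$Tx[ctr, ctr]) * dA, 1.5e-9,
               tolerance = 0.05)
  pk <- which(abs(rec$Tx) == max(abs(rec$Tx)), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(pk - (n + 1) / 2)), 1)
})
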