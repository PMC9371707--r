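test_that("PIV recovers a constructed shift in um/h", {
  pair <- render_bead_pair(bead_image_spec(size = 160, density = 0.025,
                                           sigma = 2, rng_seed = 4))
  shifted <- activegel:::fourier_shift(pair$reference, 3, 0)
  v <- piv_velocity(pair$reference, shifted, dt_min = 16, window = 48,
                    overlap = 0.5, pixel_size = 1)
  expect_equal(mean_speed(v), 3 * 60 / 16, tolerance = 0.15)

  v0 <- piv_velocity(pair$reference, pair$reference, dt_min = 16)
  expect_lt(mean_speed(v0), 1e-4)
  expect_error(piv_velocity(pair$reference, shifted, dt_min = 0), "positive")
})

test_that("mean speed handles uniform, zero and mixed fields", {
  mk <- function(vx, vy) {
    structure(list(x = 1:4, y = 1:4,
                   vx = matrix(vx, 4, 4), vy = matrix(vy, 4, 4),
                   mask = matrix(TRUE, 4, 4)),
              class = "velocity_field")
  }
  expect_equal(mean_speed(mk(3, 4)), 5)
  expect_equal(mean_speed(mk(0, 0)), 0)
  half <- mk(0, 0)
  half$vx[1:2, ] <- 10; half$vx[3:4, ] <- 20
  expect_equal(mean_speed(half), 15)
  none <- mk(1, 1); none$mask[] <- FALSE
  expect_error(mean_speed(none), "masked")
})

test_that("kymograph collapses frames along y", {
  f1 <- matrix(c(1, 3, 2, 4), 2, 2)   # [y, x]: col means (2, 3)
  k1 <- kymograph(list(f1))
  expect_equal(unname(k1$matrix[1, ]), c(2, 3))

  const <- lapply(1:5, function(k) matrix(7, 3, 4))
  k5 <- kymograph(const, pixel_size = 2, dt_min = 16)
  expect_equal(dim(k5$matrix), c(5, 4))
  expect_true(all(k5$matrix == 7))
  expect_equal(k5$x_um, c(0, 2, 4, 6))

  # y-constant stack: each kymograph row equals the frame's x-profile
  prof <- seq_len(6)
  fy <- matrix(prof, 4, 6, byrow = TRUE)
  ky <- kymograph(list(fy, fy * 2))
  expect_equal(unname(ky$matrix[1, ]), prof)
  expect_equal(unname(ky$matrix[2, ]), 2 * prof)
})

test_that("adjacent-frame Pearson correlation behaves canonically", {
  set.seed(3)
  a <- matrix(stats::rnorm(64 * 64), 64, 64)
  r_id <- pearson_adjacent(list(a, a))
  expect_equal(r_id$r, 1)
  r_neg <- pearson_adjacent(list(a, -a))
  expect_equal(r_neg$r, -1)

  # independent white-noise maps: |r| < 0.05 in at least 95% of trials
  hits <- replicate(100, {
    x <- matrix(stats::rnorm(64 * 64), 64, 64)
    y <- matrix(stats::rnorm(64 * 64), 64, 64)
    abs(pearson_adjacent(list(x, y))$r) < 0.05
  })
  expect_gte(mean(hits), 0.95)

  # affine invariance
  r_aff <- pearson_adjacent(list(a, 3 * a + 2))
  expect_equal(r_aff$r, 1, tolerance = 1e-12)

  flat <- matrix(1, 8, 8)
  r_deg <- pearson_adjacent(list(a[1:8, 1:8], flat))
  expect_true(r_deg$degenerate)

  # vector maps: concatenated components
  vm1 <- list(a, a); vm2 <- list(a, a)
  expect_equal(pearson_adjacent(list(vm1, vm2))$r, 1)
  expect_error(pearson_adjacent(list(a)), "at least 2")
})

test_that("traction component means vs field size behave as expected", {
  n <- 64
  uni <- list(Tx = matrix(5, n, n), Ty = matrix(-2, n, n), grid_spacing = 2)
  cv <- component_mean_vs_fieldsize(uni, c(16, 48, 120))
  expect_equal(cv$abs_mean_Tx, rep(5, 3))
  expect_equal(cv$abs_mean_Ty, rep(2, 3))

  x <- matrix(seq(-1, 1, length.out = n), n, n, byrow = TRUE)
  dip <- list(Tx = x, Ty = 0 * x, grid_spacing = 2)
  cd <- component_mean_vs_fieldsize(dip, c(16, 64))
  expect_true(all(cd$abs_mean_Tx < 0.03))

  expect_error(component_mean_vs_fieldsize(uni, 1000), "exceeds")
})

test_that("component means of a correlated random field decay like 1/size", {
  set.seed(9)
  n <- 256
  kx <- c(0:(n / 2), -(n / 2 - 1):-1)[1:n]
  K2 <- outer(kx^2, kx^2, "+")
  sizes <- c(16, 32, 64, 128)
  mlog <- replicate(15, {
    z <- Re(activegel:::ifft2(activegel:::fft2(matrix(stats::rnorm(n * n), n, n)) *
                              exp(-K2 / 128)))
    tr <- list(Tx = z - mean(z), Ty = z - mean(z), grid_spacing = 1)
    component_mean_vs_fieldsize(tr, sizes)$abs_mean_Tx
  })
  slope <- stats::coef(stats::lm(log(rowMeans(mlog)) ~ log(sizes)))[2]
  expect_lt(abs(slope + 1), 0.3)
})

test_that("thickness calibration recovers linear relations", {
  dens <- c(500, 1000, 1500, 2000, 2500)
  th <- 2 + 0.002 * dens
  cal <- fit_thickness_calibration(dens, th)
  expect_equal(cal$slope, 0.002, tolerance = 1e-12)
  expect_equal(cal$intercept, 2, tolerance = 1e-10)
  expect_equal(predict(cal, 1200), 2 + 0.002 * 1200)

  set.seed(5)
  dn <- stats::runif(100, 500, 3000)
  tn <- 2 + 0.002 * dn + stats::rnorm(100, 0, 0.3)
  caln <- fit_thickness_calibration(dn, tn)
  se <- summary(caln$fit)$coefficients["density", "Std. Error"]
  expect_lt(abs(caln$slope - 0.002), 3 * se)

  expect_error(fit_thickness_calibration(1000, 4), "2 distinct")
})

test_that("density map counts synthetic nuclei", {
  spec <- flow_movie_spec(frames = 1, n_nuclei = 150, size = 300, sigma = 2.5,
                          rng_seed = 8)
  img <- render_flow_movie(spec)$frames[[1]]
  dm <- density_map(img, window = 300, pixel_size = 1)
  area_mm2 <- (300 / 1000)^2
  expect_equal(max(dm$density) * area_mm2, 150, tolerance = 150 * 0.05)

  expect_warning(dm0 <- density_map(matrix(0, 64, 64), window = 20),
                 "empty image")
  expect_true(all(dm0$density == 0))

  spec2 <- flow_movie_spec(frames = 1, n_nuclei = 300, size = 300, sigma = 2.5,
                           rng_seed = 8)
  img2 <- render_flow_movie(spec2)$frames[[1]]
  dm2 <- density_map(img2, window = 300, pixel_size = 1)
  expect_equal(max(dm2$density) / max(dm$density), 2, tolerance = 0.1)
  expect_error(density_map(img, window = 5), ">= 10")
})
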