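# Shared fixtures and independent oracles for the test suite.

# internal helpers used across tests
fft2 <- activegel:::fft2
ifft2 <- activegel:::ifft2
fourier_shift <- activegel:::fourier_shift
interp_grid_ref <- activegel:::interp_grid

# Cached coarse meshes (built once per session).
tiny_mesh <- local({
  cache <- list()
  function(spacing = 0.2) {
    key <- as.character(spacing)
    if (is.null(cache[[key]])) cache[[key]] <<- disc_mesh(spacing)
    cache[[key]]
  }
})

# Build a trajectory object by hand from a displacement history, for
# testing observables independently of the solver.
manual_trajectory <- function(mesh, times, u_frames, c_frames = NULL,
                              params = model_params()) {
  n <- nrow(mesh$nodes)
  nf <- length(times)
  u <- array(0, dim = c(n, 2, nf))
  for (k in seq_len(nf)) u[, , k] <- u_frames[[k]]
  cc <- if (is.null(c_frames)) matrix(1, n, nf) else do.call(cbind, c_frames)
  structure(list(times = times, u = u, c = cc, mesh = mesh, params = params,
                 stepper = stepper_spec(), seeding = NULL,
                 groups = nondim_groups(params), c0 = 1, n_steps = nf),
            class = "gel_trajectory")
}

# Independent 1D radial finite-difference solver of the coupled
# active-gel equations for axisymmetric fields, used as an oracle for
# the 2D P1 solver. Backward Euler on the same dt sequence, Picard
# iteration on the coupled system. u(0)=u(1)=0; dc/dr = 0 at r = 0;
# c fixed (anchored) or no-flux at r = 1.
radial_oracle <- function(params, c0_fun, dt_seq, nr = 201,
                          c_boundary = "fixed") {
  g <- nondim_groups(params)
  r <- seq(0, 1, length.out = nr)
  h <- r[2] - r[1]
  u <- numeric(nr)
  cc <- c0_fun(r)
  ri <- 2:(nr - 1)
  for (dt in dt_seq) {
    u_old <- u; c_old <- cc
    for (pic in 1:60) {
      u_prev <- u; c_prev <- cc
      # displacement: (u_new - u_old)/dt = L u_new + alpha dc/dr
      # L u = d/dr[(1/r) d(r u)/dr]
      dcdr <- numeric(nr)
      dcdr[ri] <- (cc[ri + 1] - cc[ri - 1]) / (2 * h)
      # assemble tridiagonal for u on interior nodes
      main <- numeric(nr); lower <- numeric(nr); upper <- numeric(nr)
      rhs <- numeric(nr)
      for (i in ri) {
        rp <- (r[i] + r[i + 1]) / 2; rm <- (r[i] + r[i - 1]) / 2
        # L u at i: ( (1/rp)*( (r[i+1]u[i+1]-r[i]u[i])/h ) - (1/rm)*( (r[i]u[i]-r[i-1]u[i-1])/h ) ) / h
        a_up <- r[i + 1] / (rp * h^2)
        a_lo <- r[i - 1] / (rm * h^2)
        a_mid <- -r[i] / (rp * h^2) - r[i] / (rm * h^2)
        main[i] <- 1 / dt - a_mid
        upper[i] <- -a_up
        lower[i] <- -a_lo
        rhs[i] <- u_old[i] / dt + g$alpha_hat * dcdr[i]
      }
      u_new <- numeric(nr)
      u_new[ri] <- solve_tridiag(lower[ri], main[ri], upper[ri], rhs[ri])
      v <- (u_new - u_old) / dt
      # concentration: (c-c_old)/dt + v dc/dr =
      #   -(c-1)/tauc + beta (du/dr + u/r) + D (1/r) d/dr(r dc/dr)
      divu <- numeric(nr)
      divu[ri] <- (u_new[ri + 1] - u_new[ri - 1]) / (2 * h) + u_new[ri] / r[ri]
      divu[1] <- 2 * (u_new[2] - u_new[1]) / h   # 2 u'(0) by symmetry
      divu[nr] <- (u_new[nr] - u_new[nr - 1]) / h + u_new[nr] / r[nr]
      main <- numeric(nr); lower <- numeric(nr); upper <- numeric(nr)
      rhs <- numeric(nr)
      for (i in ri) {
        rp <- (r[i] + r[i + 1]) / 2; rm <- (r[i] + r[i - 1]) / 2
        d_up <- g$D_hat * rp / (r[i] * h^2)
        d_lo <- g$D_hat * rm / (r[i] * h^2)
        adv_up <- v[i] / (2 * h); adv_lo <- -v[i] / (2 * h)
        main[i] <- 1 / dt + 1 / g$tauc_hat + d_up + d_lo
        upper[i] <- -d_up + adv_up
        lower[i] <- -d_lo + adv_lo
        rhs[i] <- c_old[i] / dt + 1 / g$tauc_hat + g$beta_hat * divu[i]
      }
      # r = 0: symmetry, c'(0)=0: c[1] couples to c[2] via Laplacian 4(c2-c1)/h^2
      main[1] <- 1 / dt + 1 / g$tauc_hat + 4 * g$D_hat / h^2
      upper[1] <- -4 * g$D_hat / h^2
      rhs[1] <- c_old[1] / dt + 1 / g$tauc_hat + g$beta_hat * divu[1]
      if (c_boundary == "fixed") {
        main[nr] <- 1; lower[nr] <- 0; rhs[nr] <- 1
      } else {
        # no-flux: ghost c[nr+1] = c[nr-1]
        rmm <- (r[nr] + r[nr - 1]) / 2
        d_lo <- g$D_hat * rmm / (r[nr] * h^2)
        main[nr] <- 1 / dt + 1 / g$tauc_hat + 2 * d_lo
        lower[nr] <- -2 * d_lo
        rhs[nr] <- c_old[nr] / dt + 1 / g$tauc_hat + g$beta_hat * divu[nr]
      }
      cc <- solve_tridiag(lower, main, upper, rhs)
      u <- u_new
      if (max(abs(u - u_prev)) + max(abs(cc - c_prev)) < 1e-12) break
    }
  }
  list(r = r, u = u, c = cc)
}

# Thomas algorithm.
solve_tridiag <- function(lower, main, upper, rhs) {
  n <- length(main)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / main[1]
  dp[1] <- rhs[1] / main[1]
  for (i in 2:n) {
    den <- main[i] - lower[i] * cp[i - 1]
    cp[i] <- if (i < n) upper[i] / den else 0
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / den
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# dt sequence of the standard stepper up to t_end.
stepper_dts <- function(st, t_end = st$t_end) {
  dts <- c(); t <- 0; dt <- st$dt0
  while (t < t_end - 1e-14) {
    d <- min(dt, t_end - t)
    dts <- c(dts, d)
    t <- t + d
    dt <- min(dt * st$growth, st$dt_max)
  }
  dts
}
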