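# Synthetic data with known ground truth for validating the measurement
# pipeline: forward Boussinesq displacements, bead image pairs, nuclei
# movies with prescribed flow, and manufactured stress/traction pairs.

#' Forward Boussinesq substrate displacement
#'
#' Surface displacement of an elastic half-space under a tangential
#' surface traction field: `u = G * T` with the Boussinesq surface Green
#' tensor `G_ij(r) = (1+nu)/(pi E r^3) ((1-nu) r^2 d_ij + nu x_i x_j)`.
#' Grids up to 64 x 64 are convolved by direct real-space quadrature
#' (the self-cell uses the analytic disc-average of the kernel); larger
#' grids use Fourier multiplication with zero padding.
#'
#' @param traction list with `Tx`, `Ty` (Pa) and `grid_spacing` (um)
#' @param substrate a [substrate_spec()]
#' @param method `"auto"`, `"direct"` or `"fourier"`
#' @return a `displacement_grid` (um) compatible with [fttc_traction()]
#' @export
boussinesq_forward <- function(traction, substrate, method = "auto") {
  Tx <- traction$Tx; Ty <- traction$Ty
  ny <- nrow(Tx); nx <- ncol(Tx)
  d <- traction$grid_spacing * 1e-6
  E <- substrate$youngs_modulus; nu <- substrate$poisson_ratio
  if (method == "auto") method <- if (nx * ny <= 40L * 40L) "direct" else "fourier"
  if (method == "direct") {
    xs <- (seq_len(nx) - 1) * d
    ys <- (seq_len(ny) - 1) * d
    X <- matrix(xs, ny, nx, byrow = TRUE); Y <- matrix(ys, ny, nx)
    ux <- matrix(0, ny, nx); uy <- matrix(0, ny, nx)
    a_eq <- d / sqrt(pi)   # equivalent-area disc radius of a grid cell
    self_iso <- (1 + nu) * (1 - nu / 2) / E * 2 * a_eq   # angular average
    dA <- d^2
    # 4x4 sub-cell quadrature offsets for near-field cells
    qo <- as.matrix(expand.grid(s1 = (-1.5:1.5) / 4 * d, s2 = (-1.5:1.5) / 4 * d))
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      dx <- X[i, j] - X; dy <- Y[i, j] - Y
      r2 <- dx^2 + dy^2
      r <- sqrt(r2)
      pref <- (1 + nu) / (pi * E * pmax(r, 1e-300)^3)
      gxx <- pref * ((1 - nu) * r2 + nu * dx^2)
      gyy <- pref * ((1 - nu) * r2 + nu * dy^2)
      gxy <- pref * nu * dx * dy
      # near-field (within 2 cells, excluding self): sub-cell quadrature
      near_i <- max(1L, i - 2L):min(ny, i + 2L)
      near_j <- max(1L, j - 2L):min(nx, j + 2L)
      for (ii in near_i) for (jj in near_j) {
        if (ii == i && jj == j) next
        ddx <- X[i, j] - (X[ii, jj] + qo[, 2])
        ddy <- Y[i, j] - (Y[ii, jj] + qo[, 1])
        rr2 <- ddx^2 + ddy^2
        pr <- (1 + nu) / (pi * E * rr2^1.5)
        gxx[ii, jj] <- mean(pr * ((1 - nu) * rr2 + nu * ddx^2))
        gyy[ii, jj] <- mean(pr * ((1 - nu) * rr2 + nu * ddy^2))
        gxy[ii, jj] <- mean(pr * nu * ddx * ddy)
      }
      gxx[i, j] <- 0; gyy[i, j] <- 0; gxy[i, j] <- 0
      ux[i, j] <- sum(gxx * Tx + gxy * Ty) * dA + self_iso * Tx[i, j]
      uy[i, j] <- sum(gxy * Tx + gyy * Ty) * dA + self_iso * Ty[i, j]
    }
  } else {
    # 4x zero padding keeps the periodic images of the long-ranged
    # kernel negligible for zero-net-force fields
    NY <- 4L * ny; NX <- 4L * nx
    pTx <- matrix(0, NY, NX); pTy <- matrix(0, NY, NX)
    pTx[1:ny, 1:nx] <- Tx; pTy[1:ny, 1:nx] <- Ty
    kx1 <- 2 * pi * c(0:(NX / 2), -(NX / 2 - 1):-1)[1:NX] / (NX * d)
    ky1 <- 2 * pi * c(0:(NY / 2), -(NY / 2 - 1):-1)[1:NY] / (NY * d)
    KX <- matrix(kx1, NY, NX, byrow = TRUE); KY <- matrix(ky1, NY, NX)
    K <- sqrt(KX^2 + KY^2); K[1, 1] <- 1
    pref <- 2 * (1 + nu) / (E * K^3)
    Gxx <- pref * (K^2 - nu * KX^2)
    Gyy <- pref * (K^2 - nu * KY^2)
    Gxy <- pref * (-nu * KX * KY)
    FTx <- fft2(pTx); FTy <- fft2(pTy)
    Fux <- Gxx * FTx + Gxy * FTy
    Fuy <- Gxy * FTx + Gyy * FTy
    Fux[1, 1] <- 0; Fuy[1, 1] <- 0
    ux <- Re(ifft2(Fux))[1:ny, 1:nx]
    uy <- Re(ifft2(Fuy))[1:ny, 1:nx]
  }
  structure(list(x = traction$x, y = traction$y,
                 ux = ux * 1e6, uy = uy * 1e6,
                 mask = matrix(TRUE, ny, nx),
                 grid_spacing = traction$grid_spacing),
            class = "displacement_grid")
}

#' Bead image specification
#' @param size image side, px
#' @param density beads per um^2
#' @param sigma bead spot sigma, px
#' @param pixel_size um per pixel
#' @param noise Poisson noise scale (expected photons at unit intensity;
#'   0 disables noise)
#' @param rng_seed integer seed
#' @return object of class `bead_image_spec`
#' @export
bead_image_spec <- function(size = 256L, density = 0.02, sigma = 1.5,
                            pixel_size = 1, noise = 0, rng_seed = 1L) {
  structure(list(size = as.integer(size), density = density, sigma = sigma,
                 pixel_size = pixel_size, noise = noise,
                 rng_seed = as.integer(rng_seed)),
            class = "bead_image_spec")
}

# Render Gaussian spots at subpixel positions (positions in px).
render_spots <- function(size, pos, sigma, amplitude = 1) {
  img <- matrix(0, size, size)
  r <- ceiling(4 * sigma)
  for (k in seq_len(nrow(pos))) {
    cx <- pos[k, 1]; cy <- pos[k, 2]
    jx <- max(1L, floor(cx - r)):min(size, ceiling(cx + r))
    iy <- max(1L, floor(cy - r)):min(size, ceiling(cy + r))
    if (!length(jx) || !length(iy)) next
    gx <- exp(-(jx - cx)^2 / (2 * sigma^2))
    gy <- exp(-(iy - cy)^2 / (2 * sigma^2))
    img[iy, jx] <- img[iy, jx] + amplitude * outer(gy, gx)
  }
  img
}

#' Render a reference/deformed bead image pair
#'
#' Beads are placed uniformly at random, rendered as Gaussian spots; the
#' deformed image advects each bead by the displacement field
#' interpolated at its position. Optional Poisson photon noise is applied
#' independently to both images.
#'
#' @param spec a [bead_image_spec()]
#' @param disp a `displacement_grid` (um); `NULL` means zero displacement
#' @return list with `reference`, `deformed` (matrices), `positions`
#'   (px), `spec`
#' @export
render_bead_pair <- function(spec, disp = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$rng_seed)
  n_beads <- stats::rpois(1, spec$density * (spec$size * spec$pixel_size)^2)
  if (n_beads * pi * (2 * spec$sigma)^2 > 1.5 * spec$size^2)
    warning("bead density so high that spots overlap substantially")
  pos <- cbind(stats::runif(n_beads, 1, spec$size),
               stats::runif(n_beads, 1, spec$size))
  ref <- render_spots(spec$size, pos, spec$sigma)
  if (is.null(disp)) {
    def <- render_spots(spec$size, pos, spec$sigma)
  } else {
    ux <- interp_grid(disp$x, disp$y, disp$ux, pos[, 1] * spec$pixel_size,
                      pos[, 2] * spec$pixel_size) / spec$pixel_size
    uy <- interp_grid(disp$x, disp$y, disp$uy, pos[, 1] * spec$pixel_size,
                      pos[, 2] * spec$pixel_size) / spec$pixel_size
    if (max(abs(c(ux, uy)), na.rm = TRUE) > spec$size / 4)
      stop("displacement exceeds a quarter of the image extent", call. = FALSE)
    def <- render_spots(spec$size, pos + cbind(ux, uy), spec$sigma)
  }
  if (spec$noise > 0) {
    ref <- matrix(stats::rpois(length(ref), ref * spec$noise + 1) / spec$noise,
                  spec$size, spec$size)
    def <- matrix(stats::rpois(length(def), def * spec$noise + 1) / spec$noise,
                  spec$size, spec$size)
  }
  list(reference = ref, deformed = def, positions = pos, spec = spec)
}

# Bilinear interpolation of a grid field (coordinates ascending vectors).
interp_grid <- function(gx, gy, z, px, py) {
  jx <- findInterval(px, gx, all.inside = TRUE)
  iy <- findInterval(py, gy, all.inside = TRUE)
  x1 <- gx[jx]; x2 <- gx[jx + 1L]
  y1 <- gy[iy]; y2 <- gy[iy + 1L]
  tx <- ifelse(x2 > x1, (px - x1) / (x2 - x1), 0)
  ty <- ifelse(y2 > y1, (py - y1) / (y2 - y1), 0)
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  z11 <- z[cbind(iy, jx)]; z12 <- z[cbind(iy, jx + 1L)]
  z21 <- z[cbind(iy + 1L, jx)]; z22 <- z[cbind(iy + 1L, jx + 1L)]
  (1 - ty) * ((1 - tx) * z11 + tx * z12) + ty * ((1 - tx) * z21 + tx * z22)
}

#' Flow movie specification
#' @param frames number of frames
#' @param dt_min frame interval, minutes
#' @param flow `"none"`, `"uniform"`, `"radial"` or `"shift"`
#' @param speed flow speed, um/h (uniform / radial magnitude)
#' @param size image side, px
#' @param n_nuclei nucleus count
#' @param sigma nucleus spot sigma, px
#' @param pixel_size um per pixel
#' @param noise Poisson noise scale (0 = none)
#' @param rng_seed integer seed
#' @return object of class `flow_movie_spec`
#' @export
flow_movie_spec <- function(frames = 5L, dt_min = 16, flow = "uniform",
                            speed = 10, size = 256L, n_nuclei = 300L,
                            sigma = 3, pixel_size = 1, noise = 0,
                            rng_seed = 1L) {
  structure(list(frames = as.integer(frames), dt_min = dt_min, flow = flow,
                 speed = speed, size = as.integer(size),
                 n_nuclei = as.integer(n_nuclei), sigma = sigma,
                 pixel_size = pixel_size, noise = noise,
                 rng_seed = as.integer(rng_seed)),
            class = "flow_movie_spec")
}

#' Render a nuclei movie with prescribed flow
#'
#' Nuclei are advected frame-to-frame by the parametric flow; nuclei
#' leaving the frame respawn uniformly at random positions to keep the
#' density stationary. The per-frame ground-truth velocity field is
#' returned alongside.
#'
#' @param spec a [flow_movie_spec()]
#' @return list with `frames` (list of matrices), `truth` (function
#'   `(x_um, y_um) -> cbind(vx, vy)` in um/h), `spec`
#' @export
render_flow_movie <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$rng_seed)
  size_um <- spec$size * spec$pixel_size
  ctr <- size_um / 2
  vel <- switch(spec$flow,
    none = function(x, y) cbind(0 * x, 0 * y),
    uniform = function(x, y) cbind(rep(spec$speed, length(x)), rep(0, length(x))),
    radial = function(x, y) {
      dx <- x - ctr; dy <- y - ctr
      r <- pmax(sqrt(dx^2 + dy^2), 1e-9)
      cbind(-spec$speed * dx / r, -spec$speed * dy / r)
    },
    shift = function(x, y) cbind(rep(spec$speed, length(x)),
                                 rep(spec$speed, length(x))),
    stop("unknown flow type", call. = FALSE))
  pos <- cbind(stats::runif(spec$n_nuclei, 1, spec$size),
               stats::runif(spec$n_nuclei, 1, spec$size))
  frames <- vector("list", spec$frames)
  step_px <- spec$dt_min / 60 / spec$pixel_size   # um/h -> px/frame
  for (k in seq_len(spec$frames)) {
    img <- render_spots(spec$size, pos, spec$sigma)
    if (spec$noise > 0)
      img <- matrix(stats::rpois(length(img), img * spec$noise + 1) / spec$noise,
                    spec$size, spec$size)
    frames[[k]] <- img
    v <- vel(pos[, 1] * spec$pixel_size, pos[, 2] * spec$pixel_size)
    pos <- pos + v * step_px
    gone <- pos[, 1] < 1 | pos[, 1] > spec$size | pos[, 2] < 1 | pos[, 2] > spec$size
    if (any(gone))
      pos[gone, ] <- cbind(stats::runif(sum(gone), 1, spec$size),
                           stats::runif(sum(gone), 1, spec$size))
  }
  list(frames = frames, truth = vel, spec = spec)
}

#' Manufactured stress field with analytic traction divergence
#'
#' An elastically compatible smooth line-stress tensor vanishing at the
#' field border, built from a quartic-bump displacement potential
#' `w = (a, b) p(x) p(y)` through the plane-stress law (Poisson ratio
#' `nu`), together with the traction field `T = -div(sigma)` evaluated
#' analytically. Force-balance stress recovery returns the compatible
#' solution, so this pair is the exact-solution oracle for
#' [recover_stress()] when the same `nu` is assumed.
#'
#' @param n grid side (nodes)
#' @param grid_spacing um
#' @param amplitude peak normal stress, mN/m
#' @param nu Poisson ratio of the generating plane-stress law
#' @return list with `stress` (`sxx`, `sxy`, `syy`, `sigma_abs`, mN/m),
#'   `traction` (`Tx`, `Ty`, Pa; `grid_spacing` um), `interior`
#' @export
manufactured_stress_case <- function(n = 48L, grid_spacing = 10,
                                     amplitude = 1, nu = 0.5) {
  d <- grid_spacing * 1e-6
  L <- (n - 1L) * d
  s <- seq(0, L, length.out = n)
  # quartic bump p in [0,1], p = p' = 0 at the borders
  p <- function(t) 16 * (t * (L - t))^2 / L^4
  dp <- function(t) 32 * t * (L - t) * (L - 2 * t) / L^4
  d2p <- function(t) 32 * ((L - 2 * t)^2 - 2 * t * (L - t)) / L^4
  P <- p(s); DP <- dp(s); D2P <- d2p(s)
  rowm <- function(v) matrix(v, n, n)              # varies along y (rows)
  colm <- function(v) matrix(v, n, n, byrow = TRUE) # varies along x (cols)
  a <- 1; b <- 0.6   # displacement potential components (arbitrary units)
  # strains of w = (a PQ, b PQ), P = p(x), Q = p(y)
  exx <- a * colm(DP) * rowm(P)
  eyy <- b * colm(P) * rowm(DP)
  exy <- 0.5 * (a * colm(P) * rowm(DP) + b * colm(DP) * rowm(P))
  c1 <- 1 / (1 - nu^2); c2 <- 1 / (1 + nu)
  sxx <- c1 * (exx + nu * eyy)
  syy <- c1 * (eyy + nu * exx)
  sxy <- c2 * exy
  # analytic divergence
  dsxx_dx <- c1 * (a * colm(D2P) * rowm(P) + nu * b * colm(DP) * rowm(DP))
  dsyy_dy <- c1 * (b * colm(P) * rowm(D2P) + nu * a * colm(DP) * rowm(DP))
  dsxy_dy <- c2 * 0.5 * (a * colm(P) * rowm(D2P) + b * colm(DP) * rowm(DP))
  dsxy_dx <- c2 * 0.5 * (a * colm(DP) * rowm(DP) + b * colm(D2P) * rowm(P))
  # scale so the peak normal stress is `amplitude` mN/m
  scale <- amplitude * 1e-3 / max(abs(sxx))
  sxx <- sxx * scale; syy <- syy * scale; sxy <- sxy * scale
  Tx <- -(dsxx_dx + dsxy_dy) * scale
  Ty <- -(dsxy_dx + dsyy_dy) * scale
  margin <- max(2L, ceiling(0.1 * n))
  interior <- matrix(FALSE, n, n)
  interior[(margin + 1L):(n - margin), (margin + 1L):(n - margin)] <- TRUE
  list(stress = list(sxx = sxx * 1e3, sxy = sxy * 1e3, syy = syy * 1e3,
                     sigma_abs = abs((sxx + syy) / 2) * 1e3),
       traction = list(x = s * 1e6, y = s * 1e6, Tx = Tx, Ty = Ty,
                       grid_spacing = grid_spacing),
       interior = interior, nu = nu)
}
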