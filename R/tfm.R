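#' Elastic substrate description
#'
#' Properties of the polyacrylamide gel used for traction force
#' microscopy: Young's modulus (default 4 kPa), Poisson ratio (default
#' 0.49, near-incompressible polyacrylamide) and the camera pixel size.
#'
#' @param youngs_modulus Pa
#' @param poisson_ratio in \[0, 0.5)
#' @param pixel_size um per pixel
#' @return object of class `substrate_spec`
#' @export
substrate_spec <- function(youngs_modulus = 4000, poisson_ratio = 0.49,
                           pixel_size = 1) {
  stopifnot(youngs_modulus > 0, poisson_ratio >= 0, poisson_ratio < 0.5,
            pixel_size > 0)
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio,
                 pixel_size = pixel_size),
            class = "substrate_spec")
}

#' Rigid registration of an image stack
#'
#' Estimates a subpixel translation of every frame against the first by
#' phase correlation (with local upsampled-DFT refinement) and resamples
#' each frame onto the reference by Fourier shifting.
#'
#' @param frames list of equally sized image matrices (or 3D array
#'   y-x-frame)
#' @return list with `frames` (registered stack, same layout as input)
#'   and `offsets` (n x 2 matrix of recovered (dx, dy) in pixels)
#' @export
register_rigid <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  if (length(frames) < 2L) stop("need at least 2 frames", call. = FALSE)
  ref <- frames[[1L]]
  if (stats::sd(ref) < 1e-14)
    stop("registration failure: featureless reference frame", call. = FALSE)
  offsets <- matrix(0, length(frames), 2L,
                    dimnames = list(NULL, c("dx", "dy")))
  out <- frames
  for (k in seq_along(frames)[-1L]) {
    if (stats::sd(frames[[k]]) < 1e-14)
      stop(sprintf("registration failure: featureless frame %d", k),
           call. = FALSE)
    s <- phase_shift(ref, frames[[k]])
    offsets[k, ] <- s
    out[[k]] <- fourier_shift(frames[[k]], -s[1], -s[2])
  }
  list(frames = out, offsets = offsets)
}

# Shift image content by (dx, dy) pixels (x right, y up) using the
# Fourier shift theorem (circular boundary): f(x) -> f(x - d).
fourier_shift <- function(img, dx, dy) {
  ny <- nrow(img); nx <- ncol(img)
  ky <- c(0:(floor(ny / 2)), -(ceiling(ny / 2) - 1):-1)[1:ny]
  kx <- c(0:(floor(nx / 2)), -(ceiling(nx / 2) - 1):-1)[1:nx]
  ph <- exp(-2i * pi * (outer(ky * dy / ny, rep(1, nx)) +
                        outer(rep(1, ny), kx * dx / nx)))
  Re(ifft2(fft2(img) * ph))
}

#' Bead displacement field from an image pair
#'
#' Windowed cross-correlation with 3-point Gaussian subpixel peak
#' interpolation. Grid spacing is `window * (1 - overlap)` pixels;
#' featureless (bead-free) windows are flagged in `mask`, not silently
#' zeroed.
#'
#' @param reference unstrained bead image (matrix)
#' @param deformed strained bead image
#' @param window interrogation window, px (>= 16)
#' @param overlap window overlap fraction
#' @param pixel_size um per pixel
#' @return object of class `displacement_grid`: list with `x`, `y`
#'   (window-centre coordinates, um), `ux`, `uy` (um), `mask`,
#'   `grid_spacing` (um)
#' @export
bead_displacement <- function(reference, deformed, window = 32L,
                              overlap = 0.5, pixel_size = 1) {
  if (!all(dim(reference) == dim(deformed)))
    stop("image dimensions differ", call. = FALSE)
  if (window < 16L) stop("window must be >= 16 px", call. = FALSE)
  wd <- window_displacements(reference, deformed, window, overlap)
  structure(list(x = wd$x * pixel_size, y = wd$y * pixel_size,
                 ux = wd$dx * pixel_size, uy = wd$dy * pixel_size,
                 mask = wd$mask,
                 grid_spacing = wd$step * pixel_size),
            class = "displacement_grid")
}

#' Traction field by Fourier-transform traction cytometry
#'
#' Inverts the Boussinesq elastic half-space relation in Fourier space.
#' The surface Green tensor in Fourier space is
#' `G(k) = 2 (1 + nu) / (E k^3) * (k^2 I - nu k kT)`; tractions are
#' `T(k) = G(k)^{-1} u(k)`. The displacement grid is zero-padded to twice
#' its size before transforming; the zero-frequency (mean) mode carries
#' no traction information for an unconstrained inversion and is set to
#' zero. No regularization is applied unless `lambda > 0` is given
#' (Tikhonov term `lambda^2 I` added to `G G^T`).
#'
#' @param disp a [bead_displacement()] grid (um)
#' @param substrate a [substrate_spec()]
#' @param lambda optional Tikhonov regularization (default 0,
#'   unconstrained)
#' @return object of class `traction_field`: list with `x`, `y` (um),
#'   `Tx`, `Ty` (Pa), `grid_spacing` (um)
#' @export
fttc_traction <- function(disp, substrate, lambda = 0) {
  ux <- disp$ux; uy <- disp$uy
  if (anyNA(ux) || anyNA(uy)) {
    if (!is.null(disp$mask) && mean(disp$mask) > 0.9) {
      ux[!disp$mask] <- 0; uy[!disp$mask] <- 0
    } else stop("displacement grid contains NAs", call. = FALSE)
  }
  ny <- nrow(ux); nx <- ncol(ux)
  if (ny < 8L || nx < 8L) stop("grid too small", call. = FALSE)
  d <- disp$grid_spacing * 1e-6          # m
  E <- substrate$youngs_modulus; nu <- substrate$poisson_ratio
  NY <- 2L * ny; NX <- 2L * nx
  pux <- matrix(0, NY, NX); puy <- matrix(0, NY, NX)
  pux[1:ny, 1:nx] <- ux * 1e-6; puy[1:ny, 1:nx] <- uy * 1e-6
  Fux <- fft2(pux); Fuy <- fft2(puy)
  kx1 <- 2 * pi * c(0:(NX / 2), -(NX / 2 - 1):-1)[1:NX] / (NX * d)
  ky1 <- 2 * pi * c(0:(NY / 2), -(NY / 2 - 1):-1)[1:NY] / (NY * d)
  KX <- matrix(kx1, NY, NX, byrow = TRUE)
  KY <- matrix(ky1, NY, NX)
  K <- sqrt(KX^2 + KY^2); K[1, 1] <- 1
  pref <- 2 * (1 + nu) / (E * K^3)
  Gxx <- pref * (K^2 - nu * KX^2)
  Gyy <- pref * (K^2 - nu * KY^2)
  Gxy <- pref * (-nu * KX * KY)
  det <- Gxx * Gyy - Gxy^2
  if (lambda > 0) {
    # Tikhonov: T = (G^T G + lambda^2 I)^{-1} G^T u, G symmetric
    Axx <- Gxx^2 + Gxy^2 + lambda^2
    Ayy <- Gyy^2 + Gxy^2 + lambda^2
    Axy <- Gxy * (Gxx + Gyy)
    bx <- Gxx * Fux + Gxy * Fuy
    by <- Gxy * Fux + Gyy * Fuy
    dA <- Axx * Ayy - Axy^2
    FTx <- (Ayy * bx - Axy * by) / dA
    FTy <- (-Axy * bx + Axx * by) / dA
  } else {
    FTx <- (Gyy * Fux - Gxy * Fuy) / det
    FTy <- (-Gxy * Fux + Gxx * Fuy) / det
  }
  FTx[1, 1] <- 0; FTy[1, 1] <- 0
  Tx <- Re(ifft2(FTx))[1:ny, 1:nx]
  Ty <- Re(ifft2(FTy))[1:ny, 1:nx]
  structure(list(x = disp$x, y = disp$y, Tx = Tx, Ty = Ty,
                 grid_spacing = disp$grid_spacing),
            class = "traction_field")
}
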