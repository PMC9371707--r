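# Monolayer stress microscopy: recover the intercellular line-stress
# tensor from a traction field via the 2D force balance
#   d(sxx)/dx + d(sxy)/dy = -Tx,   d(sxy)/dx + d(syy)/dy = -Ty,
# solved as a plane-stress elastic problem on the field rectangle with a
# clamped border. The recovered stress is insensitive to the assumed
# elastic modulus (it rescales the auxiliary displacement only) and
# weakly sensitive to its Poisson ratio; results are reported with an
# interior crop to keep clear of the artificial boundary condition.

# Structured triangulation of a nx x ny node grid with spacing d (um).
rect_mesh <- function(nx, ny, d) {
  xy <- cbind(rep(seq_len(nx) - 1, each = ny) * d,
              rep(seq_len(ny) - 1, times = nx) * d)
  # node index (i=y,j=x) -> (j-1)*ny + i
  idx <- function(i, j) (j - 1L) * ny + i
  tris <- vector("list", (nx - 1L) * (ny - 1L))
  q <- 0L
  for (j in seq_len(nx - 1L)) for (i in seq_len(ny - 1L)) {
    q <- q + 1L
    tris[[q]] <- rbind(c(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L)),
                       c(idx(i, j), idx(i + 1L, j + 1L), idx(i + 1L, j)))
  }
  list(nodes = xy, triangles = do.call(rbind, tris), nx = nx, ny = ny)
}

# P1 gradients and areas for an arbitrary triangulation.
tri_geometry <- function(nodes, tri) {
  p1 <- nodes[tri[, 1], , drop = FALSE]
  p2 <- nodes[tri[, 2], , drop = FALSE]
  p3 <- nodes[tri[, 3], , drop = FALSE]
  d32 <- p3 - p2; d13 <- p1 - p3; d21 <- p2 - p1
  A <- 0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
              (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
  bx <- cbind(-d32[, 2], -d13[, 2], -d21[, 2]) / (2 * A)
  by <- cbind(d32[, 1], d13[, 1], d21[, 1]) / (2 * A)
  list(A = A, bx = bx, by = by)
}

# Plane-stress stiffness: sigma = 2 mu eps + lam tr(eps) I with
# mu = E/(2(1+nu)), lam = E nu/(1-nu^2)  (plane-stress lambda).
plane_stress_stiffness <- function(nodes, tri, E, nu) {
  g <- tri_geometry(nodes, tri)
  n <- nrow(nodes)
  mu <- E / (2 * (1 + nu)); lam <- E * nu / (1 - nu^2)
  b <- list(g$bx, g$by)
  Ki <- Kj <- Kx <- vector("list", 36)
  q <- 0L
  for (a in 1:2) for (bb in 1:2) for (i in 1:3) for (j in 1:3) {
    q <- q + 1L
    eps_eps <- 0.5 * ((a == bb) * (g$bx[, i] * g$bx[, j] + g$by[, i] * g$by[, j]) +
                      b[[bb]][, i] * b[[a]][, j])
    val <- g$A * (2 * mu * eps_eps + lam * b[[a]][, i] * b[[bb]][, j])
    Ki[[q]] <- tri[, i] + (a - 1L) * n
    Kj[[q]] <- tri[, j] + (bb - 1L) * n
    Kx[[q]] <- val
  }
  Matrix::sparseMatrix(i = unlist(Ki), j = unlist(Kj), x = unlist(Kx),
                       dims = c(2L * n, 2L * n))
}

#' Recover intercellular line stress from a traction field
#'
#' Solves the monolayer force balance for the 2D line-stress tensor
#' (mN/m) given the traction field (Pa) the sheet exerts on its
#' substrate. An auxiliary plane-stress elastic problem with clamped
#' border is solved by P1 finite elements on the traction grid; the
#' stress is evaluated per element, averaged to nodes, and reported with
#' the scalar `sigma_abs = |(sxx + syy) / 2|`.
#'
#' @param traction a [fttc_traction()] field (or compatible list with
#'   `Tx`, `Ty` in Pa and `grid_spacing` in um)
#' @param E_aux,nu_aux auxiliary elastic constants of the plane-stress
#'   solve; the recovered stress does not depend on `E_aux`
#' @return object of class `stress_map`: `sxx`, `sxy`, `syy`,
#'   `sigma_abs` (mN/m, matrices on the traction grid), `grid_spacing`
#'   (um), `interior` (logical matrix marking the 10% interior crop)
#' @export
recover_stress <- function(traction, E_aux = 1, nu_aux = 0.5) {
  Tx <- traction$Tx; Ty <- traction$Ty
  if (mean(!is.finite(Tx) | !is.finite(Ty)) > 0.1)
    stop("more than 10% of traction cells are masked", call. = FALSE)
  Tx[!is.finite(Tx)] <- 0; Ty[!is.finite(Ty)] <- 0
  ny <- nrow(Tx); nx <- ncol(Tx)
  d <- traction$grid_spacing * 1e-6              # m
  rm_ <- rect_mesh(nx, ny, d)
  n <- nrow(rm_$nodes)
  K <- plane_stress_stiffness(rm_$nodes, rm_$triangles, E_aux, nu_aux)
  # load: F_i = -int T phi_i  (lumped quadrature), T in Pa, d in m
  lump <- numeric(n)
  g <- tri_geometry(rm_$nodes, rm_$triangles)
  for (k in 1:3) {
    acc <- rowsum(g$A / 3, rm_$triangles[, k])
    lump[as.integer(rownames(acc))] <- lump[as.integer(rownames(acc))] + acc[, 1]
  }
  # rect_mesh node (i,j) -> (j-1)*ny+i matches column-major Tx[i, j].
  # Weak form of div(sigma) = -T with border-supported test functions:
  # int sigma : eps(phi) = int T . phi
  tx <- as.vector(Tx); ty <- as.vector(Ty)
  F <- c(lump * tx, lump * ty)
  iy <- rep(seq_len(ny), times = nx); jx <- rep(seq_len(nx), each = ny)
  boundary <- iy == 1L | iy == ny | jx == 1L | jx == nx
  free_nodes <- which(!boundary)
  free <- c(free_nodes, n + free_nodes)
  w <- numeric(2L * n)
  w[free] <- as.numeric(Matrix::solve(K[free, free], F[free]))
  # element stresses -> nodal average (area weighted)
  tri <- rm_$triangles
  wx <- w[seq_len(n)]; wy <- w[n + seq_len(n)]
  exx <- rowSums(matrix(wx[tri], ncol = 3) * g$bx)
  eyy <- rowSums(matrix(wy[tri], ncol = 3) * g$by)
  exy <- 0.5 * (rowSums(matrix(wx[tri], ncol = 3) * g$by) +
                rowSums(matrix(wy[tri], ncol = 3) * g$bx))
  mu <- E_aux / (2 * (1 + nu_aux)); lam <- E_aux * nu_aux / (1 - nu_aux^2)
  sxx_e <- 2 * mu * exx + lam * (exx + eyy)
  syy_e <- 2 * mu * eyy + lam * (exx + eyy)
  sxy_e <- 2 * mu * exy
  nodal <- function(se) {
    acc <- numeric(n)
    for (k in 1:3) {
      a2 <- rowsum(se * g$A / 3, tri[, k])
      acc[as.integer(rownames(a2))] <- acc[as.integer(rownames(a2))] + a2[, 1]
    }
    matrix(acc / lump, ny, nx)
  }
  to_mNm <- 1e3   # Pa*m -> mN/m
  sxx <- nodal(sxx_e) * to_mNm
  syy <- nodal(syy_e) * to_mNm
  sxy <- nodal(sxy_e) * to_mNm
  margin_x <- max(2L, ceiling(0.1 * nx)); margin_y <- max(2L, ceiling(0.1 * ny))
  interior <- matrix(FALSE, ny, nx)
  interior[(margin_y + 1L):(ny - margin_y), (margin_x + 1L):(nx - margin_x)] <- TRUE
  structure(list(sxx = sxx, sxy = sxy, syy = syy,
                 sigma_abs = abs((sxx + syy) / 2),
                 grid_spacing = traction$grid_spacing,
                 interior = interior),
            class = "stress_map")
}

#' Mean tension time series
#'
#' Spatial mean of `sigma_abs` per frame, the simulated counterpart of
#' the intercellular tension time course reported by monolayer stress
#' microscopy.
#'
#' @param stress_maps list of [recover_stress()] maps (ordered in time)
#' @param interior_only restrict the mean to the interior crop
#' @return numeric vector of mean tensions (mN/m)
#' @export
tension_timeseries <- function(stress_maps, interior_only = TRUE) {
  if (length(stress_maps) < 1L) stop("need at least one map", call. = FALSE)
  vapply(stress_maps, function(s) {
    v <- if (interior_only && !is.null(s$interior)) s$sigma_abs[s$interior] else s$sigma_abs
    mean(v)
  }, numeric(1))
}
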