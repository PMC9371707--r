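# P1 finite-element operators on a triangulated disc.
#
# Degree-of-freedom layout used throughout the solver:
#   u = (ux_1..ux_N, uy_1..uy_N), c = (c_1..c_N); the coupled vector is
#   (u, c). Dirichlet u = 0 on boundary nodes is imposed by reduction to
#   the free displacement dofs.

#' Precompute P1 operators for a mesh
#'
#' Assembles the constant sparse operators of the active-gel system:
#' consistent mass `Mc`, scalar stiffness `Kc` (diffusion), vector elastic
#' stiffness `K` (from the symmetric-gradient bilinear form
#' `int eps(u):eps(w)`), the concentration-to-force map `G`
#' (`int (grad c) . w`), the dilatation map `Bdiv` (`int (div u) q`), and
#' per-slot scatter matrices used to accumulate the nonlinear convection
#' residual triangle-wise.
#'
#' @param mesh a [disc_mesh()]
#' @return list of operators (class `fem_ops`)
#' @keywords internal
fem_operators <- function(mesh) {
  tri <- mesh$triangles
  n <- nrow(mesh$nodes); m <- nrow(tri)
  p1 <- mesh$nodes[tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tri[, 3], , drop = FALSE]
  d32 <- p3 - p2; d13 <- p1 - p3; d21 <- p2 - p1
  A <- 0.5 * (d21[, 1] * (-d13[, 2]) - (-d13[, 1]) * d21[, 2])
  # P1 shape-function gradients: b_i = (y_j - y_k, x_k - x_j) / (2A), cyclic
  bx <- cbind(-d32[, 2], -d13[, 2], -d21[, 2]) / (2 * A)
  by <- cbind(d32[, 1], d13[, 1], d21[, 1]) / (2 * A)

  ii <- as.vector(tri[, rep(1:3, each = 3)])
  jj <- as.vector(tri[, rep(1:3, times = 3)])
  pair_i <- rep(1:3, each = 3); pair_j <- rep(1:3, times = 3)

  # scalar stiffness int grad(phi_i).grad(phi_j)
  kc_vals <- unlist(lapply(seq_len(9), function(q) {
    i <- pair_i[q]; j <- pair_j[q]
    A * (bx[, i] * bx[, j] + by[, i] * by[, j])
  }))
  Kc <- Matrix::sparseMatrix(i = ii, j = jj, x = kc_vals, dims = c(n, n))

  # consistent mass int phi_i phi_j = A/12 (1 + delta_ij)
  mc_vals <- unlist(lapply(seq_len(9), function(q) {
    (A / 12) * (1 + (pair_i[q] == pair_j[q]))
  }))
  Mc <- Matrix::sparseMatrix(i = ii, j = jj, x = mc_vals, dims = c(n, n))

  # elastic stiffness int eps(phi_i e_a):eps(phi_j e_b)
  b <- list(bx, by)
  Ki <- Kj <- Kx <- vector("list", 36)
  q <- 0L
  for (a in 1:2) for (bb in 1:2) for (i in 1:3) for (j in 1:3) {
    q <- q + 1L
    val <- 0.5 * A * ((a == bb) * (bx[, i] * bx[, j] + by[, i] * by[, j]) +
                      b[[bb]][, i] * b[[a]][, j])
    Ki[[q]] <- tri[, i] + (a - 1L) * n
    Kj[[q]] <- tri[, j] + (bb - 1L) * n
    Kx[[q]] <- val
  }
  K <- Matrix::sparseMatrix(i = unlist(Ki), j = unlist(Kj), x = unlist(Kx),
                            dims = c(2L * n, 2L * n))

  # G: (2N x N), row (i,a), col j: int (d_a phi_j) phi_i = A/3 b_{a,j}
  Gi <- Gj <- Gx <- vector("list", 18)
  q <- 0L
  for (a in 1:2) for (i in 1:3) for (j in 1:3) {
    q <- q + 1L
    Gi[[q]] <- tri[, i] + (a - 1L) * n
    Gj[[q]] <- tri[, j]
    Gx[[q]] <- (A / 3) * b[[a]][, j]
  }
  G <- Matrix::sparseMatrix(i = unlist(Gi), j = unlist(Gj), x = unlist(Gx),
                            dims = c(2L * n, n))

  # Bdiv: (N x 2N), row i, col (j,b): int phi_i d_b phi_j = A/3 b_{b,j}
  Bi <- Bj <- Bx <- vector("list", 18)
  q <- 0L
  for (bb in 1:2) for (i in 1:3) for (j in 1:3) {
    q <- q + 1L
    Bi[[q]] <- tri[, i]
    Bj[[q]] <- tri[, j] + (bb - 1L) * n
    Bx[[q]] <- (A / 3) * b[[bb]][, j]
  }
  Bdiv <- Matrix::sparseMatrix(i = unlist(Bi), j = unlist(Bj), x = unlist(Bx),
                               dims = c(n, 2L * n))

  # scatter: for slot k, (N x m) incidence node(tri[,k]) <- triangle
  scat <- lapply(1:3, function(k)
    Matrix::sparseMatrix(i = tri[, k], j = seq_len(m), x = 1, dims = c(n, m)))

  structure(list(n = n, m = m, tri = tri, A = A, bx = bx, by = by,
                 Mc = Mc, Kc = Kc, K = K, G = G, Bdiv = Bdiv, scat = scat,
                 lumped = mesh$node_areas),
            class = "fem_ops")
}

# Convection residual int (v . grad c) phi_i dA, v and c P1 nodal fields.
# grad c is constant per triangle; v.grad c is linear, integrated exactly.
convection_residual <- function(ops, vx, vy, cc) {
  tri <- ops$tri
  cm <- matrix(cc[tri], ncol = 3L)
  gx <- rowSums(cm * ops$bx)
  gy <- rowSums(cm * ops$by)
  s <- lapply(1:3, function(k) gx * vx[tri[, k]] + gy * vy[tri[, k]])
  S <- s[[1]] + s[[2]] + s[[3]]
  out <- numeric(ops$n)
  for (k in 1:3)
    out <- out + as.numeric(ops$scat[[k]] %*% ((ops$A / 12) * (S + s[[k]])))
  out
}

# Jacobian blocks of the convection term (used for the exact-Jacobian
# fallback): d/dc gives the convection matrix C(v); d/du gives (1/dt) D(c).
convection_jacobian <- function(ops, vx, vy, cc, dt) {
  tri <- ops$tri; n <- ops$n; A <- ops$A
  cm <- matrix(cc[tri], ncol = 3L)
  gx <- rowSums(cm * ops$bx)
  gy <- rowSums(cm * ops$by)
  pair_i <- rep(1:3, each = 3); pair_j <- rep(1:3, times = 3)
  # C(v)_{i,j} = sum_k (A/12)(1+d_ik)(v_k . b_j)  (int phi_i phi_k v_k.grad phi_j)
  ii <- jj <- xx <- vector("list", 9)
  for (q in seq_len(9)) {
    i <- pair_i[q]; j <- pair_j[q]
    val <- numeric(ops$m)
    for (k in 1:3) {
      vb <- vx[tri[, k]] * ops$bx[, j] + vy[tri[, k]] * ops$by[, j]
      val <- val + (A / 12) * (1 + (i == k)) * vb
    }
    ii[[q]] <- tri[, i]; jj[[q]] <- tri[, j]; xx[[q]] <- val
  }
  Cv <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                             dims = c(n, n))
  # D(c)_{i,(j,b)} = (1/dt) (A/12)(1+d_ij) (grad c)_b
  g <- list(gx, gy)
  ii <- jj <- xx <- vector("list", 18)
  q <- 0L
  for (bb in 1:2) for (q2 in seq_len(9)) {
    q <- q + 1L
    i <- pair_i[q2]; j <- pair_j[q2]
    ii[[q]] <- tri[, i]
    jj[[q]] <- tri[, j] + (bb - 1L) * n
    xx[[q]] <- (1 / dt) * (A / 12) * (1 + (i == j)) * g[[bb]]
  }
  Dc <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                             dims = c(n, 2L * n))
  list(Cv = Cv, Dc = Dc)
}
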