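#' Triangulated unit-disc mesh
#'
#' Builds a triangulation of the unit disc from concentric rings of nodes.
#' Ring `k` (radius `k/K`, `K = round(1/spacing)`) carries `6k` equally
#' spaced nodes, so the radial and circumferential node spacings both match
#' the requested target and the triangles are near-equilateral. Successive
#' rings are stitched by an angular advancing-front sweep, which also covers
#' the centre fan. All triangles are oriented counter-clockwise.
#'
#' The mesh is the spatial discretisation used by [simulate_monolayer()]: nodes are
#' P1 (piecewise-linear) degrees of freedom, `node_areas` are the lumped
#' (one-third-of-incident-triangle) areas that serve as the quadrature
#' weights `dA` in area-weighted statistics such as [compute_prestress()].
#'
#' @param spacing target edge length, nondimensional (unit-disc frame).
#'   Must lie in (0, 1].
#' @return an object of class `disc_mesh`: list with `nodes` (n x 2),
#'   `triangles` (m x 3 integer, 1-based, CCW), `node_areas` (length n),
#'   `spacing`, `boundary_mask` (logical length n).
#' @examples
#' m <- disc_mesh(0.2)
#' sum(triangle_areas(m))   # close to pi
#' @export
disc_mesh <- function(spacing) {
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0 || spacing > 1)
    stop("`spacing` must be a single number in (0, 1]", call. = FALSE)
  K <- max(1L, as.integer(round(1 / spacing)))

  ring_n <- c(1L, 6L * seq_len(K))
  nodes <- matrix(0, nrow = 1L + 3L * K * (K + 1L), ncol = 2L)
  ring_start <- integer(K + 1L)  # first node index of each ring (ring 0 = centre)
  idx <- 1L
  ring_start[1L] <- 1L
  for (k in seq_len(K)) {
    n_k <- 6L * k
    ring_start[k + 1L] <- idx + 1L
    ang <- 2 * pi * (seq_len(n_k) - 1L) / n_k
    nodes[idx + seq_len(n_k), ] <- cbind((k / K) * cos(ang), (k / K) * sin(ang))
    idx <- idx + n_k
  }

  tris <- vector("list", K)
  for (k in seq_len(K)) {
    inner <- if (k == 1L) 1L else ring_start[k] - 1L + seq_len(ring_n[k])
    outer <- ring_start[k + 1L] - 1L + seq_len(ring_n[k + 1L])
    tris[[k]] <- stitch_rings(nodes, inner, outer)
  }
  triangles <- do.call(rbind, tris)

  # enforce CCW orientation
  a <- signed_areas(nodes, triangles)
  flip <- a < 0
  if (any(flip)) triangles[flip, c(2L, 3L)] <- triangles[flip, c(3L, 2L)]

  areas <- abs(a)
  node_areas <- numeric(nrow(nodes))
  for (j in 1:3) {
    acc <- rowsum(areas / 3, triangles[, j])
    node_areas[as.integer(rownames(acc))] <- node_areas[as.integer(rownames(acc))] + acc[, 1L]
  }

  boundary <- logical(nrow(nodes))
  boundary[ring_start[K + 1L] - 1L + seq_len(ring_n[K + 1L])] <- TRUE

  structure(list(nodes = nodes, triangles = triangles, node_areas = node_areas,
                 spacing = 1 / K, boundary_mask = boundary),
            class = "disc_mesh")
}

# Triangulate the annulus (or centre fan) between two node rings by merging
# the two angular sequences; emits length(inner)+length(outer) triangles
# (or length(outer) for the fan).
stitch_rings <- function(nodes, inner, outer) {
  n_out <- length(outer)
  if (length(inner) == 1L) {
    j2 <- c(seq_len(n_out)[-1L], 1L)
    return(cbind(inner, outer, outer[j2], deparse.level = 0))
  }
  n_in <- length(inner)
  ang_in <- atan2(nodes[inner, 2], nodes[inner, 1]) %% (2 * pi)
  ang_out <- atan2(nodes[outer, 2], nodes[outer, 1]) %% (2 * pi)
  # unwrapped "next" angles as the two pointers advance one full revolution
  tri <- matrix(0L, nrow = n_in + n_out, ncol = 3L)
  i <- 1L; j <- 1L; ti <- 0L
  adv_i <- 0L; adv_j <- 0L
  next_ang <- function(a, pos, adv) a[(pos %% length(a)) + 1L] + 2 * pi * ((pos + adv * 0) %/% length(a))
  # cumulative angles: angle of pointer after s advances
  cum_in <- c(ang_in, ang_in + 2 * pi)
  cum_out <- c(ang_out, ang_out + 2 * pi)
  while (adv_i < n_in || adv_j < n_out) {
    ni <- cum_in[i + 1L]; no <- cum_out[j + 1L]
    if (adv_j >= n_out || (adv_i < n_in && ni <= no)) {
      tri[ti <- ti + 1L, ] <- c(inner[(i - 1L) %% n_in + 1L],
                                inner[i %% n_in + 1L],
                                outer[(j - 1L) %% n_out + 1L])
      i <- i + 1L; adv_i <- adv_i + 1L
    } else {
      tri[ti <- ti + 1L, ] <- c(inner[(i - 1L) %% n_in + 1L],
                                outer[(j - 1L) %% n_out + 1L],
                                outer[j %% n_out + 1L])
      j <- j + 1L; adv_j <- adv_j + 1L
    }
  }
  tri[seq_len(ti), , drop = FALSE]
}

signed_areas <- function(nodes, triangles) {
  p1 <- nodes[triangles[, 1L], , drop = FALSE]
  p2 <- nodes[triangles[, 2L], , drop = FALSE]
  p3 <- nodes[triangles[, 3L], , drop = FALSE]
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

#' Triangle areas of a mesh
#' @param mesh a `disc_mesh` (or any list with `nodes`, `triangles`)
#' @return numeric vector of (positive) triangle areas
#' @export
triangle_areas <- function(mesh) abs(signed_areas(mesh$nodes, mesh$triangles))

#' Area-weighted mean concentration (prestress)
#'
#' The prestress of an initial actinomyosin field is its area-weighted mean
#' relative to the equilibrium concentration:
#' `c0 = sum(c_i * dA_i) / (c_eq * A)` with `dA_i` the lumped node areas and
#' `A` their total. For the uniform field `c = c_eq` this is exactly 1.
#'
#' @param mesh a `disc_mesh`
#' @param c per-node concentration (units of `c_eq`)
#' @param c_eq equilibrium concentration the field is normalised by
#' @return scalar prestress `c0`
#' @export
compute_prestress <- function(mesh, c, c_eq = 1) {
  if (length(c) != nrow(mesh$nodes))
    stop("concentration length does not match mesh node count", call. = FALSE)
  sum(c * mesh$node_areas) / (c_eq * sum(mesh$node_areas))
}

#' Write / read a mesh in Gmsh MSH v2 ASCII format
#'
#' Minimal MSH 2.2 exchange: nodes (z = 0) and 2-node/3-node elements;
#' only triangles (element type 2) are read back.
#'
#' @param mesh a `disc_mesh`
#' @param path file path
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes", n), con)
  writeLines(sprintf("%d %.17g %.17g 0", seq_len(n), mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(c("$EndNodes", "$Elements", m), con)
  writeLines(sprintf("%d 2 2 0 0 %d %d %d", seq_len(m),
                     mesh$triangles[, 1], mesh$triangles[, 2], mesh$triangles[, 3]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' @rdname write_msh
#' @return `read_msh` returns a `disc_mesh` (spacing estimated from the
#'   median edge length; boundary nodes detected as lying on edges that
#'   belong to a single triangle).
#' @export
read_msh <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  ni <- match("$Nodes", lines)
  n <- as.integer(lines[ni + 1L])
  node_rows <- do.call(rbind, strsplit(lines[ni + 1L + seq_len(n)], " "))
  nodes <- cbind(as.numeric(node_rows[, 2]), as.numeric(node_rows[, 3]))
  ei <- match("$Elements", lines)
  m <- as.integer(lines[ei + 1L])
  el_rows <- strsplit(lines[ei + 1L + seq_len(m)], " ")
  tri <- do.call(rbind, lapply(el_rows, function(r) {
    r <- as.integer(r)
    if (r[2] != 2L) return(NULL)
    ntags <- r[3]
    r[(4L + ntags):(6L + ntags)]
  }))
  mesh_from_triangulation(nodes, tri)
}

# Assemble a disc_mesh-like object from raw nodes + triangles.
mesh_from_triangulation <- function(nodes, triangles) {
  a <- signed_areas(nodes, triangles)
  flip <- a < 0
  if (any(flip)) triangles[flip, c(2L, 3L)] <- triangles[flip, c(3L, 2L)]
  areas <- abs(a)
  node_areas <- numeric(nrow(nodes))
  for (j in 1:3) {
    acc <- rowsum(areas / 3, triangles[, j])
    node_areas[as.integer(rownames(acc))] <- node_areas[as.integer(rownames(acc))] + acc[, 1L]
  }
  edges <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  once <- names(which(table(key) == 1L))
  bnodes <- unique(as.integer(unlist(strsplit(once, " "))))
  boundary <- logical(nrow(nodes)); boundary[bnodes] <- TRUE
  e1 <- nodes[edges[, 1], , drop = FALSE] - nodes[edges[, 2], , drop = FALSE]
  structure(list(nodes = nodes, triangles = triangles, node_areas = node_areas,
                 spacing = stats::median(sqrt(rowSums(e1^2))), boundary_mask = boundary),
            class = "disc_mesh")
}

#' @exportS3Method base::print
print.disc_mesh <- function(x, ...) {
  cat(sprintf("disc_mesh: %d nodes, %d triangles, spacing %.4g, area %.6g\n",
              nrow(x$nodes), nrow(x$triangles), x$spacing, sum(triangle_areas(x))))
  invisible(x)
}
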