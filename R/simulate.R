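#' Solve the active-gel monolayer model on a disc
#'
#' Integrates the coupled force-balance / actinomyosin-transport system in
#' nondimensional form (see [nondim_groups()]) with P1 finite elements,
#' backward-Euler time stepping and Newton iteration on the coupled
#' residual. Boundary conditions: clamped displacement `u = 0` on the unit
#' circle and, for the concentration, either the anchored condition
#' `c = c_eq` (default) or natural no-flux `grad(c) . n = 0`. The anchored
#' condition pins the actinomyosin pool to its equilibrium level at the
#' confinement edge; it selects the centred (axisymmetric) collapse mode
#' observed in serum-activated discs, whereas no-flux lets an off-centre
#' dipolar mode lead (see the methods vignette).
#'
#' The time step grows geometrically from `stepper$dt0` by `stepper$growth`
#' per step until `stepper$dt_max`, then stays constant until `t_end`.
#' The Jacobian (constant blocks plus convection blocks at a reference
#' state) is factorised once and reused across steps and Newton
#' iterations; it is refreshed at the current state whenever the
#' iteration needs more than a few steps to contract.
#'
#' @param mesh a [disc_mesh()]
#' @param params a [model_params()]
#' @param c_init per-node initial concentration (units of `c_eq`), e.g.
#'   from [seed_concentration()]
#' @param stepper a [stepper_spec()]
#' @param output_times nondimensional times at which snapshots are stored
#'   (linearly interpolated between accepted steps); defaults to a uniform
#'   grid of spacing 0.02 over the run
#' @param seeding optional [seeding_spec()] recorded as provenance
#' @param c_boundary `"fixed"` (anchored, `c = c_eq` on the rim) or
#'   `"noflux"`
#' @return object of class `gel_trajectory`: `times` (nondimensional),
#'   `u` (n x 2 x n_frames, nondimensional displacement), `c`
#'   (n x n_frames), plus `mesh`, `params`, `stepper`, `groups`
#'   (nondimensional coefficients and reporting scales), `c0` (realized
#'   prestress of `c_init`) and `n_steps`.
#' @export
simulate_monolayer <- function(mesh, params, c_init, stepper = stepper_spec(),
                               output_times = NULL, seeding = NULL,
                               c_boundary = c("fixed", "noflux"),
                               u_init = NULL) {
  c_boundary <- match.arg(c_boundary)
  n <- nrow(mesh$nodes)
  if (length(c_init) != n)
    stop("`c_init` length does not match mesh node count", call. = FALSE)
  if (is.null(u_init)) u_init <- numeric(2L * n)
  if (is.matrix(u_init)) u_init <- c(u_init[, 1L], u_init[, 2L])
  if (length(u_init) != 2L * n)
    stop("`u_init` must be an n x 2 matrix or length-2n vector", call. = FALSE)
  if (is.null(output_times))
    output_times <- seq(0, stepper$t_end, by = 0.02)
  output_times <- sort(unique(output_times))
  if (any(output_times < 0 | output_times > stepper$t_end))
    stop("`output_times` must lie within [0, t_end]", call. = FALSE)

  g <- nondim_groups(params)
  ops <- fem_operators(mesh)
  free_nodes <- which(!mesh$boundary_mask)
  free <- c(free_nodes, n + free_nodes)
  cfree <- if (c_boundary == "fixed") free_nodes else seq_len(n)

  Mv <- Matrix::bdiag(ops$Mc, ops$Mc)
  K_ff <- ops$K[free, free]
  Mv_ff <- Mv[free, free]
  G_f <- ops$G[free, cfree, drop = FALSE]
  B_f <- ops$Bdiv[cfree, free, drop = FALSE]
  Mc_cc <- ops$Mc[cfree, cfree]
  reac <- ops$Mc / g$tauc_hat + g$D_hat * ops$Kc
  reac_cc <- reac[cfree, cfree]
  ndof <- length(free) + length(cfree)

  make_jac <- function(dt, v_ref = NULL, c_ref = NULL) {
    Juu <- Mv_ff / dt + K_ff * (1 + g$eta_hat / dt)
    Jcc <- Mc_cc / dt + reac_cc
    Jcu <- -g$beta_hat * B_f
    if (!is.null(v_ref)) {
      cj <- convection_jacobian(ops, v_ref[seq_len(n)], v_ref[n + seq_len(n)],
                                c_ref, dt)
      Jcc <- Jcc + cj$Cv[cfree, cfree]
      Jcu <- Jcu + cj$Dc[cfree, free, drop = FALSE]
    }
    rbind(cbind(Juu, -g$alpha_hat * G_f),
          cbind(Jcu, Jcc))
  }

  reaction_const <- as.numeric(ops$Mc %*% rep(params$c_eq, n)) / g$tauc_hat

  # Residual split into per-step constants and per-iteration matvecs:
  #   R_u = P1 u_new - P2 u_old - alpha G c_new
  #   R_c = Q1 c_new - (Mc c_old / dt + reaction_const) + conv - beta B u_new
  P1 <- NULL; P2 <- NULL; Q1 <- NULL; op_dt <- NA_real_
  update_ops_dt <- function(dt) {
    if (!is.na(op_dt) && abs(dt - op_dt) <= 1e-15 * dt) return(invisible())
    P1 <<- Mv / dt + ops$K * (1 + g$eta_hat / dt)
    P2 <<- Mv / dt + ops$K * (g$eta_hat / dt)
    Q1 <<- ops$Mc / dt + reac
    op_dt <<- dt
  }
  residual <- function(u_new, c_new, r_u0, r_c0, u_old, dt) {
    Ru <- as.numeric(P1 %*% u_new) - r_u0 -
      g$alpha_hat * as.numeric(ops$G %*% c_new)
    v <- (u_new - u_old) / dt
    conv <- convection_residual(ops, v[seq_len(n)], v[n + seq_len(n)], c_new)
    Rc <- as.numeric(Q1 %*% c_new) - r_c0 + conv -
      g$beta_hat * as.numeric(ops$Bdiv %*% u_new)
    c(Ru[free], Rc[cfree])
  }

  u <- as.numeric(u_init)
  u[c(which(mesh$boundary_mask), n + which(mesh$boundary_mask))] <- 0
  cc <- as.numeric(c_init)
  if (c_boundary == "fixed") cc[mesh$boundary_mask] <- params$c_eq
  t <- 0
  dt <- stepper$dt0
  jac_dt <- NA_real_
  lu <- NULL
  stale <- TRUE

  nf <- length(output_times)
  u_out <- array(0, dim = c(n, 2L, nf))
  c_out <- matrix(0, n, nf)
  out_ptr <- 1L
  store <- function(w, u_lo, c_lo, u_hi, c_hi, k) {
    ui <- u_lo + w * (u_hi - u_lo)
    u_out[, 1L, k] <<- ui[seq_len(n)]
    u_out[, 2L, k] <<- ui[n + seq_len(n)]
    c_out[, k] <<- c_lo + w * (c_hi - c_lo)
  }
  while (out_ptr <= nf && output_times[out_ptr] <= 0) {
    store(0, u, cc, u, cc, out_ptr)
    out_ptr <- out_ptr + 1L
  }

  v_prev <- numeric(2L * n)
  n_steps <- 0L
  while (t < stepper$t_end - 1e-14) {
    dt_step <- min(dt, stepper$t_end - t)
    if (stale || abs(dt_step - jac_dt) > 1e-15 * dt_step) {
      lu <- Matrix::lu(make_jac(dt_step, v_prev, cc))
      jac_dt <- dt_step
      stale <- FALSE
    }
    u_old <- u; c_old <- cc
    u_new <- u; c_new <- cc
    update_ops_dt(dt_step)
    r_u0 <- as.numeric(P2 %*% u_old)
    r_c0 <- as.numeric(ops$Mc %*% c_old) / dt_step + reaction_const
    R <- residual(u_new, c_new, r_u0, r_c0, u_old, dt_step)
    r0 <- sqrt(sum(R^2))
    target <- max(stepper$newton_tol * r0, 1e-13 * sqrt(ndof))
    it <- 0L
    refreshed <- FALSE
    repeat {
      rn <- sqrt(sum(R^2))
      if (!is.finite(rn))
        stop(sprintf("non-finite residual at t = %.6g", t), call. = FALSE)
      if (rn <= target) break
      if (it >= stepper$newton_max_iter) {
        if (!refreshed) {
          # refresh linearisation at the current iterate and retry
          lu <- Matrix::lu(make_jac(dt_step, (u_new - u_old) / dt_step, c_new))
          jac_dt <- dt_step
          refreshed <- TRUE
          it <- 0L
        } else {
          stop(sprintf("Newton iteration failed at t = %.6g (residual %.3e)",
                       t, rn), call. = FALSE)
        }
      }
      delta <- as.numeric(Matrix::solve(lu, -R))
      u_new[free] <- u_new[free] + delta[seq_along(free)]
      c_new[cfree] <- c_new[cfree] + delta[length(free) + seq_along(cfree)]
      R <- residual(u_new, c_new, r_u0, r_c0, u_old, dt_step)
      it <- it + 1L
    }
    if (it > 6L) stale <- TRUE   # convergence slowing: relinearise next step
    v_prev <- (u_new - u_old) / dt_step
    u <- u_new; cc <- c_new
    if (!all(is.finite(u)) || !all(is.finite(cc)))
      stop(sprintf("non-finite field values at t = %.6g", t), call. = FALSE)
    t_new <- t + dt_step
    while (out_ptr <= nf && output_times[out_ptr] <= t_new + 1e-14) {
      w <- (output_times[out_ptr] - t) / dt_step
      store(w, u_old, c_old, u, cc, out_ptr)
      out_ptr <- out_ptr + 1L
    }
    t <- t_new
    n_steps <- n_steps + 1L
    dt <- min(dt * stepper$growth, stepper$dt_max)
  }

  structure(list(times = output_times, u = u_out, c = c_out,
                 mesh = mesh, params = params, stepper = stepper,
                 seeding = seeding, groups = g, c_boundary = c_boundary,
                 c0 = compute_prestress(mesh, c_init, params$c_eq),
                 n_steps = n_steps),
            class = "gel_trajectory")
}

#' @exportS3Method base::print
print.gel_trajectory <- function(x, ...) {
  cat(sprintf("gel_trajectory: %d frames to t = %.3g (%d steps), %d nodes, c0 = %.4f\n",
              length(x$times), max(x$times), x$n_steps, nrow(x$mesh$nodes), x$c0))
  invisible(x)
}

#' Per-snapshot traction vectors (Pa)
#'
#' Tractions follow the substrate friction law `T = Gamma * du/dt`. The
#' velocity at frame `k` is the forward finite difference of the stored
#' displacement snapshots (backward at the final frame), redimensionalized
#' by the velocity scale `R / tau_L`.
#'
#' @param traj a [simulate_monolayer()] trajectory
#' @return n_nodes x 2 x n_frames array of tractions in Pa
#' @export
traction_frames <- function(traj) {
  nf <- length(traj$times)
  if (nf < 2L) stop("need at least 2 snapshots", call. = FALSE)
  scale <- traj$groups$traction_scale_Pa
  out <- array(0, dim = dim(traj$u))
  for (k in seq_len(nf)) {
    k2 <- if (k < nf) k + 1L else k
    k1 <- if (k < nf) k else k - 1L
    dt <- traj$times[k2] - traj$times[k1]
    out[, , k] <- scale * (traj$u[, , k2] - traj$u[, , k1]) / dt
  }
  out
}

#' Mean traction magnitude over time
#'
#' Area-weighted spatial mean of `|T|` per snapshot, in Pa. This is the
#' simulated counterpart of a traction-magnitude time course measured by
#' traction force microscopy.
#'
#' @param traj a [simulate_monolayer()] trajectory
#' @return data.frame with `time` (nondimensional), `time_h` (hours) and
#'   `mean_traction_Pa`
#' @export
traction_series <- function(traj) {
  Tfr <- traction_frames(traj)
  w <- traj$mesh$node_areas / sum(traj$mesh$node_areas)
  mt <- vapply(seq_len(length(traj$times)), function(k)
    sum(w * sqrt(Tfr[, 1L, k]^2 + Tfr[, 2L, k]^2)), numeric(1))
  data.frame(time = traj$times,
             time_h = traj$times * traj$groups$tau_L / 3600,
             mean_traction_Pa = mt)
}
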