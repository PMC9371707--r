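# The quiescence-exit simulation protocol: dormant prestressed state
# construction and the canonical run wrapper used by sweeps and tests.

#' Rim-compatible dormancy envelope
#'
#' During serum depletion the excess actinomyosin accumulates under
#' diffusion and turnover while the pool at the confinement rim stays at
#' its equilibrium level. The stationary profile of a uniformly produced,
#' diffusing, relaxing species on the unit disc with `c = c_eq` at the rim
#' is `g(r) = 1 - I0(kappa r) / I0(kappa)` with
#' `kappa = 1 / sqrt(D_hat * tauc_hat)`. The returned envelope is
#' normalised to unit area-weighted mean so that multiplying a seeded
#' excess field by it leaves the realized prestress `c0` unchanged.
#'
#' @param mesh a [disc_mesh()]
#' @param params a [model_params()]
#' @return per-node envelope weights (unit area-weighted mean)
#' @export
rim_envelope <- function(mesh, params) {
  g <- nondim_groups(params)
  kappa <- 1 / sqrt(g$D_hat * g$tauc_hat)
  r <- sqrt(rowSums(mesh$nodes^2))
  env <- 1 - besselI(kappa * r, 0) / besselI(kappa, 0)
  w <- mesh$node_areas / sum(mesh$node_areas)
  env / sum(w * env)
}

#' Dormant (prestressed) initial concentration field
#'
#' Seeds the random excess via [seed_concentration()] and modulates it by
#' the [rim_envelope()], so that the accumulated prestress is compatible
#' with the anchored rim. The boundary ring itself is held at `c_eq`.
#'
#' @param mesh a [disc_mesh()]
#' @param spec a [seeding_spec()]
#' @param params a [model_params()]
#' @param envelope modulate the excess by the smooth [rim_envelope()]
#'   (`FALSE` keeps the seeded white-noise structure and only holds the
#'   boundary ring at `c_eq`)
#' @return per-node concentration (units of `c_eq`)
#' @export
dormant_concentration <- function(mesh, spec, params, envelope = FALSE) {
  ci <- seed_concentration(mesh, spec, params$c_eq)
  if (envelope) {
    env <- rim_envelope(mesh, params)
    ci <- params$c_eq + (ci - params$c_eq) * env
  }
  ci[mesh$boundary_mask] <- params$c_eq
  ci
}

#' Elastic equilibrium displacement under a concentration field
#'
#' The dormant monolayer is static: its elastic stress balances the
#' active stress, `div(eps(u)) + alpha_hat grad(c) = 0` with `u = 0` on
#' the rim. This prestrain is the standing (weak) traction pattern of the
#' quiescent sheet and is the mechanical starting state of a
#' quiescence-exit run.
#'
#' @param mesh a [disc_mesh()]
#' @param params a [model_params()]
#' @param c_field per-node concentration
#' @return n x 2 matrix of nodal displacements
#' @export
prestrain_equilibrium <- function(mesh, params, c_field) {
  ops <- fem_operators(mesh)
  n <- nrow(mesh$nodes)
  free_nodes <- which(!mesh$boundary_mask)
  free <- c(free_nodes, n + free_nodes)
  rhs <- params$alpha_hat * as.numeric(ops$G %*% c_field)
  u <- numeric(2L * n)
  u[free] <- as.numeric(Matrix::solve(ops$K[free, free], rhs[free]))
  cbind(u[seq_len(n)], u[n + seq_len(n)])
}

#' Run the canonical quiescence-exit protocol
#'
#' Builds the dormant concentration field (seeded, rim-compatible) and
#' integrates the active-gel model from the undeformed state `u = 0`:
#' serum exposure switches contractility on against the accumulated
#' prestress, producing the traction burst and the inward collective
#' response that the sweeps quantify.
#'
#' @param mesh a [disc_mesh()]
#' @param params a [model_params()]
#' @param seeding a [seeding_spec()]
#' @param stepper a [stepper_spec()]
#' @param output_times passed to [simulate_monolayer()]
#' @param prestrained start from the standing elastic equilibrium
#'   ([prestrain_equilibrium()]) instead of the undeformed state
#' @return a `gel_trajectory` (see [simulate_monolayer()])
#' @export
quiescence_run <- function(mesh, params, seeding, stepper = stepper_spec(),
                           output_times = NULL, prestrained = FALSE) {
  ci <- dormant_concentration(mesh, seeding, params)
  u0 <- if (prestrained) prestrain_equilibrium(mesh, params, ci) else NULL
  simulate_monolayer(mesh, params, ci, stepper, output_times,
                     seeding = seeding, c_boundary = "fixed", u_init = u0)
}
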