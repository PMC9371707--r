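#' Physical parameters of the active-gel monolayer model
#'
#' The monolayer is a thin linearly elastic active gel on a frictional
#' substrate. Displacement `u(x,t)` obeys the force balance
#' \deqn{\Gamma \partial_t u = h_{eq} E \nabla\cdot\epsilon
#'       + h_{eq} \eta \partial_t \nabla\cdot\epsilon
#'       + h_{eq} \alpha \nabla c}
#' and the actinomyosin concentration `c(x,t)` a
#' convection--diffusion--reaction equation
#' \deqn{\partial_t c + \partial_t u\cdot\nabla c =
#'       -(c - c_{eq})/\tau_c + \beta \nabla\cdot u + D \nabla^2 c.}
#' The traction transmitted to the substrate is the friction law
#' `T = Gamma * du/dt`.
#'
#' Defaults are the reference parameter set used throughout the package's
#' simulation studies: a 4 kPa, 8 um keratinocyte sheet on a 7 mm diameter
#' well.
#'
#' @param E monolayer Young's modulus, Pa
#' @param h_eq equilibrium monolayer thickness, m
#' @param Gamma cell--substrate friction coefficient, N s m^-3
#' @param D actinomyosin diffusivity, m^2 s^-1
#' @param beta_over_ceq magnitude of the strain-coupling rate beta/c_eq,
#'   s^-1. Note `beta_over_ceq * tau_c ~ 1`: the concentration relaxes
#'   toward a strain-shifted target `c_eq (1 -/+ div u)`.
#' @param strain_activation sign convention of the strain coupling:
#'   `"compression"` (default) lets compression concentrate actinomyosin,
#'   the mass-conservation-consistent choice that produces amplification
#'   of contractile centres; `"stretching"` is the opposite convention
#'   (purely stabilising). See the methods vignette.
#' @param tau_c relaxation time of c toward c_eq, s
#' @param eta sheet viscosity, Pa s (0 disables the viscous term)
#' @param alpha_hat nondimensional contractile strength `alpha * c_eq / E`.
#'   The default is the package's calibrated onset value: the smallest
#'   contractility for which a prefactor-1.0 seeding develops sustained
#'   inward collective migration (see the methods vignette).
#' @param c_eq equilibrium concentration (normalised scale; keep at 1)
#' @param R physical disc radius, m (7.0 mm diameter well)
#' @return object of class `model_params`
#' @export
model_params <- function(E = 4000, h_eq = 8e-6, Gamma = 2.5e8, D = 1e-9,
                         beta_over_ceq = 8e-5, tau_c = 13000, eta = 0,
                         alpha_hat = default_alpha_hat(), c_eq = 1,
                         R = 3.5e-3,
                         strain_activation = c("compression", "stretching")) {
  strain_activation <- match.arg(strain_activation)
  for (nm in c("E", "h_eq", "Gamma", "D", "tau_c", "R")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number", nm), call. = FALSE)
  }
  for (nm in c("eta", "alpha_hat", "beta_over_ceq")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("`%s` must be a single non-negative number", nm), call. = FALSE)
  }
  p <- list(E = E, h_eq = h_eq, Gamma = Gamma, D = D,
            beta_over_ceq = beta_over_ceq, tau_c = tau_c, eta = eta,
            alpha_hat = alpha_hat, c_eq = c_eq, R = R,
            strain_activation = strain_activation)
  class(p) <- "model_params"
  p
}

#' Calibrated default contractile strength
#'
#' The centred-collapse mode of the coupled system loses stability near
#' `alpha_hat ~ 18-20` on the reference meshes (located by stepwise
#' bisection on prefactor-1.0 runs; the exact onset shifts slightly with
#' mesh and seeding detail). Beyond that onset the collapse runs away
#' faster than the fixed-cap adaptive time stepper resolves. The default
#' contractility is set ~25% below the onset — the strongest contraction
#' whose transient amplification the standard stepper integrates
#' robustly. See `analysis/02_calibrate_alpha.R` and the methods
#' vignette.
#' @return scalar nondimensional contractility
#' @export
default_alpha_hat <- function() 14

#' Nondimensional groups of a parameter set
#'
#' Length scale `R`, time scale `tau_L = Gamma R^2 / (h_eq E)` (the
#' substrate-friction/elastic relaxation time of the whole disc),
#' concentration scale `c_eq`. In these units the model reads
#' `du/dt = div(eps) + eta_hat d/dt div(eps) + alpha_hat grad(c)` and
#' `dc/dt + du/dt . grad(c) = -(c-1)/tauc_hat + beta_hat div(u) + D_hat lap(c)`.
#'
#' @param params a [model_params()]
#' @return list with `tau_L` (s), `vel_scale_um_h` (um/h per nondimensional
#'   velocity unit), `traction_scale_Pa` (Pa per unit), and the
#'   nondimensional coefficients `alpha_hat`, `eta_hat`, `tauc_hat`,
#'   `beta_hat`, `D_hat`.
#' @export
nondim_groups <- function(params) {
  tau_L <- params$Gamma * params$R^2 / (params$h_eq * params$E)
  vel <- params$R / tau_L                     # m/s
  list(tau_L = tau_L,
       vel_scale_um_h = vel * 3.6e9,
       traction_scale_Pa = params$Gamma * vel,
       alpha_hat = params$alpha_hat,
       eta_hat = params$eta / (params$E * tau_L),
       tauc_hat = params$tau_c / tau_L,
       beta_hat = (if (identical(params$strain_activation, "stretching")) 1 else -1) *
         params$beta_over_ceq * tau_L,
       D_hat = params$D * tau_L / params$R^2)
}

#' Adaptive time-stepper settings
#'
#' Backward-Euler stepping with a geometrically growing step:
#' `dt_{k+1} = min(growth * dt_k, dt_max)`, starting from `dt0`, run to
#' nondimensional time `t_end`. Each step solves the coupled nonlinear
#' system by Newton iteration to relative residual `newton_tol`.
#'
#' @param dt0 initial nondimensional step
#' @param growth per-step multiplier
#' @param dt_max cap on the step
#' @param t_end final nondimensional time
#' @param newton_tol relative residual tolerance of the Newton solve
#' @param newton_max_iter iteration cap before the solver errors out
#' @return object of class `stepper_spec`
#' @export
stepper_spec <- function(dt0 = 5e-5, growth = 1.05, dt_max = 1e-3,
                         t_end = 3, newton_tol = 1e-8, newton_max_iter = 25L) {
  stopifnot(dt0 > 0, growth >= 1, dt_max >= dt0, t_end > 0,
            newton_tol > 0, newton_max_iter >= 1)
  structure(list(dt0 = dt0, growth = growth, dt_max = dt_max, t_end = t_end,
                 newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter)),
            class = "stepper_spec")
}

#' Random initial-concentration seeding specification
#'
#' Each mesh node independently has probability `probability` of being
#' seeded with a random value in \[0, 1\]; the whole random field is then
#' scaled by `prefactor` and added to the equilibrium concentration:
#' `c(x, 0) = c_eq * (1 + prefactor * s(x))`.
#'
#' The value distribution is a Gaussian truncated to \[0, 1\]. Its default
#' location 1/3 and scale 1/6 calibrate the realized prestress to
#' `c0 ~= 1 + 0.206 * prefactor` (so prefactor 0.01 gives c0 ~= 1.002 and
#' prefactor 1.0 gives c0 ~= 1.2; see the methods vignette).
#'
#' @param probability per-node seeding chance
#' @param prefactor multiplier applied to the seeded values
#' @param rng_seed integer RNG seed; identical seeds give bit-identical
#'   fields
#' @param value_mean,value_sd location and scale of the truncated Gaussian
#' @return object of class `seeding_spec`
#' @export
seeding_spec <- function(probability = 0.6, prefactor = 1,
                         rng_seed = 1L, value_mean = 1/3, value_sd = 1/6) {
  if (!is.numeric(probability) || probability < 0 || probability > 1)
    stop("`probability` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(prefactor) || prefactor < 0)
    stop("`prefactor` must be >= 0", call. = FALSE)
  structure(list(probability = probability, prefactor = prefactor,
                 rng_seed = as.integer(rng_seed),
                 value_mean = value_mean, value_sd = value_sd),
            class = "seeding_spec")
}

#' Seed an initial actinomyosin concentration field
#'
#' @param mesh a [disc_mesh()]
#' @param spec a [seeding_spec()]
#' @param c_eq equilibrium concentration
#' @return per-node concentration vector `c(x, 0)`
#' @export
seed_concentration <- function(mesh, spec, c_eq = 1) {
  n <- nrow(mesh$nodes)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$rng_seed)
  seeded <- stats::runif(n) < spec$probability
  s <- numeric(n)
  s[seeded] <- rtruncnorm01(sum(seeded), spec$value_mean, spec$value_sd)
  c_eq * (1 + spec$prefactor * s)
}

# Gaussian truncated to [0,1] by rejection; deterministic under set.seed.
rtruncnorm01 <- function(n, mean, sd) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x >= 0 & x <= 1
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}
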