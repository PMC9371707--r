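# Demonstration run configuration for the quiescence-exit protocol.
# Units are fixed: SI internally, reporting in um/h and mN/m.

model.E             = 4000      # monolayer Young's modulus, Pa
model.h_eq          = 8e-6      # equilibrium thickness, m
model.Gamma         = 2.5e8     # substrate friction, N s m^-3
model.D             = 1e-9      # actinomyosin diffusivity, m^2 s^-1
model.beta_over_ceq = 8e-5      # strain-coupling magnitude, s^-1
model.tau_c         = 13000     # relaxation time, s
model.eta           = 0         # sheet viscosity, Pa s
model.alpha_hat     = 14        # nondimensional contractility
model.c_eq          = 1         # equilibrium concentration (normalised)
model.R             = 3.5e-3    # disc radius, m
model.strain_activation = compression  # compression | stretching

stepper.dt0             = 5e-5  # initial nondimensional step
stepper.growth          = 1.05  # per-step multiplier
stepper.dt_max          = 1e-3  # step cap
stepper.t_end           = 3     # final nondimensional time
stepper.newton_tol      = 1e-8  # relative residual tolerance
stepper.newton_max_iter = 25

seeding.probability = 0.6       # per-node seeding chance
seeding.prefactor   = 1.0       # excess multiplier
seeding.rng_seed    = 42
seeding.value_mean  = 0.3333333 # truncated-normal location on [0,1]
seeding.value_sd    = 0.1666667 # truncated-normal scale

mesh.spacing = 0.1              # nondimensional target edge length

substrate.youngs_modulus = 4000 # Pa (TFM gel)
substrate.poisson_ratio  = 0.49

imaging.pixel_size         = 1  # um per pixel
imaging.frame_interval_min = 16 # minutes
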