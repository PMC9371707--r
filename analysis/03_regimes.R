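#!/usr/bin/env Rscript
# Regime comparison. Three quiescence-exit runs on the coarse mesh:
#   (a) low prestress (prefactor 0.01): local contractions only, no
#       collective displacement;
#   (b) reference prestress (prefactor 1.0): traction burst followed by
#       inward collective response;
#   (c) reference prestress with contractility reduced 10x: traction
#       activation abrogated.
#
# Outputs: results/regime_radial_velocity.csv, results/regime_traction.csv

library(activegel)

dir.create("results", showWarnings = FALSE)

mesh <- disc_mesh(0.1)
stepper <- stepper_spec()
# standard output grid (the windowing statistics are defined on it)
out_t <- seq(0, 3, 0.02)

run <- function(pf, alpha = default_alpha_hat()) {
  quiescence_run(mesh, model_params(alpha_hat = alpha),
                 seeding_spec(prefactor = pf, rng_seed = 42),
                 stepper, output_times = out_t)
}

cases <- list(low_prestress = run(0.01),
              reference = run(1),
              reduced_alpha = run(1, alpha = default_alpha_hat() / 10))

vel <- do.call(rbind, lapply(names(cases), function(nm) {
  rs <- radial_velocity_series(cases[[nm]])
  rs$case <- nm
  rs
}))
trc <- do.call(rbind, lapply(names(cases), function(nm) {
  ts <- traction_series(cases[[nm]])
  ts$case <- nm
  ts
}))

v_of <- function(nm) tryCatch(
  averaged_radial_velocity(radial_velocity_series(cases[[nm]])),
  activegel_window_error = function(e) 0)

message(sprintf("averaged radial velocity: low %.2f vs reference %.2f um/h (ratio %.3f)",
                v_of("low_prestress"), v_of("reference"),
                v_of("low_prestress") / v_of("reference")))
message(sprintf("peak mean traction: reference %.2f Pa, alpha/10 %.2f Pa (ratio %.3f)",
                max(trc$mean_traction_Pa[trc$case == "reference"]),
                max(trc$mean_traction_Pa[trc$case == "reduced_alpha"]),
                max(trc$mean_traction_Pa[trc$case == "reduced_alpha"]) /
                  max(trc$mean_traction_Pa[trc$case == "reference"])))

write.csv(vel, "results/regime_radial_velocity.csv", row.names = FALSE)
write.csv(trc, "results/regime_traction.csv", row.names = FALSE)
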