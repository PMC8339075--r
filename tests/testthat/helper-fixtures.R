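# Shared fixtures: the canonical freezing scenario (liver-like properties,
# probe at -54 degC, onset -23 degC, body 37 degC) and small record builders.

default_props <- liver_tissue_properties()
default_bc <- boundary_conditions(T_surface = -54, T_onset = -23, T_body = 37)
default_sol <- solve_front_constant(default_props, default_bc)

# records lying exactly on given laws
make_records <- function(water, rate, onset, latent) {
  data.frame(sample_id = seq_along(water), liver_id = "liver_1",
             water_fraction = water, cooling_rate = rate,
             T_onset = onset, latent_heat = latent)
}

# noise-free scenario used by several DSC op tests
quiet_scenario <- function(...) {
  run_scenario(noise_sd = 0, recalescence_K = 0, L_true = 0, seed = 1, ...)
}
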