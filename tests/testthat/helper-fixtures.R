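# Shared fixtures: pore-class tables for the two crop-rotation treatments,
# scenario parameter sets, and the compaction-recovery setup.  All synthetic
# data are generated in code from these known parameters.

# Pore classes (cm^3/cm^3) for the ley-dominated (A) and arable (D)
# rotations; textural split is site-level (phi_t = 0.3, f_t_mic = 0.295/0.3).
treatment_pools <- function() {
  data.frame(
    label = c("A", "D"),
    phi_t_mic = 0.295, phi_t_mes = 0.005, phi_t = 0.3,
    phi_s_mic = c(0.120, 0.118), phi_s_mes = c(0.168, 0.147),
    phi_s = c(0.288, 0.265),
    phi_mic = c(0.415, 0.413), phi_mes = c(0.173, 0.152),
    phi_mat = c(0.588, 0.565))
}

# Scenario parameters for the recovery-from-compaction simulations:
# silty soil, annual crop, high/low root production and bioturbation.
scenario_params <- function(R_g = 0.0012, tau_s = 0.12) {
  list(roots = root_params(B_r = R_g, tau_r = 1, gamma_r = 1.2, f_r_c = 0.2),
       worms = worm_params(tau_s = tau_s, eps_casts = 0.6,
                           f_casts_mic = 0.8),
       phi = 0.4, phi_min = 0.3, f_t_mic = 0.8, gamma_s = 2.7)
}

scenario_initial <- function(layer_thickness = 25) {
  state_from_porosities(phi_mic = 0.32, phi_mes = 0.08, phi_mac = 0,
                        phi_min = 0.3, f_t_mic = 0.8,
                        layer_thickness = layer_thickness)
}

# Bare-soil compaction-recovery setup: fixed quantities, a compacted
# initial state and the generating bioturbation parameters used as ground
# truth in recovery experiments.
recovery_fixture <- function() {
  fixed <- list(gamma_s = 2.56, E_bio = areal_to_volumetric(655, 30),
                phi_min = 0.35, f_t_mic = 0.966, layer_thickness = 30)
  initial <- state_from_porosities(phi_mic = 0.36, phi_mes = 0.012,
                                   phi_mac = 0.01, phi_min = 0.35,
                                   f_t_mic = 0.966, layer_thickness = 30)
  truth <- list(I_r = 2.79, eps_casts = 0.714, f_casts_mic = 0.845,
                phi_mac_c = 0.057)
  list(fixed = fixed, initial = initial, truth = truth)
}
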