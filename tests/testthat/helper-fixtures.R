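# Shared fixtures: built in code, no stored data.

water_phase <- function() {
  phase_spec("water", molar_mass = 18.02, viscosity = 0.89, density = 998,
             association_factor = 2.6)
}

heptane_phase <- function() {
  phase_spec("n-heptane", molar_mass = 100.2, viscosity = 0.39, density = 684,
             vapour_pressure = 48, toxicity_class = 3, association_factor = 1.0)
}

carvone <- function() {
  solute_spec("(S)-(+)-carvone", "C10H14O", molar_mass = 150.22)
}

study_module <- function() {
  membrane_module(n_fibres = 3, d_i = 3e-3, d_o = 3.3e-3, length = 0.2,
                  pore_size = 1e-6, porosity = 0.5, tortuosity = 2,
                  shell_inner_diameter = 10e-3, beta = 5.8)
}

study_operating <- function(mode = "in-out") {
  operating_point(mode = mode,
                  Q_lumen = ml_min_to_m3_s(3), Q_shell = ml_min_to_m3_s(40),
                  temperature = 298.15,
                  V_w = ml_to_m3(100), V_s = ml_to_m3(50),
                  c_w0 = mg_ml_to_kg_m3(0.15))
}
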