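# shared fixtures: reference geometry and particles used throughout

ref_geometry <- function(...) cell_geometry(...)
ref_particle <- function(d = 1, rho = 1050) particle_spec(d, rho)

# a small, fast configuration for pipeline / rendering smoke tests
quick_cfg <- function(preset = "SiO2Carbo1000", phi_S = 0.22, ...) {
  load_preset(preset,
              coating = list(phi_S = phi_S),
              sim = list(duration_s = 7200, dt_s = 600, n_aggregates = 3),
              optics = list(fov_um = 400, pixel_size_um = 2),
              ...)
}

# clean Delta/R values from the conservation model across a coverage ladder
clean_delta_ratio <- function(phi_S, phi_is, a, phi_S0, g = ref_geometry(),
                              p = ref_particle(), R = 5000) {
  vapply(phi_S, function(ph) {
    up <- uptake_params(phi_is, a = a, phi_S0 = phi_S0)
    up$phi_s <- membrane_fraction(ph, up)
    aureole_width(R, ph, up, g, p) / R
  }, numeric(1))
}

# asymptotic Delta/R slope predicted by the conservation model
theory_slope <- function(phi_S, phi_is, g = ref_geometry(), p = ref_particle()) {
  phi_S * p$diameter * g$A_cell / (3 * phi_is * g$V_cell)
}
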