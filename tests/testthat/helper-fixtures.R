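# Shared helpers for the test suite: closed-form traces, energy-domain
# integration, and a tiny two-spectrum family with a known crossing.

# exact exponential approach to a plateau, no bump, no noise
exact_formation_trace <- function(k_obs, a_inf = 0.2, t_max = 8 / k_obs,
                                  n = 400) {
  t <- seq(0, t_max, length.out = n)
  kinetic_trace(t, a_inf * (1 - exp(-k_obs * t)), wavelength_nm = 678,
                path_cm = 0.5)
}

# exact second-order decay 1/A = 1/a0 + slope * t
exact_decay_trace <- function(slope, a0 = 0.3, t_max = 8e-5, n = 400) {
  t <- seq(0, t_max, length.out = n)
  kinetic_trace(t, 1 / (1 / a0 + slope * t), wavelength_nm = 678,
                path_cm = 0.5)
}

# trapezoidal integral of a spectrum over photon energy (eV)
energy_domain_area <- function(spec) {
  e <- nm_to_ev(spec$wavelength_nm)
  o <- order(e)
  sum(diff(e[o]) * (spec$value[o][-1] + spec$value[o][-length(e)]) / 2)
}

# family of straight-line "spectra" crossing exactly at x0
crossing_family <- function(grid = 300:500, x0 = 375, slopes = c(-1, 0, 1)) {
  lapply(slopes, function(s) {
    spectrum(grid, 10 + s * (grid - x0), kind = "differential")
  })
}
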