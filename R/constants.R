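# Physical constants (CODATA 2018), in the units used throughout the package.

# Planck constant times speed of light, eV nm: E[eV] = HC_EV_NM / lambda[nm]
HC_EV_NM <- 1239.84198

# Boltzmann constant, eV / K
KB_EV <- 8.617333262e-5

# Room temperature of the experiments, K (22 degrees C)
ROOM_TEMP_K <- 295

#' Convert between photon wavelength and energy
#'
#' @param wavelength_nm Wavelength in nm.
#' @param energy_ev Photon energy in eV.
#' @return The corresponding energy in eV (`nm_to_ev()`) or wavelength in nm
#'   (`ev_to_nm()`).
#' @examples
#' nm_to_ev(441)   # ~2.81 eV, the main crocin band
#' ev_to_nm(nm_to_ev(678))
#' @export
nm_to_ev <- function(wavelength_nm) {
  stopifnot(all(wavelength_nm > 0))
  HC_EV_NM / wavelength_nm
}

#' @rdname nm_to_ev
#' @export
ev_to_nm <- function(energy_ev) {
  stopifnot(all(energy_ev > 0))
  HC_EV_NM / energy_ev
}
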