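# Thermochemical arithmetic on top of external quantum-chemistry outputs:
# Wertz-corrected association free energies and redox-potential deduction,
# plus the tabulated reaction free energies of the crocin oxidation network.

#' Wertz-corrected association free energy
#'
#' Solution-phase association free energies computed with a continuum model
#' overestimate the entropy loss; the empirical Wertz correction halves the
#' gas-phase entropic contribution:
#' `G_corr = G_pcm - 0.5 (G_gp - H_gp) + kB T`,
#' where the `+ kB T` term cancels the PV contribution to the gas-phase
#' enthalpy. All energies are per particle, in eV.
#'
#' @param g_pcm Continuum-model (PCM) reaction free energy, eV.
#' @param g_gp Gas-phase reaction free energy, eV.
#' @param h_gp Gas-phase reaction enthalpy, eV.
#' @param temperature_k Temperature in K (default 295 K, the 22 degC of the
#'   experiments).
#' @return Corrected free energy in eV.
#' @examples
#' wertz_correct(-1.00, g_gp = -0.90, h_gp = -0.50) # -1.00 + 0.20 + kB T
#' @export
wertz_correct <- function(g_pcm, g_gp, h_gp, temperature_k = ROOM_TEMP_K) {
  if (any(temperature_k <= 0)) stop("temperature must be > 0", call. = FALSE)
  g_pcm - 0.5 * (g_gp - h_gp) + KB_EV * temperature_k
}

#' Redox potential from a reaction free energy
#'
#' One-equivalent convention: for a couple whose reduced form scavenges a
#' reference oxidant with reaction free energy `delta_g_ev` (eV per H-atom /
#' electron equivalent), the couple's potential is
#' `E = E_ref + delta_g_ev` volts versus the same reference scale (a more
#' negative scavenging free energy places the couple further below the
#' reference). With the -2 eV H-abstraction free energy of the crocin model
#' against the 2.0 V_NHE OH./H2O couple this puts the oxidized-radical
#' couple at ~0 V_NHE.
#'
#' @param delta_g_ev Reaction free energy in eV per equivalent.
#' @param e_ref_v Reference couple potential in V (default 2.0, OH./H2O at
#'   pH 7).
#' @return Potential in V on the reference scale (V_NHE by default).
#' @examples
#' redox_potential(-1.98) # ~0.02 V_NHE
#' @export
redox_potential <- function(delta_g_ev, e_ref_v = 2.0) {
  e_ref_v + delta_g_ev
}

#' Tabulated reaction free energies of the oxidation network
#'
#' Reads the package's machine-readable table of computed molar reaction
#' free energies (eV) for the processes in the oxidation of the crocin model
#' compound Me2-crocetin: H-abstraction at the two methyl sites, covalent
#' dimerizations, the disproportionation channels with their primary and
#' cyclic products, and radical-parent complexations.
#'
#' @return data.frame with columns `label`, `reactants`, `products`,
#'   `delta_g_ev`.
#' @export
reaction_free_energies <- function() {
  path <- system.file("extdata", "reaction_free_energies.tsv",
                      package = "crocinrad", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Look up one tabulated reaction free energy
#'
#' @param label Reaction label (see [reaction_free_energies()] for the list).
#' @return Reaction free energy in eV.
#' @examples
#' reaction_free_energy("oxidation_Ca")    # -1.98 eV
#' reaction_free_energy("dimer_CaCa")      # -1.09 eV
#' reaction_free_energy("complex_Ca")      # -0.52 eV
#' @export
reaction_free_energy <- function(label) {
  tab <- reaction_free_energies()
  i <- match(label, tab$label)
  if (is.na(i)) {
    stop("unknown reaction label: ", label, call. = FALSE)
  }
  tab$delta_g_ev[i]
}
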