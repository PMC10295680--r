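# Radiolytic yields (G values) of water radiolysis and the per-scheme
# consumption / product yields of the crocin oxidation schemes.

#' Primary radiolytic yields of water
#'
#' Container for the yields (G values) of the primary species produced by
#' water radiolysis at a scavenging time of ~100 ns:
#' e-_aq, H+, H., H2, OH., H2O2. Values are stored in SI units (mol/J); the
#' print method displays them in the conventional 1e-7 mol/J units.
#'
#' @param e_aq,h_plus,h_atom,h2,oh,h2o2 Yields in mol/J. The defaults are the
#'   accepted values for dilute water: 2.8, 2.8, 0.62, 0.47, 2.8 and
#'   0.73 x 1e-7 mol/J respectively.
#' @return An object of class `primary_yields`, a named numeric vector in
#'   mol/J.
#' @examples
#' g <- primary_yields()
#' oh_yield(g) # 5.6e-7 mol/J in N2O-saturated solution
#' @export
primary_yields <- function(e_aq = 2.8e-7, h_plus = 2.8e-7, h_atom = 0.62e-7,
                           h2 = 0.47e-7, oh = 2.8e-7, h2o2 = 0.73e-7) {
  g <- c(e_aq = e_aq, h_plus = h_plus, h_atom = h_atom,
         h2 = h2, oh = oh, h2o2 = h2o2)
  if (any(!is.finite(g)) || any(g < 0)) {
    stop("all primary yields must be finite and >= 0", call. = FALSE)
  }
  structure(g, class = "primary_yields")
}

#' @export
print.primary_yields <- function(x, ...) {
  cat("Primary radiolytic yields (1e-7 mol/J):\n")
  print(round(unclass(x) * 1e7, 3))
  invisible(x)
}

#' Hydroxyl radical yield in N2O-saturated solution
#'
#' In N2O-saturated solution the hydrated electrons are converted into OH.
#' radicals, so the effective OH. yield is G(e-_aq) + G(OH.). The small H.
#' contribution is not included (its conversion by N2O is slow).
#'
#' @param yields A [primary_yields()] object.
#' @return OH. yield in mol/J (default yields give 5.6e-7 mol/J).
#' @export
oh_yield <- function(yields = primary_yields()) {
  stopifnot(inherits(yields, "primary_yields"))
  unname(yields["e_aq"] + yields["oh"])
}

#' Concentration of a radiolytic species from dose and yield
#'
#' Uses the dilute-water convention 1 Gy = 1 J/L (density 1 kg/L), so the
#' concentration is simply dose x G.
#'
#' @param dose_gy Absorbed dose in Gy.
#' @param g Radiolytic yield in mol/J.
#' @return Concentration in mol/L.
#' @examples
#' dose_to_concentration(97, 5.6e-7) # ~5.4e-5 M of OH. per 97 Gy pulse
#' @export
dose_to_concentration <- function(dose_gy, g) {
  if (any(dose_gy < 0) || any(g < 0)) {
    stop("dose and yield must be >= 0", call. = FALSE)
  }
  dose_gy * g
}

#' Dose per pulse from the hydrated-electron absorbance
#'
#' Pulse-radiolysis dosimetry: the dose is derived from the absorbance of
#' e-_aq at 660 nm in pure water, through Beer-Lambert and the known
#' hydrated-electron yield at 5 ns.
#'
#' @param a660 Absorbance of the hydrated electron at 660 nm.
#' @param eps660 Molar absorption coefficient of e-_aq at 660 nm, M^-1 cm^-1
#'   (default 18,000).
#' @param path_cm Optical path in cm (default 0.5, the pulse cuvette).
#' @param g_eaq Hydrated electron yield at 5 ns, mol/J (default 3.3e-7).
#' @return Dose in Gy.
#' @examples
#' dose_from_eaq_absorbance(0.2882) # ~97 Gy
#' @export
dose_from_eaq_absorbance <- function(a660, eps660 = 18000, path_cm = 0.5,
                                     g_eaq = 3.3e-7) {
  if (eps660 <= 0 || path_cm <= 0 || g_eaq <= 0) {
    stop("eps660, path_cm and g_eaq must be > 0", call. = FALSE)
  }
  if (any(a660 < 0)) stop("absorbance must be >= 0", call. = FALSE)
  a660 / (eps660 * path_cm * g_eaq)
}

#' Calculated consumption / product yields of the oxidation schemes
#'
#' Bookkeeping of the reaction schemes that link the primary radiolytic
#' yields to the calculated crocin consumption (or product formation) yield:
#'
#' * `"pulse_N2O"`: pulse radiolysis in N2O-saturated solution; every OH.
#'   (from e-_aq conversion and the direct yield) plus the H. channel oxidizes
#'   one crocin, so G(-croc) = G(e-_aq) + G(OH.) + G(H.).
#' * `"gamma_N2O_disproportionation"`: steady-state gamma radiolysis where the
#'   radicals disproportionate via the (croc, croc(-H)). complex and H2O2 also
#'   oxidizes crocin; G = 1/2 (G(e-_aq) + G(OH.) + G(H.) + 2 G(H2O2)).
#' * `"gamma_Ag_plus"`: gamma radiolysis with Ag+ scavenging H. and the silver
#'   atoms regenerating crocin; G = 1/2 (G(e-_aq) + G(OH.) - G(H.)).
#'
#' The covalent-dimer yield in pulse radiolysis is half of the pulse
#' consumption yield (two radicals per dimer); see `dimer = TRUE`.
#'
#' @param scheme One of `"pulse_N2O"`, `"gamma_N2O_disproportionation"`,
#'   `"gamma_Ag_plus"`.
#' @param yields A [primary_yields()] object.
#' @param dimer If `TRUE` and `scheme = "pulse_N2O"`, return the dimer
#'   formation yield (half the consumption yield).
#' @return Yield in mol/J.
#' @examples
#' scheme_yield("pulse_N2O")                      # 6.22e-7
#' scheme_yield("pulse_N2O", dimer = TRUE)        # 3.11e-7
#' scheme_yield("gamma_N2O_disproportionation")   # 3.84e-7
#' scheme_yield("gamma_Ag_plus")                  # 2.49e-7
#' @export
scheme_yield <- function(scheme = c("pulse_N2O", "gamma_N2O_disproportionation",
                                    "gamma_Ag_plus"),
                         yields = primary_yields(), dimer = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(yields, "primary_yields"))
  g <- unclass(yields)
  out <- switch(scheme,
    pulse_N2O = g[["e_aq"]] + g[["oh"]] + g[["h_atom"]],
    gamma_N2O_disproportionation =
      0.5 * (g[["e_aq"]] + g[["oh"]] + g[["h_atom"]] + 2 * g[["h2o2"]]),
    gamma_Ag_plus = 0.5 * (g[["e_aq"]] + g[["oh"]] - g[["h_atom"]])
  )
  if (dimer) {
    if (scheme != "pulse_N2O") {
      stop("dimer yield is only defined for the pulse_N2O scheme", call. = FALSE)
    }
    out <- out / 2
  }
  unname(out)
}
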