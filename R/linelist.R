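# Electronic-transition line lists and their conversion into UV-vis spectra:
# trajectory subsampling, spin-contamination screening, Gaussian convolution
# in the energy domain, and probability-weighted species mixing.

#' Ensemble of electronic transition lines
#'
#' Holds TDDFT-style excitation lines grouped by the sampled configuration
#' they were computed on, together with the ground-state spin expectation of
#' the species and the sampling metadata.
#'
#' @param lines data.frame with columns `config` (integer configuration /
#'   step index), `energy_ev` (> 0), `osc_strength` (>= 0), `s2` (spin
#'   expectation, >= 0).
#' @param ground_s2 Ground-state spin expectation of the species (0 for a
#'   closed shell, 0.75 for a doublet radical).
#' @param species Species label.
#' @param total_steps,burn_in,stride Sampling metadata of the trajectory the
#'   configurations came from (optional, recorded for provenance).
#' @return Object of class `line_ensemble`.
#' @export
line_ensemble <- function(lines, ground_s2, species = NULL,
                          total_steps = NA_integer_, burn_in = 0L,
                          stride = 1L) {
  need <- c("config", "energy_ev", "osc_strength", "s2")
  if (!all(need %in% names(lines))) {
    stop("lines must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(lines) > 0) {
    if (any(lines$energy_ev <= 0)) stop("energies must be > 0", call. = FALSE)
    if (any(lines$osc_strength < 0)) {
      stop("oscillator strengths must be >= 0", call. = FALSE)
    }
    if (any(lines$s2 < 0)) stop("<S2> must be >= 0", call. = FALSE)
  }
  if (ground_s2 < 0) stop("ground_s2 must be >= 0", call. = FALSE)
  structure(list(lines = lines, ground_s2 = ground_s2, species = species,
                 total_steps = total_steps, burn_in = burn_in,
                 stride = stride),
            class = "line_ensemble")
}

#' @export
print.line_ensemble <- function(x, ...) {
  cat(sprintf(
    "Line ensemble%s: %d lines on %d configurations, ground <S2> = %g\n",
    if (is.null(x$species)) "" else paste0(" of ", x$species),
    nrow(x$lines), length(unique(x$lines$config)), x$ground_s2))
  invisible(x)
}

#' Uniform trajectory subsampling of a line ensemble
#'
#' Keeps the configurations of an equilibrated stretch of the sampling
#' trajectory: indices at or beyond `burn_in`, taken every `stride` steps.
#' Configuration indices are interpreted as 1-based trajectory steps, so a
#' 60,000-step run with a 20,000-step burn-in at stride 100 retains
#' (60000 - 20000) / 100 = 400 configurations.
#'
#' @param ensemble A [line_ensemble()].
#' @param burn_in Number of initial steps discarded (must be below the total).
#' @param stride Keep every `stride`-th step after the burn-in.
#' @return A [line_ensemble()] restricted to the retained configurations.
#' @export
subsample <- function(ensemble, burn_in, stride = 100L) {
  stopifnot(inherits(ensemble, "line_ensemble"))
  total <- ensemble$total_steps
  if (is.na(total)) total <- max(ensemble$lines$config)
  if (burn_in >= total) {
    stop("burn_in must be smaller than the total number of steps",
         call. = FALSE)
  }
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  keep_idx <- seq(burn_in + stride, total, by = stride)
  lines <- ensemble$lines[ensemble$lines$config %in% keep_idx, , drop = FALSE]
  line_ensemble(lines, ensemble$ground_s2, ensemble$species,
                total_steps = total, burn_in = as.integer(burn_in),
                stride = as.integer(stride))
}

#' Spin-contamination screening of transition lines
#'
#' One-determinant DFT descriptions of open-shell species can produce
#' spin-contaminated excited states. Lines whose spin expectation exceeds
#' the ground-state value by more than the screening parameter are discarded.
#' By default the excess is relative: the cutoff is
#' `ground_s2 * (1 + parameter)` (a 20% parameter on a doublet keeps lines
#' with <S2> up to 0.90). With `mode = "absolute"` the cutoff is
#' `ground_s2 + parameter`. For a closed-shell species (ground <S2> = 0) both
#' modes reduce to keeping uncontaminated lines only under the relative rule.
#'
#' @param ensemble A [line_ensemble()].
#' @param parameter Screening parameter (>= 0), default 0.2.
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return A [line_ensemble()] with the contaminated lines removed.
#' @export
spin_screen <- function(ensemble, parameter = 0.2,
                        mode = c("relative", "absolute")) {
  stopifnot(inherits(ensemble, "line_ensemble"))
  mode <- match.arg(mode)
  if (parameter < 0) stop("parameter must be >= 0", call. = FALSE)
  cutoff <- switch(mode,
                   relative = ensemble$ground_s2 * (1 + parameter),
                   absolute = ensemble$ground_s2 + parameter)
  keep <- ensemble$lines$s2 <= cutoff
  out <- ensemble
  out$lines <- ensemble$lines[keep, , drop = FALSE]
  out
}

#' Convolve a line ensemble into an absorption spectrum
#'
#' Each transition line contributes a Gaussian in the energy domain, centred
#' at its excitation energy, with area proportional to its oscillator
#' strength and the requested full width at half maximum. Per-configuration
#' line sums are averaged over the configurations of the ensemble, and the
#' resulting energy-domain profile is evaluated on a wavelength grid (no
#' Jacobian reweighting beyond the variable change).
#'
#' Three conventional widths cover the band classes: 0.70 eV for lines of
#' optimized structures, 0.50 eV for intense bands and weak high-energy
#' bands, and 0.20 eV for weak low-energy bands (see [fwhm_registry]).
#'
#' @param ensemble A [line_ensemble()].
#' @param fwhm Gaussian full width at half maximum in eV (> 0).
#' @param grid_nm Wavelength grid (nm), default 200-900 nm at 1 nm.
#' @return A [spectrum()] (kind `"absorbance"`-like arbitrary intensity
#'   units; the scale is oscillator strength per eV).
#' @examples
#' ens <- line_ensemble(
#'   data.frame(config = 1L, energy_ev = nm_to_ev(441),
#'              osc_strength = 3.22, s2 = 0),
#'   ground_s2 = 0)
#' sp <- convolve_lines(ens, fwhm = 0.5)
#' sp$wavelength_nm[which.max(sp$value)] # 441 nm
#' @export
convolve_lines <- function(ensemble, fwhm, grid_nm = 200:900) {
  stopifnot(inherits(ensemble, "line_ensemble"))
  if (fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  grid_nm <- as.numeric(grid_nm)
  e_grid <- nm_to_ev(grid_nm)
  lines <- ensemble$lines
  if (nrow(lines) == 0) {
    warning("empty line ensemble: returning a zero spectrum")
    return(spectrum(grid_nm, rep(0, length(grid_nm)), kind = "absorbance",
                    species = ensemble$species))
  }
  n_conf <- length(unique(lines$config))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  vals <- numeric(length(e_grid))
  for (i in seq_len(nrow(lines))) {
    vals <- vals + lines$osc_strength[i] *
      stats::dnorm(e_grid, mean = lines$energy_ev[i], sd = sigma)
  }
  spectrum(grid_nm, vals / n_conf, kind = "absorbance",
           species = ensemble$species)
}

#' Conventional Gaussian broadening widths (eV)
#'
#' Named registry of the full widths at half maximum used for the different
#' band classes: `optimized` (0.70 eV, single optimized-structure line
#' lists), `intense` (0.50 eV, intense bands and weak high-energy bands of a
#' sampled trajectory) and `weak_low_energy` (0.20 eV).
#'
#' @format Named numeric vector of length 3.
#' @export
fwhm_registry <- c(optimized = 0.70, intense = 0.50, weak_low_energy = 0.20)

#' Probability-weighted mixture of species spectra
#'
#' Pointwise weighted sum of spectra on a common grid, used to combine the
#' spectra of alternative oxidation products (e.g. the radicals formed at the
#' two methyl sites) with their formation probabilities.
#'
#' @param spectra Named list of [spectrum()] objects on a common grid.
#' @param weights Named numeric vector of probabilities (>= 0, summing to 1
#'   within 1e-12); every name must match a spectrum.
#' @return A [spectrum()] on the common grid.
#' @examples
#' # equal-probability "1/2 1/2" mixture of two radicals
#' # mix_spectra(list(a = sp_a, b = sp_b), c(a = 0.5, b = 0.5))
#' @export
mix_spectra <- function(spectra, weights) {
  weights <- validate_weights(weights)
  missing <- setdiff(names(weights), names(spectra))
  if (length(missing)) {
    stop("no spectrum for label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  grid <- spectra[[names(weights)[1]]]$wavelength_nm
  vals <- rep(0, length(grid))
  for (lab in names(weights)) {
    s <- spectra[[lab]]
    if (!isTRUE(all.equal(s$wavelength_nm, grid))) {
      stop("spectra must share a common wavelength grid", call. = FALSE)
    }
    vals <- vals + weights[[lab]] * s$value
  }
  spectrum(grid, vals, kind = attr(spectra[[names(weights)[1]]], "kind"))
}

validate_weights <- function(weights) {
  if (is.null(names(weights)) || any(names(weights) == "")) {
    stop("weights must be a fully named numeric vector", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-12) {
    stop("weights must sum to 1 (within 1e-12)", call. = FALSE)
  }
  weights
}

#' Dimer probabilities from monomer probabilities
#'
#' If two radicals a and b form with probabilities `p_a` and `p_b`, random
#' pairing gives their covalent dimers the binomial probabilities
#' (p_a^2, 2 p_a p_b, p_b^2).
#'
#' @param p_a,p_b Monomer formation probabilities; must be nonnegative and
#'   sum to 1.
#' @return Named numeric vector `c(aa, ab, bb)` summing to 1.
#' @examples
#' monomer_to_dimer_weights(5 / 6, 1 / 6) # (0.69, 0.28, 0.03)
#' @export
monomer_to_dimer_weights <- function(p_a, p_b) {
  if (p_a < 0 || p_b < 0 || abs(p_a + p_b - 1) > 1e-12) {
    stop("p_a and p_b must be nonnegative and sum to 1", call. = FALSE)
  }
  c(aa = p_a^2, ab = 2 * p_a * p_b, bb = p_b^2)
}

#' Sugar-driven site probabilities of radical formation
#'
#' The OH radical meets the polyene chain directly with probability
#' `chain_encounter_fraction`, in which case the two methyl sites a and b are
#' attacked with equal probability. With the complementary probability it
#' first meets a sugar substituent, which it cannot oxidize; migrating on the
#' sugar surface it is delivered to the neighbouring site a. Hence
#' `p_a = (1 - f) + f/2` and `p_b = f/2`. A chain fraction of 1/3 gives the
#' (5/6, 1/6) weights; a fraction of 1 recovers the no-sugar-influence
#' (1/2, 1/2) limit.
#'
#' @param chain_encounter_fraction Probability in `[0, 1]` that the radical
#'   encounters the chain rather than a sugar.
#' @return Named numeric vector `c(a, b)` summing to 1.
#' @examples
#' sugar_driven_weights(1 / 3) # (5/6, 1/6)
#' @export
sugar_driven_weights <- function(chain_encounter_fraction) {
  f <- chain_encounter_fraction
  if (f < 0 || f > 1) {
    stop("chain_encounter_fraction must be in [0, 1]", call. = FALSE)
  }
  c(a = (1 - f) + f / 2, b = f / 2)
}
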