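# Synthetic-data generators emulating the experimental inputs: transient
# absorbance traces (radical formation with the early electron "bump",
# second-order radical decay), crocin-like and product-like molar
# absorptivity spectra, gamma dose series with an isosbestic point, and
# quantum-chemistry line lists with a controlled fraction of
# spin-contaminated lines. Every generator is deterministic given its seed.

#' Recipe for a synthetic kinetic trace
#'
#' @param mechanism `"formation"` (pseudo-first-order radical growth) or
#'   `"second_order_decay"` (radical recombination).
#' @param k2 Bimolecular scavenging rate constant, M^-1 s^-1 (formation).
#' @param scavenger_conc Crocin concentration, mol/L (formation; in excess).
#' @param c_radical0 Initial radical pool: OH. concentration delivered by the
#'   pulse (formation, mol/L) or radical concentration at t = 0 (decay).
#' @param two_k Recombination rate constant 2k, M^-1 s^-1 (decay).
#' @param eps_radical,eps_parent Molar absorption coefficients at the trace
#'   wavelength, M^-1 cm^-1. The parent coefficient lets isosbestic traces
#'   (equal coefficients) be emulated.
#' @param wavelength_nm Detection wavelength.
#' @param path_cm Optical path of the cell (default 0.5, the pulse cuvette).
#' @param conversion_path_cm Path folded into the decay's absorbance
#'   convention (default 1; see [fit_second_order()]).
#' @param bump_amplitude,bump_tau_s Additive early transient emulating the
#'   hydrated-electron bump: amplitude (absorbance) decaying exponentially
#'   with time constant `bump_tau_s` (default 50 ns).
#' @param noise_fraction Relative standard deviation of the multiplicative
#'   Gaussian noise (default 0.05, the instrumental +/-5%).
#' @param seed Integer RNG seed.
#' @param time_s Time grid, strictly increasing (s).
#' @return Object of class `trace_recipe` (a list).
#' @export
trace_recipe <- function(mechanism = c("formation", "second_order_decay"),
                         k2 = 3.4e10, scavenger_conc = 1.3e-4,
                         c_radical0 = 5.4e-5, two_k = 3.7e9,
                         eps_radical = 6230, eps_parent = 0,
                         wavelength_nm = 678, path_cm = 0.5,
                         conversion_path_cm = 1,
                         bump_amplitude = 0.01, bump_tau_s = 5e-8,
                         noise_fraction = 0.05, seed = 1L,
                         time_s = NULL) {
  mechanism <- match.arg(mechanism)
  if (is.null(time_s)) {
    time_s <- if (mechanism == "formation") {
      seq(0, 1.5e-6, length.out = 601)
    } else {
      seq(0, 8.4e-5, length.out = 601)
    }
  }
  if (noise_fraction < 0) stop("noise_fraction must be >= 0", call. = FALSE)
  if (any(diff(time_s) <= 0)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  structure(list(mechanism = mechanism, k2 = k2,
                 scavenger_conc = scavenger_conc, c_radical0 = c_radical0,
                 two_k = two_k, eps_radical = eps_radical,
                 eps_parent = eps_parent, wavelength_nm = wavelength_nm,
                 path_cm = path_cm, conversion_path_cm = conversion_path_cm,
                 bump_amplitude = bump_amplitude, bump_tau_s = bump_tau_s,
                 noise_fraction = noise_fraction, seed = as.integer(seed),
                 time_s = time_s),
            class = "trace_recipe")
}

apply_noise <- function(values, fraction) {
  if (fraction == 0) return(values)
  values * (1 + fraction * stats::rnorm(length(values)))
}

#' Synthetic pseudo-first-order formation trace
#'
#' Radical concentration grows as
#' `c_r(t) = c_radical0 (1 - exp(-k2 * scavenger_conc * t))` while the parent
#' is depleted stoichiometrically; the absorbance is the Beer-Lambert sum of
#' both species plus the additive electron bump, with multiplicative
#' Gaussian noise. At a wavelength where parent and radical coefficients are
#' equal the noiseless post-bump trace is constant (isosbestic behaviour).
#'
#' @param recipe A [trace_recipe()] with `mechanism = "formation"`.
#' @return A [kinetic_trace()].
#' @export
gen_formation_trace <- function(recipe) {
  stopifnot(inherits(recipe, "trace_recipe"))
  if (recipe$mechanism != "formation") {
    stop("recipe mechanism must be 'formation'", call. = FALSE)
  }
  if (recipe$eps_radical < 0 || recipe$eps_parent < 0) {
    stop("molar absorption coefficients must be >= 0", call. = FALSE)
  }
  t <- recipe$time_s
  k_obs <- recipe$k2 * recipe$scavenger_conc
  c_r <- recipe$c_radical0 * (1 - exp(-k_obs * t))
  c_parent <- pmax(recipe$scavenger_conc - c_r, 0)
  a <- recipe$path_cm * (recipe$eps_radical * c_r +
                         recipe$eps_parent * c_parent) +
    recipe$bump_amplitude * exp(-t / recipe$bump_tau_s)
  set.seed(recipe$seed)
  a <- apply_noise(a, recipe$noise_fraction)
  kinetic_trace(t, a, recipe$wavelength_nm, recipe$path_cm)
}

#' Synthetic second-order decay trace
#'
#' Exact second-order kinetics in the absorbance convention: the reciprocal
#' absorbance is a straight line, `1/A(t) = 1/A0 + (2k / (eps * l)) * t`,
#' with `A0 = eps * c_radical0 * l`. Multiplicative noise as configured.
#'
#' @param recipe A [trace_recipe()] with `mechanism = "second_order_decay"`.
#' @return A [kinetic_trace()].
#' @export
gen_decay_trace <- function(recipe) {
  stopifnot(inherits(recipe, "trace_recipe"))
  if (recipe$mechanism != "second_order_decay") {
    stop("recipe mechanism must be 'second_order_decay'", call. = FALSE)
  }
  t <- recipe$time_s
  l <- recipe$conversion_path_cm
  a0 <- recipe$eps_radical * recipe$c_radical0 * l
  slope <- recipe$two_k / (recipe$eps_radical * l)
  a <- 1 / (1 / a0 + slope * t)
  set.seed(recipe$seed)
  a <- apply_noise(a, recipe$noise_fraction)
  kinetic_trace(t, a, recipe$wavelength_nm, recipe$path_cm)
}

#' Synthetic crocin-like molar absorptivity spectrum
#'
#' Sum of Gaussian bands reproducing the characteristic features of the
#' crocin spectrum: the intense visible band at 441 nm, its 460 nm shoulder,
#' and the weak UV bands at 333 and 250 nm; the whole spectrum is scaled so
#' that the 441 nm value equals `eps_max`. Absorption is negligible
#' (< 1% of the peak) beyond 550 nm.
#'
#' @param eps_max Molar absorptivity at 441 nm (default 1.35e5 M^-1 cm^-1).
#' @param grid_nm Wavelength grid (default 230-700 nm at 1 nm).
#' @param amplitudes Relative band amplitudes, named
#'   `c(main, shoulder, uv333, uv250)`; setting all to zero returns a zero
#'   spectrum.
#' @return A [spectrum()] of kind `"molar_absorptivity"`.
#' @export
gen_crocin_like_spectrum <- function(eps_max = 1.35e5, grid_nm = 230:700,
                                     amplitudes = c(main = 1, shoulder = 0.32,
                                                    uv333 = 0.056,
                                                    uv250 = 0.09)) {
  centers <- c(main = 441, shoulder = 460, uv333 = 333, uv250 = 250)
  sigmas <- c(main = 33, shoulder = 18, uv333 = 18, uv250 = 16)
  grid_nm <- as.numeric(grid_nm)
  shape <- rep(0, length(grid_nm))
  for (b in names(centers)) {
    shape <- shape + amplitudes[[b]] *
      exp(-((grid_nm - centers[[b]])^2) / (2 * sigmas[[b]]^2))
  }
  at441 <- sum(amplitudes * exp(-((441 - centers)^2) / (2 * sigmas^2)))
  vals <- if (at441 > 0) shape * eps_max / at441 else shape
  spectrum(grid_nm, vals, kind = "molar_absorptivity", species = "crocin")
}

#' Synthetic product-like molar absorptivity spectrum
#'
#' Emulates the final twice-oxidized product: a 330 nm band, a weak 441 nm
#' band, and an exact crossing with a reference crocin-like spectrum at the
#' isosbestic wavelength. Three Gaussian amplitudes are solved from the
#' three constraints `eps(330) = eps330`, `eps(441) = eps441` and
#' `eps(isosbestic) = eps_ref(isosbestic)`.
#'
#' @param eps_ref Reference parent [spectrum()] (molar absorptivity) whose
#'   grid the product spectrum is built on.
#' @param eps330,eps441 Product coefficients at 330 and 441 nm (defaults
#'   0.25e5 and 0.11e5 M^-1 cm^-1).
#' @param isosbestic_nm Wavelength of the exact crossing (default 375 nm).
#' @return A [spectrum()] of kind `"molar_absorptivity"`.
#' @export
gen_product_like_spectrum <- function(eps_ref, eps330 = 0.25e5,
                                      eps441 = 0.11e5, isosbestic_nm = 375) {
  stopifnot(inherits(eps_ref, "spectrum"))
  centers <- c(330, 380, 441)
  sigmas <- c(20, 24, 22)
  anchors <- c(330, isosbestic_nm, 441)
  targets <- c(eps330, spectrum_at(eps_ref, isosbestic_nm), eps441)
  m <- outer(anchors, seq_along(centers), function(l, j) {
    exp(-((l - centers[j])^2) / (2 * sigmas[j]^2))
  })
  amps <- solve(m, targets)
  if (any(amps < 0)) {
    warning("negative component amplitude in the product spectrum; ",
            "constraints may be inconsistent")
  }
  grid_nm <- eps_ref$wavelength_nm
  vals <- rep(0, length(grid_nm))
  for (j in seq_along(centers)) {
    vals <- vals + amps[j] * exp(-((grid_nm - centers[j])^2) / (2 * sigmas[j]^2))
  }
  spectrum(grid_nm, pmax(vals, 0), kind = "molar_absorptivity",
           species = "product")
}

#' Recipe for a synthetic gamma dose series
#'
#' @param eps_known Parent molar absorptivity [spectrum()] (default:
#'   [gen_crocin_like_spectrum()]).
#' @param eps_product Product [spectrum()] on the same grid (default:
#'   [gen_product_like_spectrum()] crossing the parent at 375 nm).
#' @param doses_gy Doses in Gy, must include 0 (default 0-97 Gy, the linear
#'   range).
#' @param g Consumption yield in mol/J (default 4.0e-7).
#' @param c0 Initial parent concentration, mol/L (default 5.7e-5).
#' @param path_cm Optical path (default 0.1 cm, the 1 mm cell).
#' @param noise_fraction Multiplicative noise level (default 0.05).
#' @param seed Integer RNG seed.
#' @return Object of class `spectrum_recipe`.
#' @export
spectrum_recipe <- function(eps_known = gen_crocin_like_spectrum(),
                            eps_product = gen_product_like_spectrum(eps_known),
                            doses_gy = c(0, 16, 32, 48, 64, 80, 97),
                            g = 4.0e-7, c0 = 5.7e-5, path_cm = 0.1,
                            noise_fraction = 0.05, seed = 1L) {
  if (!any(doses_gy == 0)) stop("doses must include 0", call. = FALSE)
  if (!isTRUE(all.equal(eps_known$wavelength_nm, eps_product$wavelength_nm))) {
    stop("parent and product spectra must share a grid", call. = FALSE)
  }
  structure(list(eps_known = eps_known, eps_product = eps_product,
                 doses_gy = doses_gy, g = g, c0 = c0, path_cm = path_cm,
                 noise_fraction = noise_fraction, seed = as.integer(seed)),
            class = "spectrum_recipe")
}

#' Synthetic dose-indexed absorbance series
#'
#' For each dose D the parent is consumed as `c_parent = c0 - G D` (floored
#' at 0) and the product formed as `c_product = G D` (capped at `c0`); the
#' absorbance spectrum is the Beer-Lambert sum, with multiplicative noise.
#' Mass balance `c_parent + c_product = c0` holds exactly before flooring,
#' and all noiseless spectra agree exactly at wavelengths where the two
#' component spectra are equal (the isosbestic point).
#'
#' @param recipe A [spectrum_recipe()].
#' @return List with `spectra` (list of absorbance [spectrum()]s), `doses`
#'   (Gy) and `concentrations` (data.frame: dose_gy, c_known, c_product).
#' @export
gen_dose_series <- function(recipe) {
  stopifnot(inherits(recipe, "spectrum_recipe"))
  set.seed(recipe$seed)
  grid <- recipe$eps_known$wavelength_nm
  spectra <- vector("list", length(recipe$doses_gy))
  c_known <- c_prod <- numeric(length(recipe$doses_gy))
  for (i in seq_along(recipe$doses_gy)) {
    d <- recipe$doses_gy[i]
    x <- min(recipe$g * d, recipe$c0)
    c_known[i] <- max(recipe$c0 - recipe$g * d, 0)
    c_prod[i] <- x
    a <- recipe$path_cm * (recipe$eps_known$value * c_known[i] +
                           recipe$eps_product$value * c_prod[i])
    a <- apply_noise(a, recipe$noise_fraction)
    spectra[[i]] <- spectrum(grid, a, kind = "absorbance",
                             path_cm = recipe$path_cm)
  }
  list(spectra = spectra, doses = recipe$doses_gy,
       concentrations = data.frame(dose_gy = recipe$doses_gy,
                                   c_known = c_known, c_product = c_prod))
}

#' Recipe for a synthetic electronic-transition line list
#'
#' @param n_config Number of sampled configurations.
#' @param centers_ev Band-centre excitation energies (eV); each configuration
#'   carries one line per centre.
#' @param energy_jitter_ev Gaussian jitter of the line energies around their
#'   centres (eV).
#' @param f_means Mean oscillator strengths, one per centre.
#' @param f_jitter Relative Gaussian jitter of the oscillator strengths.
#' @param ground_s2 Ground-state spin expectation (default 0.75, a doublet
#'   radical).
#' @param contamination_fraction Fraction of lines flagged as
#'   spin-contaminated (in `[0, 1]`).
#' @param contamination_excess Relative <S2> excess of contaminated lines:
#'   their spin expectation is `ground_s2 * (1 + excess)`.
#' @param seed Integer RNG seed.
#' @return Object of class `linelist_recipe`.
#' @export
linelist_recipe <- function(n_config = 400L,
                            centers_ev = nm_to_ev(c(441, 333, 678)),
                            energy_jitter_ev = 0.08,
                            f_means = c(3.0, 0.2, 0.05), f_jitter = 0.1,
                            ground_s2 = 0.75,
                            contamination_fraction = 0.0,
                            contamination_excess = 0.5, seed = 1L) {
  if (contamination_fraction < 0 || contamination_fraction > 1) {
    stop("contamination_fraction must be in [0, 1]", call. = FALSE)
  }
  if (length(f_means) != length(centers_ev)) {
    stop("f_means must match centers_ev in length", call. = FALSE)
  }
  structure(list(n_config = as.integer(n_config), centers_ev = centers_ev,
                 energy_jitter_ev = energy_jitter_ev, f_means = f_means,
                 f_jitter = f_jitter, ground_s2 = ground_s2,
                 contamination_fraction = contamination_fraction,
                 contamination_excess = contamination_excess,
                 seed = as.integer(seed)),
            class = "linelist_recipe")
}

#' Synthetic electronic-transition line list
#'
#' Draws, per configuration, one line per band centre with jittered energy
#' and oscillator strength; a Bernoulli fraction of all lines is marked as
#' spin-contaminated with `<S2> = ground_s2 * (1 + excess)`, the rest carry
#' the ground-state value.
#'
#' @param recipe A [linelist_recipe()].
#' @return A [line_ensemble()].
#' @export
gen_linelist <- function(recipe) {
  stopifnot(inherits(recipe, "linelist_recipe"))
  set.seed(recipe$seed)
  nb <- length(recipe$centers_ev)
  n <- recipe$n_config * nb
  config <- rep(seq_len(recipe$n_config), each = nb)
  energy <- rep(recipe$centers_ev, times = recipe$n_config) +
    stats::rnorm(n, sd = recipe$energy_jitter_ev)
  energy <- pmax(energy, 1e-3)
  f <- pmax(rep(recipe$f_means, times = recipe$n_config) *
              (1 + recipe$f_jitter * stats::rnorm(n)), 0)
  contaminated <- stats::runif(n) < recipe$contamination_fraction
  s2 <- ifelse(contaminated,
               recipe$ground_s2 * (1 + recipe$contamination_excess),
               recipe$ground_s2)
  line_ensemble(data.frame(config = config, energy_ev = energy,
                           osc_strength = f, s2 = s2),
                ground_s2 = recipe$ground_s2,
                total_steps = recipe$n_config)
}
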