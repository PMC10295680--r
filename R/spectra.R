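# Spectrum container and the molar-absorptivity calibration algebra anchored
# on the isosbestic points of the crocin / radical / dimer / product system.

#' Wavelength-gridded spectrum
#'
#' @param wavelength_nm Strictly increasing wavelength grid in nm.
#' @param value Absorbance, molar absorptivity (M^-1 cm^-1) or differential
#'   molar absorptivity, same length as the grid.
#' @param kind One of `"absorbance"`, `"molar_absorptivity"`,
#'   `"differential"`. Negative values are only allowed for
#'   `kind = "differential"`.
#' @param path_cm Optional optical path in cm (absorbance spectra).
#' @param species Optional species label.
#' @return Object of class `spectrum` (a data.frame with metadata
#'   attributes).
#' @export
spectrum <- function(wavelength_nm, value,
                     kind = c("absorbance", "molar_absorptivity", "differential"),
                     path_cm = NULL, species = NULL) {
  kind <- match.arg(kind)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) != length(value)) {
    stop("wavelength and value must have the same length", call. = FALSE)
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  if (kind == "molar_absorptivity" && any(value < 0)) {
    stop("molar absorptivity must be >= 0 (use kind = 'differential')",
         call. = FALSE)
  }
  structure(
    data.frame(wavelength_nm = wavelength_nm, value = value),
    kind = kind, path_cm = path_cm, species = species,
    class = c("spectrum", "data.frame")
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("Spectrum [%s]%s: %d points, %g-%g nm\n",
              attr(x, "kind"),
              if (is.null(attr(x, "species"))) "" else
                paste0(" of ", attr(x, "species")),
              nrow(x), min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  ylab <- switch(attr(x, "kind"),
                 absorbance = "Absorbance",
                 molar_absorptivity = expression(epsilon ~ (M^-1 ~ cm^-1)),
                 differential = expression(Delta * epsilon ~ (M^-1 ~ cm^-1)))
  plot(x$wavelength_nm, x$value, type = "l",
       xlab = "Wavelength (nm)", ylab = ylab, ...)
  invisible(x)
}

#' Evaluate a spectrum at given wavelengths (linear interpolation)
#'
#' @param spec A [spectrum()].
#' @param wavelength_nm Wavelengths (nm) inside the spectrum's range;
#'   extrapolation is refused.
#' @return Numeric vector of interpolated values.
#' @export
spectrum_at <- function(spec, wavelength_nm) {
  stopifnot(inherits(spec, "spectrum"))
  rng <- range(spec$wavelength_nm)
  if (any(wavelength_nm < rng[1]) || any(wavelength_nm > rng[2])) {
    stop("requested wavelength outside the spectrum range (no extrapolation)",
         call. = FALSE)
  }
  stats::approx(spec$wavelength_nm, spec$value, xout = wavelength_nm)$y
}

#' Resample a spectrum onto a reference grid
#'
#' Linear interpolation onto `grid_nm`; the grid must lie inside the
#' spectrum's wavelength range.
#'
#' @param spec A [spectrum()].
#' @param grid_nm Target wavelength grid (strictly increasing, nm).
#' @return A [spectrum()] on `grid_nm` with the same metadata.
#' @export
resample_spectrum <- function(spec, grid_nm) {
  spectrum(grid_nm, spectrum_at(spec, grid_nm), kind = attr(spec, "kind"),
           path_cm = attr(spec, "path_cm"), species = attr(spec, "species"))
}

#' Calibrate a molar absorption coefficient by an absorbance ratio
#'
#' Under 1:1 stoichiometry (established by the isosbestic points) and equal
#' optical paths, the unknown coefficient follows from a reference
#' coefficient and the ratio of the two absorbances:
#' eps_target = eps_ref * A_target / A_ref. This is how the radical
#' coefficient at 678 nm is obtained from the parent crocin band at 441 nm.
#'
#' @param eps_ref Reference molar absorption coefficient, M^-1 cm^-1.
#' @param a_ref Reference absorbance (> 0).
#' @param a_target Absorbance of the species being calibrated.
#' @return Molar absorption coefficient in M^-1 cm^-1.
#' @examples
#' calibrate_by_ratio(1.35e5, 0.52, 0.024) # ~6230 M^-1 cm^-1
#' @export
calibrate_by_ratio <- function(eps_ref, a_ref, a_target) {
  if (a_ref <= 0) stop("a_ref must be > 0", call. = FALSE)
  if (eps_ref < 0) stop("eps_ref must be >= 0", call. = FALSE)
  eps_ref * a_target / a_ref
}

#' Absolute spectrum from a differential spectrum and a reference
#'
#' Reconstructs the absolute molar-absorptivity spectrum of a transient as
#' the algebraic sum of the parent spectrum and the differential (transient
#' minus parent) spectrum, both in molar absorption coefficients. The
#' differential spectrum is resampled onto the reference grid; small negative
#' results are clipped to zero with a warning.
#'
#' @param diff A [spectrum()] with `kind = "differential"`.
#' @param ref A [spectrum()] with `kind = "molar_absorptivity"`.
#' @return A [spectrum()] of kind `"molar_absorptivity"` on the grid of
#'   `ref`.
#' @export
differential_to_absolute <- function(diff, ref) {
  stopifnot(inherits(diff, "spectrum"), inherits(ref, "spectrum"))
  if (attr(diff, "kind") != "differential") {
    stop("diff must have kind = 'differential'", call. = FALSE)
  }
  if (attr(ref, "kind") != "molar_absorptivity") {
    stop("ref must have kind = 'molar_absorptivity'", call. = FALSE)
  }
  if (min(diff$wavelength_nm) > min(ref$wavelength_nm) ||
      max(diff$wavelength_nm) < max(ref$wavelength_nm)) {
    if (max(diff$wavelength_nm) < min(ref$wavelength_nm) ||
        min(diff$wavelength_nm) > max(ref$wavelength_nm)) {
      stop("differential and reference spectra have disjoint wavelength ranges",
           call. = FALSE)
    }
    stop("differential spectrum does not cover the reference grid ",
         "(extrapolation is not allowed)", call. = FALSE)
  }
  d <- spectrum_at(diff, ref$wavelength_nm)
  v <- ref$value + d
  if (any(v < 0)) {
    warning("negative molar absorptivity clipped to zero at ",
            sum(v < 0), " grid point(s)")
    v <- pmax(v, 0)
  }
  spectrum(ref$wavelength_nm, v, kind = "molar_absorptivity",
           species = attr(diff, "species"))
}

#' Molar absorptivity of the radical dimer from differential absorbances
#'
#' Two radicals give one covalent dimer, so the dimer concentration is half
#' that of its radical precursor. The dimer coefficient at the bleaching
#' wavelength then follows from the ratio of the late (dimer) to early
#' (radical) differential absorbances:
#' `(eps_croc - eps_dimer/2) / (eps_croc - eps_radical) = ratio`, i.e.
#' `eps_dimer = 2 (eps_croc - ratio (eps_croc - eps_radical))`.
#'
#' @param eps_croc Parent crocin coefficient at the wavelength, M^-1 cm^-1.
#' @param eps_radical Radical coefficient at the same wavelength; must be
#'   below `eps_croc` (bleaching regime).
#' @param ratio Ratio of the differential absorbances, late / early (> 0).
#' @return Dimer molar absorption coefficient, M^-1 cm^-1; negative results
#'   are flagged with a warning (unphysical).
#' @examples
#' dimer_epsilon(1.35e5, 1.17e5, 0.43 / 0.18) # ~1.84e5
#' @export
dimer_epsilon <- function(eps_croc, eps_radical, ratio) {
  if (eps_croc <= eps_radical) {
    stop("eps_croc must exceed eps_radical (bleaching regime)", call. = FALSE)
  }
  if (ratio <= 0) stop("ratio must be > 0", call. = FALSE)
  out <- 2 * (eps_croc - ratio * (eps_croc - eps_radical))
  if (out < 0) warning("negative dimer molar absorptivity: unphysical inputs")
  out
}

# Inverse of dimer_epsilon, used for round-trip property checks.
dimer_ratio <- function(eps_croc, eps_radical, eps_dimer) {
  (eps_croc - eps_dimer / 2) / (eps_croc - eps_radical)
}

#' Locate isosbestic points in a family of spectra
#'
#' An isosbestic point is a wavelength where all members of a family of
#' spectra (e.g. spectra at increasing dose) take the same value, indicating
#' a 1:1 interconversion of two species. The across-family spread
#' (max - min) is computed per wavelength; wavelengths where it falls below
#' `tolerance` times the global maximum spread are flagged, and contiguous
#' runs are merged to the spread-minimizing wavelength.
#'
#' @param spectra List of [spectrum()] objects sharing one wavelength grid.
#' @param tolerance Relative spread threshold (default 0.01).
#' @return Numeric vector of isosbestic wavelengths (possibly empty). If all
#'   spectra are identical every wavelength is trivially isosbestic: an empty
#'   vector with attribute `degenerate = TRUE` is returned instead.
#' @export
find_isosbestic <- function(spectra, tolerance = 0.01) {
  if (length(spectra) < 2) stop("need at least two spectra", call. = FALSE)
  grids <- lapply(spectra, function(s) s$wavelength_nm)
  if (!all(vapply(grids[-1], function(g) identical(g, grids[[1]]), logical(1)))) {
    stop("spectra must share a common wavelength grid", call. = FALSE)
  }
  m <- vapply(spectra, function(s) s$value, numeric(length(grids[[1]])))
  spread <- apply(m, 1, function(v) max(v) - min(v))
  gmax <- max(spread)
  if (gmax == 0) {
    out <- numeric(0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  hit <- spread < tolerance * gmax
  if (!any(hit)) return(numeric(0))
  runs <- rle(hit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- numeric(0)
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    idx <- starts[i]:ends[i]
    out <- c(out, grids[[1]][idx[which.min(spread[idx])]])
  }
  out
}

#' Experimental consumption yield from a bleaching amplitude
#'
#' Converts an observed absorbance change at a given dose into a radiolytic
#' consumption yield via Beer-Lambert:
#' G = delta_A / (delta_eps * path * dose), with the dilute-water convention
#' 1 Gy = 1 J/L.
#'
#' @param delta_a Absorbance change (positive magnitude).
#' @param delta_eps Differential molar absorption coefficient (parent minus
#'   product), M^-1 cm^-1, > 0.
#' @param path_cm Optical path in cm, > 0.
#' @param dose_gy Absorbed dose in Gy, > 0.
#' @return Yield in mol/J.
#' @examples
#' g_exp_from_bleach(0.49, 1.24e5, 0.1, 97) # ~4.07e-7 mol/J
#' @export
g_exp_from_bleach <- function(delta_a, delta_eps, path_cm, dose_gy) {
  if (delta_eps <= 0 || path_cm <= 0 || dose_gy <= 0) {
    stop("delta_eps, path_cm and dose_gy must be > 0", call. = FALSE)
  }
  if (delta_a < 0) stop("delta_a must be >= 0 (use the magnitude)", call. = FALSE)
  delta_a / (delta_eps * path_cm * dose_gy)
}
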