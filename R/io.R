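# Plain-text file formats: delimited tables with `# key=value` metadata
# header lines, for kinetic traces, spectra and line lists.

read_metadata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    if (!grepl("=", kv)) next
    key <- trimws(sub("=.*$", "", kv))
    val <- trimws(sub("^[^=]*=", "", kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (is.na(num)) val else num
  }
  meta
}

#' Read / write a kinetic trace file
#'
#' Comma-delimited text with a `time_s,absorbance` header and metadata lines
#' `# wavelength_nm=...` and `# path_cm=...`.
#'
#' @param path File path.
#' @param trace A [kinetic_trace()] (for writing).
#' @return `read_trace()` returns a [kinetic_trace()]; `write_trace()`
#'   returns `path` invisibly.
#' @export
read_trace <- function(path) {
  meta <- read_metadata(path)
  if (is.null(meta$wavelength_nm) || is.null(meta$path_cm)) {
    stop("trace file must carry '# wavelength_nm=' and '# path_cm=' metadata",
         call. = FALSE)
  }
  d <- utils::read.csv(path, comment.char = "#")
  kinetic_trace(d$time_s, d$absorbance, meta$wavelength_nm, meta$path_cm)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# wavelength_nm=%.10g", attr(trace, "wavelength_nm")),
               sprintf("# path_cm=%.10g", attr(trace, "path_cm"))), con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' Read / write a spectrum file
#'
#' Comma-delimited text with a `wavelength_nm,value` header and metadata
#' lines `# kind=`, and optionally `# path_cm=`, `# dose_Gy=`, `# species=`.
#'
#' @param path File path.
#' @param spec A [spectrum()] (for writing).
#' @param dose_gy Optional dose metadata written alongside the spectrum.
#' @return `read_spectrum()` returns a [spectrum()] (with attribute
#'   `dose_gy` if present in the file); `write_spectrum()` returns `path`
#'   invisibly.
#' @export
read_spectrum <- function(path) {
  meta <- read_metadata(path)
  if (is.null(meta$kind)) {
    stop("spectrum file must carry '# kind=' metadata", call. = FALSE)
  }
  d <- utils::read.csv(path, comment.char = "#")
  s <- spectrum(d$wavelength_nm, d$value, kind = meta$kind,
                path_cm = meta$path_cm, species = meta$species)
  if (!is.null(meta$dose_Gy)) attr(s, "dose_gy") <- meta$dose_Gy
  s
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spec, path, dose_gy = NULL) {
  stopifnot(inherits(spec, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- sprintf("# kind=%s", attr(spec, "kind"))
  if (!is.null(attr(spec, "path_cm"))) {
    hdr <- c(hdr, sprintf("# path_cm=%.10g", attr(spec, "path_cm")))
  }
  if (!is.null(dose_gy)) hdr <- c(hdr, sprintf("# dose_Gy=%.10g", dose_gy))
  if (!is.null(attr(spec, "species"))) {
    hdr <- c(hdr, sprintf("# species=%s", attr(spec, "species")))
  }
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(spec), con, row.names = FALSE)
  invisible(path)
}

#' Read / write a line-list file
#'
#' Comma-delimited text with columns `config,energy_ev,osc_strength,s2` and
#' metadata lines `# ground_s2=`, `# total_steps=` (optional `# species=`).
#'
#' @param path File path.
#' @param ensemble A [line_ensemble()] (for writing).
#' @return `read_linelist()` returns a [line_ensemble()];
#'   `write_linelist()` returns `path` invisibly.
#' @export
read_linelist <- function(path) {
  meta <- read_metadata(path)
  if (is.null(meta$ground_s2)) {
    stop("line-list file must carry '# ground_s2=' metadata", call. = FALSE)
  }
  d <- utils::read.csv(path, comment.char = "#")
  line_ensemble(d, ground_s2 = meta$ground_s2, species = meta$species,
                total_steps = if (is.null(meta$total_steps)) NA_integer_
                              else as.integer(meta$total_steps))
}

#' @rdname read_linelist
#' @export
write_linelist <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "line_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- sprintf("# ground_s2=%.10g", ensemble$ground_s2)
  if (!is.na(ensemble$total_steps)) {
    hdr <- c(hdr, sprintf("# total_steps=%d", ensemble$total_steps))
  }
  if (!is.null(ensemble$species)) {
    hdr <- c(hdr, sprintf("# species=%s", ensemble$species))
  }
  writeLines(hdr, con)
  utils::write.csv(ensemble$lines, con, row.names = FALSE)
  invisible(path)
}
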