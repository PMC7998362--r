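#' Acquisition windows and mineral reference peaks
#'
#' Inner-shell spectra are recorded in three spectral windows covering
#' 380–880, 880–1380 and 1380–1880 cm\eqn{^{-1}}. Each window carries one
#' internal wavenumber reference from the shell's own mineral phase:
#' calcite at 703 cm\eqn{^{-1}} (window 1), aragonite at 1085
#' cm\eqn{^{-1}} (window 2) and carbonate at 1547 cm\eqn{^{-1}}
#' (window 3).
#'
#' @return `window_range()` returns a numeric length-2 vector; both
#'   `window_reference()` and `window_references()` return data on the
#'   reference mineral (name and nominal position).
#' @param window Window id, 1, 2 or 3.
#' @export
window_range <- function(window) {
  window <- check_window(window)
  list(c(380, 880), c(880, 1380), c(1380, 1880))[[window]]
}

#' @rdname window_range
#' @export
window_reference <- function(window) {
  window <- check_window(window)
  refs <- window_references()
  as.list(refs[refs$window == window, ])
}

#' @rdname window_range
#' @export
window_references <- function() {
  tibble::tibble(
    window   = 1:3,
    mineral  = c("calcite", "aragonite", "carbonate"),
    position = c(703, 1085, 1547)
  )
}

check_window <- function(window) {
  if (length(window) != 1L || !window %in% 1:3) {
    stop("`window` must be 1, 2 or 3", call. = FALSE)
  }
  as.integer(window)
}

#' Construct a Raman spectrum object
#'
#' A spectrum is one acquisition window of one measurement: a strictly
#' increasing wavenumber grid, the detector counts on that grid, the window
#' id and sample metadata.
#'
#' @param wavenumber Numeric vector of Raman shifts in cm^-1, strictly
#'   increasing.
#' @param intensity Numeric vector of detector counts, same length.
#' @param window Window id (1, 2 or 3).
#' @param sample_id Sample identifier string.
#' @param phenotype Optional phenotype label (e.g. "red", "albino").
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumber, intensity, window,
                           sample_id = "sample", phenotype = NA_character_) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity)) {
    stop("`wavenumber` and `intensity` must have equal length", call. = FALSE)
  }
  if (length(wavenumber) < 2L) {
    stop("a spectrum needs at least two points", call. = FALSE)
  }
  if (any(diff(wavenumber) <= 0)) {
    stop("`wavenumber` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(
      wavenumber = wavenumber,
      intensity = intensity,
      window = check_window(window),
      sample_id = as.character(sample_id),
      phenotype = as.character(phenotype)
    ),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf(
    "<raman_spectrum> sample %s (%s), window %d, %d points, %.1f-%.1f cm-1\n",
    x$sample_id, x$phenotype, x$window, length(x$wavenumber),
    min(x$wavenumber), max(x$wavenumber)
  ))
  invisible(x)
}

# Median grid step; grids are uniform in practice but interpolation-derived
# grids can carry floating-point jitter.
grid_step_of <- function(s) stats::median(diff(s$wavenumber))

#' Read and write two-column spectrum CSV files
#'
#' The on-disk format is a CSV with header `wavenumber_cm1,intensity`.
#' Window and sample metadata travel in a sidecar table (see
#' [write_cohort()]) or are supplied by the caller.
#'
#' @param path File path.
#' @param window,sample_id,phenotype Metadata attached to the returned
#'   spectrum.
#' @return `read_spectrum_csv()` returns a [raman_spectrum()];
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, window, sample_id = "sample",
                              phenotype = NA_character_) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wavenumber_cm1", "intensity")
  if (!all(need %in% names(tab))) {
    stop(sprintf(
      "spectrum file %s must have columns %s",
      path, paste(need, collapse = ", ")
    ), call. = FALSE)
  }
  raman_spectrum(tab$wavenumber_cm1, tab$intensity, window,
    sample_id = sample_id, phenotype = phenotype
  )
}

#' @rdname read_spectrum_csv
#' @param s A [raman_spectrum()].
#' @export
write_spectrum_csv <- function(s, path) {
  utils::write.csv(
    data.frame(wavenumber_cm1 = s$wavenumber, intensity = s$intensity),
    path,
    row.names = FALSE
  )
  invisible(path)
}
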