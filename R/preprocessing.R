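#' Preprocessing configuration
#'
#' @param smooth_width Odd number of points for the centred moving average
#'   (default 5, the "lightweight smoothing").
#' @param baseline_lambda Smoothness weight of the asymmetric-least-squares
#'   baseline (larger = stiffer baseline).
#' @param baseline_p Asymmetry weight in (0, 1); points above the running
#'   baseline estimate get this weight.
#' @param baseline_iters Reweighting iterations.
#' @param calib_halfwidth Half-width (cm^-1) of the search interval around
#'   the nominal mineral reference position.
#' @param order Order of the three stages; any permutation of
#'   `c("smooth", "baseline", "calibrate")`. Default smooths, subtracts the
#'   baseline, then calibrates.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(smooth_width = 5,
                              baseline_lambda = 1e5,
                              baseline_p = 0.01,
                              baseline_iters = 10,
                              calib_halfwidth = 20,
                              order = c("smooth", "baseline", "calibrate")) {
  if (smooth_width %% 2 != 1 || smooth_width < 1) {
    stop("`smooth_width` must be an odd integer >= 1", call. = FALSE)
  }
  if (!setequal(order, c("smooth", "baseline", "calibrate")) ||
      length(order) != 3L) {
    stop("`order` must be a permutation of smooth, baseline, calibrate",
         call. = FALSE)
  }
  structure(
    list(
      smooth_width = as.integer(smooth_width),
      baseline_lambda = baseline_lambda,
      baseline_p = baseline_p,
      baseline_iters = as.integer(baseline_iters),
      calib_halfwidth = calib_halfwidth,
      order = order
    ),
    class = "preprocess_config"
  )
}

#' Lightweight smoothing: centred moving average
#'
#' Centred moving average of odd width with symmetric (mirror) padding at
#' the edges, which preserves the total signal exactly.
#'
#' @param s A [raman_spectrum()].
#' @param width Odd window width in points, `1 <= width <= length`.
#' @return A smoothed [raman_spectrum()] on the same wavenumber grid.
#' @export
smooth_spectrum <- function(s, width = 5) {
  stopifnot(inherits(s, "raman_spectrum"))
  n <- length(s$intensity)
  if (width %% 2 != 1 || width < 1 || width > n) {
    stop("`width` must be odd and between 1 and the spectrum length",
         call. = FALSE)
  }
  if (width == 1) return(s)
  h <- (width - 1L) / 2L
  x <- s$intensity
  padded <- c(rev(x[seq_len(h)]), x, rev(x[(n - h + 1L):n]))
  sm <- as.numeric(stats::filter(padded, rep(1 / width, width),
                                 sides = 2))[(h + 1L):(h + n)]
  out <- s
  out$intensity <- sm
  out
}

#' Baseline subtraction by asymmetric least squares
#'
#' Iteratively reweighted Whittaker smoother: minimises
#' `sum(w * (y - z)^2) + lambda * sum(diff(z, d = 2)^2)` with asymmetric
#' weights (`p` for points above the baseline, `1 - p` below), so the
#' estimate hugs the lower envelope of the spectrum while staying smooth.
#' The corrected spectrum plus the returned baseline reconstructs the input
#' exactly.
#'
#' @param s A [raman_spectrum()].
#' @param lambda Smoothness weight.
#' @param p Asymmetry weight in (0, 1).
#' @param iters Reweighting iterations.
#' @return A list with `spectrum` (baseline-subtracted [raman_spectrum()])
#'   and `baseline` (numeric vector).
#' @export
subtract_baseline <- function(s, lambda = 1e5, p = 0.01, iters = 10) {
  stopifnot(inherits(s, "raman_spectrum"), p > 0, p < 1, lambda > 0)
  y <- s$intensity
  n <- length(y)
  d2 <- Matrix::bandSparse(n - 2L, n,
    k = 0:2,
    diagonals = list(rep(1, n - 2L), rep(-2, n - 2L), rep(1, n - 2L))
  )
  penalty <- lambda * Matrix::crossprod(d2)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(iters)) {
    lhs <- penalty + Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(lhs, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  out <- s
  out$intensity <- y - z
  list(spectrum = out, baseline = z)
}

# Parabolic apex refinement through the discrete maximum and its two
# neighbours; falls back to the grid point at spectrum edges or for a
# degenerate (flat) vertex.
refine_apex <- function(wavenumber, intensity, idx) {
  n <- length(intensity)
  if (idx <= 1L || idx >= n) {
    return(list(position = wavenumber[idx], value = intensity[idx]))
  }
  y1 <- intensity[idx - 1L]; y2 <- intensity[idx]; y3 <- intensity[idx + 1L]
  denom <- y1 - 2 * y2 + y3
  if (abs(denom) < .Machine$double.eps * max(1, abs(y2))) {
    return(list(position = wavenumber[idx], value = y2))
  }
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(min(delta, 0.5), -0.5)
  step <- wavenumber[idx + 1L] - wavenumber[idx]
  list(
    position = wavenumber[idx] + delta * step,
    value = y2 - 0.25 * (y1 - y3) * delta
  )
}

# Indices of strict local maxima; for plateaus the leftmost plateau point
# is reported. Endpoints are never maxima.
local_maxima_idx <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  d <- sign(diff(y))
  # back-fill zero slopes with the next nonzero slope so a plateau's class
  # is decided by how it ends
  nz <- d
  for (i in (n - 2L):1L) {
    if (nz[i] == 0) nz[i] <- nz[i + 1L]
  }
  which(d[-(n - 1L)] > 0 & nz[-1L] < 0) + 1L
}

#' Per-window wavenumber calibration against the mineral reference
#'
#' Finds the highest local maximum within `halfwidth` of the window's
#' nominal mineral reference position (calcite 703, aragonite 1085,
#' carbonate 1547 cm^-1), refines its apex by parabolic interpolation, and
#' rigidly shifts the wavenumber axis by `reference - observed` so the
#' reference apex lands on its nominal position.
#'
#' @param s A [raman_spectrum()] with its window id set.
#' @param halfwidth Search half-width in cm^-1.
#' @return A list with `spectrum` (calibrated) and `calibration`, a one-row
#'   tibble `window, mineral, reference, observed, offset`.
#' @export
calibrate_window <- function(s, halfwidth = 20) {
  stopifnot(inherits(s, "raman_spectrum"))
  ref <- window_reference(s$window)
  in_search <- which(
    s$wavenumber >= ref$position - halfwidth &
      s$wavenumber <= ref$position + halfwidth
  )
  maxima <- local_maxima_idx(s$intensity)
  maxima <- maxima[maxima %in% in_search]
  if (length(maxima) == 0L) {
    stop(sprintf(
      "calibration failure in window %d: no local maximum within [%g, %g] cm-1",
      s$window, ref$position - halfwidth, ref$position + halfwidth
    ), call. = FALSE)
  }
  best <- maxima[which.max(s$intensity[maxima])]
  apex <- refine_apex(s$wavenumber, s$intensity, best)
  offset <- ref$position - apex$position
  out <- s
  out$wavenumber <- s$wavenumber + offset
  list(
    spectrum = out,
    calibration = tibble::tibble(
      window = s$window,
      mineral = ref$mineral,
      reference = ref$position,
      observed = apex$position,
      offset = offset
    )
  )
}

#' Run the full preprocessing chain on one spectrum
#'
#' Applies smoothing, baseline subtraction and calibration in the order
#' given by the configuration (default smooth, baseline, calibrate).
#'
#' @param s A [raman_spectrum()].
#' @param config A [preprocess_config()].
#' @return A list with `spectrum` (fully preprocessed), `baseline` (numeric
#'   vector or NULL) and `calibration` (one-row tibble or NULL).
#' @export
preprocess_spectrum <- function(s, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  baseline <- NULL
  calibration <- NULL
  for (stage in config$order) {
    if (stage == "smooth") {
      s <- smooth_spectrum(s, config$smooth_width)
    } else if (stage == "baseline") {
      res <- subtract_baseline(s, config$baseline_lambda, config$baseline_p,
                               config$baseline_iters)
      s <- res$spectrum
      baseline <- res$baseline
    } else {
      res <- calibrate_window(s, config$calib_halfwidth)
      s <- res$spectrum
      calibration <- res$calibration
    }
  }
  list(spectrum = s, baseline = baseline, calibration = calibration)
}
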