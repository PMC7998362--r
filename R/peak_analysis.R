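#' Peak detection parameters
#'
#' Operational, reproducible counterpart of the visual three-way peak
#' screening: a peak is *clear* when its intensity reaches `snr_clear`
#' times the noise level, *putative* at `snr_putative` times, and *none*
#' below that.
#'
#' @param min_prominence Minimum prominence (counts) for a local maximum to
#'   be reported. `NULL` (default) means `snr_putative` times the noise
#'   estimate in force when peaks are detected.
#' @param snr_clear,snr_putative Signal-to-noise multipliers;
#'   `snr_clear > snr_putative > 0`.
#' @param local_window Half-width (cm^-1) of the neighbourhood in which the
#'   peak's lowest point is sought for the intensity measure.
#' @return A list of class `peak_params`.
#' @export
peak_params <- function(min_prominence = NULL, snr_clear = 5,
                        snr_putative = 3, local_window = 15) {
  if (!(snr_clear > snr_putative && snr_putative > 0)) {
    stop("need snr_clear > snr_putative > 0", call. = FALSE)
  }
  if (!is.null(min_prominence) && min_prominence < 0) {
    stop("`min_prominence` must be >= 0", call. = FALSE)
  }
  structure(
    list(
      min_prominence = min_prominence,
      snr_clear = snr_clear,
      snr_putative = snr_putative,
      local_window = local_window
    ),
    class = "peak_params"
  )
}

#' Robust noise estimate
#'
#' Scaled median absolute deviation of the first differences of the signal:
#' `mad(diff(y)) / sqrt(2)`. First-differencing removes peaks and baseline
#' (both locally smooth), leaving approximately the difference of two
#' independent noise draws. Estimate noise on the *raw* spectrum; smoothing
#' correlates neighbouring points and deflates this statistic.
#'
#' @param s A [raman_spectrum()].
#' @return Estimated noise standard deviation in counts.
#' @export
estimate_noise_sd <- function(s) {
  stopifnot(inherits(s, "raman_spectrum"))
  stats::mad(diff(s$intensity)) / sqrt(2)
}

# Prominence of the local maximum at index `idx`: apex height above the
# higher of the two key saddles, where each side's saddle is the minimum
# between the peak and the nearest strictly higher point (or the series
# edge if none exists).
peak_prominence <- function(y, idx) {
  apex <- y[idx]
  left_min <- apex
  j <- idx - 1L
  while (j >= 1L && y[j] <= apex) {
    if (y[j] < left_min) left_min <- y[j]
    j <- j - 1L
  }
  right_min <- apex
  j <- idx + 1L
  n <- length(y)
  while (j <= n && y[j] <= apex) {
    if (y[j] < right_min) right_min <- y[j]
    j <- j + 1L
  }
  apex - max(left_min, right_min)
}

#' Detect peaks in a preprocessed spectrum
#'
#' Finds all strict local maxima (leftmost point of a plateau), filters by
#' prominence, refines apex positions by parabolic interpolation, and
#' attaches the intensity measure used throughout the pipeline: apex counts
#' minus the lowest counts within `local_window` of the apex. Peaks are
#' classified clear/putative/none against `noise_sd` (see
#' [classify_peak()]).
#'
#' @param s A [raman_spectrum()], normally preprocessed.
#' @param params A [peak_params()].
#' @param noise_sd Noise level in counts; defaults to
#'   [estimate_noise_sd()] of `s`. Pass the raw-spectrum estimate when `s`
#'   has been smoothed.
#' @return A tibble sorted by position with columns `position`,
#'   `apex_value`, `local_min_value`, `intensity`, `prominence`,
#'   `classification`, `window`, `sample_id`.
#' @export
detect_peaks <- function(s, params = peak_params(),
                         noise_sd = estimate_noise_sd(s)) {
  stopifnot(inherits(s, "raman_spectrum"), inherits(params, "peak_params"))
  y <- s$intensity
  idx <- local_maxima_idx(y)
  min_prom <- params$min_prominence %||% (params$snr_putative * noise_sd)
  if (length(idx) > 0L) {
    prom <- vapply(idx, function(i) peak_prominence(y, i), 0)
    keep <- prom >= min_prom & prom > 0
    idx <- idx[keep]
    prom <- prom[keep]
  } else {
    prom <- numeric(0)
  }
  if (length(idx) == 0L) {
    return(empty_peak_table(s))
  }
  refined <- lapply(idx, function(i) refine_apex(s$wavenumber, y, i))
  position <- vapply(refined, `[[`, 0, "position")
  apex_value <- vapply(refined, `[[`, 0, "value")
  local_min_value <- vapply(seq_along(idx), function(k) {
    nb <- abs(s$wavenumber - position[k]) <= params$local_window
    min(y[nb])
  }, 0)
  intensity <- abs(apex_value - local_min_value)
  out <- tibble::tibble(
    position = position,
    apex_value = apex_value,
    local_min_value = local_min_value,
    intensity = intensity,
    prominence = prom,
    # a noise-free spectrum (estimate 0) makes every detected peak clear
    classification = if (is.finite(noise_sd) && noise_sd > 0) {
      classify_peak(intensity, noise_sd, params)
    } else {
      rep("clear", length(intensity))
    },
    window = s$window,
    sample_id = s$sample_id
  )
  out[order(out$position), ]
}

empty_peak_table <- function(s) {
  tibble::tibble(
    position = numeric(0), apex_value = numeric(0),
    local_min_value = numeric(0), intensity = numeric(0),
    prominence = numeric(0), classification = character(0),
    window = integer(0), sample_id = character(0)
  )
}

#' Classify peak intensities against the noise level
#'
#' @param intensity Peak intensity (counts); vectorised.
#' @param noise_sd Positive noise estimate (counts).
#' @param params A [peak_params()].
#' @return Character vector: "clear" if
#'   `intensity >= snr_clear * noise_sd`, "putative" if
#'   `>= snr_putative * noise_sd`, else "none".
#' @export
classify_peak <- function(intensity, noise_sd, params = peak_params()) {
  if (!is.finite(noise_sd) || noise_sd <= 0) {
    stop("`noise_sd` must be a positive finite number", call. = FALSE)
  }
  ifelse(intensity >= params$snr_clear * noise_sd, "clear",
    ifelse(intensity >= params$snr_putative * noise_sd, "putative", "none")
  )
}

#' Peak intensity at a given position
#'
#' The pipeline's intensity measure for the peak nearest `position`: the
#' apex value of the nearest local maximum minus the lowest value within
#' `local_window` cm^-1 of it, as an absolute difference (so overlapping
#' peaks are measured from their shared valley).
#'
#' @param s A [raman_spectrum()].
#' @param position Query position in cm^-1; must lie within the spectrum
#'   range.
#' @param local_window Half-width (cm^-1) for the local minimum.
#' @return Non-negative intensity in counts.
#' @export
peak_intensity <- function(s, position, local_window = 15) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (position < min(s$wavenumber) || position > max(s$wavenumber)) {
    stop("`position` lies outside the spectrum range", call. = FALSE)
  }
  idx <- local_maxima_idx(s$intensity)
  if (length(idx) == 0L) {
    stop("spectrum has no local maxima", call. = FALSE)
  }
  nearest <- idx[which.min(abs(s$wavenumber[idx] - position))]
  apex <- refine_apex(s$wavenumber, s$intensity, nearest)
  nb <- abs(s$wavenumber - apex$position) <= local_window
  abs(apex$value - min(s$intensity[nb]))
}

#' Ratio of a peak intensity to the reference peak intensity
#'
#' Normalises peak intensities across acquisitions by dividing by the
#' intensity of the mineral reference peak of the same spectrum.
#'
#' @param peak_intensity Peak intensity (counts).
#' @param reference_intensity Reference-peak intensity (counts), > 0.
#' @return Dimensionless ratio.
#' @export
intensity_ratio <- function(peak_intensity, reference_intensity) {
  if (any(!is.finite(reference_intensity) | reference_intensity <= 0)) {
    stop("`reference_intensity` must be > 0", call. = FALSE)
  }
  peak_intensity / reference_intensity
}
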