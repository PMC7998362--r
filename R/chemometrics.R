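#' Assemble a cohort spectra matrix
#'
#' Interpolates every sample's three windows onto a common per-window grid
#' (the overlap of all samples' coverage, at `grid_step`) and concatenates
#' the windows, giving one row per sample. PCA of raw spectra operates on
#' this matrix.
#'
#' @param samples List of samples, each a list with `sample_id`,
#'   `phenotype` and `spectra` (list of 3 [raman_spectrum()], one per
#'   window), as produced by [generate_cohort()] or [read_cohort()].
#' @param grid_step Common grid step in cm^-1.
#' @return An object of class `spectra_matrix`: list with `matrix`
#'   (samples x grid points), `grid` (tibble `window, wavenumber`) and
#'   `meta` (tibble `sample_id, phenotype`).
#' @export
build_spectra_matrix <- function(samples, grid_step = 1) {
  if (length(samples) < 2L) {
    stop("need at least two samples", call. = FALSE)
  }
  windows <- sort(unique(unlist(lapply(samples, function(smp) {
    vapply(smp$spectra, `[[`, 0L, "window")
  }))))
  grids <- list()
  for (w in windows) {
    los <- his <- numeric(0)
    for (smp in samples) {
      s <- spectrum_for_window(smp, w)
      los <- c(los, min(s$wavenumber))
      his <- c(his, max(s$wavenumber))
    }
    lo <- max(los); hi <- min(his)
    if (hi - lo < grid_step) {
      stop(sprintf("window %d: no overlapping wavenumber coverage", w),
           call. = FALSE)
    }
    grids[[as.character(w)]] <- seq(lo, hi, by = grid_step)
  }
  grid <- do.call(rbind, lapply(windows, function(w) {
    tibble::tibble(window = w, wavenumber = grids[[as.character(w)]])
  }))
  mat <- t(vapply(samples, function(smp) {
    unlist(lapply(windows, function(w) {
      s <- spectrum_for_window(smp, w)
      stats::approx(s$wavenumber, s$intensity,
                    xout = grids[[as.character(w)]])$y
    }))
  }, numeric(nrow(grid))))
  rownames(mat) <- vapply(samples, `[[`, "", "sample_id")
  structure(
    list(
      matrix = mat,
      grid = grid,
      meta = tibble::tibble(
        sample_id = vapply(samples, `[[`, "", "sample_id"),
        phenotype = vapply(samples, `[[`, "", "phenotype")
      )
    ),
    class = "spectra_matrix"
  )
}

spectrum_for_window <- function(smp, w) {
  for (s in smp$spectra) {
    if (s$window == w) return(s)
  }
  stop(sprintf("sample %s is missing window %d", smp$sample_id, w),
       call. = FALSE)
}

#' Principal component analysis of a spectra matrix
#'
#' Column-mean-centred PCA without variance scaling. For reproducible score
#' signs each loading vector is flipped so its largest-magnitude element is
#' positive.
#'
#' @param m A [build_spectra_matrix()] result, or a plain numeric matrix
#'   (rows = samples).
#' @param n_components Number of components,
#'   `<= min(nrow - 1, ncol)`.
#' @return A list of class `spectra_pca`: `scores` (tibble with sample_id,
#'   phenotype and PC columns), `explained_variance` (fractions, summing to
#'   <= 1), `loadings` (grid points x components, orthonormal columns) and
#'   `degenerate` (TRUE when the matrix has zero total variance, in which
#'   case scores are all zero and explained variance is NA).
#' @export
pca_scores <- function(m, n_components = 2) {
  if (inherits(m, "spectra_matrix")) {
    x <- m$matrix
    meta <- m$meta
  } else {
    x <- as.matrix(m)
    meta <- tibble::tibble(
      sample_id = rownames(x) %||% paste0("sample_", seq_len(nrow(x))),
      phenotype = NA_character_
    )
  }
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (n_components > kmax) {
    stop(sprintf("`n_components` must be <= %d", kmax), call. = FALSE)
  }
  centered <- sweep(x, 2, colMeans(x))
  total_var <- sum(centered^2)
  if (total_var < .Machine$double.eps * length(centered)) {
    scores <- matrix(0, nrow(x), n_components)
    colnames(scores) <- paste0("PC", seq_len(n_components))
    return(structure(list(
      scores = tibble::as_tibble(cbind(meta, tibble::as_tibble(scores))),
      explained_variance = rep(NA_real_, n_components),
      loadings = matrix(NA_real_, ncol(x), n_components),
      degenerate = TRUE
    ), class = "spectra_pca"))
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$rotation))
  loadings <- fit$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    v <- loadings[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2, flip, `*`)
  scores <- centered %*% loadings
  colnames(scores) <- paste0("PC", seq_len(k))
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(
    scores = tibble::as_tibble(cbind(meta, tibble::as_tibble(scores))),
    explained_variance = ev[seq_len(k)],
    loadings = loadings,
    degenerate = FALSE
  ), class = "spectra_pca")
}
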