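#' Pseudo-Voigt line shape
#'
#' Height-normalised pseudo-Voigt profile: a linear mix of a Lorentzian and
#' a Gaussian of common full width at half maximum. Solid-state Raman lines
#' are well approximated with a Lorentzian fraction around 0.7.
#'
#' @param x Evaluation points (cm^-1).
#' @param center Peak centre (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1), > 0.
#' @param eta Lorentzian fraction in `[0, 1]`.
#' @return Values in `[0, 1]`, equal to 1 at `center`.
#' @export
pseudo_voigt <- function(x, center, fwhm, eta = 0.7) {
  stopifnot(fwhm > 0, eta >= 0, eta <= 1)
  u <- (x - center) / (fwhm / 2)
  lor <- 1 / (1 + u^2)
  gau <- exp(-log(2) * u^2)
  eta * lor + (1 - eta) * gau
}

#' Synthetic measurement profile
#'
#' A profile describes one simulated individual: which pigments are present
#' and at what peak height, the mineral backbone heights, the fluorescence
#' baseline amplitude, the detector noise level, and a per-window rigid
#' wavenumber mis-calibration. Defaults emulate a shell spectrum whose
#' mineral lines dominate the pigment lines by roughly an order of
#' magnitude, with weak fluorescence and photon noise small relative to the
#' weakest planted pigment peak.
#'
#' @param phenotype One of red, yellow, green, black, albino.
#' @param pigment_heights Named numeric vector mapping pigment name to peak
#'   height in counts; every database peak of a planted pigment is generated
#'   at that height. Must be empty for the albino phenotype.
#' @param mineral_heights Named numeric vector with entries calcite,
#'   aragonite, carbonate (counts).
#' @param baseline_amplitude Amplitude of the smooth fluorescence baseline
#'   (counts).
#' @param noise_sd Standard deviation of additive i.i.d. Gaussian noise
#'   (counts), >= 0.
#' @param wavenumber_offset Rigid wavenumber offset per window (cm^-1);
#'   a scalar is recycled to all three windows.
#' @param fwhm Line width (FWHM, cm^-1) used for all generated peaks.
#' @param seed Integer seed; the window-`w` noise stream is seeded with
#'   `seed * 10 + w`, so keep seeds below ~2e8.
#' @return An object of class `spectrum_profile`.
#' @export
spectrum_profile <- function(phenotype,
                             pigment_heights = numeric(0),
                             mineral_heights = c(
                               calcite = 600, aragonite = 1000,
                               carbonate = 500
                             ),
                             baseline_amplitude = 200,
                             noise_sd = 2,
                             wavenumber_offset = 0,
                             fwhm = 8,
                             seed = 1L) {
  phenotype <- match.arg(phenotype,
                         c("red", "yellow", "green", "black", "albino"))
  pigment_heights <- unlist(pigment_heights)
  if (phenotype == "albino" && length(pigment_heights) > 0L) {
    stop("an albino profile must have no pigment heights", call. = FALSE)
  }
  if (length(pigment_heights) > 0L &&
      (is.null(names(pigment_heights)) || any(!nzchar(names(pigment_heights))))) {
    stop("`pigment_heights` must be a named vector", call. = FALSE)
  }
  if (any(pigment_heights <= 0)) {
    stop("pigment heights must be > 0", call. = FALSE)
  }
  need <- c("calcite", "aragonite", "carbonate")
  if (!all(need %in% names(mineral_heights))) {
    stop("`mineral_heights` needs calcite, aragonite and carbonate entries",
         call. = FALSE)
  }
  if (any(mineral_heights[need] <= 0)) {
    stop("mineral heights must be > 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (fwhm <= 0) stop("`fwhm` must be > 0", call. = FALSE)
  offset <- rep_len(as.numeric(wavenumber_offset), 3L)
  structure(
    list(
      phenotype = phenotype,
      pigment_heights = pigment_heights,
      mineral_heights = mineral_heights[need],
      baseline_amplitude = as.numeric(baseline_amplitude),
      noise_sd = as.numeric(noise_sd),
      wavenumber_offset = offset,
      fwhm = as.numeric(fwhm),
      seed = as.integer(seed)
    ),
    class = "spectrum_profile"
  )
}

# Smooth fluorescence-like baseline on the *nominal* grid: a broad Gaussian
# hump centred in the window plus a gentle linear tilt.
synthetic_baseline <- function(nominal, amplitude) {
  if (amplitude == 0) return(rep(0, length(nominal)))
  lo <- min(nominal); hi <- max(nominal)
  span <- hi - lo
  mid <- (lo + hi) / 2
  amplitude * exp(-((nominal - mid) / (0.45 * span))^2) +
    0.15 * amplitude * (nominal - lo) / span
}

# Planted peaks (mineral reference of the window + in-window database peaks
# of every planted pigment) on the nominal wavenumber axis.
planted_peaks_for_window <- function(profile, window, db) {
  rng <- window_range(window)
  ref <- window_reference(window)
  planted <- tibble::tibble(
    wavenumber = ref$position,
    height = unname(profile$mineral_heights[[ref$mineral]]),
    fwhm = profile$fwhm,
    pigment = "mineral"
  )
  if (length(profile$pigment_heights) > 0L) {
    db_norm <- normalize_pigment(db$pigment)
    for (pig in names(profile$pigment_heights)) {
      rows <- db_norm == normalize_pigment(pig)
      if (!any(rows)) {
        stop(sprintf("pigment '%s' is not in the signature database", pig),
             call. = FALSE)
      }
      wn <- db$wavenumber[rows]
      wn <- wn[wn >= rng[1] & wn <= rng[2]]
      if (length(wn) > 0L) {
        planted <- rbind(planted, tibble::tibble(
          wavenumber = wn,
          height = unname(profile$pigment_heights[[pig]]),
          fwhm = profile$fwhm,
          pigment = db$pigment[rows][1]
        ))
      }
    }
  }
  planted[order(planted$wavenumber), ]
}

#' Generate one synthetic spectrum window with ground truth
#'
#' The signal is the analytic sum of pseudo-Voigt peaks (the window's
#' mineral reference plus all in-window database peaks of each planted
#' pigment), a smooth baseline, and seeded Gaussian noise. A planted
#' wavenumber offset shifts the recorded wavenumber axis rigidly, emulating
#' instrument mis-calibration: a line whose true position is 703 cm^-1 is
#' recorded at 703 + offset.
#'
#' @param profile A [spectrum_profile()].
#' @param window Window id (1, 2 or 3).
#' @param db A [pigment_db()] supplying the planted pigment wavenumbers.
#' @param grid_step Wavenumber grid step in cm^-1.
#' @param sample_id Sample identifier stored in the spectrum.
#' @return A list with elements `spectrum` (a [raman_spectrum()]) and
#'   `truth` (a tibble of planted peaks: true wavenumber, height, fwhm,
#'   pigment, plus the window, offset and seed).
#' @export
generate_spectrum <- function(profile, window, db, grid_step = 1,
                              sample_id = profile$phenotype) {
  stopifnot(inherits(profile, "spectrum_profile"), grid_step > 0)
  window <- check_window(window)
  rng <- window_range(window)
  offset <- profile$wavenumber_offset[window]
  nominal <- seq(rng[1], rng[2], by = grid_step)
  recorded <- nominal + offset

  planted <- planted_peaks_for_window(profile, window, db)
  signal <- synthetic_baseline(nominal, profile$baseline_amplitude)
  for (i in seq_len(nrow(planted))) {
    signal <- signal + planted$height[i] *
      pseudo_voigt(nominal, planted$wavenumber[i], planted$fwhm[i])
  }
  if (profile$noise_sd > 0) {
    noise <- with_seed(profile$seed * 10L + window,
                       stats::rnorm(length(signal), 0, profile$noise_sd))
    signal <- signal + noise
  }

  truth <- planted
  truth$window <- window
  truth$offset <- offset
  truth$seed <- profile$seed
  list(
    spectrum = raman_spectrum(recorded, signal, window,
      sample_id = sample_id, phenotype = profile$phenotype
    ),
    truth = truth
  )
}

#' Generate a synthetic cohort (all three windows per individual)
#'
#' Replicate `r` of a profile reuses the profile with seed
#' `seed + (r - 1)`, so a cohort is fully determined by its profiles.
#'
#' @param profiles List of [spectrum_profile()] objects.
#' @param db A [pigment_db()].
#' @param replicates Individuals per profile, >= 1.
#' @param grid_step Wavenumber grid step in cm^-1.
#' @return A list of samples; each sample is a list with `sample_id`,
#'   `phenotype`, `spectra` (list of 3 [raman_spectrum()]) and `truth`
#'   (row-bound truth tibble across windows).
#' @export
generate_cohort <- function(profiles, db, replicates = 1, grid_step = 1) {
  stopifnot(replicates >= 1)
  if (inherits(profiles, "spectrum_profile")) profiles <- list(profiles)
  samples <- list()
  for (p in seq_along(profiles)) {
    for (r in seq_len(replicates)) {
      prof <- profiles[[p]]
      prof$seed <- prof$seed + (r - 1L)
      sid <- sprintf("%s_%02d_%02d", prof$phenotype, p, r)
      winres <- lapply(1:3, function(w) {
        generate_spectrum(prof, w, db, grid_step = grid_step, sample_id = sid)
      })
      samples[[length(samples) + 1L]] <- list(
        sample_id = sid,
        phenotype = prof$phenotype,
        spectra = lapply(winres, `[[`, "spectrum"),
        truth = do.call(rbind, lapply(winres, `[[`, "truth"))
      )
    }
  }
  samples
}

#' Write / read a synthetic cohort as plain-text CSV
#'
#' Spectra are written one CSV per sample per window
#' (`<sample_id>_w<window>.csv`, columns `wavenumber_cm1,intensity`) with a
#' sidecar `metadata.csv` (`sample_id,phenotype,window,seed,offset,file`)
#' and, when available, `truth.csv`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Directory to create/fill.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a list of samples in the [generate_cohort()] layout (without truth
#'   heights unless `truth.csv` is present).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list()
  for (smp in cohort) {
    for (s in smp$spectra) {
      f <- sprintf("%s_w%d.csv", smp$sample_id, s$window)
      write_spectrum_csv(s, file.path(dir, f))
      tr <- smp$truth[smp$truth$window == s$window, ]
      meta[[length(meta) + 1L]] <- data.frame(
        sample_id = smp$sample_id, phenotype = smp$phenotype,
        window = s$window,
        seed = if (nrow(tr) > 0) tr$seed[1] else NA_integer_,
        offset = if (nrow(tr) > 0) tr$offset[1] else NA_real_,
        file = f
      )
    }
  }
  if (all(vapply(cohort, function(x) !is.null(x$truth), TRUE))) {
    truth_all <- do.call(rbind, lapply(cohort, `[[`, "truth"))
    truth_all$sample_id <- rep(
      vapply(cohort, `[[`, "", "sample_id"),
      vapply(cohort, function(x) nrow(x$truth), 0L)
    )
    utils::write.csv(truth_all, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(do.call(rbind, meta), file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  ids <- unique(meta$sample_id)
  lapply(ids, function(sid) {
    rows <- meta[meta$sample_id == sid, ]
    rows <- rows[order(rows$window), ]
    spectra <- lapply(seq_len(nrow(rows)), function(i) {
      read_spectrum_csv(file.path(dir, rows$file[i]), rows$window[i],
        sample_id = sid, phenotype = rows$phenotype[i]
      )
    })
    list(
      sample_id = sid, phenotype = rows$phenotype[1],
      spectra = spectra, truth = NULL
    )
  })
}

#' Generate synthetic pairwise differential-expression tables
#'
#' Emulates DE summary tables for the three pairwise phenotype comparisons
#' (red vs yellow, red vs green, yellow vs green). Each planted
#' phenotype-associated gene is significant (adjusted p < 0.05) in both
#' comparisons involving its phenotype, with log2 fold changes whose signs
#' are consistent relative to that phenotype; all other (comparison, gene)
#' entries receive adjusted p >= 0.05 and small fold changes.
#'
#' @param n_genes Total genes per table.
#' @param planted Named list mapping phenotype (red/yellow/green) to
#'   `c(over = ..., under = ...)` counts of planted associated genes.
#' @param effect_size Magnitude of planted log2 fold changes.
#' @param seed Integer seed.
#' @return A list with `tables` (named list of three tibbles `gene_id,
#'   log2fc, pvalue, padj`, each carrying a `comparison` attribute, a
#'   length-2 character vector `c(A, B)` with log2fc meaning A relative to
#'   B) and `truth` (tibble `gene_id, phenotype, direction`).
#' @export
generate_deg_tables <- function(n_genes, planted = list(),
                                effect_size = 2, seed = 1L) {
  phenos <- c("red", "yellow", "green")
  comparisons <- list(
    red_vs_yellow = c("red", "yellow"),
    red_vs_green = c("red", "green"),
    yellow_vs_green = c("yellow", "green")
  )
  planted <- planted[intersect(names(planted), phenos)]
  counts <- vapply(planted, function(x) {
    sum(x[c("over", "under")], na.rm = TRUE)
  }, 0)
  n_planted <- sum(counts)
  if (n_planted > n_genes) {
    stop("more planted genes than `n_genes`", call. = FALSE)
  }

  gene_id <- sprintf("gene_%05d", seq_len(n_genes))
  truth <- tibble::tibble(
    gene_id = character(0), phenotype = character(0), direction = character(0)
  )
  k <- 0L
  for (p in names(planted)) {
    for (d in c("over", "under")) {
      nd <- planted[[p]][[d]] %||% 0
      if (is.na(nd) || nd == 0) next
      truth <- rbind(truth, tibble::tibble(
        gene_id = gene_id[k + seq_len(nd)], phenotype = p, direction = d
      ))
      k <- k + as.integer(nd)
    }
  }

  with_seed(seed, {
    tables <- lapply(names(comparisons), function(cmp_name) {
      ab <- comparisons[[cmp_name]]
      log2fc <- stats::rnorm(n_genes, 0, 0.3)
      padj <- stats::runif(n_genes, 0.05, 1)
      pvalue <- padj * stats::runif(n_genes, 0.2, 1)
      for (i in seq_len(nrow(truth))) {
        g <- match(truth$gene_id[i], gene_id)
        p <- truth$phenotype[i]
        if (!p %in% ab) next
        rel <- if (truth$direction[i] == "over") 1 else -1
        sgn <- if (p == ab[1]) rel else -rel
        log2fc[g] <- sgn * (effect_size + stats::runif(1, 0, 0.5))
        padj[g] <- stats::runif(1, 1e-6, 0.045)
        pvalue[g] <- padj[g] * stats::runif(1, 0.2, 1)
      }
      tab <- tibble::tibble(
        gene_id = gene_id, log2fc = log2fc, pvalue = pvalue, padj = padj
      )
      attr(tab, "comparison") <- ab
      tab
    })
    names(tables) <- names(comparisons)
    list(tables = tables, truth = truth)
  })
}
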