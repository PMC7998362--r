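#' Pipeline run configuration
#'
#' Defaults follow the analysis protocol where it states values (5-point
#' smoothing, mineral references 703/1085/1547 cm^-1, FDR alpha 0.05) and
#' documented choices elsewhere (matching tolerance 5 cm^-1, SNR
#' multipliers 5/3, in-window reference ratios).
#'
#' @param preprocess A [preprocess_config()].
#' @param peaks A [peak_params()].
#' @param tolerance Pigment-matching tolerance in cm^-1.
#' @param include_putative Admit putative peaks as matching evidence.
#' @param ratio_reference `"window"` (each window's own mineral reference
#'   peak) or `"calcite"` (the sample's window-1 calcite intensity for all
#'   windows).
#' @param pca_input `"raw"` (PCA directly on raw spectra, the default) or
#'   `"preprocessed"`.
#' @param n_components PCA components to report.
#' @param alpha FDR threshold for DE filtering.
#' @param seed Seed recorded in the run manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       peaks = peak_params(),
                       tolerance = 5,
                       include_putative = TRUE,
                       ratio_reference = c("window", "calcite"),
                       pca_input = c("raw", "preprocessed"),
                       n_components = 2,
                       alpha = 0.05,
                       seed = 1L) {
  structure(list(
    preprocess = preprocess,
    peaks = peaks,
    tolerance = tolerance,
    include_putative = include_putative,
    ratio_reference = match.arg(ratio_reference),
    pca_input = match.arg(pca_input),
    n_components = n_components,
    alpha = alpha,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Analyze one sample (three windows) end to end
#'
#' Per window: estimate the noise level on the raw spectrum, preprocess
#' (smooth, baseline-subtract, calibrate), detect and classify peaks, and
#' measure the mineral reference intensity. Peak intensities are then
#' normalised by the reference intensity (in-window reference by default,
#' or the sample's window-1 calcite) and the combined peak list is matched
#' against the signature database.
#'
#' @param sample A list with `sample_id`, `phenotype` and `spectra` (list
#'   of [raman_spectrum()], one per window 1-3).
#' @param db A [pigment_db()].
#' @param config A [run_config()].
#' @return An object of class `sample_report`: list with `sample_id`,
#'   `phenotype`, `calibration` (tibble, one row per window), `peaks`
#'   (combined tibble with `ratio` column), `matches`
#'   (a [match_pigments()] result), `n_clear`, `n_putative` and
#'   `noise_sd` (per-window estimates).
#' @export
analyze_sample <- function(sample, db, config = run_config()) {
  windows <- vapply(sample$spectra, `[[`, 0L, "window")
  missing_w <- setdiff(1:3, windows)
  if (length(missing_w) > 0L) {
    stop(sprintf("sample %s is missing window(s) %s", sample$sample_id,
                 paste(missing_w, collapse = ", ")), call. = FALSE)
  }
  calib <- list()
  peak_tabs <- list()
  ref_intensity <- numeric(3)
  noise <- numeric(3)
  for (w in 1:3) {
    s <- spectrum_for_window(sample, w)
    noise[w] <- estimate_noise_sd(s)
    pp <- preprocess_spectrum(s, config$preprocess)
    calib[[w]] <- pp$calibration
    pk <- detect_peaks(pp$spectrum, config$peaks, noise_sd = noise[w])
    ref <- window_reference(w)
    ref_intensity[w] <- peak_intensity(pp$spectrum, ref$position,
                                       config$peaks$local_window)
    peak_tabs[[w]] <- pk
  }
  for (w in 1:3) {
    denom <- switch(config$ratio_reference,
      window = ref_intensity[w],
      calcite = ref_intensity[1]
    )
    peak_tabs[[w]]$ratio <- intensity_ratio(peak_tabs[[w]]$intensity, denom)
  }
  peaks <- do.call(rbind, peak_tabs)
  matches <- match_pigments(peaks, db,
    tolerance = config$tolerance,
    include_putative = config$include_putative
  )
  structure(list(
    sample_id = sample$sample_id,
    phenotype = sample$phenotype,
    calibration = do.call(rbind, calib),
    peaks = peaks,
    matches = matches,
    n_clear = sum(peaks$classification == "clear"),
    n_putative = sum(peaks$classification == "putative"),
    noise_sd = noise
  ), class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("<sample_report> %s (%s): %d clear, %d putative peaks\n",
              x$sample_id, x$phenotype, x$n_clear, x$n_putative))
  print(x$matches$summary)
  invisible(x)
}

#' Run the full Raman identification pipeline on a cohort
#'
#' Analyzes every sample ([analyze_sample()]), aggregates the per-phenotype
#' pigment summary ([summarize_phenotype()]), and computes cohort PCA
#' scores on the raw (default) or preprocessed spectra. Samples whose
#' calibration fails are skipped with a warning and listed in the manifest.
#'
#' @param samples List of samples (see [generate_cohort()],
#'   [read_cohort()]).
#' @param db A [pigment_db()].
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, reports, the phenotype
#'   summary, PCA scores, calibration log and a run manifest are written as
#'   CSV/text files.
#' @return A list of class `raman_run`: `reports` (list of
#'   `sample_report`), `phenotype_summary`, `pca` (a [pca_scores()] result,
#'   or NULL for a single-sample cohort), `skipped` (sample ids) and
#'   `manifest`.
#' @export
run_raman <- function(samples, db, config = run_config(), out_dir = NULL) {
  reports <- list()
  skipped <- character(0)
  for (smp in samples) {
    res <- tryCatch(analyze_sample(smp, db, config), error = function(e) e)
    if (inherits(res, "error")) {
      if (grepl("missing window", conditionMessage(res))) stop(res)
      warning(sprintf("sample %s skipped: %s", smp$sample_id,
                      conditionMessage(res)), call. = FALSE)
      skipped <- c(skipped, smp$sample_id)
    } else {
      reports[[length(reports) + 1L]] <- res
    }
  }
  if (length(reports) == 0L) {
    stop("no sample could be analyzed", call. = FALSE)
  }
  summary_tab <- summarize_phenotype(reports)
  analyzed <- samples[!vapply(samples, `[[`, "", "sample_id") %in% skipped]
  pca <- NULL
  if (length(analyzed) >= 2L) {
    mat_input <- if (config$pca_input == "raw") {
      analyzed
    } else {
      lapply(seq_along(analyzed), function(i) {
        smp <- analyzed[[i]]
        smp$spectra <- lapply(smp$spectra, function(s) {
          preprocess_spectrum(s, config$preprocess)$spectrum
        })
        smp
      })
    }
    m <- build_spectra_matrix(mat_input)
    kmax <- min(nrow(m$matrix) - 1L, ncol(m$matrix))
    pca <- pca_scores(m, min(config$n_components, kmax))
  }
  manifest <- tibble::tibble(
    key = c("package_version", "seed", "tolerance", "ratio_reference",
            "pca_input", "smooth_width", "alpha", "n_samples", "skipped"),
    value = c(
      as.character(utils::packageVersion("shellraman")),
      as.character(config$seed), as.character(config$tolerance),
      config$ratio_reference, config$pca_input,
      as.character(config$preprocess$smooth_width),
      as.character(config$alpha), as.character(length(reports)),
      paste(skipped, collapse = ";")
    )
  )
  bundle <- structure(list(
    reports = reports,
    phenotype_summary = summary_tab,
    pca = pca,
    skipped = skipped,
    manifest = manifest
  ), class = "raman_run")
  if (!is.null(out_dir)) write_raman_run(bundle, out_dir)
  bundle
}

write_raman_run <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$phenotype_summary,
                   file.path(out_dir, "phenotype_summary.csv"),
                   row.names = FALSE)
  calib <- do.call(rbind, lapply(bundle$reports, function(r) {
    cbind(sample_id = r$sample_id, r$calibration)
  }))
  utils::write.csv(calib, file.path(out_dir, "calibration_log.csv"),
                   row.names = FALSE)
  peaks <- do.call(rbind, lapply(bundle$reports, `[[`, "peaks"))
  utils::write.csv(peaks, file.path(out_dir, "peaks.csv"), row.names = FALSE)
  matches <- do.call(rbind, lapply(bundle$reports, function(r) {
    m <- r$matches$matches
    if (nrow(m) == 0L) return(NULL)
    cbind(sample_id = r$sample_id, m)
  }))
  if (!is.null(matches)) {
    utils::write.csv(matches, file.path(out_dir, "matches.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$pca)) {
    utils::write.csv(bundle$pca$scores, file.path(out_dir, "pca_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(component = seq_along(bundle$pca$explained_variance),
                 explained_variance = bundle$pca$explained_variance),
      file.path(out_dir, "pca_explained_variance.csv"), row.names = FALSE
    )
  }
  utils::write.csv(bundle$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Run the DEG phenotype-association pipeline
#'
#' Filters the three pairwise DE tables at FDR < `alpha` and applies the
#' shared-DEG association rule.
#'
#' @param tables Named list of three DE tibbles with `comparison`
#'   attributes (see [read_deg_table()], [generate_deg_tables()]).
#' @param config A [run_config()]; only `alpha` is used.
#' @param out_dir Optional output directory for the per-phenotype gene
#'   sets and Venn-count table.
#' @return A list of class `deg_run`: `significant` (filtered tables),
#'   `association` (a [associate_phenotypes()] result) and `alpha`.
#' @export
run_deg <- function(tables, config = run_config(), out_dir = NULL) {
  if (length(tables) != 3L) {
    stop("`tables` must contain the three pairwise comparisons",
         call. = FALSE)
  }
  significant <- lapply(tables, filter_degs, alpha = config$alpha)
  association <- associate_phenotypes(significant)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(association$associations,
                     file.path(out_dir, "phenotype_gene_sets.csv"),
                     row.names = FALSE)
    utils::write.csv(association$venn,
                     file.path(out_dir, "venn_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(association$unshared,
                     file.path(out_dir, "unshared_degs.csv"),
                     row.names = FALSE)
  }
  structure(list(
    significant = significant,
    association = association,
    alpha = config$alpha
  ), class = "deg_run")
}
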