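#' Match detected peaks against the signature database
#'
#' For each pigment in the database, detected peaks (clear peaks, plus
#' putative ones when `include_putative` is TRUE) are assigned one-to-one
#' to that pigment's signature wavenumbers by greedy nearest-distance
#' matching: candidate (peak, record) pairs within `tolerance` are taken in
#' ascending order of absolute distance, skipping peaks or records already
#' used *for that pigment*. A peak may serve several pigments whose
#' signature wavenumbers coincide (e.g. 1402/1403), but never two records
#' of the same pigment. Pigments with no match are still reported
#' (`n_matched = 0`): absence of a peak is never evidence of absence of the
#' molecule, so the report counts evidence only.
#'
#' @param peaks Peak table as returned by [detect_peaks()] (rows from all
#'   three windows may be concatenated); an optional `ratio` column is
#'   carried through.
#' @param db A [pigment_db()].
#' @param tolerance Maximum |detected - database| distance in cm^-1.
#' @param include_putative Admit putative peaks as matchable evidence
#'   (default TRUE); clear peaks are always admitted.
#' @return An object of class `pigment_matches`: a list with `summary`
#'   (tibble `pigment, color_class, n_matched, n_total`, one row per
#'   database pigment in alphabetical order) and `matches` (tibble
#'   `pigment, db_wavenumber, detected_position, distance, intensity,
#'   ratio, classification, window`).
#' @export
match_pigments <- function(peaks, db, tolerance = 5, include_putative = TRUE) {
  stopifnot(inherits(db, "pigment_db"), tolerance > 0)
  admit <- c("clear", if (include_putative) "putative")
  peaks <- peaks[peaks$classification %in% admit, , drop = FALSE]
  if (!"ratio" %in% names(peaks)) peaks$ratio <- NA_real_
  if (!"window" %in% names(peaks)) peaks$window <- NA_integer_

  db_norm <- normalize_pigment(db$pigment)
  pigments <- unique(db_norm)
  display <- db$pigment[match(pigments, db_norm)]
  color <- db$color_class[match(pigments, db_norm)]

  matches <- list()
  n_matched <- integer(length(pigments))
  n_total <- integer(length(pigments))
  for (k in seq_along(pigments)) {
    wn <- db$wavenumber[db_norm == pigments[k]]
    n_total[k] <- length(wn)
    if (nrow(peaks) == 0L) next
    cand <- expand.grid(rec = seq_along(wn), pk = seq_len(nrow(peaks)))
    cand$dist <- abs(wn[cand$rec] - peaks$position[cand$pk])
    cand <- cand[cand$dist <= tolerance, , drop = FALSE]
    cand <- cand[order(cand$dist, cand$rec, cand$pk), , drop = FALSE]
    used_rec <- logical(length(wn))
    used_pk <- logical(nrow(peaks))
    for (i in seq_len(nrow(cand))) {
      r <- cand$rec[i]; q <- cand$pk[i]
      if (used_rec[r] || used_pk[q]) next
      used_rec[r] <- TRUE
      used_pk[q] <- TRUE
      matches[[length(matches) + 1L]] <- tibble::tibble(
        pigment = display[k],
        db_wavenumber = wn[r],
        detected_position = peaks$position[q],
        distance = cand$dist[i],
        intensity = peaks$intensity[q],
        ratio = peaks$ratio[q],
        classification = peaks$classification[q],
        window = peaks$window[q]
      )
    }
    n_matched[k] <- sum(used_rec)
  }

  ord <- order(display)
  structure(
    list(
      summary = tibble::tibble(
        pigment = display, color_class = color,
        n_matched = n_matched, n_total = n_total
      )[ord, ],
      matches = if (length(matches) > 0L) {
        do.call(rbind, matches)
      } else {
        tibble::tibble(
          pigment = character(0), db_wavenumber = numeric(0),
          detected_position = numeric(0), distance = numeric(0),
          intensity = numeric(0), ratio = numeric(0),
          classification = character(0), window = integer(0)
        )
      }
    ),
    class = "pigment_matches"
  )
}

#' @export
print.pigment_matches <- function(x, ...) {
  cat("<pigment_matches>\n")
  print(x$summary)
  invisible(x)
}

#' Aggregate sample reports into a per-phenotype pigment summary
#'
#' @param reports List of sample reports as produced by [analyze_sample()].
#' @return A tibble ordered by (phenotype, pigment) with, per pigment:
#'   number of individuals with at least one matched signature peak, mean
#'   matched-peak count, and the mean reference ratio over matched peaks
#'   (NA when nothing matched).
#' @export
summarize_phenotype <- function(reports) {
  if (length(reports) == 0L) {
    stop("`reports` must contain at least one sample report", call. = FALSE)
  }
  rows <- list()
  for (rep in reports) {
    summ <- rep$matches$summary
    det <- rep$matches$matches
    for (i in seq_len(nrow(summ))) {
      pig <- summ$pigment[i]
      ratios <- det$ratio[det$pigment == pig]
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = rep$phenotype,
        pigment = pig,
        n_matched = summ$n_matched[i],
        mean_ratio_sample = if (length(ratios) > 0L) {
          mean(ratios, na.rm = TRUE)
        } else {
          NA_real_
        }
      )
    }
  }
  long <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(
    split(long, list(long$phenotype, long$pigment), drop = TRUE),
    function(g) {
      data.frame(
        phenotype = g$phenotype[1],
        pigment = g$pigment[1],
        n_individuals_matched = sum(g$n_matched > 0),
        mean_n_matched = mean(g$n_matched),
        mean_ratio = if (all(is.na(g$mean_ratio_sample))) {
          NA_real_
        } else {
          mean(g$mean_ratio_sample, na.rm = TRUE)
        }
      )
    }
  ))
  agg <- agg[order(agg$phenotype, agg$pigment), ]
  rownames(agg) <- NULL
  tibble::as_tibble(agg)
}
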