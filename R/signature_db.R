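#' Pigment signature databases
#'
#' A signature database is the searchable inventory of literature-reported
#' Raman peaks: one row per (pigment, wavenumber) pair, with the pigment's
#' colour class and the source reference. Detected peaks are matched against
#' it by [match_pigments()].
#'
#' @param records A data frame with columns `pigment`, `color_class`,
#'   `wavenumber`, `citation`.
#' @param provenance Free-text description of where the records come from.
#' @return A tibble of class `pigment_db` with a `provenance` attribute.
#'   Row order is preserved.
#' @details Validation enforces: non-empty pigment names; wavenumbers within
#'   the instrument's 300–1800 cm^-1 range; colour class one of red, yellow,
#'   green, black, other; and uniqueness of (pigment, wavenumber) pairs
#'   (pigment names compared case-insensitively with whitespace collapsed).
#' @export
pigment_db <- function(records, provenance = "") {
  need <- c("pigment", "color_class", "wavenumber", "citation")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0L) {
    stop(sprintf(
      "signature database is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  records <- tibble::as_tibble(records)[, need]
  records$pigment <- as.character(records$pigment)
  records$color_class <- as.character(records$color_class)
  records$wavenumber <- as.numeric(records$wavenumber)
  records$citation <- as.character(records$citation)

  if (nrow(records) > 0L) {
    if (any(is.na(records$pigment) | !nzchar(trimws(records$pigment)))) {
      bad <- which(is.na(records$pigment) | !nzchar(trimws(records$pigment)))
      stop(sprintf("empty pigment name in row(s) %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    out_of_range <- which(
      is.na(records$wavenumber) |
        records$wavenumber < 300 | records$wavenumber > 1800
    )
    if (length(out_of_range) > 0L) {
      stop(sprintf(
        "wavenumber outside [300, 1800] cm-1 in row(s) %s",
        paste(out_of_range, collapse = ", ")
      ), call. = FALSE)
    }
    classes <- c("red", "yellow", "green", "black", "other")
    bad_class <- which(!records$color_class %in% classes)
    if (length(bad_class) > 0L) {
      stop(sprintf(
        "color_class must be one of %s (row(s) %s)",
        paste(classes, collapse = ", "), paste(bad_class, collapse = ", ")
      ), call. = FALSE)
    }
    key <- paste(normalize_pigment(records$pigment), records$wavenumber)
    dup <- which(duplicated(key))
    if (length(dup) > 0L) {
      stop(sprintf(
        "duplicate (pigment, wavenumber) pair(s) in row(s) %s",
        paste(dup, collapse = ", ")
      ), call. = FALSE)
    }
  }
  structure(records,
    provenance = as.character(provenance),
    class = c("pigment_db", class(records))
  )
}

#' @rdname pigment_db
#' @param path Path to a CSV file with header
#'   `pigment,color_class,wavenumber,citation` (UTF-8, wavenumber in decimal
#'   cm^-1).
#' @export
read_pigment_db <- function(path, provenance = path) {
  if (!file.exists(path)) {
    stop(sprintf("no such file: %s", path), call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                         colClasses = "character")
  pigment_db(tab, provenance = provenance)
}

#' @rdname pigment_db
#' @param db A `pigment_db`.
#' @export
write_pigment_db <- function(db, path) {
  utils::write.csv(as.data.frame(db), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Packaged 40-peak signature inventory
#'
#' The nine-pigment, 40-peak inventory of signature peaks observed in
#' red, yellow and green pearl-oyster inner shells: uroporphyrin I (3
#' peaks), copper-uroporphyrin (6), FeIII-uroporphyrin (6), biliverdin (4),
#' cobalamin (2), xanthine (8), pheomelanin (4), bilirubin (2) and
#' melanin/eumelanin (5). "Uroporphyrin I or III" is stored under the single
#' name `uroporphyrin I`; the citation notes the ambiguity. The CSV schema
#' accepts arbitrarily larger user-supplied databases.
#'
#' @return A [pigment_db()] with 40 records.
#' @export
signature_db_table2 <- function() {
  path <- system.file("extdata", "table2_pigment_signatures.csv",
    package = "shellraman", mustWork = TRUE
  )
  read_pigment_db(path,
    provenance = "packaged 40-peak inner-shell pigment signature inventory"
  )
}

#' Count database peaks for one pigment
#'
#' @param db A [pigment_db()].
#' @param pigment Pigment name; matched exactly after case folding and
#'   whitespace collapsing. An unknown pigment yields 0.
#' @return Non-negative integer count.
#' @export
count_pigment_peaks <- function(db, pigment) {
  sum(normalize_pigment(db$pigment) == normalize_pigment(pigment))
}
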