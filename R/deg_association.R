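#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values (a validated
#' wrapper around `stats::p.adjust(method = "BH")`).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    stop("all p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Read a pairwise differential-expression table
#'
#' @param path CSV with columns `gene_id, log2fc, padj` and optionally
#'   `pvalue`.
#' @param comparison Length-2 character vector `c(A, B)`; `log2fc` is the
#'   fold change of A relative to B.
#' @return A tibble carrying a `comparison` attribute.
#' @export
read_deg_table <- function(path, comparison) {
  stopifnot(length(comparison) == 2L)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(tab))) {
    stop(sprintf("DE table %s must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  tab <- tibble::as_tibble(tab)
  attr(tab, "comparison") <- as.character(comparison)
  tab
}

#' Filter DE records at an FDR threshold
#'
#' Keeps records with adjusted p strictly below `alpha` (FDR < alpha),
#' preserving input order and the `comparison` attribute.
#'
#' @param records A DE tibble with a `padj` column.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return The significant subset.
#' @export
filter_degs <- function(records, alpha = 0.05) {
  if (!(alpha > 0 && alpha <= 1)) {
    stop("`alpha` must be in (0, 1]", call. = FALSE)
  }
  out <- records[!is.na(records$padj) & records$padj < alpha, , drop = FALSE]
  attr(out, "comparison") <- attr(records, "comparison")
  out
}

#' Associate shared DEGs with colour phenotypes
#'
#' Implements the shared-pairwise-DEG rule: a gene is associated with
#' phenotype P when it is significant in *both* pairwise comparisons
#' involving P and its fold changes, re-signed so that positive means
#' higher in P, agree in sign. The shared sign classifies the gene as over-
#' or under-represented in P. Genes significant in only one comparison are
#' reported as unshared; genes whose two P-relative signs disagree are
#' excluded from P and flagged; genes significant in all three comparisons
#' may be attributed to several phenotypes and are flagged as ambiguous.
#'
#' @param tables Named list of three significant-record tibbles (e.g. from
#'   [filter_degs()]), each with columns `gene_id, log2fc, padj` and a
#'   `comparison` attribute `c(A, B)` covering the three pairs among red,
#'   yellow and green.
#' @param require_consistent_sign Require sign agreement across the two
#'   comparisons (default TRUE; FALSE attributes any gene shared between
#'   both of P's comparisons to P, classified by its mean P-relative sign).
#' @return An object of class `phenotype_association`: list with
#'   `associations` (tibble `phenotype, gene_id, direction,
#'   mean_log2fc_rel`), `venn` (tibble `phenotype, comparison_1,
#'   comparison_2, n_shared, n_over, n_under`), `unshared` (tibble
#'   `gene_id, comparison`), `inconsistent` and `ambiguous` gene-id
#'   vectors.
#' @export
associate_phenotypes <- function(tables, require_consistent_sign = TRUE) {
  comps <- lapply(tables, attr, "comparison")
  if (any(vapply(comps, is.null, TRUE))) {
    stop("every table needs a `comparison` attribute", call. = FALSE)
  }
  pair_key <- vapply(comps, function(ab) {
    paste(sort(ab), collapse = "|")
  }, "")
  want <- c("green|red", "red|yellow", "green|yellow")
  if (!setequal(pair_key, want)) {
    stop("`tables` must cover the three pairwise comparisons among red, yellow and green",
         call. = FALSE)
  }

  phenos <- c("red", "yellow", "green")
  sig_in <- lapply(seq_along(tables), function(i) tables[[i]]$gene_id)
  n_sig <- table(unlist(sig_in))
  ambiguous <- names(n_sig)[n_sig == 3L]

  # P-relative log2fc of gene g in table i (NA when not significant there)
  rel_fc <- function(i, p) {
    ab <- comps[[i]]
    s <- if (p == ab[1]) 1 else -1
    stats::setNames(s * tables[[i]]$log2fc, tables[[i]]$gene_id)
  }

  assoc <- list()
  venn <- list()
  inconsistent <- character(0)
  for (p in phenos) {
    involved <- which(vapply(comps, function(ab) p %in% ab, TRUE))
    stopifnot(length(involved) == 2L)
    fc1 <- rel_fc(involved[1], p)
    fc2 <- rel_fc(involved[2], p)
    shared <- intersect(names(fc1), names(fc2))
    n_over <- n_under <- 0L
    for (g in shared) {
      consistent <- sign(fc1[[g]]) == sign(fc2[[g]])
      if (require_consistent_sign && !consistent) {
        inconsistent <- union(inconsistent, g)
        next
      }
      m <- mean(c(fc1[[g]], fc2[[g]]))
      dir <- if (m > 0) "over" else "under"
      if (dir == "over") n_over <- n_over + 1L else n_under <- n_under + 1L
      assoc[[length(assoc) + 1L]] <- data.frame(
        phenotype = p, gene_id = g, direction = dir, mean_log2fc_rel = m
      )
    }
    venn[[length(venn) + 1L]] <- data.frame(
      phenotype = p,
      comparison_1 = paste(comps[[involved[1]]], collapse = "_vs_"),
      comparison_2 = paste(comps[[involved[2]]], collapse = "_vs_"),
      n_shared = n_over + n_under,
      n_over = n_over,
      n_under = n_under
    )
  }

  all_sig <- unlist(sig_in)
  once <- names(n_sig)[n_sig == 1L]
  unshared <- do.call(rbind, lapply(seq_along(tables), function(i) {
    g <- intersect(tables[[i]]$gene_id, once)
    if (length(g) == 0L) return(NULL)
    data.frame(gene_id = g,
               comparison = paste(comps[[i]], collapse = "_vs_"))
  })) %||% data.frame(gene_id = character(0), comparison = character(0))

  associations <- if (length(assoc) > 0L) {
    tibble::as_tibble(do.call(rbind, assoc))
  } else {
    tibble::tibble(phenotype = character(0), gene_id = character(0),
                   direction = character(0), mean_log2fc_rel = numeric(0))
  }
  associations <- associations[order(associations$phenotype,
                                     associations$gene_id), ]
  structure(list(
    associations = associations,
    venn = tibble::as_tibble(do.call(rbind, venn)),
    unshared = tibble::as_tibble(unshared[order(unshared$gene_id), ]),
    inconsistent = sort(inconsistent),
    ambiguous = sort(ambiguous)
  ), class = "phenotype_association")
}

#' @export
print.phenotype_association <- function(x, ...) {
  cat("<phenotype_association>\n")
  print(x$venn)
  invisible(x)
}
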