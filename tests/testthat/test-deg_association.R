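test_that("BH adjustment matches hand-worked and boundary cases", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.01)), "\\[0, 1\\]")
})

test_that("BH adjustment equals the step-up definition on random vectors", {
  set.seed(99)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, brute_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= 0 & adj <= 1))
    # monotone: adjusted order follows raw order
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("FDR filtering uses a strict threshold and preserves order", {
  tab <- tibble::tibble(
    gene_id = c("a", "b", "c"), log2fc = 1,
    padj = c(0.04, 0.05, 0.06)
  )
  attr(tab, "comparison") <- c("red", "yellow")
  kept <- filter_degs(tab, 0.05)
  expect_equal(kept$gene_id, "a")
  expect_equal(attr(kept, "comparison"), c("red", "yellow"))
  expect_equal(nrow(filter_degs(tab[0, ], 0.05)), 0L)
  expect_equal(filter_degs(tab, 1.0)$gene_id, c("a", "b", "c"))
  expect_error(filter_degs(tab, 0), "alpha")
})

sig_tables <- function(rows_ry, rows_rg, rows_yg) {
  mk <- function(rows, ab) {
    tab <- tibble::as_tibble(rows)
    attr(tab, "comparison") <- ab
    tab
  }
  list(
    red_vs_yellow = mk(rows_ry, c("red", "yellow")),
    red_vs_green = mk(rows_rg, c("red", "green")),
    yellow_vs_green = mk(rows_yg, c("yellow", "green"))
  )
}

row0 <- data.frame(gene_id = character(0), log2fc = numeric(0),
                   padj = numeric(0))

test_that("the shared-DEG rule assigns genes by comparison pair and sign", {
  tabs <- sig_tables(
    data.frame(gene_id = "g1", log2fc = 2, padj = 0.01),
    data.frame(gene_id = "g1", log2fc = 2, padj = 0.02),
    data.frame(gene_id = "g2", log2fc = -1, padj = 0.01)
  )
  res <- associate_phenotypes(tabs)
  expect_equal(res$associations$gene_id, "g1")
  expect_equal(res$associations$phenotype, "red")
  expect_equal(res$associations$direction, "over")
  # g2 significant in a single comparison: unshared, not associated
  expect_equal(res$unshared$gene_id, "g2")
  venn <- res$venn
  expect_equal(venn$n_shared[venn$phenotype == "red"], 1L)
  expect_equal(sum(venn$n_shared), 1L)
})

test_that("inconsistent directions exclude a gene from the phenotype", {
  tabs <- sig_tables(
    data.frame(gene_id = "g1", log2fc = 2, padj = 0.01),
    data.frame(gene_id = "g1", log2fc = -2, padj = 0.01),
    row0
  )
  res <- associate_phenotypes(tabs)
  expect_equal(nrow(res$associations), 0L)
  expect_equal(res$inconsistent, "g1")
  relaxed <- associate_phenotypes(tabs, require_consistent_sign = FALSE)
  expect_equal(relaxed$associations$gene_id, "g1")
})

test_that("under-representation is read relative to the phenotype", {
  # higher in yellow than red, and higher in yellow than green:
  # yellow-associated, over-represented
  tabs <- sig_tables(
    data.frame(gene_id = "g1", log2fc = -2.5, padj = 0.01),
    row0,
    data.frame(gene_id = "g1", log2fc = 2.2, padj = 0.01)
  )
  res <- associate_phenotypes(tabs)
  expect_equal(res$associations$phenotype, "yellow")
  expect_equal(res$associations$direction, "over")
  expect_gt(res$associations$mean_log2fc_rel, 0)
})

test_that("genes significant in all three comparisons are flagged ambiguous", {
  tabs <- sig_tables(
    data.frame(gene_id = "g1", log2fc = 2, padj = 0.01),
    data.frame(gene_id = "g1", log2fc = 2, padj = 0.01),
    data.frame(gene_id = "g1", log2fc = 2, padj = 0.01)
  )
  res <- associate_phenotypes(tabs)
  expect_equal(res$ambiguous, "g1")
  # red: +2, +2 consistent -> red-associated over; yellow: -2 (ry), +2 (yg)
  # inconsistent... direction handling still yields at most one set per
  # consistent pair
  expect_true("red" %in% res$associations$phenotype)
})

test_that("planted phenotype associations are recovered exactly across seeds", {
  for (seed in 1:20) {
    res <- generate_deg_tables(
      300,
      planted = list(red = c(over = 3, under = 2),
                     yellow = c(over = 1, under = 4),
                     green = c(over = 10, under = 9)),
      seed = seed
    )
    sig <- lapply(res$tables, filter_degs, alpha = 0.05)
    assoc <- associate_phenotypes(sig)
    got <- assoc$associations
    for (p in c("red", "yellow", "green")) {
      truth_p <- res$truth[res$truth$phenotype == p, ]
      got_p <- got[got$phenotype == p, ]
      expect_setequal(got_p$gene_id, truth_p$gene_id)
      expect_equal(
        sort(got_p$gene_id[got_p$direction == "over"]),
        sort(truth_p$gene_id[truth_p$direction == "over"])
      )
    }
    expect_equal(nrow(assoc$unshared), 0L)
    expect_equal(length(assoc$ambiguous), 0L)
  }
})
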