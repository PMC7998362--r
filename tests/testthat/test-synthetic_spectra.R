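test_that("generation is deterministic given seed and parameters", {
  db <- table2_db()
  prof <- spectrum_profile("red", pigment_heights = c("uroporphyrin I" = 60),
                           seed = 42)
  a <- generate_spectrum(prof, 3, db)
  b <- generate_spectrum(prof, 3, db)
  expect_identical(a$spectrum$intensity, b$spectrum$intensity)
  expect_identical(a$truth, b$truth)
  prof2 <- prof
  prof2$seed <- 43L
  c <- generate_spectrum(prof2, 3, db)
  expect_false(identical(a$spectrum$intensity, c$spectrum$intensity))
})

test_that("noise-free, baseline-free signal equals the analytic peak sum", {
  db <- table2_db()
  prof <- spectrum_profile("green",
    pigment_heights = c(biliverdin = 40, cobalamin = 25),
    baseline_amplitude = 0, noise_sd = 0, seed = 7
  )
  g <- generate_spectrum(prof, 3, db)
  tr <- g$truth
  expected <- analytic_signal(
    g$spectrum$wavenumber - tr$offset[1],
    tr$wavenumber, tr$height, tr$fwhm[1]
  )
  expect_equal(g$spectrum$intensity, expected, tolerance = 1e-12)
})

test_that("albino window-2 spectrum peaks at the aragonite reference", {
  db <- table2_db()
  prof <- spectrum_profile("albino", baseline_amplitude = 0, noise_sd = 0)
  g <- generate_spectrum(prof, 2, db)
  expect_equal(g$spectrum$wavenumber[which.max(g$spectrum$intensity)], 1085)
})

test_that("a single mineral peak is constructed at its stated height", {
  db <- table2_db()
  prof <- spectrum_profile("albino",
    mineral_heights = c(calcite = 77, aragonite = 1, carbonate = 1),
    baseline_amplitude = 0, noise_sd = 0
  )
  g <- generate_spectrum(prof, 1, db)
  i <- which.max(g$spectrum$intensity)
  expect_equal(g$spectrum$wavenumber[i], 703, tolerance = 1)
  expect_equal(g$spectrum$intensity[i], 77, tolerance = 1e-9)
})

test_that("truth lists every planted peak inside its shifted window", {
  db <- table2_db()
  prof <- spectrum_profile("yellow",
    pigment_heights = c(pheomelanin = 50, xanthine = 30),
    wavenumber_offset = c(3, -2, 5), seed = 9
  )
  for (w in 1:3) {
    g <- generate_spectrum(prof, w, db)
    rng <- window_range(w)
    expect_true(all(g$truth$wavenumber >= rng[1] &
                      g$truth$wavenumber <= rng[2]))
    shifted <- g$truth$wavenumber + g$truth$offset
    expect_true(all(shifted >= min(g$spectrum$wavenumber) &
                      shifted <= max(g$spectrum$wavenumber)))
    planted_pigments <- setdiff(unique(g$truth$pigment), "mineral")
    db_in_window <- db$wavenumber >= rng[1] & db$wavenumber <= rng[2]
    for (pig in planted_pigments) {
      expect_setequal(
        g$truth$wavenumber[g$truth$pigment == pig],
        db$wavenumber[db$pigment == pig & db_in_window]
      )
    }
  }
})

test_that("unknown pigments are rejected", {
  db <- table2_db()
  prof <- spectrum_profile("red", pigment_heights = c(unknownium = 10))
  expect_error(generate_spectrum(prof, 1, db), "unknownium")
})

test_that("cohorts have one sample per profile x replicate with 3 windows", {
  db <- table2_db()
  profiles <- lapply(c("red", "yellow", "green", "black", "albino"),
                     function(p) {
    heights <- switch(p,
      red = c("uroporphyrin I" = 50), yellow = c(pheomelanin = 50),
      green = c(biliverdin = 50), black = c(melanin = 50), NULL
    )
    spectrum_profile(p, pigment_heights = heights, seed = 100)
  })
  cohort <- generate_cohort(profiles, db, replicates = 3)
  expect_length(cohort, 15L)
  expect_true(all(vapply(cohort, function(s) length(s$spectra) == 3L, TRUE)))
  cohort2 <- generate_cohort(profiles, db, replicates = 3)
  expect_identical(
    lapply(cohort, function(s) lapply(s$spectra, `[[`, "intensity")),
    lapply(cohort2, function(s) lapply(s$spectra, `[[`, "intensity"))
  )
  # replicates differ through their derived seeds
  expect_false(identical(cohort[[1]]$spectra[[1]]$intensity,
                         cohort[[2]]$spectra[[1]]$intensity))
})

test_that("cohorts round-trip through the on-disk CSV layout", {
  db <- table2_db()
  prof <- spectrum_profile("red", pigment_heights = c("uroporphyrin I" = 50),
                           seed = 2)
  cohort <- generate_cohort(list(prof), db, replicates = 2)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_length(back, 2L)
  expect_equal(back[[1]]$sample_id, cohort[[1]]$sample_id)
  expect_equal(back[[1]]$spectra[[2]]$intensity,
               cohort[[1]]$spectra[[2]]$intensity)
  expect_equal(back[[2]]$phenotype, "red")
})

test_that("synthetic DE tables plant associations with the promised structure", {
  res <- generate_deg_tables(200, planted = list(red = c(over = 2, under = 1)),
                             seed = 4)
  expect_named(res$tables, c("red_vs_yellow", "red_vs_green",
                             "yellow_vs_green"))
  expect_equal(nrow(res$truth), 3L)
  for (g in res$truth$gene_id) {
    ry <- res$tables$red_vs_yellow
    rg <- res$tables$red_vs_green
    yg <- res$tables$yellow_vs_green
    expect_lt(ry$padj[ry$gene_id == g], 0.05)
    expect_lt(rg$padj[rg$gene_id == g], 0.05)
    expect_gte(yg$padj[yg$gene_id == g], 0.05)
    expect_equal(sign(ry$log2fc[ry$gene_id == g]),
                 sign(rg$log2fc[rg$gene_id == g]))
  }
  dir <- res$truth$direction[res$truth$gene_id == res$truth$gene_id[1]]
  # over-represented in red means positive log2fc in red-vs-* tables
  over_gene <- res$truth$gene_id[res$truth$direction == "over"][1]
  expect_gt(res$tables$red_vs_yellow$log2fc[
    res$tables$red_vs_yellow$gene_id == over_gene], 0)
  # non-planted genes stay non-significant everywhere
  bg <- setdiff(res$tables$red_vs_yellow$gene_id, res$truth$gene_id)
  for (tab in res$tables) {
    expect_true(all(tab$padj[tab$gene_id %in% bg] >= 0.05))
  }
})

test_that("an empty planting yields no significant genes", {
  res <- generate_deg_tables(50, planted = list(), seed = 1)
  expect_equal(nrow(res$truth), 0L)
  for (tab in res$tables) expect_true(all(tab$padj >= 0.05))
})
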