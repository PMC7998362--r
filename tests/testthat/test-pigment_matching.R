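make_peaks <- function(positions, classification = "clear") {
  tibble::tibble(
    position = positions,
    apex_value = 100, local_min_value = 0, intensity = 100,
    prominence = 100,
    classification = rep_len(classification, length(positions)),
    window = NA_integer_, sample_id = "s", ratio = NA_real_
  )
}

test_that("no detected peaks means zero matches for every pigment", {
  db <- table2_db()
  res <- match_pigments(make_peaks(numeric(0)), db)
  expect_equal(nrow(res$summary), 9L)
  expect_true(all(res$summary$n_matched == 0L))
  expect_equal(sort(res$summary$n_total),
               sort(c(3L, 6L, 6L, 4L, 2L, 4L, 8L, 2L, 5L)))
})

test_that("peaks at 862 and 870 match xanthine 2/8 and nothing else", {
  db <- table2_db()
  res <- match_pigments(make_peaks(c(862.3, 869.8)), db, tolerance = 5)
  summ <- res$summary
  expect_equal(summ$n_matched[summ$pigment == "xanthine"], 2L)
  expect_true(all(summ$n_matched[summ$pigment != "xanthine"] == 0L))
  # brute-force pairing oracle over all peak-record pairs
  expect_equal(
    brute_assignment_count(db$wavenumber[db$pigment == "xanthine"],
                           c(862.3, 869.8), 5),
    2
  )
})

test_that("putative peaks are admitted only when requested", {
  db <- table2_db()
  pks <- make_peaks(c(692, 1294), classification = c("clear", "putative"))
  with_put <- match_pigments(pks, db, include_putative = TRUE)
  without <- match_pigments(pks, db, include_putative = FALSE)
  bili <- function(r) r$summary$n_matched[r$summary$pigment == "bilirubin"]
  expect_equal(bili(with_put), 2L)
  expect_equal(bili(without), 1L)
})

test_that("match counts grow monotonically with tolerance", {
  db <- table2_db()
  pks <- make_peaks(c(505, 864, 1147, 1299, 1490.5, 1517))
  totals <- vapply(c(0.5, 1, 2, 5, 10), function(tol) {
    sum(match_pigments(pks, db, tolerance = tol)$summary$n_matched)
  }, 0L)
  expect_true(all(diff(totals) >= 0))
})

test_that("one peak serves at most one record per pigment but may cross pigments", {
  db <- table2_db()
  # single peak between the pheomelanin 1488/1490 pair and the FeIII 1489 line
  res <- match_pigments(make_peaks(1489), db, tolerance = 5)
  summ <- res$summary
  expect_equal(summ$n_matched[summ$pigment == "pheomelanin"], 1L)
  expect_equal(summ$n_matched[summ$pigment == "FeIII-uroporphyrin"], 1L)
  m <- res$matches
  expect_equal(sum(m$pigment == "pheomelanin"), 1L)
})

test_that("greedy assignment attains the optimal match count on small instances", {
  db <- table2_db()
  set.seed(31)
  for (rep_i in 1:25) {
    pig <- sample(unique(db$pigment), 1)
    wn <- db$wavenumber[db$pigment == pig]
    wn <- wn[seq_len(min(6, length(wn)))]
    n_pk <- sample(0:5, 1)
    positions <- sort(runif(n_pk, min(wn) - 12, max(wn) + 12))
    sub <- pigment_db(tibble::tibble(
      pigment = pig, color_class = "other", wavenumber = wn, citation = "x"
    ))
    got <- match_pigments(make_peaks(positions), sub, tolerance = 5)
    expect_equal(
      got$summary$n_matched[got$summary$pigment == pig],
      brute_assignment_count(wn, positions, 5),
      info = sprintf("instance %d (%s)", rep_i, pig)
    )
  }
})

test_that("phenotype summaries aggregate sample evidence deterministically", {
  db <- table2_db()
  cfg <- run_config()
  mk_sample <- function(prof, id) {
    list(sample_id = id, phenotype = prof$phenotype,
         spectra = lapply(1:3, function(w) {
           generate_spectrum(prof, w, db, sample_id = id)$spectrum
         }))
  }
  albino <- lapply(1:3, function(i) {
    mk_sample(spectrum_profile("albino", seed = 20 + i), paste0("alb", i))
  })
  reports <- lapply(albino, analyze_sample, db = db, config = cfg)
  summ <- summarize_phenotype(reports)
  expect_true(all(summ$n_individuals_matched == 0L))
  expect_true(all(summ$mean_n_matched == 0))

  # identical reports average to the single-report value
  rep1 <- reports[[1]]
  same <- summarize_phenotype(list(rep1, rep1, rep1))
  one <- summarize_phenotype(list(rep1))
  expect_equal(same$mean_n_matched, one$mean_n_matched)

  expect_error(summarize_phenotype(list()), "at least one")
})

test_that("a red cohort shows stronger uroporphyrin than xanthine evidence", {
  db <- table2_db()
  prof <- spectrum_profile("red",
    pigment_heights = c("uroporphyrin I" = 120, "copper-uroporphyrin" = 100,
                        xanthine = 25),
    noise_sd = 4, seed = 50
  )
  cohort <- generate_cohort(list(prof), db, replicates = 3)
  reports <- lapply(cohort, analyze_sample, db = db)
  summ <- summarize_phenotype(reports)
  uro <- summ$mean_n_matched[summ$pigment == "uroporphyrin I"]
  xan <- summ$mean_n_matched[summ$pigment == "xanthine"]
  expect_gte(uro / 3, xan / 8) # matched fraction of the signature
})
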