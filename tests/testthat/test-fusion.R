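test_that("expected ratios reproduce the diploid-vs-fusion arithmetic", {
  expect_equal(expected_ratio(3, FALSE), 1.5)
  expect_equal(expected_ratio(1, FALSE), 0.5)
  expect_equal(expected_ratio(3, TRUE), 1.25)
  expect_equal(expected_ratio(1, TRUE), 0.75)
  expect_equal(expected_ratio(2, FALSE), 1.0)
  expect_equal(expected_ratio(2, TRUE), 1.0)
  expect_equal(expected_ratio(0:4, TRUE), c(0.5, 0.75, 1, 1.25, 1.5))
  expect_error(expected_ratio(-1), ">= 0")
})

test_that("fusing with an all-zero partner leaves the ratio profile unchanged", {
  g <- test_genome(n_bins = 400)
  tum <- simulate_counts(g$truth, g$bm, sim_config(total_reads = 2e5, seed = 1))
  zero <- manual_cell(rep(0, 400), g$bm)
  expect_equal(synthesize_fusion_profile(tum, zero, g$bm)$ratio,
               bin_ratio_profile(tum, g$bm)$ratio)
})

test_that("attenuation is ~1 for the reference cell, ~0.5 for a fusion, ~0 for a WBC", {
  g <- test_genome(n_bins = 800)
  cfg <- sim_config(total_reads = 1e6, exact = TRUE)
  tum <- simulate_counts(g$truth, g$bm, cfg, cell_id = "tumor")
  wbc <- simulate_counts(make_truth_profile(g$bm, list()), g$bm, cfg,
                         cell_id = "wbc", cell_type = "WBC")
  ref <- truth_segments(g$truth, g$bm)

  self <- attenuation_statistic(bin_ratio_profile(tum, g$bm), ref)
  expect_equal(self$attenuation, 1, tolerance = 0.03)
  expect_equal(self$verdict, "non-fusion-consistent")

  fus <- attenuation_statistic(synthesize_fusion_profile(tum, wbc, g$bm), ref)
  expect_equal(fus$attenuation, 0.5, tolerance = 0.03)
  expect_equal(fus$verdict, "fusion-consistent")

  pure <- attenuation_statistic(bin_ratio_profile(wbc, g$bm), ref)
  expect_equal(pure$attenuation, 0, tolerance = 0.03)
})

test_that("attenuation is invariant to global rescaling of the query", {
  g <- test_genome(n_bins = 800)
  ref <- truth_segments(g$truth, g$bm)
  set.seed(5)
  q <- expected_ratios(g$truth) + rnorm(800, 0, 0.05)
  a1 <- attenuation_statistic(ratio_profile(q, chrom = as.character(g$bm$chrom)), ref)
  a2 <- attenuation_statistic(ratio_profile(3.7 * q, chrom = as.character(g$bm$chrom)), ref)
  expect_equal(a1$attenuation, a2$attenuation, tolerance = 1e-12)
})

test_that("attenuation decreases as the diploid read fraction grows, as 1 - w", {
  g <- test_genome(n_bins = 800)
  ref <- truth_segments(g$truth, g$bm)
  diploid <- make_truth_profile(g$bm, list())
  total <- 1e6
  a <- vapply(c(0, 0.25, 0.5), function(w) {
    tum <- simulate_counts(g$truth, g$bm,
      sim_config(total_reads = total * (1 - w), exact = TRUE))
    mixed <- if (w == 0) tum else fuse_counts(tum,
      simulate_counts(diploid, g$bm,
        sim_config(total_reads = total * w, exact = TRUE)))
    attenuation_statistic(bin_ratio_profile(mixed, g$bm), ref)$attenuation
  }, 0)
  expect_true(all(diff(a) < 0))
  expect_equal(a, 1 - c(0, 0.25, 0.5), tolerance = 0.04)
})

test_that("too few informative bins gives an uninformative verdict", {
  g <- test_genome(n_bins = 800)
  ref <- truth_segments(g$truth, g$bm)
  prof <- ratio_profile(expected_ratios(g$truth), chrom = as.character(g$bm$chrom))
  res <- attenuation_statistic(prof, ref, min_informative = 1e6)
  expect_equal(res$verdict, "uninformative")
  expect_true(is.na(res$attenuation))
  # a reference with no non-neutral segments is uninformative too
  flat_ref <- truth_segments(make_truth_profile(g$bm, list()), g$bm)
  flat_ref <- call_states(flat_ref)
  expect_equal(attenuation_statistic(prof, flat_ref)$verdict, "uninformative")
})

test_that("clonal events are detected across cells and controls stay unflagged", {
  g <- test_genome(n_bins = 800)
  clone_seg <- truth_segments(g$truth, g$bm)
  wbc_seg <- truth_segments(make_truth_profile(g$bm, list()), g$bm)

  cells <- c(
    stats::setNames(rep(list(clone_seg), 10), paste0("ctc", 1:10)),
    stats::setNames(rep(list(wbc_seg), 4), paste0("wbc", 1:4))
  )
  rep1 <- detect_clonal_events(cells)
  n_events <- sum(clone_seg$state != 2)
  expect_equal(sum(rep1$events$clonal), n_events)
  ctc_rows <- rep1$cells[grepl("^ctc", rep1$cells$cell_id), ]
  wbc_rows <- rep1$cells[grepl("^wbc", rep1$cells$cell_id), ]
  expect_true(all(ctc_rows$clonal))
  expect_equal(ctc_rows$n_clonal_events_carried, rep(n_events, 10))
  expect_true(all(!wbc_rows$clonal))
  expect_true(all(wbc_rows$n_clonal_events_carried == 0))

  # order invariance
  rep2 <- detect_clonal_events(rev(cells))
  expect_equal(rep1$events, rep2$events)
  expect_equal(rep1$cells[order(rep1$cells$cell_id), ],
               rep2$cells[order(rep2$cells$cell_id), ],
               ignore_attr = TRUE)
})

test_that("cells with only private losses produce no clonal events", {
  g <- test_genome(n_bins = 800)
  # nine cells, each with at most a private loss on its own chromosome
  cells <- lapply(1:9, function(i) {
    ev <- if (i <= 2) list(cna_event(paste0("chr", i), 1, 10, 1L)) else list()
    truth_segments(make_truth_profile(g$bm, ev), g$bm)
  })
  names(cells) <- paste0("cand", 1:9)
  rep <- detect_clonal_events(cells)
  expect_equal(sum(rep$events$clonal), 0)
  expect_true(all(!rep$cells$clonal))
  expect_error(detect_clonal_events(cells[1]), "at least 2")
})
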