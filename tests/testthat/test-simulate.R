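test_that("truth profiles start diploid and apply events with overwrite", {
  g <- test_genome()
  base <- make_truth_profile(g$bm, list())
  expect_true(all(base$state == 2L))

  truth <- g$truth
  chr16 <- ctcfusion:::chrom_bins(g$bm, "chr16")
  cut <- floor(0.45 * length(chr16))
  expect_true(all(truth$state[chr16[1:cut]] == 3L))              # 16p gain
  expect_true(all(truth$state[chr16[(cut + 1):length(chr16)]] == 1L))  # 16q loss
  q4 <- ctcfusion:::chrom_bins(g$bm, "chr4", arm = "q")
  expect_true(all(truth$state[q4] == 1L))
  # firestorm: >= 4 alternating state changes on chr8
  chr8 <- ctcfusion:::chrom_bins(g$bm, "chr8")
  runs <- rle(truth$state[chr8])
  expect_gte(sum(runs$values != 2L), 4)

  # later events overwrite earlier ones
  over <- make_truth_profile(g$bm, list(
    cna_event("chr2", 1, 20, 3L), cna_event("chr2", 10, 30, 1L)
  ))
  chr2 <- ctcfusion:::chrom_bins(g$bm, "chr2")
  expect_true(all(over$state[chr2[10:30]] == 1L))
  expect_true(all(over$state[chr2[1:9]] == 3L))

  expect_error(make_truth_profile(g$bm, list(cna_event("chr2", 1, 1e6, 1L))),
               "out of range")
})

test_that("simulated counts match the closed-form expectation at dispersion 0", {
  bm <- equal_bin_map(50, len = 1e5)
  truth <- make_truth_profile(bm, list())
  total <- 5e4
  reps <- 1000
  means <- rowMeans(vapply(seq_len(reps), function(i) {
    simulate_counts(truth, bm, sim_config(total_reads = total, seed = i))$counts
  }, numeric(50)))
  expect_true(all(abs(means - total / 50) / (total / 50) < 0.02))
})

test_that("a one-copy gain yields a 3:2 mean count ratio over replicates", {
  bm <- equal_bin_map(100, len = 1e5)
  truth <- make_truth_profile(bm, list(cna_event("chr1", 1, 50, 3L)))
  ratios <- vapply(1:200, function(i) {
    cts <- simulate_counts(truth, bm, sim_config(total_reads = 2e5, seed = i))$counts
    mean(cts[1:50]) / mean(cts[51:100])
  }, 0)
  expect_equal(mean(ratios), 1.5, tolerance = 0.02)
})

test_that("count simulation is deterministic per seed and validates input", {
  g <- test_genome(n_bins = 200)
  cfg <- sim_config(total_reads = 1e5, dispersion = 0.1, seed = 99)
  a <- simulate_counts(g$truth, g$bm, cfg)
  b <- simulate_counts(g$truth, g$bm, cfg)
  expect_identical(a$counts, b$counts)
  zero <- make_truth_profile(g$bm, list(), baseline_ploidy = 0L)
  expect_error(simulate_counts(zero, g$bm, cfg), "all-zero")
  expect_error(sim_config(dispersion = -1), ">= 0")
  expect_error(sim_config(total_reads = 0), "positive")
})

test_that("fusing counts is an elementwise, commutative sum recording parents", {
  g <- test_genome(n_bins = 300)
  cfg <- sim_config(total_reads = 1e5, seed = 1)
  tum <- simulate_counts(g$truth, g$bm, cfg, cell_id = "tum")
  wbc <- simulate_counts(make_truth_profile(g$bm, list()), g$bm,
                         sim_config(total_reads = 1e5, seed = 2),
                         cell_id = "wbc", cell_type = "WBC")
  fused <- fuse_counts(tum, wbc)
  expect_equal(fused$counts, tum$counts + wbc$counts)
  expect_setequal(fused$parents, c("tum", "wbc"))
  expect_equal(fuse_counts(wbc, tum)$counts, fused$counts)
  # identity under an all-zero partner
  zero <- manual_cell(rep(0, nrow(g$bm)), g$bm)
  expect_equal(fuse_counts(tum, zero)$counts, tum$counts)
  # mismatched maps refused
  other <- make_bin_map(300, 16, seed = 77)
  tum2 <- simulate_counts(make_truth_profile(other, list()), other, cfg)
  expect_error(fuse_counts(tum, tum2), "different bin maps")
})

test_that("feature tables honor population fractions exactly and are seeded", {
  pops <- list(
    bg = list(fraction = 0.9, ck_mean = 100, ck_sd = 10,
              cd45_mean = 400, cd45_sd = 60),
    dp = list(fraction = 0.075, ck_mean = 300, ck_sd = 20,
              cd45_mean = 400, cd45_sd = 60),
    sp = list(fraction = 0.025, ck_mean = 300, ck_sd = 20,
              cd45_mean = 50, cd45_sd = 15)
  )
  tbl <- simulate_feature_table(400, pops, seed = 3)
  expect_equal(as.vector(table(tbl$label)[c("bg", "dp", "sp")]), c(360, 30, 10))
  expect_true(all(tbl$ck >= 0 & tbl$cd45 >= 0))
  expect_identical(tbl, simulate_feature_table(400, pops, seed = 3))
  expect_equal(nrow(simulate_feature_table(0, pops, seed = 1)), 0)
  pops$bg$fraction <- 0.5
  expect_error(simulate_feature_table(10, pops, seed = 1), "sum to 1")
  expect_error(simulate_feature_table(10, list(), seed = 1), "empty")
})

test_that("ion count tables plant QC failures exactly and respect noise mode", {
  pops <- imc_populations_default(n_per_pop = c(50, 40, 30, 20, 30, 20, 10))
  tbl <- simulate_ion_counts(pops, frac_fail_area = 0.1, frac_fail_dna1 = 0.05,
                             seed = 4)
  n <- nrow(tbl)
  expect_equal(n, 200)
  expect_equal(sum(tbl$qc_fail == "area"), round(0.1 * n))
  expect_equal(sum(tbl$qc_fail == "dna1"), round(0.05 * n))
  expect_true(all(tbl$area[tbl$qc_fail == "area"] < 40))
  expect_true(all(tbl$DNA1[tbl$qc_fail == "dna1"] < 4))
  expect_true(all(as.matrix(tbl[, imc_marker_panel()]) >= 0))
  expect_identical(tbl, simulate_ion_counts(pops, frac_fail_area = 0.1,
                                            frac_fail_dna1 = 0.05, seed = 4))

  one <- simulate_ion_counts(list(only = list(n = 5, means = pops[[1]]$means)),
                             noise = "none", seed = 1)
  mat <- as.matrix(one[, imc_marker_panel()])
  expect_true(all(apply(mat, 2, function(col) length(unique(col)) == 1)))

  bad <- pops
  bad[[1]]$n <- -1
  expect_error(simulate_ion_counts(bad), "negative")
})
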