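test_that("mask filtering applies inclusive area bounds and the DNA1 floor", {
  tbl <- data.frame(
    cell_id = paste0("m", 1:6),
    area = c(39, 40, 200, 201, 100, 100),
    DNA1 = c(10, 10, 10, 10, 3.999, 4)
  )
  kept <- filter_masks(tbl)
  expect_equal(kept$area, c(40, 200, 100))
  expect_equal(kept$DNA1, c(10, 10, 4))
  # idempotent
  expect_equal(filter_masks(kept), kept)
  # empty in, empty out
  expect_equal(nrow(filter_masks(tbl[0, ])), 0)
  expect_error(filter_masks(data.frame(x = 1)), "area")
})

test_that("pre-identified CTC masks bypass the QC filter", {
  pops <- imc_populations_default(n_per_pop = c(30, 20, 20, 10, 20, 15, 5))
  tbl <- simulate_ion_counts(pops, frac_fail_area = 0.2, seed = 6)
  is_ctc <- tbl$population %in% c("im.CTC", "epi.CTC")
  kept <- filter_masks(tbl, bypass = is_ctc)
  expect_equal(sum(kept$population %in% c("im.CTC", "epi.CTC")), sum(is_ctc))
  # without bypass, exactly the planted passes remain
  plain <- filter_masks(tbl)
  expect_equal(nrow(plain), sum(tbl$qc_fail == "none"))
})

test_that("arcsinh transform has its closed form and monotonicity", {
  expect_equal(arcsinh_transform(0), 0)
  expect_equal(arcsinh_transform(1, cofactor = 1), log(1 + sqrt(2)),
               tolerance = 1e-9)
  x <- seq(0, 50, by = 0.5)
  expect_true(all(diff(arcsinh_transform(x, 5)) > 0))
  expect_error(arcsinh_transform(1, cofactor = 0), "positive")
})

test_that("percentile normalization divides by the interpolated percentile", {
  tbl <- data.frame(a = rep(4, 100), b = 1:100, c = rep(0, 100))
  attr(tbl, "markers") <- c("a", "b", "c")
  norm <- percentile_normalize(tbl, p = 99)
  expect_equal(norm$a, rep(1, 100))
  expect_equal(norm$b, (1:100) / 99.01)
  expect_gt(max(norm$b), 1)  # no clipping
  expect_equal(norm$c, rep(0, 100))
  expect_equal(attr(norm, "unscaled_markers"), "c")
  expect_error(percentile_normalize(tbl[0, ]), "empty")
  expect_error(percentile_normalize(tbl, p = 0), "in \\(0, 100\\]")
})

test_that("graph clustering separates well-separated populations exactly", {
  skip_if_not_installed("mclust")
  set.seed(17)
  X <- rbind(
    matrix(rnorm(500 * 3, 0, 1), ncol = 3),
    matrix(rnorm(500 * 3, 10, 1), ncol = 3)
  )
  tbl <- as.data.frame(X)
  attr(tbl, "markers") <- names(tbl)
  labels <- cluster_graph(tbl, k_neighbors = 30, seed = 1)
  truth <- rep(1:2, each = 500)
  expect_equal(mclust::adjustedRandIndex(labels, truth), 1)
  # determinism
  expect_identical(labels, cluster_graph(tbl, k_neighbors = 30, seed = 1))
  # single tight population collapses to one cluster
  one <- as.data.frame(matrix(rnorm(200 * 3, 0, 1e-4), ncol = 3))
  attr(one, "markers") <- names(one)
  expect_equal(length(unique(cluster_graph(one, k_neighbors = 20, seed = 1))), 1)
  expect_error(cluster_graph(one, k_neighbors = 200), "< number of cells")
})

test_that("hierarchical gating assigns lineages and honors exclusion markers", {
  gates <- default_gate_tree()
  mk <- function(...) {
    row <- stats::setNames(as.list(rep(0, 22)), imc_marker_panel())
    over <- list(...)
    row[names(over)] <- over
    as.data.frame(row)
  }
  cells <- rbind(
    mk(CD45 = 60, CD3 = 40, CD4 = 30),              # CD4 T
    mk(CD45 = 60, CD3 = 40, CD8a = 30),             # CD8 T
    mk(CD45 = 55, CD20 = 35),                       # B
    mk(CD45 = 50, CD56 = 30),                       # NK
    mk(CD45 = 50, CD14 = 35, CD68 = 25),            # monocyte
    mk(CD45 = 55, CD3 = 35, CD4 = 35, CK8 = 40, CK18 = 40),  # CK+ excluded
    mk()                                            # all zero
  )
  got <- apply_gates(cells, gates)
  expect_equal(got, c("CD4 T", "CD8 T", "B", "NK", "monocyte", "CK+", "ungated"))
  expect_error(apply_gates(cells[, 1:3], gates), "missing from table")
  cyc <- list(
    list(name = "a", parent = "b", rules = list()),
    list(name = "b", parent = "a", rules = list())
  )
  expect_error(gate_tree(cyc), "cycle")
})

test_that("gate trees round-trip through YAML", {
  gates <- default_gate_tree()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_gate_tree(gates, path)
  back <- read_gate_tree(path)
  tbl <- simulate_ion_counts(imc_populations_default(
    n_per_pop = c(40, 30, 20, 10, 20, 10, 5)), seed = 9)
  expect_equal(apply_gates(tbl, back), apply_gates(tbl, gates))
})

test_that("the default scenario is recovered by clustering and gating", {
  skip_if_not_installed("mclust")
  pops <- imc_populations_default(n_per_pop = c(200, 150, 120, 80, 120, 90, 25))
  tbl <- simulate_ion_counts(pops, seed = 20)
  norm <- percentile_normalize(tbl, p = 99)
  labels <- cluster_graph(norm, k_neighbors = 30, seed = 2)
  expect_gte(mclust::adjustedRandIndex(labels, tbl$population), 0.9)

  # im.CTC centroid falls nearest the CD4 T centroid among leukocyte gates
  gated <- apply_gates(tbl, default_gate_tree())
  X <- as.matrix(norm[, imc_marker_panel()])
  centroid <- function(rows) colMeans(X[rows, , drop = FALSE])
  im_c <- centroid(tbl$population == "im.CTC")
  leuko <- c("CD4 T", "CD8 T", "B", "NK", "monocyte")
  d_gate <- vapply(leuko, function(g) sqrt(sum((im_c - centroid(gated == g))^2)), 0)
  expect_equal(names(which.min(d_gate)), "CD4 T")
  d_truth <- vapply(leuko, function(g) {
    sqrt(sum((im_c - centroid(tbl$population == g))^2))
  }, 0)
  expect_equal(names(which.min(d_truth)), "CD4 T")
})

test_that("marker statistics produce valid Spearman correlations", {
  pops <- imc_populations_default(n_per_pop = c(50, 40, 30, 20, 30, 60, 25))
  tbl <- simulate_ion_counts(pops, seed = 8)
  res <- marker_stats(tbl, "population", "im.CTC", "epi.CTC")
  corr <- res$correlation
  expect_equal(unname(diag(corr)), rep(1, ncol(corr)))
  expect_equal(corr, t(corr))
  expect_true(all(corr >= -1 & corr <= 1))
  expect_equal(sort(unique(res$summary$group)), c("epi.CTC", "im.CTC"))
  expect_error(marker_stats(tbl, "population", "im.CTC", "nope"), "non-empty")

  # rank invariance and the antitone case
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  df <- data.frame(g = "a", m1 = x, m2 = exp(x), m3 = -x)
  df <- rbind(df, transform(df, g = "b"))
  attr(df, "markers") <- c("m1", "m2", "m3")
  rho <- marker_stats(df, "g", "a", "b")$correlation
  expect_equal(rho["m1", "m2"], 1)
  expect_equal(rho["m1", "m3"], -1)
})
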