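# Shared fixtures, built in code at test time.

# A bin map whose bins all have identical length (for closed-form count
# expectations).
equal_bin_map <- function(n_bins, n_chromosomes = 1L, len = 1e5, gc = NULL) {
  bm <- make_bin_map(n_bins, n_chromosomes, seed = 1)
  start <- unlist(lapply(split(seq_len(n_bins), bm$chrom), function(i) {
    (seq_along(i) - 1) * len
  }), use.names = FALSE)
  bm$start <- start
  bm$end <- start + len
  if (!is.null(gc)) bm$gc <- gc
  attr(bm, "map_id") <- ctcfusion:::.map_signature(bm)
  bm
}

# Small breast-like genome used across modules: 16 chromosomes so the clonal
# event list (chr1, 4q, chr8 firestorm, chr16) fits.
test_genome <- function(n_bins = 800, seed = 11) {
  bm <- make_bin_map(n_bins, n_chromosomes = 16, seed = seed)
  events <- breast_clone_events(bm)
  list(bm = bm, events = events, truth = make_truth_profile(bm, events))
}

# A cell_counts object with arbitrary counts on a given map (e.g. all-zero).
manual_cell <- function(counts, bm, cell_id = "manual", cell_type = "manual") {
  structure(
    list(counts = counts, cell_id = cell_id, cell_type = cell_type,
         draw = 1L, patient = NA_character_, parents = NULL,
         map_id = ctcfusion:::map_id(bm)),
    class = "cell_counts"
  )
}

# Independent exhaustive CBS oracle: loop over every arc (i, j] with both
# sides >= min_width, pooled two-sample t via its textbook formula.
oracle_max_arc <- function(x, min_width = 3L) {
  n <- length(x)
  best <- list(stat = -Inf)
  for (start in 1:(n - min_width + 1L)) {
    for (end in (start + min_width - 1L):min(n, start + n - min_width - 1L)) {
      if (end - start + 1L > n - min_width) next
      a <- x[start:end]
      b <- x[-(start:end)]
      sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n - 2)
      if (sp2 <= 0) next
      tval <- abs(mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
      if (tval > best$stat) best <- list(start = start, end = end, stat = tval)
    }
  }
  best
}
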