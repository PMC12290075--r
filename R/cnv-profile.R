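# GC-bias correction and genome-mean ratio normalization of bin counts.

.as_counts <- function(x) {
  if (inherits(x, "cell_counts")) x$counts else as.numeric(x)
}

#' Correct bin counts for GC bias
#'
#' Fits a smooth trend of length-normalized counts against bin GC fraction —
#' a robust locally weighted fit (`lowess`, span 0.3) when at least 100 bins
#' are available, a quadratic fit otherwise — and divides counts by the
#' relative fitted bias. The genome-wide mean count is preserved.
#'
#' @param counts A `cell_counts` object or numeric vector of bin counts.
#' @param bin_map The matching `bin_map` (provides GC and bin length).
#' @param span Lowess smoother span.
#' @return Numeric vector of corrected counts, same mean as the input.
#' @export
gc_correct <- function(counts, bin_map, span = 0.3) {
  x <- .as_counts(counts)
  if (length(x) != nrow(bin_map)) stop_invalid("counts and bin map lengths differ")
  if (sum(x) <= 0) stop_invalid("non-positive total count")
  if (sum(x > 0) < 10) stop_invalid("insufficient data: fewer than 10 nonzero bins")
  y <- x / bin_lengths(bin_map)     # per-bp rate, the quantity GC distorts
  gc <- bin_map$gc
  fit <- if (length(x) >= 100) {
    lo <- stats::lowess(gc, y, f = span)
    stats::approx(lo$x, lo$y, xout = gc, rule = 2)$y
  } else {
    stats::fitted(stats::lm(y ~ gc + I(gc^2)))
  }
  # guard against non-positive fitted bias in sparse tails
  floor_val <- 0.05 * mean(y)
  fit <- pmax(fit, floor_val)
  corrected <- x / (fit / mean(fit))
  corrected * (mean(x) / mean(corrected))
}

#' Normalize corrected counts to genome-mean ratios
#'
#' Divides per-bin values by the genome-wide mean so the profile averages to
#' exactly 1 (ratio 1 = baseline ploidy). When a bin map is supplied, counts
#' are first divided by bin length, since expected counts scale with the
#' (variable) bin length.
#'
#' @param x Corrected counts (numeric or `cell_counts`).
#' @param bin_map Optional `bin_map`; if given, values are length-normalized
#'   before taking ratios and chromosome labels are attached to the profile.
#' @param cell_id,cell_type,draw Metadata (taken from `x` when it is a
#'   `cell_counts`).
#' @return A `ratio_profile`: list with numeric `ratio` (mean exactly 1),
#'   optional `chrom` labels, and metadata.
#' @export
ratio_normalize <- function(x, bin_map = NULL, cell_id = NA_character_,
                            cell_type = NA_character_, draw = NA) {
  if (inherits(x, "cell_counts")) {
    if (is.na(cell_id)) cell_id <- x$cell_id
    if (is.na(cell_type)) cell_type <- x$cell_type
    if (is.na(draw)) draw <- x$draw
    x <- x$counts
  }
  v <- as.numeric(x)
  chrom <- NULL
  if (!is.null(bin_map)) {
    if (length(v) != nrow(bin_map)) stop_invalid("length does not match bin map")
    v <- v / bin_lengths(bin_map)
    chrom <- as.character(bin_map$chrom)
  }
  if (mean(v) <= 0) stop_invalid("non-positive mean; cannot form ratios")
  ratio_profile(v, chrom = chrom, cell_id = cell_id, cell_type = cell_type,
                draw = draw)
}

#' Construct a ratio profile
#'
#' Low-level constructor: rescales `ratio` to mean exactly 1 and attaches
#' metadata. Useful for building profiles directly from expected ratios plus
#' noise in simulations.
#'
#' @param ratio Positive-mean numeric vector.
#' @param chrom Optional chromosome label per bin.
#' @param cell_id,cell_type,draw Metadata.
#' @return A `ratio_profile` object.
#' @export
ratio_profile <- function(ratio, chrom = NULL, cell_id = NA_character_,
                          cell_type = NA_character_, draw = NA) {
  ratio <- as.numeric(ratio)
  m <- mean(ratio)
  if (!is.finite(m) || m <= 0) stop_invalid("ratio mean must be positive")
  ratio <- ratio / m
  if (!is.null(chrom)) stopifnot(length(chrom) == length(ratio))
  structure(
    list(ratio = ratio, chrom = chrom, cell_id = cell_id,
         cell_type = cell_type, draw = draw),
    class = "ratio_profile"
  )
}

#' Full counts-to-ratios pipeline for one cell
#'
#' GC-corrects bin counts and normalizes them to genome-mean ratios — the
#' standard preprocessing before segmentation.
#'
#' @inheritParams gc_correct
#' @return A `ratio_profile`.
#' @export
bin_ratio_profile <- function(counts, bin_map, span = 0.3) {
  corrected <- gc_correct(counts, bin_map, span = span)
  ratio_normalize(
    corrected, bin_map,
    cell_id = if (inherits(counts, "cell_counts")) counts$cell_id else NA_character_,
    cell_type = if (inherits(counts, "cell_counts")) counts$cell_type else NA_character_,
    draw = if (inherits(counts, "cell_counts")) counts$draw else NA
  )
}

#' Average ratio profiles across cells
#'
#' Per-bin arithmetic mean over a set of cells (e.g. all classical CTCs), as
#' used to build a population consensus profile.
#'
#' @param cells Non-empty list of `ratio_profile`s over the same bins.
#' @param cell_id Identifier for the averaged profile.
#' @return A `ratio_profile`.
#' @export
mean_profile <- function(cells, cell_id = "mean") {
  if (length(cells) == 0L) stop_invalid("empty cell list")
  n <- length(cells[[1]]$ratio)
  for (c in cells) {
    if (!inherits(c, "ratio_profile") || length(c$ratio) != n) {
      stop_invalid("cells must be ratio_profiles over a common bin map")
    }
  }
  m <- Reduce(`+`, lapply(cells, `[[`, "ratio")) / length(cells)
  ratio_profile(m, chrom = cells[[1]]$chrom, cell_id = cell_id,
                cell_type = "mean")
}

#' Pooled-variance two-sided Student's t-test on region ratios
#'
#' Compares a genomic region's copy-number ratios between two cell groups
#' (e.g. the *PTPRC* region in immune-like vs classical CTCs) with the
#' textbook pooled two-sample t statistic and a two-sided p-value on
#' `nA + nB - 2` degrees of freedom. Degenerate zero-variance inputs are
#' handled explicitly: equal means give t = 0, p = 1; unequal means give
#' p = 0 with `degenerate = TRUE`.
#'
#' @param a,b Numeric vectors of ratios (each of length >= 2).
#' @return List with `statistic`, `df`, `p.value`, `degenerate`.
#' @export
region_ratio_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop_invalid("each group needs n >= 2")
  na <- length(a); nb <- length(b)
  df <- na + nb - 2L
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  delta <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (delta == 0) {
      return(list(statistic = 0, df = df, p.value = 1, degenerate = FALSE))
    }
    return(list(statistic = sign(delta) * Inf, df = df, p.value = 0,
                degenerate = TRUE))
  }
  tstat <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = tstat, df = df,
       p.value = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
       degenerate = FALSE)
}
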