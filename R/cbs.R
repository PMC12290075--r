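# Circular binary segmentation of ratio profiles.
#
# Change-points are found recursively: within a (sub-)chromosome, the
# circular arc maximizing the pooled two-sample t statistic between in-arc
# and out-of-arc bins is located by exhaustive scan, and the split is
# accepted when its permutation p-value falls below alpha. Scanning linear
# contiguous arcs of every admissible length is equivalent to scanning all
# circular arcs, because an arc that wraps has a contiguous complement and
# the two-sample |t| is symmetric in the two groups.

#' Segmentation configuration
#'
#' @param alpha Significance level for accepting a split (permutation
#'   p-value must be strictly below it).
#' @param n_perm Number of permutations per candidate split (>= 100).
#' @param min_width Minimum segment width in bins (>= 2).
#' @param seed Integer seed for the permutation stream.
#' @return A `cbs_config` list.
#' @export
cbs_config <- function(alpha = 0.01, n_perm = 1000L, min_width = 3L, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop_invalid("`alpha` must be in (0, 1)")
  if (n_perm < 100L) stop_invalid("`n_perm` must be >= 100")
  if (min_width < 2L) stop_invalid("`min_width` must be >= 2")
  structure(
    list(alpha = alpha, n_perm = as.integer(n_perm),
         min_width = as.integer(min_width), seed = as.integer(seed)),
    class = "cbs_config"
  )
}

#' Best circular arc of a numeric sequence
#'
#' Exhaustive scan over all arcs (contiguous windows, each admissible
#' length) for the one maximizing the absolute pooled-variance two-sample
#' t statistic between in-arc and out-of-arc values. Ties break toward the
#' shortest, left-most arc. Exposed so its choice can be checked against an
#' independent search.
#'
#' @param x Numeric vector (typically log2 ratios of one chromosome).
#' @param min_width Minimum bins in the arc and in its complement.
#' @return List with `start`, `end` (1-based inclusive), `stat` (abs t), or
#'   `NULL` when `length(x) < 2 * min_width`.
#' @export
cbs_max_arc <- function(x, min_width = 3L) {
  n <- length(x)
  if (n < 2L * min_width) return(NULL)
  S <- c(0, cumsum(x))
  Q <- c(0, cumsum(x * x))
  tot <- S[n + 1L]
  qtot <- Q[n + 1L]
  sp_floor <- .Machine$double.eps * (qtot / n + 1)
  best_stat <- -Inf
  best_start <- NA_integer_
  best_k <- NA_integer_
  for (k in min_width:(n - min_width)) {
    i <- seq_len(n - k + 1L)               # window start positions
    sums <- S[i + k] - S[i]
    qw <- Q[i + k] - Q[i]
    m1 <- sums / k
    m2 <- (tot - sums) / (n - k)
    ss <- (qw - sums^2 / k) + (qtot - qw - (tot - sums)^2 / (n - k))
    sp2 <- pmax(ss / (n - 2L), sp_floor)
    tval <- abs(m1 - m2) / sqrt(sp2 * (1 / k + 1 / (n - k)))
    j <- which.max(tval)
    if (tval[j] > best_stat) {
      best_stat <- tval[j]
      best_start <- i[j]
      best_k <- k
    }
  }
  list(start = best_start, end = best_start + best_k - 1L, stat = best_stat)
}

# Max arc statistic only (permutation inner loop).
.cbs_scan_stat <- function(x, min_width) {
  cbs_max_arc(x, min_width)$stat
}

# Test the best split of x; returns the arc if its permutation p-value is
# < alpha, else NULL. Permutations stop early once the exceedance count c
# makes p = (1 + c) / (1 + n_perm) >= alpha unreachable.
.cbs_test_split <- function(x, config) {
  obs <- cbs_max_arc(x, config$min_width)
  if (is.null(obs) || obs$stat <= 0) return(NULL)
  reject_at <- config$alpha * (config$n_perm + 1) - 1  # c >= this => no split
  exceed <- 0
  for (b in seq_len(config$n_perm)) {
    if (.cbs_scan_stat(x[sample.int(length(x))], config$min_width) >= obs$stat) {
      exceed <- exceed + 1
      if (exceed >= reject_at) return(NULL)
    }
  }
  if ((1 + exceed) / (1 + config$n_perm) < config$alpha) obs else NULL
}

# Recursive segmentation of one chromosome; returns sorted internal cut
# positions (a cut at p means a boundary between bins p and p+1).
.cbs_recurse <- function(x, config) {
  n <- length(x)
  if (n < 2L * config$min_width) return(integer(0))
  spl <- .cbs_test_split(x, config)
  if (is.null(spl)) return(integer(0))
  cuts <- c(spl$start - 1L, spl$end)
  cuts <- cuts[cuts >= 1L & cuts < n]
  bounds <- c(0L, cuts, n)
  out <- cuts
  for (p in seq_len(length(bounds) - 1L)) {
    a <- bounds[p]
    b <- bounds[p + 1L]
    out <- c(out, a + .cbs_recurse(x[(a + 1L):b], config))
  }
  sort(unique(out))
}

#' Segment a ratio profile by circular binary segmentation
#'
#' Segments each chromosome's log2 ratios recursively (see module notes) and
#' reports per-segment mean ratios on the linear scale. Chromosomes shorter
#' than `2 * min_width` bins are returned as single segments.
#'
#' @param profile A `ratio_profile` with chromosome labels (or a numeric
#'   vector combined with `chrom`).
#' @param config A [cbs_config()].
#' @param chrom Chromosome label per bin; defaults to the profile's own.
#' @return A `segment_set`: data.frame with `chrom`, `start_bin`, `end_bin`
#'   (1-based inclusive global bin indices), `n_bins`, `mean_ratio` and
#'   `state` (NA until [call_states()]). Segments tile each chromosome.
#' @export
segment_cbs <- function(profile, config = cbs_config(), chrom = NULL) {
  ratio <- if (inherits(profile, "ratio_profile")) profile$ratio else as.numeric(profile)
  if (is.null(chrom)) {
    chrom <- if (inherits(profile, "ratio_profile")) profile$chrom else NULL
  }
  if (is.null(chrom)) chrom <- rep("chr1", length(ratio))
  stopifnot(length(chrom) == length(ratio))
  chrom <- as.character(chrom)
  xlog <- log2(ratio + 1e-6)
  segs <- with_seed(config$seed, {
    out <- list()
    for (cl in unique(chrom)) {
      idx <- which(chrom == cl)
      cuts <- .cbs_recurse(xlog[idx], config)
      ends <- c(cuts, length(idx))
      starts <- c(1L, cuts + 1L)
      out[[cl]] <- data.frame(
        chrom = cl,
        start_bin = idx[starts],
        end_bin = idx[ends],
        n_bins = ends - starts + 1L,
        mean_ratio = vapply(seq_along(starts), function(i) {
          mean(ratio[idx[starts[i]:ends[i]]])
        }, 0),
        state = NA_integer_
      )
    }
    do.call(rbind, out)
  })
  rownames(segs) <- NULL
  class(segs) <- c("segment_set", "data.frame")
  attr(segs, "cell_id") <- if (inherits(profile, "ratio_profile")) profile$cell_id else NA_character_
  segs
}

#' Call integer copy states from segment mean ratios
#'
#' A ratio of 1 corresponds to the baseline ploidy, so the state is the mean
#' ratio times the baseline, rounded half-up to the nearest non-negative
#' integer (1.5 -> 3 copies, 0.5 -> 1 copy at ploidy 2).
#'
#' @param segments A `segment_set`.
#' @param baseline_ploidy Baseline integer ploidy (default diploid).
#' @return The `segment_set` with its `state` column filled.
#' @export
call_states <- function(segments, baseline_ploidy = 2L) {
  if (any(segments$mean_ratio < 0)) stop_invalid("mean ratios must be non-negative")
  segments$state <- pmax(0L, as.integer(round_half_up(
    segments$mean_ratio * baseline_ploidy
  )))
  segments
}

#' Write a segment table as TSV
#'
#' Columns: cell, chrom, start_bin, end_bin, n_bins, mean_ratio, state.
#'
#' @param segments A `segment_set`.
#' @param path Output path.
#' @param cell Cell identifier column value.
#' @export
write_segments <- function(segments, path, cell = attr(segments, "cell_id")) {
  df <- cbind(cell = if (is.null(cell)) NA_character_ else cell,
              as.data.frame(segments))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
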