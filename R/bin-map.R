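# Synthetic genomic bin maps.
#
# Single-cell whole-genome copy-number profiling counts reads in a few
# thousand variable-length genomic bins. The analysis downstream depends only
# on the bin structure (chromosome membership, length, GC fraction), so the
# generator builds an abstract genome with hg19-like relative chromosome
# sizes rather than shipping a reference.

# Approximate chromosome sizes (Mb) used as allocation weights, chr1..22,X,Y.
.chrom_size_mb <- c(
  249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
  115, 107, 103, 90, 81, 78, 59, 63, 48, 51, 155, 59
)

.chrom_labels <- function(n) {
  if (n <= 24L) {
    c(paste0("chr", 1:22), "chrX", "chrY")[seq_len(n)]
  } else {
    paste0("chr", seq_len(n))
  }
}

# Largest-remainder apportionment of n_bins over weights, each chromosome
# getting at least one bin.
.apportion_bins <- function(n_bins, weights) {
  k <- length(weights)
  w <- weights / sum(weights)
  base <- floor(w * (n_bins - k)) + 1L
  rem <- n_bins - sum(base)
  if (rem > 0L) {
    frac <- w * (n_bins - k) - floor(w * (n_bins - k))
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate a synthetic genomic bin map
#'
#' Builds an ordered set of variable-length genomic bins partitioned over
#' chromosomes, each with a GC fraction. Bin lengths are log-normal around a
#' common mean and GC fractions are Beta-distributed, truncated to (0.2, 0.8).
#' Chromosomes receive bins in proportion to human-like relative sizes (up to
#' 24 chromosomes labelled chr1..chr22, chrX, chrY).
#'
#' @param n_bins Total number of bins (the profiling method in view uses
#'   roughly 5000).
#' @param n_chromosomes Number of chromosomes to partition the bins over.
#' @param seed Integer seed; the map is a pure function of its arguments.
#' @param mean_bin_length Mean bin length in base pairs.
#' @param gc_shape Length-2 shape parameters of the Beta distribution GC
#'   fractions are drawn from before truncation.
#'
#' @return A `bin_map`: a data.frame with columns `chrom` (factor, genome
#'   order), `start`, `end` (0-based half-open base-pair coordinates) and
#'   `gc`, plus a `map_id` attribute used to check that two objects were
#'   built on the same map.
#' @examples
#' bm <- make_bin_map(500, n_chromosomes = 8, seed = 1)
#' table(bm$chrom)
#' @export
make_bin_map <- function(n_bins, n_chromosomes = 24L, seed = 1L,
                         mean_bin_length = 6e5, gc_shape = c(14, 18)) {
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 1) {
    stop_invalid("`n_bins` must be a positive integer")
  }
  n_bins <- as.integer(n_bins)
  n_chromosomes <- as.integer(n_chromosomes)
  if (n_chromosomes < 1L || n_bins < n_chromosomes) {
    stop_invalid("need n_bins >= n_chromosomes >= 1")
  }
  labels <- .chrom_labels(n_chromosomes)
  weights <- if (n_chromosomes <= 24L) {
    .chrom_size_mb[seq_len(n_chromosomes)]
  } else {
    rep(1, n_chromosomes)
  }
  per_chrom <- .apportion_bins(n_bins, weights)

  with_seed(seed, {
    len <- pmax(1000, round(stats::rlnorm(n_bins, log(mean_bin_length), 0.25)))
    gc <- stats::rbeta(n_bins, gc_shape[1], gc_shape[2])
    bad <- gc <= 0.2 | gc >= 0.8
    while (any(bad)) {
      gc[bad] <- stats::rbeta(sum(bad), gc_shape[1], gc_shape[2])
      bad <- gc <= 0.2 | gc >= 0.8
    }
    chrom <- factor(rep(labels, per_chrom), levels = labels)
    start <- unlist(lapply(split(len, chrom), function(l) cumsum(c(0, l[-length(l)]))),
                    use.names = FALSE)
    bm <- data.frame(
      chrom = chrom,
      start = start,
      end = start + len,
      gc = gc
    )
    class(bm) <- c("bin_map", "data.frame")
    attr(bm, "map_id") <- .map_signature(bm)
    bm
  })
}

.map_signature <- function(bm) {
  paste(nrow(bm), nlevels(bm$chrom), sum(as.numeric(bm$end)),
        format(sum(bm$gc), digits = 12), sep = ":")
}

map_id <- function(bm) {
  id <- attr(bm, "map_id")
  if (is.null(id)) .map_signature(bm) else id
}

bin_lengths <- function(bm) {
  as.numeric(bm$end - bm$start)
}

# 1-based global bin indices for a chromosome (and optionally an arm:
# p = first 45% of the chromosome's bins, q = remainder).
chrom_bins <- function(bm, chrom, arm = NULL) {
  idx <- which(as.character(bm$chrom) == chrom)
  if (length(idx) == 0L) stop_invalid("chromosome not in bin map: ", chrom)
  if (is.null(arm)) return(idx)
  cut <- max(1L, floor(0.45 * length(idx)))
  if (arm == "p") idx[seq_len(cut)] else idx[(cut + 1L):length(idx)]
}

#' Write / read a bin map as BED-like TSV
#'
#' Columns `chrom`, `start`, `end`, `gc` with 0-based half-open coordinates.
#'
#' @param bm A `bin_map`.
#' @param path File path.
#' @return `read_bin_map` returns a `bin_map`; `write_bin_map` returns `path`
#'   invisibly.
#' @export
write_bin_map <- function(bm, path) {
  utils::write.table(
    data.frame(chrom = as.character(bm$chrom), start = bm$start,
               end = bm$end, gc = bm$gc),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_bin_map
#' @export
read_bin_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "gc") %in% names(df)))
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  class(df) <- c("bin_map", "data.frame")
  attr(df, "map_id") <- .map_signature(df)
  df
}
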