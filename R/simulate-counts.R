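# Ground-truth copy-number profiles and simulated per-cell bin read counts.

#' Describe a copy-number alteration event
#'
#' Events are expressed in 1-based bin indices *within* a chromosome and set
#' the integer copy state of that interval. Later events overwrite earlier
#' ones where they overlap.
#'
#' @param chrom Chromosome label present in the bin map.
#' @param start_bin,end_bin 1-based inclusive bin indices within the
#'   chromosome.
#' @param state Target integer copy state (non-negative).
#' @return A `cna_event` list.
#' @export
cna_event <- function(chrom, start_bin, end_bin, state) {
  stopifnot(length(chrom) == 1L, length(state) == 1L)
  if (state < 0 || state != round(state)) {
    stop_invalid("`state` must be a non-negative integer")
  }
  if (start_bin < 1 || end_bin < start_bin) {
    stop_invalid("invalid bin range [", start_bin, ", ", end_bin, "]")
  }
  structure(
    list(chrom = as.character(chrom), start_bin = as.integer(start_bin),
         end_bin = as.integer(end_bin), state = as.integer(state)),
    class = "cna_event"
  )
}

#' Build a ground-truth copy-state vector from CNA events
#'
#' Starts from a uniform baseline ploidy (default 2, diploid) and applies
#' each event in order; overlapping events overwrite.
#'
#' @param bin_map A `bin_map`.
#' @param events List of [cna_event()] objects (possibly empty).
#' @param clone Clone label stored with the profile.
#' @param baseline_ploidy Baseline integer copy state.
#' @return A `copy_state` object: list with integer `state` (one per bin),
#'   `clone`, and the bin map's `map_id`.
#' @export
make_truth_profile <- function(bin_map, events = list(), clone = "clone1",
                               baseline_ploidy = 2L) {
  state <- rep.int(as.integer(baseline_ploidy), nrow(bin_map))
  for (ev in events) {
    if (!inherits(ev, "cna_event")) stop_invalid("events must be cna_event objects")
    idx <- which(as.character(bin_map$chrom) == ev$chrom)
    if (length(idx) == 0L) stop_invalid("event chromosome not in map: ", ev$chrom)
    if (ev$end_bin > length(idx)) {
      stop_invalid("event [", ev$start_bin, ", ", ev$end_bin, "] out of range for ",
                   ev$chrom, " (", length(idx), " bins)")
    }
    state[idx[ev$start_bin:ev$end_bin]] <- ev$state
  }
  structure(
    list(state = state, clone = clone,
         baseline_ploidy = as.integer(baseline_ploidy),
         map_id = map_id(bin_map)),
    class = "copy_state"
  )
}

#' Breast-cancer-like clonal event list
#'
#' Returns the set of clonal alterations used as the default tumor genome in
#' simulations: gain and loss on chromosome 1 (the gain placed on 1q, where
#' *PTPRC* resides), loss of 4q, a "firestorm"-like run of alternating narrow
#' gains and losses on chromosome 8, 16p gain and 16q loss. Event extents are
#' fractions of each chromosome's bins, so the list adapts to any bin map
#' that contains chr1, chr4, chr8 and chr16.
#'
#' @param bin_map A `bin_map` with at least 16 chromosomes.
#' @return List of [cna_event()] objects.
#' @export
breast_clone_events <- function(bin_map) {
  nb <- function(chrom) length(chrom_bins(bin_map, chrom))
  frac <- function(chrom, lo, hi) {
    n <- nb(chrom)
    c(max(1L, ceiling(lo * n)), max(1L, floor(hi * n)))
  }
  ev <- list()
  r <- frac("chr1", 0.05, 0.30)   # 1p loss
  ev <- c(ev, list(cna_event("chr1", r[1], r[2], 1L)))
  r <- frac("chr1", 0.55, 0.90)   # 1q gain (PTPRC-like region)
  ev <- c(ev, list(cna_event("chr1", r[1], r[2], 3L)))
  n4 <- nb("chr4")                 # 4q loss
  ev <- c(ev, list(cna_event("chr4", max(1L, floor(0.45 * n4) + 1L), n4, 1L)))
  # chr8 firestorm: >= 4 alternating narrow gains/losses
  n8 <- nb("chr8")
  cuts <- unique(pmax(1L, round(seq(0.1, 0.9, length.out = 7) * n8)))
  states <- rep(c(3L, 1L), length.out = length(cuts) - 1L)
  for (i in seq_len(length(cuts) - 1L)) {
    ev <- c(ev, list(cna_event("chr8", cuts[i], cuts[i + 1L] - 1L, states[i])))
  }
  n16 <- nb("chr16")
  cut16 <- max(1L, floor(0.45 * n16))
  ev <- c(ev, list(cna_event("chr16", 1L, cut16, 3L)))          # 16p gain
  ev <- c(ev, list(cna_event("chr16", cut16 + 1L, n16, 1L)))    # 16q loss
  ev
}

#' Simulation configuration for per-cell read counts
#'
#' @param total_reads Expected total reads per cell (depth is a free choice
#'   of the simulation; the default 1e6 gives ~200 reads per bin at 5000
#'   bins).
#' @param gc_bias Quadratic multiplicative bias coefficients `c(b0, b1, b2)`:
#'   expected count is scaled by `b0 + b1*gc + b2*gc^2`. The default
#'   `c(1, 0, 0)` is flat (no GC bias).
#' @param dispersion Overdispersion parameter (>= 0). 0 gives multinomial
#'   (Poisson-like) sampling; > 0 mixes the per-bin rate with Gamma noise of
#'   variance `dispersion`, i.e. negative-binomial-style counts.
#' @param seed Integer seed.
#' @param exact If TRUE, return the (non-integer) expected counts instead of
#'   sampling — a noise-free cell.
#' @return A `sim_config` list.
#' @export
sim_config <- function(total_reads = 1e6, gc_bias = c(1, 0, 0),
                       dispersion = 0, seed = 1L, exact = FALSE) {
  if (total_reads <= 0) stop_invalid("`total_reads` must be positive")
  if (dispersion < 0) stop_invalid("`dispersion` must be >= 0")
  stopifnot(length(gc_bias) == 3L)
  structure(
    list(total_reads = total_reads, gc_bias = as.numeric(gc_bias),
         dispersion = dispersion, seed = as.integer(seed),
         exact = isTRUE(exact)),
    class = "sim_config"
  )
}

gc_bias_fun <- function(coef) {
  function(gc) coef[1] + coef[2] * gc + coef[3] * gc^2
}

#' Simulate one cell's bin read counts
#'
#' Expected reads per bin are proportional to copy state x bin length x
#' GC bias, scaled to `total_reads`. With `dispersion = 0` counts are
#' multinomial; with `dispersion > 0` they are Gamma-Poisson (negative
#' binomial) around the same expectations; with `exact = TRUE` the
#' expectations themselves are returned.
#'
#' @param truth A `copy_state` from [make_truth_profile()].
#' @param bin_map The `bin_map` the truth was built on.
#' @param config A [sim_config()].
#' @param cell_id,cell_type,draw,patient Metadata carried with the cell.
#' @return A `cell_counts` object: list with numeric `counts` (one per bin),
#'   metadata fields and the bin map's `map_id`.
#' @export
simulate_counts <- function(truth, bin_map, config = sim_config(),
                            cell_id = "cell1", cell_type = "tumor",
                            draw = 1L, patient = NA_character_) {
  stopifnot(inherits(truth, "copy_state"), inherits(config, "sim_config"))
  if (length(truth$state) != nrow(bin_map)) {
    stop_invalid("truth and bin map lengths differ")
  }
  if (!identical(truth$map_id, map_id(bin_map))) {
    stop_invalid("truth was built on a different bin map")
  }
  if (all(truth$state == 0L)) stop_invalid("all-zero copy state")
  bias <- gc_bias_fun(config$gc_bias)(bin_map$gc)
  if (any(bias <= 0)) stop_invalid("gc_bias is non-positive at some GC values")
  w <- truth$state * bin_lengths(bin_map) * bias
  p <- w / sum(w)
  mu <- config$total_reads * p
  counts <- if (config$exact) {
    mu
  } else {
    with_seed(config$seed, {
      if (config$dispersion == 0) {
        as.numeric(stats::rmultinom(1, size = round(config$total_reads), prob = p))
      } else {
        lambda <- mu * stats::rgamma(length(mu), shape = 1 / config$dispersion,
                                     scale = config$dispersion)
        as.numeric(stats::rpois(length(mu), lambda))
      }
    })
  }
  structure(
    list(counts = counts, cell_id = cell_id, cell_type = cell_type,
         draw = draw, patient = patient, parents = NULL,
         map_id = map_id(bin_map)),
    class = "cell_counts"
  )
}

#' Sum two cells' bin counts into a synthetic fusion cell
#'
#' The early-fusion model: a hybrid cell retains both parental genomes, so
#' its expected bin counts are the sum of the parents' counts.
#'
#' @param a,b `cell_counts` objects built on the same bin map.
#' @return A `cell_counts` whose counts are the elementwise sum; metadata
#'   records both parents.
#' @export
fuse_counts <- function(a, b) {
  stopifnot(inherits(a, "cell_counts"), inherits(b, "cell_counts"))
  if (!identical(a$map_id, b$map_id) || length(a$counts) != length(b$counts)) {
    stop_invalid("cells were built on different bin maps")
  }
  structure(
    list(counts = a$counts + b$counts,
         cell_id = paste0(a$cell_id, "+", b$cell_id),
         cell_type = "fusion", draw = a$draw, patient = a$patient,
         parents = c(a$cell_id, b$cell_id), map_id = a$map_id),
    class = "cell_counts"
  )
}

#' Expected normalized bin ratios for a truth profile
#'
#' The noise-free ratio a copy-state vector implies after GC correction and
#' genome-mean normalization: `state / mean(state)` (bin-length weighted by
#' construction of the profiling method, unweighted here since ratios are
#' already per-length). With `fused = TRUE`, a full diploid genome is added
#' first: `(state + 2) / mean(state + 2)`.
#'
#' @param truth A `copy_state`.
#' @param fused Add a diploid genome before normalizing?
#' @return Numeric vector of expected ratios (mean 1).
#' @export
expected_ratios <- function(truth, fused = FALSE) {
  s <- truth$state + if (isTRUE(fused)) 2 else 0
  s / mean(s)
}

#' Segment table of a truth profile
#'
#' Collapses a copy-state vector into maximal runs of constant state per
#' chromosome — the ideal segmentation, with mean ratios on the
#' genome-mean-normalized scale. Used as the clonal reference in
#' simulations.
#'
#' @param truth A `copy_state`.
#' @param bin_map The matching `bin_map`.
#' @return A `segment_set` data.frame (see [segment_cbs()]).
#' @export
truth_segments <- function(truth, bin_map) {
  stopifnot(length(truth$state) == nrow(bin_map))
  ratio <- expected_ratios(truth)
  chrom <- as.character(bin_map$chrom)
  key <- paste(chrom, truth$state)
  run <- rle(key)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  seg <- data.frame(
    chrom = chrom[starts],
    start_bin = starts,
    end_bin = ends,
    n_bins = run$lengths,
    mean_ratio = vapply(seq_along(starts),
                        function(i) mean(ratio[starts[i]:ends[i]]), 0),
    state = truth$state[starts]
  )
  class(seg) <- c("segment_set", "data.frame")
  seg
}
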