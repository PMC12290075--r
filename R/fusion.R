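# Fusion-compression analysis and clonality scoring.
#
# If a CD45+/CK+ cell were a tumor-leukocyte hybrid, its genome would be the
# tumor genome plus a full diploid complement. On a genome-mean-normalized
# ratio profile that addition compresses every CNA toward 1: a single-copy
# gain moves from 3:2 (1.5) to 5:4 (1.25) and a single-copy loss from 2:1
# (0.5) to 4:3 (0.75). The attenuation statistic formalizes "compression" as
# the through-origin regression slope of the query's deviations from 1
# against the clonal reference's deviations: ~1 for a bona fide tumor cell,
# ~0.5 for an equal-depth 1:1 fusion, ~0 for a plain leukocyte.

#' Expected normalized ratio of a tumor segment, with or without fusion
#'
#' For a near-diploid tumor genome where altered segments are a small
#' fraction of the genome: a segment at integer state `s` has ratio `s / 2`;
#' after fusion with a diploid cell at equal depth the ratio becomes
#' `(s + 2) / 4`.
#'
#' @param tumor_state Integer copy state(s) in the tumor genome (>= 0).
#' @param fused_with_diploid Has a full diploid genome been added?
#' @return Expected ratio(s).
#' @examples
#' expected_ratio(3, FALSE)  # 1.5
#' expected_ratio(3, TRUE)   # 1.25
#' @export
expected_ratio <- function(tumor_state, fused_with_diploid = FALSE) {
  if (any(tumor_state < 0)) stop_invalid("tumor_state must be >= 0")
  if (isTRUE(fused_with_diploid)) (tumor_state + 2) / 4 else tumor_state / 2
}

#' Synthesize a fusion ratio profile from two cells
#'
#' The synthetic-hybrid recipe: sum the two cells' bin read counts, correct
#' the summed counts for GC content, then normalize to genome-mean ratios.
#'
#' @param tumor,wbc `cell_counts` objects on the same bin map.
#' @param bin_map The shared `bin_map`.
#' @param span Lowess span passed to [gc_correct()].
#' @return A `ratio_profile` of the synthetic hybrid.
#' @export
synthesize_fusion_profile <- function(tumor, wbc, bin_map, span = 0.3) {
  fused <- fuse_counts(tumor, wbc)
  bin_ratio_profile(fused, bin_map, span = span)
}

#' CNA-amplitude attenuation of a query profile against a clonal reference
#'
#' Over bins falling in the reference's non-neutral segments (state != 2,
#' X chromosome excluded by default because subclonal X loss would
#' contaminate the clonal reference), regresses `query ratio - 1` on
#' `reference segment mean ratio - 1` through the origin. Using segment
#' means on the reference side avoids errors-in-variables attenuation bias.
#' Slope ~1: the query carries the clonal CNAs at full amplitude (not
#' fusion-consistent). Slope ~0.5: amplitudes compressed as a 1:1
#' tumor-diploid hybrid would show. Slope ~0: no shared CNAs.
#'
#' @param query A `ratio_profile`.
#' @param reference_segments A `segment_set` with called states (see
#'   [call_states()] or [truth_segments()]).
#' @param min_informative Minimum informative bins for a verdict.
#' @param fusion_threshold Attenuation below which the profile is called
#'   fusion-consistent (default 0.75, midpoint of the two hypotheses'
#'   expectations 1.0 and 0.5).
#' @param exclude_chrom Chromosomes excluded from the regression.
#' @return A `fusion_assessment` data.frame row: `cell_id`, `attenuation`,
#'   `n_informative_bins`, `verdict` (one of `"non-fusion-consistent"`,
#'   `"fusion-consistent"`, `"uninformative"`).
#' @export
attenuation_statistic <- function(query, reference_segments,
                                  min_informative = 50L,
                                  fusion_threshold = 0.75,
                                  exclude_chrom = c("chrX", "X")) {
  stopifnot(inherits(query, "ratio_profile"))
  seg <- reference_segments
  if (is.null(seg$state) || all(is.na(seg$state))) {
    stop_invalid("reference segments need called states (run call_states())")
  }
  keep <- !is.na(seg$state) & seg$state != 2L &
    !(as.character(seg$chrom) %in% exclude_chrom)
  seg <- seg[keep, , drop = FALSE]
  q <- query$ratio
  ref <- rep(NA_real_, length(q))
  for (i in seq_len(nrow(seg))) {
    if (seg$end_bin[i] > length(q)) stop_invalid("reference segments exceed query length")
    ref[seg$start_bin[i]:seg$end_bin[i]] <- seg$mean_ratio[i]
  }
  idx <- which(!is.na(ref))
  n_inf <- length(idx)
  if (n_inf < min_informative || sum((ref[idx] - 1)^2) == 0) {
    a <- NA_real_
    verdict <- "uninformative"
  } else {
    x <- ref[idx] - 1
    y <- q[idx] - 1
    a <- sum(x * y) / sum(x * x)
    verdict <- if (a < fusion_threshold) "fusion-consistent" else "non-fusion-consistent"
  }
  out <- data.frame(
    cell_id = query$cell_id,
    attenuation = a,
    n_informative_bins = n_inf,
    verdict = verdict
  )
  class(out) <- c("fusion_assessment", "data.frame")
  out
}

# Reciprocal overlap of two 1-based inclusive bin intervals.
.reciprocal_overlap <- function(s1, e1, s2, e2) {
  inter <- min(e1, e2) - max(s1, s2) + 1L
  if (inter <= 0L) return(0)
  min(inter / (e1 - s1 + 1L), inter / (e2 - s2 + 1L))
}

#' Detect clonal copy-number events across single cells
#'
#' A clonal event is a non-neutral segment (state != 2) recurring with the
#' same gain/loss direction and reciprocal bin overlap >= `min_overlap` in at
#' least `min_cell_fraction` of the cells. A cell is flagged clonal when it
#' carries at least half of the clonal events. Results are invariant to the
#' order of the cell list.
#'
#' @param cells Named list of `segment_set`s with called states (names are
#'   cell ids; unnamed lists get `cell1..n`).
#' @param min_cell_fraction Minimum supporting cell fraction for clonality.
#' @param min_overlap Minimum reciprocal overlap between matching segments.
#' @return A `clonality_report`: list with `events` (data.frame of candidate
#'   events: chrom, start_bin, end_bin, direction, n_cells, cell_fraction,
#'   clonal) and `cells` (data.frame: cell_id, n_clonal_events_carried,
#'   clonal).
#' @export
detect_clonal_events <- function(cells, min_cell_fraction = 0.5,
                                 min_overlap = 0.5) {
  if (length(cells) < 2L) stop_invalid("need at least 2 cells")
  if (is.null(names(cells)) || any(names(cells) == "")) {
    names(cells) <- paste0("cell", seq_along(cells))
  }
  n_cells <- length(cells)
  # all non-neutral segments, canonically ordered for order invariance
  cand <- do.call(rbind, lapply(names(cells), function(id) {
    s <- cells[[id]]
    if (is.null(s$state) || all(is.na(s$state))) {
      stop_invalid("segment sets need called states")
    }
    s <- s[!is.na(s$state) & s$state != 2L, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    data.frame(cell = id, chrom = as.character(s$chrom),
               start_bin = s$start_bin, end_bin = s$end_bin,
               direction = ifelse(s$state > 2L, "gain", "loss"))
  }))
  events <- data.frame(chrom = character(), start_bin = integer(),
                       end_bin = integer(), direction = character(),
                       n_cells = integer(), cell_fraction = numeric(),
                       clonal = logical())
  carried <- stats::setNames(rep(0L, n_cells), names(cells))
  if (!is.null(cand) && nrow(cand) > 0L) {
    cand <- cand[order(cand$chrom, cand$start_bin, cand$end_bin, cand$direction,
                       cand$cell), , drop = FALSE]
    cluster <- rep(NA_integer_, nrow(cand))
    reps <- list()  # first-member representatives
    for (i in seq_len(nrow(cand))) {
      for (j in seq_along(reps)) {
        r <- reps[[j]]
        if (r$chrom == cand$chrom[i] && r$direction == cand$direction[i] &&
            .reciprocal_overlap(r$start_bin, r$end_bin,
                                cand$start_bin[i], cand$end_bin[i]) >= min_overlap) {
          cluster[i] <- j
          break
        }
      }
      if (is.na(cluster[i])) {
        reps[[length(reps) + 1L]] <- cand[i, ]
        cluster[i] <- length(reps)
      }
    }
    ev <- lapply(seq_along(reps), function(j) {
      members <- cand[cluster == j, , drop = FALSE]
      support <- unique(members$cell)
      data.frame(
        chrom = reps[[j]]$chrom,
        start_bin = reps[[j]]$start_bin,
        end_bin = reps[[j]]$end_bin,
        direction = reps[[j]]$direction,
        n_cells = length(support),
        cell_fraction = length(support) / n_cells,
        clonal = length(support) / n_cells >= min_cell_fraction
      )
    })
    events <- do.call(rbind, ev)
    clonal_idx <- which(events$clonal)
    if (length(clonal_idx) > 0L) {
      for (id in names(cells)) {
        sup <- vapply(clonal_idx, function(j) {
          any(cand$cell == id & cluster == j)
        }, TRUE)
        carried[id] <- sum(sup)
      }
    }
  }
  n_clonal <- sum(events$clonal)
  cell_df <- data.frame(
    cell_id = names(cells),
    n_clonal_events_carried = as.integer(carried),
    clonal = n_clonal > 0L & 2L * carried >= n_clonal,
    row.names = NULL
  )
  structure(list(events = events, cells = cell_df),
            class = "clonality_report")
}
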