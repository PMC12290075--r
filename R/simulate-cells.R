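# Simulated immunofluorescence feature tables and IMC ion-count tables.

#' Default immunofluorescence population mixture
#'
#' Three populations on one slide: CK-negative background leukocytes
#' (CD45-bright), CD45+/CK+ immune-like CTCs and CD45-/CK+ classical CTCs.
#' CK+ means sit far (> 6 population SDs) above the background CK mean so
#' the slide-wide threshold rule can recover them, and the double-positive
#' population dominates the CK+ pool (> 97% of it), mirroring a case where
#' immune-like CTCs vastly outnumber classical ones.
#'
#' @return Named list of populations, each with `fraction`, `ck_mean`,
#'   `ck_sd`, `cd45_mean`, `cd45_sd`.
#' @export
feature_populations_default <- function() {
  list(
    "WBC" = list(fraction = 0.98, ck_mean = 100, ck_sd = 10,
                 cd45_mean = 400, cd45_sd = 60),
    "CD45+/CK+" = list(fraction = 0.0195, ck_mean = 300, ck_sd = 20,
                       cd45_mean = 400, cd45_sd = 60),
    "CD45-/CK+" = list(fraction = 0.0005, ck_mean = 300, ck_sd = 20,
                       cd45_mean = 50, cd45_sd = 15)
  )
}

#' Simulate a per-cell fluorescence feature table
#'
#' Draws per-cell mean CK and mean CD45 intensities from per-population
#' normal distributions (truncated at 0). Population counts follow the
#' requested fractions exactly (largest-remainder rounding), so generator
#' bookkeeping is deterministic.
#'
#' @param n_cells Number of cells.
#' @param populations Named list as in [feature_populations_default()];
#'   fractions must sum to 1.
#' @param seed Integer seed.
#' @param slide Slide identifier stored with every cell.
#' @return A data.frame with columns `cell_id`, `slide`, `ck`, `cd45`,
#'   `label` (the ground-truth population name).
#' @export
simulate_feature_table <- function(n_cells, populations = feature_populations_default(),
                                   seed = 1L, slide = "slide1") {
  if (length(populations) == 0L) stop_invalid("empty population list")
  fr <- vapply(populations, function(p) p$fraction, 0)
  if (abs(sum(fr) - 1) > 1e-8) stop_invalid("population fractions must sum to 1")
  n_cells <- as.integer(n_cells)
  if (n_cells < 0L) stop_invalid("`n_cells` must be >= 0")
  if (n_cells == 0L) {
    return(data.frame(cell_id = character(), slide = character(),
                      ck = numeric(), cd45 = numeric(), label = character()))
  }
  base <- floor(fr * n_cells)
  rem <- n_cells - sum(base)
  if (rem > 0L) {
    extra <- order(fr * n_cells - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  with_seed(seed, {
    rows <- lapply(seq_along(populations), function(i) {
      n <- base[i]
      if (n == 0L) return(NULL)
      p <- populations[[i]]
      data.frame(
        ck = pmax(0, stats::rnorm(n, p$ck_mean, p$ck_sd)),
        cd45 = pmax(0, stats::rnorm(n, p$cd45_mean, p$cd45_sd)),
        label = names(populations)[i]
      )
    })
    df <- do.call(rbind, rows)
    df <- df[sample.int(nrow(df)), , drop = FALSE]  # shuffle population order
    data.frame(
      cell_id = sprintf("cell%05d", seq_len(nrow(df))),
      slide = slide,
      ck = df$ck, cd45 = df$cd45, label = df$label,
      row.names = NULL
    )
  })
}

#' IMC analysis marker panel (22 markers)
#'
#' The marker set retained for analysis after signal-to-noise triage:
#' leukocyte lineage and T-cell markers, monocyte/macrophage markers,
#' cytokeratins and epithelial/breast markers, plus CD44, vimentin and Ki67.
#' The DNA intercalator (`DNA1`) and mask `area` are carried as separate
#' columns, not panel members.
#'
#' @return Character vector of 22 marker names.
#' @export
imc_marker_panel <- function() {
  c("CD45", "CD45RA", "CD45RO", "CD3", "CD4", "CD8a", "CD20", "CD56",
    "CD14", "CD68", "CD16", "CD11b", "HLADR", "CD44", "CK8", "CK18",
    "panCK", "EpCAM", "Ecadherin", "HER2", "Vimentin", "Ki67")
}

.pop_means <- function(...) {
  m <- stats::setNames(rep(0.5, 22), imc_marker_panel())
  over <- c(...)
  m[names(over)] <- over
  m
}

#' Default IMC population scenario
#'
#' Seven populations with qualitative marker patterns: five leukocyte
#' lineages (CD4 T, CD8 T, B, NK, monocyte) plus immune-like CTCs
#' (cytokeratin+, CD45+, CD3+, CD4+, CD44-high, moderate CD14, no CD68 —
#' closest to the CD4 T profile among leukocytes by construction) and
#' classical epithelial CTCs (cytokeratin+, CD45-).
#'
#' @param n_per_pop Named or unnamed integer vector of cells per population
#'   (recycled if length 1).
#' @return Named list of populations, each with `n` and a named `means`
#'   vector over [imc_marker_panel()].
#' @export
imc_populations_default <- function(n_per_pop = c(400, 300, 250, 150, 250, 172, 25)) {
  pops <- list(
    "CD4 T" = .pop_means(CD45 = 60, CD3 = 40, CD4 = 30, CD45RA = 15,
                         CD45RO = 15, CD44 = 10),
    "CD8 T" = .pop_means(CD45 = 60, CD3 = 40, CD8a = 30, CD45RA = 15,
                         CD45RO = 10, CD44 = 8),
    "B" = .pop_means(CD45 = 55, CD20 = 35, HLADR = 25, CD45RA = 20),
    "NK" = .pop_means(CD45 = 50, CD56 = 30, CD16 = 20),
    "monocyte" = .pop_means(CD45 = 50, CD14 = 35, CD68 = 25, CD11b = 30,
                            CD16 = 10, HLADR = 20),
    "im.CTC" = .pop_means(CD45 = 55, CD3 = 35, CD4 = 35, CD44 = 50,
                          CD14 = 12, CD68 = 0.2, CD45RO = 12, CD45RA = 6,
                          CK8 = 40, CK18 = 40, panCK = 30, Ki67 = 8),
    "epi.CTC" = .pop_means(CD45 = 1, CD44 = 15, CK8 = 45, CK18 = 45,
                           panCK = 35, EpCAM = 3, Ecadherin = 3, HER2 = 3,
                           Ki67 = 8)
  )
  n <- rep_len(n_per_pop, length(pops))
  for (i in seq_along(pops)) pops[[i]] <- list(n = n[i], means = pops[[i]])
  pops
}

#' Simulate an IMC cell-by-marker ion-count table
#'
#' Ion counts are Poisson around per-population marker means (or exactly the
#' means with `noise = "none"`). Mask areas and DNA-intercalator counts are
#' drawn inside the QC-pass window; a configurable fraction of masks is
#' planted as QC failures (undersized area or low DNA1) to exercise the mask
#' filter, with the planted outcome recorded in `qc_fail`.
#'
#' @param populations Named list as from [imc_populations_default()].
#' @param frac_fail_area,frac_fail_dna1 Fractions of cells planted as area /
#'   DNA1 filter failures (exact counts by rounding).
#' @param area_range QC-passing mask area range (pixels).
#' @param dna1_mean Mean DNA1 ion count for passing masks.
#' @param noise `"poisson"` or `"none"`.
#' @param seed Integer seed.
#' @param draw Draw identifier.
#' @return Data.frame with `cell_id`, `population` (truth), `draw`, `area`,
#'   `DNA1`, one column per panel marker, and `qc_fail`
#'   (`"none"`/`"area"`/`"dna1"`); marker names in attribute `markers`.
#' @export
simulate_ion_counts <- function(populations = imc_populations_default(),
                                frac_fail_area = 0, frac_fail_dna1 = 0,
                                area_range = c(60, 150), dna1_mean = 20,
                                noise = c("poisson", "none"), seed = 1L,
                                draw = 1L) {
  noise <- match.arg(noise)
  ns <- vapply(populations, function(p) as.integer(p$n), 0L)
  if (any(ns < 0L)) stop_invalid("negative requested cell counts")
  panel <- names(populations[[1]]$means)
  for (p in populations) {
    if (!identical(names(p$means), panel)) {
      stop_invalid("marker names differ across populations")
    }
  }
  n_total <- sum(ns)
  with_seed(seed, {
    mat <- matrix(0, n_total, length(panel), dimnames = list(NULL, panel))
    pop_lab <- rep(names(populations), ns)
    row0 <- 0L
    for (i in seq_along(populations)) {
      n <- ns[i]
      if (n == 0L) next
      mu <- populations[[i]]$means
      block <- if (noise == "none") {
        matrix(rep(mu, each = n), n, length(panel))
      } else {
        matrix(stats::rpois(n * length(panel), rep(mu, each = n)),
               n, length(panel))
      }
      mat[row0 + seq_len(n), ] <- block
      row0 <- row0 + n
    }
    area <- round(stats::runif(n_total, area_range[1], area_range[2]))
    dna1 <- if (noise == "none") rep(dna1_mean, n_total) else
      stats::rpois(n_total, dna1_mean) + 4  # keep passing masks at >= 4
    qc <- rep("none", n_total)
    n_fail_area <- round(frac_fail_area * n_total)
    n_fail_dna1 <- round(frac_fail_dna1 * n_total)
    if (n_fail_area + n_fail_dna1 > n_total) {
      stop_invalid("planted failure fractions exceed 1")
    }
    fail_idx <- sample.int(n_total, n_fail_area + n_fail_dna1)
    if (n_fail_area > 0L) {
      ia <- fail_idx[seq_len(n_fail_area)]
      area[ia] <- round(stats::runif(n_fail_area, 5, 39))
      qc[ia] <- "area"
    }
    if (n_fail_dna1 > 0L) {
      id <- fail_idx[n_fail_area + seq_len(n_fail_dna1)]
      dna1[id] <- stats::runif(n_fail_dna1, 0, 3.9)
      qc[id] <- "dna1"
    }
    out <- data.frame(
      cell_id = sprintf("mask%05d", seq_len(n_total)),
      population = pop_lab, draw = draw,
      area = area, DNA1 = dna1
    )
    out <- cbind(out, as.data.frame(mat))
    out$qc_fail <- qc
    attr(out, "markers") <- panel
    out
  })
}
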