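# Imaging mass cytometry table analytics: mask QC, transforms, gating,
# graph clustering, marker statistics.

.imc_markers <- function(table, markers = NULL) {
  if (!is.null(markers)) return(markers)
  m <- attr(table, "markers")
  if (is.null(m)) {
    m <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                 c("area", "DNA1", "draw"))
  }
  m
}

#' Filter segmentation masks on area and DNA signal
#'
#' Keeps masks with `area_min <= area <= area_max` (bounds inclusive) and
#' `DNA1 >= dna1_min`, removing poorly segmented or non-nucleated objects.
#' Rows flagged in `bypass` (e.g. CTCs already identified by matched
#' immunofluorescence) are kept regardless. Idempotent.
#'
#' @param table Data.frame with `area` and `DNA1` columns.
#' @param area_min,area_max Inclusive mask area bounds (pixels).
#' @param dna1_min Minimum DNA intercalator ion count.
#' @param bypass Optional logical vector: rows exempt from the filter.
#' @return The filtered table (attributes preserved).
#' @export
filter_masks <- function(table, area_min = 40, area_max = 200, dna1_min = 4,
                         bypass = NULL) {
  if (!all(c("area", "DNA1") %in% names(table))) {
    stop_invalid("table needs `area` and `DNA1` columns")
  }
  keep <- table$area >= area_min & table$area <= area_max &
    table$DNA1 >= dna1_min
  if (!is.null(bypass)) {
    stopifnot(is.logical(bypass), length(bypass) == nrow(table))
    keep <- keep | bypass
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "markers") <- attr(table, "markers")
  out
}

#' Inverse hyperbolic sine transform of ion counts
#'
#' `asinh(x / cofactor)`, the standard variance-stabilizing display
#' transform for mass cytometry; cofactor 1 for IMC ion counts.
#'
#' @param x Numeric vector or matrix of ion counts.
#' @param cofactor Positive divisor applied before the transform.
#' @return Transformed values, same shape as `x`.
#' @export
arcsinh_transform <- function(x, cofactor = 1) {
  if (cofactor <= 0) stop_invalid("`cofactor` must be positive")
  asinh(x / cofactor)
}

#' Scale marker columns to their p-th percentile
#'
#' Divides each marker column by its `p`-th percentile (linear-interpolation
#' definition). Values above the percentile are allowed to exceed 1 (no
#' clipping). Columns whose percentile is zero are left unscaled and listed
#' in the `unscaled_markers` attribute.
#'
#' @param table Data.frame of ion counts.
#' @param p Percentile in (0, 100].
#' @param markers Marker columns to scale (defaults to the table's `markers`
#'   attribute, else all numeric columns except `area`/`DNA1`/`draw`).
#' @return The table with scaled marker columns.
#' @export
percentile_normalize <- function(table, p = 99, markers = NULL) {
  if (nrow(table) == 0L) stop_invalid("empty table")
  if (p <= 0 || p > 100) stop_invalid("`p` must be in (0, 100]")
  markers <- .imc_markers(table, markers)
  unscaled <- character(0)
  for (m in markers) {
    q <- as.numeric(stats::quantile(table[[m]], p / 100, type = 7, names = FALSE))
    if (q == 0) {
      unscaled <- c(unscaled, m)
    } else {
      table[[m]] <- table[[m]] / q
    }
  }
  attr(table, "markers") <- markers
  attr(table, "unscaled_markers") <- unscaled
  table
}

#' Graph-based clustering of cells (kNN + Jaccard + Louvain)
#'
#' Phenograph-style community detection: builds a k-nearest-neighbour graph
#' on Euclidean distance over the marker columns, reweights edges by the
#' Jaccard overlap of the endpoints' neighbour sets, and maximizes
#' modularity with Louvain community detection. Deterministic given the
#' seed.
#'
#' The default `resolution` is deliberately coarse: well-separated
#' populations form disconnected (or near-disconnected) components of the
#' kNN graph, and merging communities with no connecting edges never
#' increases modularity at any resolution, so a low resolution recovers each
#' separated population as a single cluster instead of subdividing it.
#' Raise it to look for finer substructure.
#'
#' @param table Data.frame of (normalized) ion counts.
#' @param k_neighbors Neighbours per cell (must be < number of cells).
#' @param seed Integer seed.
#' @param markers Marker columns used (see [percentile_normalize()]).
#' @param resolution Louvain resolution parameter (> 0).
#' @return Integer vector of cluster labels, one per row.
#' @export
cluster_graph <- function(table, k_neighbors = 30L, seed = 1L, markers = NULL,
                          resolution = 0.1) {
  markers <- .imc_markers(table, markers)
  X <- as.matrix(table[, markers, drop = FALSE])
  n <- nrow(X)
  if (k_neighbors >= n) stop_invalid("`k_neighbors` must be < number of cells")
  d <- as.matrix(stats::dist(X))
  diag(d) <- Inf
  nbr <- t(apply(d, 1, function(row) order(row)[seq_len(k_neighbors)]))
  edges <- cbind(rep(seq_len(n), each = k_neighbors), as.vector(t(nbr)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  jac <- igraph::similarity(g, method = "jaccard")
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- jac[el]
  keep <- w > 0
  g <- igraph::subgraph_from_edges(
    g, igraph::E(g)[keep], delete.vertices = FALSE
  )
  comm <- with_seed(seed, igraph::cluster_louvain(g, weights = w[keep],
                                                  resolution = resolution))
  as.integer(igraph::membership(comm))
}

#' Define a gate tree
#'
#' A gate tree is an ordered list of nodes; each node has a `name`, an
#' optional `parent` (another node's name) and a list of `rules`, each a
#' threshold predicate `list(marker, op, threshold)` with `op` one of
#' `">"`, `">="`, `"<"`, `"<="`. A cell is assigned the first *leaf* (node
#' without children) whose full root-to-leaf rule chain it satisfies;
#' otherwise it is `"ungated"`. Exclusion markers are expressed as `<`
#' rules.
#'
#' @param nodes List of nodes as described above.
#' @return A `gate_tree` object (validated: acyclic, parents defined).
#' @export
gate_tree <- function(nodes) {
  nms <- vapply(nodes, `[[`, "", "name")
  if (anyDuplicated(nms)) stop_invalid("duplicate gate names")
  for (nd in nodes) {
    parent <- nd$parent
    if (!is.null(parent) && !is.na(parent) && !parent %in% nms) {
      stop_invalid("undefined parent gate: ", parent)
    }
    # walk to root, detecting cycles
    seen <- nd$name
    while (!is.null(parent) && !is.na(parent)) {
      if (parent %in% seen) stop_invalid("gate tree contains a cycle at ", parent)
      seen <- c(seen, parent)
      parent <- nodes[[match(parent, nms)]]$parent
    }
  }
  structure(nodes, class = "gate_tree")
}

.gate_path_rules <- function(gates, leaf_idx) {
  nms <- vapply(gates, `[[`, "", "name")
  rules <- list()
  i <- leaf_idx
  repeat {
    rules <- c(gates[[i]]$rules, rules)
    parent <- gates[[i]]$parent
    if (is.null(parent) || is.na(parent)) break
    i <- match(parent, nms)
  }
  rules
}

#' Assign cells to populations by hierarchical gating
#'
#' Evaluates threshold predicates on arcsinh-transformed ion counts (or raw
#' counts with `cofactor = NULL`); cells descend the tree and take the label
#' of the first matching leaf, in tree order, or `"ungated"`. Because child
#' rules are conjoined with their ancestors', CD4/CD8 leaves under a CD3+
#' node are only ever evaluated inside the CD3+ population.
#'
#' @param table Data.frame of ion counts.
#' @param gates A [gate_tree()].
#' @param cofactor arcsinh cofactor applied to marker columns before gating
#'   (`NULL` gates on the values as given).
#' @return Character vector of population labels.
#' @export
apply_gates <- function(table, gates, cofactor = 1) {
  if (!inherits(gates, "gate_tree")) gates <- gate_tree(gates)
  nms <- vapply(gates, `[[`, "", "name")
  parents <- vapply(gates, function(g) {
    p <- g$parent
    if (is.null(p) || is.na(p)) NA_character_ else p
  }, "")
  leaves <- which(!nms %in% parents)
  all_markers <- unique(unlist(lapply(gates, function(g) {
    vapply(g$rules, `[[`, "", "marker")
  })))
  missing <- setdiff(all_markers, names(table))
  if (length(missing)) stop_invalid("gate markers missing from table: ",
                                    paste(missing, collapse = ", "))
  vals <- table[, all_markers, drop = FALSE]
  if (!is.null(cofactor)) vals[] <- lapply(vals, arcsinh_transform, cofactor = cofactor)
  label <- rep("ungated", nrow(table))
  unassigned <- rep(TRUE, nrow(table))
  for (lf in leaves) {
    rules <- .gate_path_rules(gates, lf)
    ok <- rep(TRUE, nrow(table))
    for (r in rules) {
      v <- vals[[r$marker]]
      ok <- ok & switch(r$op,
        ">" = v > r$threshold,
        ">=" = v >= r$threshold,
        "<" = v < r$threshold,
        "<=" = v <= r$threshold,
        stop_invalid("unknown gate operator: ", r$op)
      )
    }
    hit <- ok & unassigned
    label[hit] <- nms[lf]
    unassigned[hit] <- FALSE
  }
  label
}

#' Default leukocyte gate tree for the simulated IMC scenario
#'
#' Leukocyte lineage gating on arcsinh(cofactor 1) ion counts: a CD45+ root
#' with CK8/CK18 as negative exclusion markers, CD3+ T cells split into
#' CD4/CD8 subsets, plus B (CD20), NK (CD56) and monocyte (CD14/CD68)
#' leaves, and a terminal CK+ leaf capturing cytokeratin-positive cells
#' excluded from the leukocyte gates. Thresholds are configuration, not
#' biology: they match the scale of [simulate_ion_counts()] and should be
#' re-tuned (or loaded from YAML) for other data.
#'
#' @return A `gate_tree`.
#' @export
default_gate_tree <- function() {
  r <- function(marker, op, threshold) list(marker = marker, op = op,
                                            threshold = threshold)
  gate_tree(list(
    list(name = "leukocyte", parent = NA,
         rules = list(r("CD45", ">", 3), r("CK8", "<", 2.4), r("CK18", "<", 2.4))),
    list(name = "T cell", parent = "leukocyte", rules = list(r("CD3", ">", 2.8))),
    list(name = "CD4 T", parent = "T cell",
         rules = list(r("CD4", ">", 2.5), r("CD8a", "<", 2))),
    list(name = "CD8 T", parent = "T cell",
         rules = list(r("CD8a", ">", 2.5), r("CD4", "<", 2))),
    list(name = "B", parent = "leukocyte",
         rules = list(r("CD20", ">", 2.5), r("CD3", "<", 2))),
    list(name = "NK", parent = "leukocyte",
         rules = list(r("CD56", ">", 2.5), r("CD3", "<", 2), r("CD20", "<", 2))),
    list(name = "monocyte", parent = "leukocyte",
         rules = list(r("CD14", ">", 2.5), r("CD68", ">", 2), r("CD3", "<", 2))),
    list(name = "CK+", parent = NA,
         rules = list(r("CK8", ">", 2.4), r("CK18", ">", 2.4)))
  ))
}

#' Read / write a gate tree as YAML
#'
#' @param gates A `gate_tree`.
#' @param path File path.
#' @return `read_gate_tree` returns a `gate_tree`; the writer returns `path`
#'   invisibly.
#' @export
write_gate_tree <- function(gates, path) {
  yaml::write_yaml(list(gates = unclass(gates)), path)
  invisible(path)
}

#' @rdname write_gate_tree
#' @export
read_gate_tree <- function(path) {
  obj <- yaml::read_yaml(path)
  gate_tree(obj$gates)
}

#' Per-marker group summaries and Spearman correlation matrix
#'
#' Summarizes each marker's distribution in two labelled cell groups and
#' returns the Spearman (average-rank) correlation matrix of the markers
#' over the union of the two groups.
#'
#' @param table Data.frame of ion counts with a grouping column.
#' @param group_col Name of the grouping column.
#' @param group_a,group_b Group labels to compare.
#' @param markers Marker columns (default: table's `markers` attribute).
#' @return List with `summary` (data.frame: group, marker, n, mean, median,
#'   q25, q75) and `correlation` (symmetric matrix, unit diagonal).
#' @export
marker_stats <- function(table, group_col, group_a, group_b, markers = NULL) {
  markers <- .imc_markers(table, markers)
  if (!group_col %in% names(table)) stop_invalid("missing group column: ", group_col)
  g <- as.character(table[[group_col]])
  if (!any(g == group_a) || !any(g == group_b)) {
    stop_invalid("both groups must be non-empty")
  }
  rows <- table[g %in% c(group_a, group_b), , drop = FALSE]
  summ <- do.call(rbind, lapply(c(group_a, group_b), function(gr) {
    sub <- rows[rows[[group_col]] == gr, markers, drop = FALSE]
    data.frame(
      group = gr, marker = markers, n = nrow(sub),
      mean = vapply(sub, mean, 0),
      median = vapply(sub, stats::median, 0),
      q25 = vapply(sub, stats::quantile, 0, probs = 0.25, names = FALSE),
      q75 = vapply(sub, stats::quantile, 0, probs = 0.75, names = FALSE),
      row.names = NULL
    )
  }))
  corr <- stats::cor(as.matrix(rows[, markers, drop = FALSE]),
                     method = "spearman")
  list(summary = summ, correlation = corr)
}
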