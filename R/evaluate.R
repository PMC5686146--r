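# Consistency of MSC clusters against a reference classification, and
# summary statistics of the clustered network.

#' Consistency of a clustering with a reference classification
#'
#' A cluster is consistent at a reference depth when all of its member
#' sequences carry the same label at that depth; the consistency is the
#' fraction of evaluated clusters that are consistent. Outliers (and, by
#' default, singletons) are excluded from both numerator and denominator.
#' Zero-distance super-nodes count through their member sequences, so a
#' conserved group mixing labels makes its cluster inconsistent.
#'
#' @param hierarchy An `msc_hierarchy` from [run_msc()] (or an
#'   `msc_level` whose units are sequence ids).
#' @param reference Reference classification tibble: column `id` then one
#'   label column per level, coarsest first (see
#'   [read_reference_classification()]).
#' @param ref_depth Depth of the reference labels to compare at.
#' @param level Hierarchy level to evaluate (default 1).
#' @param missing `"error"` (default) if a member id is absent from the
#'   reference, or `"skip"` to drop such ids from the evaluation.
#' @param include_singletons Also count outlier singletons (always
#'   consistent) in the denominator; default FALSE.
#' @return A `consistency_report`: list with `clusters` (tibble `cluster`,
#'   `n_members`, `n_labels`, `consistent`), `fraction`, `n_evaluated`,
#'   `ref_depth`, `level`.
#' @export
consistency <- function(hierarchy, reference, ref_depth = 1L, level = 1L,
                        missing = c("error", "skip"),
                        include_singletons = FALSE) {
  missing <- match.arg(missing)
  mem <- membership_for_consistency(hierarchy, level)
  lab <- reference_labels(reference, ref_depth)
  absent <- setdiff(mem$sequence_id[!mem$is_outlier], names(lab))
  if (length(absent) > 0) {
    if (missing == "error") {
      abort(sprintf("%d cluster member(s) missing from the reference, e.g. %s",
                    length(absent), absent[1]))
    }
    mem <- filter(mem, !.data$sequence_id %in% absent)
  }
  clusters <- mem |>
    filter(!.data$is_outlier) |>
    mutate(label = unname(lab[.data$sequence_id])) |>
    group_by(cluster = .data$cluster_label) |>
    summarise(n_members = n(),
              n_labels = dplyr::n_distinct(.data$label),
              consistent = dplyr::n_distinct(.data$label) == 1,
              .groups = "drop")
  if (include_singletons) {
    singles <- mem |>
      filter(.data$is_outlier) |>
      mutate(cluster = .data$sequence_id, n_members = 1L, n_labels = 1L,
             consistent = TRUE) |>
      select("cluster", "n_members", "n_labels", "consistent")
    clusters <- bind_rows(clusters, singles)
  }
  structure(list(
    clusters = clusters,
    fraction = if (nrow(clusters) == 0) NA_real_ else mean(clusters$consistent),
    n_evaluated = nrow(clusters),
    ref_depth = ref_depth,
    level = level
  ), class = "consistency_report")
}

membership_for_consistency <- function(hierarchy, level) {
  if (inherits(hierarchy, "msc_hierarchy")) {
    if (level > length(hierarchy$levels)) abort("no such level in the hierarchy")
    hierarchy$assignments |>
      filter(.data$level == !!level) |>
      select("sequence_id", "cluster_label", "is_outlier")
  } else if (inherits(hierarchy, "msc_level")) {
    tibble(sequence_id = hierarchy$membership$unit,
           cluster_label = hierarchy$membership$cluster,
           is_outlier = hierarchy$membership$is_outlier)
  } else {
    abort("expected an msc_hierarchy or msc_level")
  }
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("Consistency at reference depth %d (level %d): %.3f over %d clusters\n",
              x$ref_depth, x$level, x$fraction, x$n_evaluated))
  invisible(x)
}

#' @rdname consistency
#' @param x A `consistency_report`.
#' @param ... Unused.
#' @method tidy consistency_report
#' @export
tidy.consistency_report <- function(x, ...) x$clusters

#' @rdname consistency
#' @method glance consistency_report
#' @export
glance.consistency_report <- function(x, ...) {
  tibble(level = x$level, ref_depth = x$ref_depth,
         n_evaluated = x$n_evaluated, fraction = x$fraction)
}

#' Network summary statistics of a clustered level
#'
#' Mean intra-cluster distance (over all finite within-cluster sequence
#' pairs), mean inter-cluster distance (over renormalized cluster-cluster
#' distances), log-binned sequence-sequence and cluster-cluster distance
#' histograms, node degrees of the coarse-grained spanning forest, and the
#' most connected hub per forest component.
#'
#' @param hierarchy An `msc_hierarchy`.
#' @param distances The original sequence-level distance edge table.
#' @param level Level to summarise (default 1).
#' @param bin_width Histogram bin width in log10 decades (default 5).
#' @return A list with `mean_intra`, `mean_inter`, `degrees`, `hubs`,
#'   `seq_hist`, `cluster_hist`.
#' @export
network_stats <- function(hierarchy, distances, level = 1L, bin_width = 5) {
  stopifnot(inherits(hierarchy, "msc_hierarchy"))
  assert_distances(distances)
  if (level > length(hierarchy$levels)) abort("no such level in the hierarchy")
  part <- partition_at(hierarchy, level)
  grp <- setNames(part$group, part$sequence_id)
  is_cl <- setNames(!part$is_outlier, part$sequence_id)

  d <- distances |>
    mutate(g1 = unname(grp[.data$id1]), g2 = unname(grp[.data$id2]))
  intra <- d |> filter(!is.na(.data$g1), .data$g1 == .data$g2,
                       is_cl[.data$id1])
  ren <- hierarchy$renormalized[[level]]
  cl_units <- unique(part$group[!part$is_outlier])
  inter <- ren |> filter(.data$id1 %in% cl_units, .data$id2 %in% cl_units)

  forest <- cluster_forest(hierarchy, level)
  comp <- forest_components(forest)
  hubs <- forest$nodes |>
    left_join(comp, by = "node") |>
    group_by(.data$component) |>
    arrange(dplyr::desc(.data$degree), .data$node, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select("component", hub = "node", "degree")

  list(
    mean_intra = if (nrow(intra)) mean(intra$distance) else NA_real_,
    mean_inter = if (nrow(inter)) mean(inter$distance) else NA_real_,
    degrees = forest$nodes[, c("node", "degree")],
    hubs = hubs,
    seq_hist = log_distance_hist(distances$distance, bin_width),
    cluster_hist = log_distance_hist(ren$distance, bin_width)
  )
}

forest_components <- function(forest) {
  g <- igraph::graph_from_data_frame(
    forest$edges[, c("from", "to")], directed = FALSE,
    vertices = forest$nodes$node)
  m <- igraph::components(g)$membership
  tibble(node = names(m), component = as.integer(m))
}

log_distance_hist <- function(d, bin_width = 5) {
  d <- d[is.finite(d) & d > 0]
  if (length(d) == 0) {
    return(tibble(bin_lo = double(), bin_hi = double(), count = integer()))
  }
  ld <- log10(d)
  lo <- floor(min(ld))
  breaks <- seq(lo, lo + bin_width * ceiling(max(max(ld) - lo, bin_width) / bin_width),
                by = bin_width)
  if (max(breaks) <= max(ld)) breaks <- c(breaks, max(breaks) + bin_width)
  cnt <- as.integer(table(cut(ld, breaks, right = FALSE, include.lowest = TRUE)))
  tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1], count = cnt)
}
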