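# Minimum spanning forests of the (possibly renormalized) network, and
# graph export in GraphML / DOT / edge-list TSV.

# MST edge table of a distance edge table (per connected component).
mst_edges <- function(distances) {
  assert_distances(distances)
  if (nrow(distances) == 0) {
    return(tibble(from = character(), to = character(), distance = double()))
  }
  edges <- canonicalize_edges(distances)
  g <- igraph::graph_from_data_frame(edges[, c("id1", "id2")], directed = FALSE)
  igraph::E(g)$weight <- edges$distance
  m <- igraph::mst(g, weights = igraph::E(g)$weight)
  el <- igraph::as_data_frame(m, what = "edges")
  tibble(from = pmin(el$from, el$to), to = pmax(el$from, el$to),
         distance = el$weight) |>
    arrange(.data$distance, .data$from, .data$to)
}

#' Minimum spanning forest of a network
#'
#' One minimum spanning tree per connected component of the distance graph
#' (total edge weight minimal). Nodes without any finite distance appear
#' as isolated nodes when listed in `ids`.
#'
#' @param distances Distance edge table (original or renormalized).
#' @param node_attrs Optional tibble of node attributes, first column
#'   `node`; typical columns are the cluster label, member count and a
#'   reference-classification label.
#' @param ids Optional node universe.
#' @return An `msc_forest`: list with `edges` (tibble `from`, `to`,
#'   `distance`) and `nodes` (tibble `node`, `degree`, plus any supplied
#'   attributes).
#' @export
spanning_forest <- function(distances, node_attrs = NULL, ids = NULL) {
  ids <- edge_ids(distances, ids)
  edges <- mst_edges(distances)
  deg <- table(factor(c(edges$from, edges$to), levels = ids))
  nodes <- tibble(node = ids, degree = as.integer(deg[ids]))
  if (!is.null(node_attrs)) {
    stopifnot(is.data.frame(node_attrs), names(node_attrs)[1] == "node")
    nodes <- left_join(nodes, node_attrs, by = "node")
  }
  structure(list(edges = edges, nodes = nodes), class = "msc_forest")
}

#' @export
print.msc_forest <- function(x, ...) {
  cat(sprintf("Minimum spanning forest: %d nodes, %d edges, max degree %s\n",
              nrow(x$nodes), nrow(x$edges),
              if (nrow(x$nodes)) max(x$nodes$degree) else 0))
  invisible(x)
}

#' Coarse-grained spanning tree of the clusters at one level
#'
#' Builds the minimum spanning forest of the renormalized network at a
#' hierarchy level — each cluster coarse-grained as one node — carrying
#' member counts and, optionally, a reference label per node (the majority
#' label of the node's member sequences).
#'
#' @param hierarchy An `msc_hierarchy` from [run_msc()].
#' @param level Level number (default 1).
#' @param reference Optional reference classification (see
#'   [read_reference_classification()]).
#' @param ref_depth Label depth used for node colouring (default 1).
#' @return An `msc_forest` over the level's units.
#' @export
cluster_forest <- function(hierarchy, level = 1L, reference = NULL, ref_depth = 1L) {
  stopifnot(inherits(hierarchy, "msc_hierarchy"))
  if (level > length(hierarchy$levels)) abort("no such level in the hierarchy")
  part <- partition_at(hierarchy, level)
  attrs <- part |>
    group_by(node = .data$group) |>
    summarise(n_members = n(), .groups = "drop")
  if (!is.null(reference)) {
    lab <- reference_labels(reference, ref_depth)
    maj <- part |>
      mutate(label = unname(lab[.data$sequence_id])) |>
      group_by(node = .data$group) |>
      summarise(ref_label = names(sort(table(.data$label), decreasing = TRUE))[1],
                .groups = "drop")
    attrs <- left_join(attrs, maj, by = "node")
  }
  spanning_forest(hierarchy$renormalized[[level]], node_attrs = attrs)
}

# id -> label lookup at a given depth of a reference classification table.
reference_labels <- function(reference, ref_depth) {
  if (ref_depth < 1 || ref_depth > ncol(reference) - 1) {
    abort(sprintf("ref_depth %d exceeds the reference label depth %d",
                  ref_depth, ncol(reference) - 1))
  }
  setNames(reference[[ref_depth + 1]], reference$id)
}

#' Write a spanning forest to a graph file
#'
#' Every edge carries its endpoint ids and length; node attributes (cluster
#' label, member count, reference label) are serialized where the format
#' supports them (GraphML and DOT).
#'
#' @param forest An `msc_forest`.
#' @param path Output path.
#' @param format `"graphml"`, `"dot"` or `"edge-tsv"`.
#' @return `path`, invisibly.
#' @export
write_forest <- function(forest, path, format = c("graphml", "dot", "edge-tsv")) {
  stopifnot(inherits(forest, "msc_forest"))
  format <- match.arg(format)
  if (format == "edge-tsv") {
    readr::write_tsv(forest$edges, path, progress = FALSE)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(forest$edges)) forest$edges else
      tibble(from = character(), to = character(), distance = double()),
    directed = FALSE, vertices = forest$nodes)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
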