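# Symmetrized sequence distances from directed E-values, and handling of
# zero-distance (fully conserved) groups.

#' Symmetrize a directed E-value table into a distance matrix
#'
#' The distance between sequences i and j is the geometric mean of the two
#' directed BLAST E-values, `d_ij = sqrt(E_ij * E_ji)`, computed in log
#' space to avoid underflow. E-values above `evalue_ceiling` carry no
#' useful similarity signal and are removed beforehand. Pairs reported in
#' only one direction are either dropped (default; the geometric mean is
#' undefined with one term) or completed with `cap_value` standing in for
#' the unreported direction.
#'
#' @param evalues A data frame with columns `query`, `subject`, `evalue`
#'   (see [read_evalue_table()]).
#' @param missing_policy `"drop"` or `"cap"` for one-directional pairs.
#' @param cap_value Positive number used for the missing direction under
#'   `"cap"`; defaults to 10, BLAST's default reporting cutoff.
#' @param evalue_ceiling E-values strictly greater than this are discarded
#'   before symmetrization (default 1).
#' @return A tibble with columns `id1`, `id2`, `distance` (`id1 < id2`),
#'   sorted by ascending distance, with the node universe in
#'   `attr(, "ids")`. Zero distances are retained; see [zero_groups()].
#' @export
symmetrize <- function(evalues, missing_policy = c("drop", "cap"),
                       cap_value = 10, evalue_ceiling = 1) {
  missing_policy <- match.arg(missing_policy)
  if (!all(c("query", "subject", "evalue") %in% names(evalues))) {
    abort("`evalues` must have columns query, subject, evalue")
  }
  if (missing_policy == "cap" && (!is.numeric(cap_value) || cap_value <= 0)) {
    abort("`cap_value` must be a positive number under missing_policy = 'cap'")
  }
  if (any(evalues$evalue < 0, na.rm = TRUE)) abort("negative E-value")
  ids <- edge_ids(NULL, attr(evalues, "ids")) %||%
    sort(unique(c(evalues$query, evalues$subject)))

  tab <- evalues |>
    filter(.data$query != .data$subject, .data$evalue <= evalue_ceiling) |>
    group_by(.data$query, .data$subject) |>
    summarise(evalue = min(.data$evalue), .groups = "drop")

  if (nrow(tab) == 0) {
    out <- tibble(id1 = character(), id2 = character(), distance = double())
    attr(out, "ids") <- ids
    return(out)
  }

  lo <- pmin(tab$query, tab$subject)
  hi <- pmax(tab$query, tab$subject)
  fwd <- tab$query == lo
  pairs <- tibble(id1 = lo, id2 = hi,
                  e_fwd = ifelse(fwd, tab$evalue, NA_real_),
                  e_rev = ifelse(fwd, NA_real_, tab$evalue)) |>
    group_by(.data$id1, .data$id2) |>
    summarise(e_fwd = suppressWarnings(min(.data$e_fwd, na.rm = TRUE)),
              e_rev = suppressWarnings(min(.data$e_rev, na.rm = TRUE)),
              .groups = "drop") |>
    mutate(e_fwd = ifelse(is.finite(.data$e_fwd), .data$e_fwd, NA_real_),
           e_rev = ifelse(is.finite(.data$e_rev), .data$e_rev, NA_real_))

  if (missing_policy == "drop") {
    pairs <- filter(pairs, !is.na(.data$e_fwd) & !is.na(.data$e_rev))
  } else {
    pairs <- pairs |>
      mutate(e_fwd = dplyr::coalesce(.data$e_fwd, cap_value),
             e_rev = dplyr::coalesce(.data$e_rev, cap_value))
  }
  out <- pairs |>
    mutate(distance = geometric_mean_pair(.data$e_fwd, .data$e_rev)) |>
    select("id1", "id2", "distance") |>
    canonicalize_edges()
  attr(out, "ids") <- ids
  out
}

# sqrt(a*b) without intermediate underflow; exact 0 if either term is 0.
geometric_mean_pair <- function(a, b) {
  ifelse(a == 0 | b == 0, 0, exp((log(a) + log(b)) / 2))
}

#' Zero-distance groups of a distance matrix
#'
#' Maximal groups of sequences whose pairwise distance is zero (mutual
#' E-value 0), computed as connected components of the zero-distance edge
#' set; all remaining ids are singleton groups. These are the fully
#' conserved super-nodes drawn as hexagons in the network diagrams.
#'
#' @param distances Distance edge table (see [symmetrize()]).
#' @param ids Optional node universe; defaults to `attr(distances, "ids")`
#'   or the ids on the edges.
#' @return A tibble with columns `id`, `zero_group` (representative member,
#'   the lexicographically smallest id in the group) and `group_size`.
#' @export
zero_groups <- function(distances, ids = NULL) {
  assert_distances(distances)
  ids <- edge_ids(distances, ids)
  zero <- filter(distances, .data$distance == 0)
  rep_of <- setNames(ids, ids)
  if (nrow(zero) > 0) {
    g <- igraph::graph_from_data_frame(zero[, c("id1", "id2")],
                                       directed = FALSE, vertices = ids)
    comp <- igraph::components(g)$membership
    reps <- vapply(split(names(comp), comp), min, character(1))
    rep_of[names(comp)] <- reps[as.character(comp[names(comp)])]
  }
  out <- tibble(id = ids, zero_group = unname(rep_of[ids]))
  out |>
    group_by(.data$zero_group) |>
    mutate(group_size = n()) |>
    ungroup() |>
    arrange(.data$zero_group, .data$id)
}

#' Collapse zero-distance groups into super-nodes
#'
#' Each zero-distance group becomes one node named after its
#' lexicographically smallest member; the distance between two super-nodes
#' is the minimum distance over all cross-member pairs. Total member count
#' is preserved in the `members` mapping.
#'
#' @inheritParams zero_groups
#' @return A list with `distances` (edge tibble over super-nodes, zero
#'   edges removed, `attr(, "ids")` = super-node universe) and `members`
#'   (tibble `node`, `id`).
#' @export
collapse_zero_groups <- function(distances, ids = NULL) {
  assert_distances(distances)
  zg <- zero_groups(distances, ids)
  map <- setNames(zg$zero_group, zg$id)
  nodes <- sort(unique(zg$zero_group))
  members <- tibble(node = unname(map[zg$id]), id = zg$id) |>
    arrange(.data$node, .data$id)
  if (nrow(distances) == 0) {
    empty <- tibble(id1 = character(), id2 = character(), distance = double())
    attr(empty, "ids") <- nodes
    return(list(distances = empty, members = members))
  }
  cross <- distances |>
    mutate(id1 = unname(map[.data$id1]), id2 = unname(map[.data$id2])) |>
    filter(.data$id1 != .data$id2)
  if (nrow(cross) == 0) {
    empty <- tibble(id1 = character(), id2 = character(), distance = double())
    attr(empty, "ids") <- nodes
    return(list(distances = empty, members = members))
  }
  collapsed <- cross |>
    group_by(g1 = pmin(.data$id1, .data$id2), g2 = pmax(.data$id1, .data$id2)) |>
    summarise(distance = min(.data$distance), .groups = "drop") |>
    rename(id1 = "g1", id2 = "g2") |>
    canonicalize_edges()
  attr(collapsed, "ids") <- nodes
  list(distances = collapsed, members = members)
}
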