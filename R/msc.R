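# The minimum span clustering algorithm: nearest-neighbour simplification,
# ascending-distance cluster growth, threshold truncation, and
# renormalization into a multi-level hierarchy.

#' Nearest-neighbour list of a distance matrix
#'
#' For every node with at least one finite distance, the single entry
#' (node, closest neighbour, distance), sorted by ascending distance. Ties
#' in the per-node argmin resolve to the lexicographically smallest
#' neighbour; the list is ordered by (distance, node, neighbour) so that a
#' mutual nearest pair contributes two adjacent entries. Instead of the
#' full N^2 matrix, all later steps work from these at most N entries.
#'
#' @param distances Distance edge table (`id1`, `id2`, `distance`).
#' @return A tibble with columns `node`, `neighbor`, `distance`.
#' @export
nearest_neighbor_list <- function(distances) {
  assert_distances(distances)
  if (nrow(distances) == 0) {
    return(tibble(node = character(), neighbor = character(), distance = double()))
  }
  long <- bind_rows(
    tibble(node = distances$id1, neighbor = distances$id2, distance = distances$distance),
    tibble(node = distances$id2, neighbor = distances$id1, distance = distances$distance)
  )
  long |>
    arrange(.data$distance, .data$neighbor) |>
    group_by(.data$node) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$distance, .data$node, .data$neighbor)
}

# -- union-find ---------------------------------------------------------

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Grow clusters from a nearest-neighbour list
#'
#' Pairs are taken in ascending-distance order. A pair with neither
#' endpoint assigned founds a new cluster (its core pair); a pair with one
#' endpoint assigned grows that cluster; a pair joining two existing
#' clusters merges them, so the resulting clusters are exactly the
#' connected components of the undirected nearest-neighbour graph. Each
#' accepted pair is recorded as a spanning edge, so every cluster carries a
#' spanning tree of member count minus one edges.
#'
#' @param nn A [nearest_neighbor_list()] result.
#' @param units Node universe; nodes absent from `nn` become outliers.
#' @param level Integer resolution level used in cluster labels
#'   (`C<level>-<index>`).
#' @return An `msc_level` object: list with `level`, `membership` (tibble
#'   `unit`, `cluster`, `is_outlier`), `edges` (tibble `cluster`, `u`, `v`,
#'   `distance`, `is_core`, `join_order`) and `threshold` (`NA` until
#'   truncation).
#' @export
build_clusters <- function(nn, units = NULL, level = 1L) {
  units <- units %||% sort(unique(c(nn$node, nn$neighbor)))
  n <- length(units)
  idx <- setNames(seq_len(n), units)
  parent <- seq_len(n)
  m <- nrow(nn)
  eu <- character(m); ev <- character(m); ed <- double(m); keep <- logical(m)
  if (m > 0) {
    ui <- idx[nn$node]; vi <- idx[nn$neighbor]
    for (k in seq_len(m)) {
      ru <- uf_find(parent, ui[k])
      rv <- uf_find(parent, vi[k])
      if (ru != rv) {
        parent[rv] <- ru
        eu[k] <- nn$node[k]; ev[k] <- nn$neighbor[k]; ed[k] <- nn$distance[k]
        keep[k] <- TRUE
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  edges <- tibble(u = eu[keep], v = ev[keep], distance = ed[keep],
                  join_order = seq_len(sum(keep)))
  finalize_level(units, roots, edges, level = level, threshold = NA_real_)
}

# Shared by build_clusters and truncate_clusters: turn component roots and
# spanning edges into a labelled msc_level. Clusters (components of size
# >= 2) are labelled C<level>-<index> by ascending smallest member.
finalize_level <- function(units, roots, edges, level, threshold) {
  comp <- split(units, roots)
  sizes <- lengths(comp)
  clusters <- comp[sizes >= 2]
  if (length(clusters) > 0) {
    ord <- order(vapply(clusters, min, character(1)))
    clusters <- clusters[ord]
    labels <- sprintf("C%d-%03d", level, seq_along(clusters))
  } else {
    labels <- character()
  }
  unit2cl <- setNames(rep(labels, lengths(clusters)), unlist(clusters, use.names = FALSE))
  membership <- tibble(
    unit = units,
    cluster = unname(unit2cl[units]),
    is_outlier = !(units %in% names(unit2cl))
  ) |> arrange(.data$unit)
  if (nrow(edges) > 0) {
    edges <- edges |>
      mutate(cluster = unname(unit2cl[.data$u])) |>
      group_by(.data$cluster) |>
      mutate(is_core = .data$join_order == min(.data$join_order)) |>
      ungroup() |>
      select("cluster", "u", "v", "distance", "is_core", "join_order") |>
      arrange(.data$join_order)
  } else {
    edges <- tibble(cluster = character(), u = character(), v = character(),
                    distance = double(), is_core = logical(), join_order = integer())
  }
  structure(list(level = as.integer(level), membership = membership,
                 edges = edges, threshold = threshold),
            class = "msc_level")
}

#' @export
print.msc_level <- function(x, ...) {
  ncl <- dplyr::n_distinct(x$membership$cluster[!is.na(x$membership$cluster)])
  cat(sprintf("MSC level %d: %d cluster(s), %d outlier(s), threshold %s\n",
              x$level, ncl, sum(x$membership$is_outlier),
              if (is.na(x$threshold)) "none" else format(x$threshold)))
  invisible(x)
}

#' Edge-length histograms of a clustered network
#'
#' Log10-binned length distributions of all spanning-tree edges of the
#' network (`p_all`: the minimum spanning tree, which contains both intra-
#' and inter-cluster edges) and of the intra-cluster spanning edges only
#' (`p_intra`). Their ratio departs from 1 where inter-cluster edges
#' dominate, which is how the truncation threshold is located. Zero-length
#' edges are excluded (they live in collapsed zero groups).
#'
#' @param all_lengths Numeric vector of all spanning-tree edge lengths.
#' @param intra_lengths Numeric vector of intra-cluster edge lengths.
#' @param bin_width Bin width in log10 decades (default 5).
#' @return A tibble with columns `bin_lo`, `bin_hi` (log10 edges), `n_all`,
#'   `n_intra`, `p_all`, `p_intra`.
#' @export
edge_length_histogram <- function(all_lengths, intra_lengths, bin_width = 5) {
  all_lengths <- all_lengths[is.finite(all_lengths) & all_lengths > 0]
  intra_lengths <- intra_lengths[is.finite(intra_lengths) & intra_lengths > 0]
  if (length(all_lengths) == 0 || length(intra_lengths) == 0) {
    abort("cannot build edge-length histograms from empty edge sets")
  }
  la <- log10(all_lengths); li <- log10(intra_lengths)
  lo <- floor(min(la, li)); hi <- max(la, li)
  breaks <- seq(lo, lo + bin_width * ceiling(max(hi - lo, bin_width) / bin_width),
                by = bin_width)
  if (max(breaks) <= hi) breaks <- c(breaks, max(breaks) + bin_width)
  n_all <- as.integer(table(cut(la, breaks, right = FALSE, include.lowest = TRUE)))
  n_intra <- as.integer(table(cut(li, breaks, right = FALSE, include.lowest = TRUE)))
  tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
         n_all = n_all, n_intra = n_intra,
         p_all = n_all / sum(n_all), p_intra = n_intra / sum(n_intra))
}

#' Estimate the truncation threshold from edge-length histograms
#'
#' Locates the shortest edge length at which the overall bond-length
#' distribution departs from the intra-cluster one, i.e. the first bin
#' (ascending length) where `p_all / p_intra - 1 > epsilon` (with the
#' ratio taken as infinite where `p_intra` is zero but `p_all` is not).
#' A candidate bin is accepted when either (a) it is separated from the
#' preceding populated bin by at least `gap_bins` empty bins — the
#' unambiguous bimodal case, where the threshold is placed at the log
#' midpoint of the empty gap — or (b) the next `persistence` populated
#' bins also qualify with non-decreasing ratio, in which case the
#' threshold is the candidate bin's lower edge. Returns `NULL` when no
#' bin qualifies (single-cluster data).
#'
#' @param hist An [edge_length_histogram()] result.
#' @param epsilon Minimum excess of `p_all/p_intra` over 1 (default 0.5).
#' @param persistence Number of subsequent populated bins that must confirm
#'   the departure when there is no empty gap (default 2).
#' @param gap_bins Number of consecutive empty bins that count as an
#'   unambiguous separation (default 2).
#' @return The threshold distance `D_t` (linear scale), or `NULL`.
#' @export
estimate_threshold <- function(hist, epsilon = 0.5, persistence = 2L, gap_bins = 2L) {
  if (!is.data.frame(hist) || nrow(hist) == 0) abort("empty histogram")
  if (epsilon <= 0) abort("`epsilon` must be positive")
  ratio <- ifelse(hist$p_intra > 0, hist$p_all / hist$p_intra,
                  ifelse(hist$p_all > 0, Inf, NA_real_))
  populated <- hist$n_all > 0 | hist$n_intra > 0
  qualifies <- hist$n_all > 0 & !is.na(ratio) & (ratio - 1) > epsilon
  pop_idx <- which(populated)
  for (b in which(qualifies)) {
    prev_pop <- pop_idx[pop_idx < b]
    if (length(prev_pop) == 0) next  # nothing below: no intra support yet
    i_prev <- max(prev_pop)
    gap <- b - i_prev - 1L
    accept <- FALSE
    if (gap >= gap_bins) {
      accept <- TRUE
    } else {
      # Confirmation bins must lie in the same mode as the candidate: the
      # window stops at the first run of `gap_bins` empty bins, since bins
      # beyond such a gap argue for a larger threshold, not this one.
      nxt <- pop_idx[pop_idx > b & hist$n_all[pop_idx] > 0]
      if (length(nxt) > 0) {
        gaps <- diff(c(b, nxt)) - 1L
        reachable <- cumsum(gaps >= gap_bins) == 0
        nxt <- nxt[reachable]
      }
      if (length(nxt) >= persistence) {
        win <- head(nxt, persistence)
        r_seq <- c(ratio[b], ratio[win])
        # Inf >= Inf holds, so fully saturated windows pass monotonicity.
        accept <- all(qualifies[win]) &&
          all(r_seq[-1] >= r_seq[-length(r_seq)])
      }
    }
    if (accept) {
      dt_log <- (hist$bin_hi[i_prev] + hist$bin_lo[b]) / 2
      return(10^dt_log)
    }
  }
  NULL
}

#' Truncate intra-cluster bonds longer than the threshold
#'
#' Spanning edges longer than `D_t` are deleted; each remaining connected
#' component of two or more units is a cluster, and units left alone become
#' outliers (their shortest bond to their cluster exceeded the threshold).
#'
#' @param level An `msc_level` from [build_clusters()].
#' @param d_t Positive threshold distance.
#' @return A relabelled `msc_level` with `threshold` recorded.
#' @export
truncate_clusters <- function(level, d_t) {
  stopifnot(inherits(level, "msc_level"))
  if (!is.numeric(d_t) || length(d_t) != 1 || is.na(d_t) || d_t <= 0) {
    abort("`d_t` must be a single positive number")
  }
  units <- level$membership$unit
  kept <- filter(level$edges, .data$distance <= d_t)
  idx <- setNames(seq_along(units), units)
  parent <- seq_along(units)
  if (nrow(kept) > 0) {
    for (k in seq_len(nrow(kept))) {
      ru <- uf_find(parent, idx[[kept$u[k]]])
      rv <- uf_find(parent, idx[[kept$v[k]]])
      if (ru != rv) parent[rv] <- ru
    }
  }
  roots <- vapply(seq_along(units), function(i) uf_find(parent, i), integer(1))
  out <- finalize_level(units, roots,
                        kept[, c("u", "v", "distance", "join_order")],
                        level = level$level, threshold = d_t)
  out
}

#' Renormalize a clustered level into a coarser distance matrix
#'
#' Every cluster becomes a single node (named by its cluster label) and
#' every outlier is carried along as a singleton node under its own name.
#' The distance between two renormalized nodes is the shortest distance
#' over all cross pairs of their members; node pairs with no finite cross
#' distance get no edge.
#'
#' @param level A (truncated) `msc_level`.
#' @param distances The unit-level distance edge table the level was built
#'   from.
#' @return A distance edge table over renormalized nodes with the new node
#'   universe in `attr(, "ids")`.
#' @export
renormalize <- function(level, distances) {
  stopifnot(inherits(level, "msc_level"))
  assert_distances(distances)
  mem <- level$membership
  map <- setNames(ifelse(mem$is_outlier, mem$unit, mem$cluster), mem$unit)
  if (nrow(distances) == 0) {
    out <- tibble(id1 = character(), id2 = character(), distance = double())
    attr(out, "ids") <- sort(unique(unname(map)))
    return(out)
  }
  cross <- distances |>
    mutate(id1 = unname(map[.data$id1]), id2 = unname(map[.data$id2])) |>
    filter(!is.na(.data$id1), !is.na(.data$id2), .data$id1 != .data$id2)
  if (nrow(cross) == 0) {
    out <- tibble(id1 = character(), id2 = character(), distance = double())
  } else {
    out <- cross |>
      group_by(g1 = pmin(.data$id1, .data$id2), g2 = pmax(.data$id1, .data$id2)) |>
      summarise(distance = min(.data$distance), .groups = "drop") |>
      rename(id1 = "g1", id2 = "g2") |>
      canonicalize_edges()
  }
  attr(out, "ids") <- sort(unique(unname(map)))
  out
}
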