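# Multi-level driver: repeat simplification, clustering, truncation and
# renormalization until the network stops contracting.

#' Run multi-level minimum span clustering
#'
#' Starting from a symmetrized distance matrix, repeats the four steps —
#' nearest-neighbour list, ascending-distance cluster growth, truncation at
#' the threshold distance, renormalization of clusters into nodes — until a
#' single unit remains, a level produces no merge, or `max_levels` is
#' reached. Zero-distance groups are collapsed into conserved super-nodes
#' before clustering (see [collapse_zero_groups()]); all reported
#' memberships are expanded back to the original sequence ids.
#'
#' The truncation threshold is estimated from the level-1 edge-length
#' histograms and, by default, reused at the coarser levels
#' (`threshold_policy = "reuse-first"`), where too few edges remain for a
#' stable re-estimate; `"per-level"` re-estimates at every level. Explicit
#' `thresholds` overrides win at their level in either policy.
#'
#' @param distances Distance edge table (see [symmetrize()]).
#' @param ids Optional node universe (defaults to `attr(distances, "ids")`).
#' @param max_levels Maximum number of resolution levels (default 10).
#' @param epsilon,persistence,gap_bins,bin_width Threshold-estimation
#'   controls, see [estimate_threshold()] and [edge_length_histogram()].
#' @param thresholds Optional named numeric vector of per-level threshold
#'   overrides, names are level numbers (e.g. `c("1" = 1e-80)`).
#' @param threshold_policy `"reuse-first"` or `"per-level"`.
#' @param collapse_zeros Collapse zero-distance groups first (default TRUE).
#' @return An `msc_hierarchy` object with elements `levels` (list of
#'   `msc_level` over units), `assignments` (tibble `sequence_id`, `level`,
#'   `unit`, `cluster_label`, `is_outlier`, expanded to original ids),
#'   `parents` (tibble `level`, `unit`, `parent`), `thresholds`,
#'   `renormalized` (per-level coarse distance tables), `zero_members`,
#'   and `ids`.
#' @export
run_msc <- function(distances, ids = NULL, max_levels = 10L,
                    epsilon = 0.5, persistence = 2L, gap_bins = 2L,
                    bin_width = 5, thresholds = NULL,
                    threshold_policy = c("reuse-first", "per-level"),
                    collapse_zeros = TRUE) {
  threshold_policy <- match.arg(threshold_policy)
  assert_distances(distances)
  ids <- edge_ids(distances, ids)
  if (length(ids) == 0) abort("empty distance matrix")

  if (collapse_zeros) {
    cz <- collapse_zero_groups(distances, ids)
    em <- cz$distances
    zero_members <- cz$members
    unit_members <- split(cz$members$id, cz$members$node)
  } else {
    em <- canonicalize_edges(distances)
    zero_members <- tibble(node = ids, id = ids)
    unit_members <- split(ids, ids)
  }
  unit_members <- unit_members[sort(names(unit_members))]

  levels <- list()
  assign_rows <- list()
  parent_rows <- list()
  renorm <- list()
  thr <- numeric()
  reuse_dt <- NULL

  for (k in seq_len(max_levels)) {
    cur_units <- names(unit_members)
    if (length(cur_units) <= 1) break
    nn <- nearest_neighbor_list(em)
    if (nrow(nn) == 0) break
    pre <- build_clusters(nn, units = cur_units, level = k)

    dt <- threshold_for_level(k, thresholds)
    if (is.null(dt) && threshold_policy == "reuse-first" && !is.null(reuse_dt)) {
      dt <- reuse_dt
    }
    if (is.null(dt)) {
      hist <- edge_length_histogram(mst_edges(em)$distance, pre$edges$distance,
                                    bin_width = bin_width)
      dt <- estimate_threshold(hist, epsilon = epsilon,
                               persistence = persistence, gap_bins = gap_bins)
    }
    lvl <- if (is.null(dt)) pre else truncate_clusters(pre, dt)
    if (k == 1 && !is.null(dt)) reuse_dt <- dt

    n_clusters <- sum(!is.na(unique(lvl$membership$cluster)))
    if (n_clusters == 0) break  # pure truncation level: nothing merged

    mem <- lvl$membership
    group <- setNames(ifelse(mem$is_outlier, mem$unit, mem$cluster), mem$unit)
    msc_log("level %d: %d units -> %d clusters, %d outliers (D_t %s)",
            k, length(cur_units), n_clusters, sum(mem$is_outlier),
            if (is.null(dt)) "none" else format(dt))

    levels[[k]] <- lvl
    thr[k] <- if (is.null(dt)) NA_real_ else dt
    parent_rows[[k]] <- tibble(level = k, unit = cur_units,
                               parent = unname(group[cur_units]))
    assign_rows[[k]] <- tibble(
      sequence_id = unlist(unit_members, use.names = FALSE),
      level = k,
      unit = rep(unname(group[names(unit_members)]), lengths(unit_members))
    )

    new_members <- lapply(split(unit_members, unname(group[names(unit_members)])),
                          function(x) sort(unlist(x, use.names = FALSE)))
    unit_members <- new_members[sort(names(new_members))]
    em <- renormalize(lvl, em)
    renorm[[k]] <- em
    if (length(unit_members) == length(cur_units)) break
  }

  if (length(levels) == 0) {
    # trivially small input: a single (possibly collapsed) unit
    assignments <- tibble(sequence_id = character(), level = integer(),
                          unit = character(), cluster_label = character(),
                          is_outlier = logical())
  } else {
    assignments <- bind_rows(assign_rows) |>
      mutate(is_cluster = grepl("^C\\d+-\\d+$", .data$unit),
             cluster_label = if_else(.data$is_cluster, .data$unit, NA_character_),
             is_outlier = !.data$is_cluster) |>
      select("sequence_id", "level", "unit", "cluster_label", "is_outlier") |>
      arrange(.data$level, .data$unit, .data$sequence_id)
  }
  structure(list(
    levels = levels,
    assignments = assignments,
    parents = if (length(parent_rows)) bind_rows(parent_rows) else
      tibble(level = integer(), unit = character(), parent = character()),
    thresholds = tibble(level = seq_along(levels), threshold = thr[seq_along(levels)]),
    renormalized = renorm,
    zero_members = zero_members,
    ids = ids
  ), class = "msc_hierarchy")
}

threshold_for_level <- function(k, thresholds) {
  if (is.null(thresholds) || !as.character(k) %in% names(thresholds)) return(NULL)
  v <- thresholds[[as.character(k)]]
  if (is.null(v) || is.na(v)) NULL else v
}

#' @export
print.msc_hierarchy <- function(x, ...) {
  cat(sprintf("MSC hierarchy over %d sequences, %d level(s)\n",
              length(x$ids), length(x$levels)))
  for (lvl in x$levels) print(lvl)
  invisible(x)
}

#' Partition of the original ids at one level
#'
#' Each sequence is assigned to its level-`level` cluster, or to its
#' carried (outlier) unit. Unlike the per-level cluster list, this is a
#' complete partition of the id universe.
#'
#' @param hierarchy An `msc_hierarchy`.
#' @param level Level number; `Inf` (default) means the coarsest level run.
#' @return A tibble with columns `sequence_id`, `group`, `is_outlier`.
#' @export
partition_at <- function(hierarchy, level = Inf) {
  stopifnot(inherits(hierarchy, "msc_hierarchy"))
  if (length(hierarchy$levels) == 0) {
    return(tibble(sequence_id = hierarchy$ids,
                  group = hierarchy$ids, is_outlier = TRUE))
  }
  level <- min(level, length(hierarchy$levels))
  hierarchy$assignments |>
    filter(.data$level == !!level) |>
    select(sequence_id = "sequence_id", group = "unit",
           is_outlier = "is_outlier")
}

# Long per-sequence membership table used by write_clusters() and tidy().
tidy_membership <- function(x) {
  if (inherits(x, "msc_hierarchy")) {
    return(x$assignments |>
             select("sequence_id", "level", "cluster_label", "is_outlier"))
  }
  if (inherits(x, "msc_level")) {
    return(x$membership |>
             transmute_level(x$level))
  }
  abort("expected an msc_hierarchy or msc_level")
}

transmute_level <- function(mem, level) {
  tibble(sequence_id = mem$unit, level = level,
         cluster_label = mem$cluster, is_outlier = mem$is_outlier)
}

#' @rdname run_msc
#' @param x An `msc_hierarchy`.
#' @param ... Unused.
#' @method tidy msc_hierarchy
#' @export
tidy.msc_hierarchy <- function(x, ...) tidy_membership(x)

#' @rdname run_msc
#' @method glance msc_hierarchy
#' @export
glance.msc_hierarchy <- function(x, ...) {
  if (length(x$levels) == 0) {
    return(tibble(n_sequences = length(x$ids), n_levels = 0L,
                  n_level1_clusters = 0L, n_level1_outliers = length(x$ids),
                  threshold_level1 = NA_real_))
  }
  l1 <- x$assignments |> filter(.data$level == 1L)
  tibble(
    n_sequences = length(x$ids),
    n_levels = length(x$levels),
    n_level1_clusters = dplyr::n_distinct(l1$cluster_label[!is.na(l1$cluster_label)]),
    n_level1_outliers = sum(l1$is_outlier),
    threshold_level1 = x$thresholds$threshold[1]
  )
}
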