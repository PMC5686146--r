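# Minimum-distance family detection: a query belongs to the target family
# when its minimum distance to the target sequences is below 10^V_t, with
# V_t tuned to maximize the F measure on labelled data.

#' F measure (harmonic mean of precision and recall)
#'
#' Defined as 0 when both inputs are 0.
#'
#' @param precision,recall Fractions in \[0, 1\].
#' @return `2 * precision * recall / (precision + recall)`.
#' @export
f_measure <- function(precision, recall) {
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1, na.rm = TRUE)) {
    abort("precision and recall must lie in [0, 1]")
  }
  ifelse(precision + recall == 0, 0, 2 * precision * recall / (precision + recall))
}

#' Minimum distance from each node to a target set
#'
#' For ids inside the target set the distance to themselves is excluded
#' (every target would otherwise trivially match itself). Ids with no
#' finite distance to any target get `Inf`.
#'
#' @param distances Distance edge table.
#' @param target_ids Character vector of target (positive-class) ids.
#' @param ids Node universe to report on (defaults to the matrix universe).
#' @return A tibble with columns `id`, `min_distance`, `min_log_distance`
#'   (`-Inf` for an exact zero distance).
#' @export
min_target_distance <- function(distances, target_ids, ids = NULL) {
  assert_distances(distances)
  ids <- edge_ids(distances, ids)
  long <- bind_rows(
    tibble(id = distances$id1, other = distances$id2, distance = distances$distance),
    tibble(id = distances$id2, other = distances$id1, distance = distances$distance)
  ) |>
    filter(.data$other %in% target_ids) |>
    group_by(.data$id) |>
    summarise(min_distance = min(.data$distance), .groups = "drop")
  out <- tibble(id = ids) |>
    left_join(long, by = "id") |>
    mutate(min_distance = dplyr::coalesce(.data$min_distance, Inf),
           min_log_distance = ifelse(.data$min_distance == 0, -Inf,
                                     log10(.data$min_distance)))
  out
}

#' Tune the detection threshold by maximizing the F measure
#'
#' Computes, for every labelled sequence, the minimum distance to the
#' positive (target) class — excluding self-matches — and scans the log10
#' threshold `V_t` over a regular grid covering the observed support,
#' augmented with midpoints between consecutive distinct observed values so
#' that every achievable prediction set is visited. Returns the `V_t`
#' maximizing `F`, taking the smallest (most stringent) `V_t` on ties.
#'
#' @param distances Distance edge table over the labelled sequences.
#' @param labels A data frame with columns `id` and `positive` (logical).
#' @param grid_step Grid step in log10 units (default 0.05).
#' @return A `detection_model`: list with `target_ids`, `v_t`,
#'   `f_at_optimum`, and the scanned `grid` (tibble `v_t`, `precision`,
#'   `recall`, `f`).
#' @export
tune_threshold <- function(distances, labels, grid_step = 0.05) {
  stopifnot(is.data.frame(labels), all(c("id", "positive") %in% names(labels)))
  if (grid_step <= 0) abort("`grid_step` must be positive")
  pos_ids <- labels$id[labels$positive]
  neg_ids <- labels$id[!labels$positive]
  if (length(pos_ids) == 0 || length(neg_ids) == 0) {
    abort("both the positive and the negative class must be non-empty")
  }
  md <- min_target_distance(distances, pos_ids, ids = labels$id)
  md <- left_join(md, labels, by = "id")

  obs <- sort(unique(md$min_log_distance[is.finite(md$min_log_distance)]))
  if (length(obs) == 0) obs <- 0
  grid <- seq(floor(min(obs)) - grid_step, ceiling(max(obs)) + grid_step,
              by = grid_step)
  mids <- if (length(obs) > 1) (head(obs, -1) + tail(obs, -1)) / 2 else numeric()
  cand <- sort(unique(c(grid, mids, max(obs) + grid_step)))

  stats_at <- function(v_t) {
    pred <- md$min_log_distance < v_t
    tp <- sum(pred & md$positive)
    fp <- sum(pred & !md$positive)
    fn <- sum(!pred & md$positive)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    c(precision, recall, f_measure(precision, recall))
  }
  res <- vapply(cand, stats_at, numeric(3))
  grid_tbl <- tibble(v_t = cand, precision = res[1, ], recall = res[2, ], f = res[3, ])
  best <- which(grid_tbl$f == max(grid_tbl$f))[1]
  structure(list(target_ids = pos_ids,
                 v_t = grid_tbl$v_t[best],
                 f_at_optimum = grid_tbl$f[best],
                 grid = grid_tbl),
            class = "detection_model")
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf("Detection model: %d targets, V_t = %.4g, F = %.4g\n",
              length(x$target_ids), x$v_t, x$f_at_optimum))
  invisible(x)
}

#' @rdname tune_threshold
#' @param x A `detection_model`.
#' @param ... Unused.
#' @method tidy detection_model
#' @export
tidy.detection_model <- function(x, ...) x$grid

#' @rdname tune_threshold
#' @method glance detection_model
#' @export
glance.detection_model <- function(x, ...) {
  tibble(n_targets = length(x$target_ids), v_t = x$v_t,
         f_at_optimum = x$f_at_optimum)
}

#' Classify queries with a tuned detection model
#'
#' A query is predicted to belong to the family when the log10 of its
#' minimum distance to the targets is below the model's `v_t`; queries
#' with no finite distance to any target are predicted negative, and an
#' exact zero distance (log `-Inf`) is always predicted positive.
#'
#' @param model A `detection_model` from [tune_threshold()].
#' @param query_distances Either a distance edge table containing
#'   query-target pairs, or a precomputed tibble with columns `id` and
#'   `min_distance`.
#' @param query_ids Queries to report on when `query_distances` is an edge
#'   table (defaults to all non-target ids in it).
#' @return A tibble with columns `id`, `min_log_distance`, `predicted`.
#' @export
detect <- function(model, query_distances, query_ids = NULL) {
  stopifnot(inherits(model, "detection_model"))
  if (all(c("id", "min_distance") %in% names(query_distances))) {
    md <- tibble(id = query_distances$id,
                 min_distance = query_distances$min_distance) |>
      mutate(min_log_distance = ifelse(.data$min_distance == 0, -Inf,
                                       log10(.data$min_distance)))
  } else {
    ids <- query_ids %||% setdiff(edge_ids(query_distances), model$target_ids)
    md <- min_target_distance(query_distances, model$target_ids, ids = ids)
  }
  md |>
    mutate(predicted = .data$min_log_distance < model$v_t) |>
    select("id", "min_log_distance", "predicted")
}
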