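# Internal helpers: validation, logging, canonical pair ordering.

# Order an edge table so that id1 < id2 lexicographically and rows sort by
# (distance, id1, id2). Canonical form makes every downstream step (nearest
# neighbours, cluster growth, label assignment) deterministic.
canonicalize_edges <- function(edges) {
  stopifnot(all(c("id1", "id2", "distance") %in% names(edges)))
  swap <- edges$id1 > edges$id2
  tmp <- edges$id1[swap]
  edges$id1[swap] <- edges$id2[swap]
  edges$id2[swap] <- tmp
  edges <- dplyr::arrange(edges, .data$distance, .data$id1, .data$id2)
  tibble::as_tibble(edges)
}

# Node universe of a distance table: attribute set by symmetrize(), else
# every id appearing on an edge.
edge_ids <- function(edges, ids = NULL) {
  ids <- ids %||% attr(edges, "ids")
  ids %||% sort(unique(c(edges$id1, edges$id2)))
}

assert_distances <- function(edges, arg = "distances") {
  if (!is.data.frame(edges) || !all(c("id1", "id2", "distance") %in% names(edges))) {
    abort(sprintf("`%s` must be a data frame with columns id1, id2, distance", arg))
  }
  if (any(edges$distance < 0, na.rm = TRUE)) {
    abort(sprintf("`%s` contains negative distances", arg))
  }
  invisible(edges)
}

#' Set or query the logging verbosity
#'
#' Messages are written to `stderr`. Levels: 0 silent, 1 informational,
#' 2 debug.
#'
#' @param level Integer verbosity level, or `NULL` to query.
#' @return The current verbosity, invisibly when setting.
#' @export
msc_verbosity <- function(level = NULL) {
  if (is.null(level)) {
    return(getOption("mscnet.verbosity", 0L))
  }
  options(mscnet.verbosity = as.integer(level))
  invisible(as.integer(level))
}

msc_log <- function(msg, ..., level = 1L) {
  if (msc_verbosity() >= level) {
    message(sprintf("[mscnet] %s", sprintf(msg, ...)))
  }
  invisible(NULL)
}

#' Read a JSON configuration file
#'
#' A flat JSON object whose keys mirror the command-line flags of the `msc`
#' script; values override defaults supplied in `defaults`.
#'
#' @param path Path to a JSON file.
#' @param defaults Named list of default values.
#' @return Named list of settings.
#' @export
read_msc_config <- function(path, defaults = list()) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(cfg)) abort("config file must contain a JSON object")
  utils::modifyList(defaults, cfg)
}
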