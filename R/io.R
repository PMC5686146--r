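# Readers and writers for the external formats the tool touches: FASTA,
# BLAST tabular E-value output, cluster tables, distance tables and
# reference classifications. Graph export lives in forest.R.

#' Read sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header, the
#' remainder is kept as the description. Ids must be unique and sequences
#' non-empty.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`; stored on the result, not used to
#'   restrict characters at read time.
#' @return A tibble with columns `id`, `description`, `residues`, `alphabet`,
#'   in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  validate_fasta_lines(path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(tibble(id = character(), description = character(),
                  residues = character(), alphabet = character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sequence id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tibble(id = unname(ids), description = unname(desc),
         residues = unname(as.character(set)), alphabet = alphabet)
}

# Structural validation with line numbers, which the stringset parser does
# not report.
validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(invisible(NULL))
  is_header <- startsWith(lines, ">")
  nonblank <- nzchar(trimws(lines))
  first_content <- which(nonblank)[1]
  if (!is.na(first_content) && !is_header[first_content]) {
    abort(sprintf("FASTA format error at line %d: expected '>' header", first_content))
  }
  hdr_idx <- which(is_header)
  for (k in seq_along(hdr_idx)) {
    if (!nzchar(trimws(sub("^>", "", lines[hdr_idx[k]])))) {
      abort(sprintf("FASTA format error at line %d: empty header", hdr_idx[k]))
    }
    to <- if (k < length(hdr_idx)) hdr_idx[k + 1] - 1L else length(lines)
    body <- lines[seq2(hdr_idx[k] + 1L, to)]
    if (sum(nchar(trimws(body))) == 0L) {
      abort(sprintf("FASTA format error at line %d: record has empty sequence", hdr_idx[k]))
    }
  }
  invisible(NULL)
}

seq2 <- function(from, to) if (from > to) integer() else seq.int(from, to)

#' Write sequences to a FASTA file
#'
#' @param records A data frame with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "residues") %in% names(records)))
  desc <- records[["description"]] %||% rep("", nrow(records))
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  writeLines(paste0(">", hdr, "\n", records$residues), path)
  invisible(path)
}

#' Read an all-vs-all E-value table
#'
#' Accepts either standard 12-column BLAST tabular output (`-outfmt 6`,
#' E-value in column 11) or a minimal whitespace-delimited three-column
#' `query subject evalue` table. Multiple rows for the same ordered pair
#' (for example several HSPs) collapse to the minimum E-value; self hits
#' are dropped.
#'
#' @param path Path to the table.
#' @param dialect `"blast-tab-6"` or `"three-column"`.
#' @return A tibble with columns `query`, `subject`, `evalue` (one row per
#'   ordered pair), with the full id universe (including ids seen only in
#'   self hits) in `attr(, "ids")`.
#' @export
read_evalue_table <- function(path, dialect = c("blast-tab-6", "three-column")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("E-value table not found: %s", path))
  if (dialect == "blast-tab-6") {
    raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                           comment = "#", progress = FALSE)
    if (nrow(raw) > 0 && ncol(raw) < 12) {
      abort(sprintf("blast-tab-6 input must have 12 columns, found %d", ncol(raw)))
    }
    tab <- tibble(query = raw[[1]] %||% character(),
                  subject = raw[[2]] %||% character(),
                  evalue_raw = raw[[11]] %||% character())
  } else {
    raw <- readr::read_table(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                             comment = "#", progress = FALSE)
    if (nrow(raw) > 0 && ncol(raw) != 3) {
      abort(sprintf("three-column input must have 3 columns, found %d", ncol(raw)))
    }
    tab <- tibble(query = raw[[1]] %||% character(),
                  subject = raw[[2]] %||% character(),
                  evalue_raw = raw[[3]] %||% character())
  }
  ev <- suppressWarnings(as.numeric(tab$evalue_raw))
  bad <- which(is.na(ev) | ev < 0)
  if (length(bad) > 0) {
    abort(sprintf("non-numeric or negative E-value in row %d: '%s'",
                  bad[1], tab$evalue_raw[bad[1]]))
  }
  ids <- sort(unique(c(tab$query, tab$subject)))
  out <- tab |>
    mutate(evalue = ev) |>
    filter(.data$query != .data$subject) |>
    group_by(.data$query, .data$subject) |>
    summarise(evalue = min(.data$evalue), .groups = "drop") |>
    arrange(.data$query, .data$subject)
  out <- out[, c("query", "subject", "evalue")]
  attr(out, "ids") <- ids
  out
}

#' Write cluster assignments to a TSV file
#'
#' One row per sequence per level with columns `sequence_id`, `level`,
#' `cluster_label`, `is_outlier`. Outliers carry an `NA` label. Labels are
#' `C<level>-<zero-padded index>` and are stable across reruns on identical
#' input.
#'
#' @param hierarchy An [run_msc()] result or a single cluster level.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(hierarchy, path) {
  tab <- tidy_membership(hierarchy)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a reference classification table
#'
#' Tab-separated, one row per sequence: first column the sequence id, the
#' remaining columns hierarchical labels from coarsest to finest. All rows
#' carry the same depth.
#'
#' @param path Path to the TSV file (with header).
#' @return A tibble with column `id` followed by one column per level.
#' @export
read_reference_classification <- function(path) {
  ref <- readr::read_tsv(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  if (ncol(ref) < 2) abort("reference classification needs an id column and at least one label column")
  names(ref)[1] <- "id"
  if (anyDuplicated(ref$id)) abort("duplicate ids in reference classification")
  labs <- as.matrix(ref[, -1, drop = FALSE])
  if (any(is.na(labs)) || any(!nzchar(labs))) {
    abort("reference classification labels must be non-empty at every level")
  }
  ref
}

#' Write / read a distance table as three-column TSV
#'
#' Columns `id1`, `id2`, `distance`, one row per unordered pair. An optional
#' companion TSV lists the zero-distance groups (`id`, `zero_group`).
#'
#' @param distances Distance edge table (see [symmetrize()]).
#' @param path Output path.
#' @param zero_group_path Optional path for the zero-group table.
#' @return `path`, invisibly.
#' @export
write_distances <- function(distances, path, zero_group_path = NULL) {
  assert_distances(distances)
  readr::write_tsv(distances[, c("id1", "id2", "distance")], path, progress = FALSE)
  if (!is.null(zero_group_path)) {
    readr::write_tsv(zero_groups(distances), zero_group_path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_distances
#' @export
read_distances <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    id1 = "c", id2 = "c", distance = "d"), progress = FALSE)
  if (any(out$distance < 0)) abort("negative distance in distance table")
  out <- canonicalize_edges(out)
  attr(out, "ids") <- sort(unique(c(out$id1, out$id2)))
  out
}
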