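# Nei-Gojobori estimation of synonymous and nonsynonymous substitution
# rates from aligned codon sequence pairs, with Jukes-Cantor multiple-hit
# correction and selection-class summaries.

NUC <- c("A", "C", "G", "T")

# memoized per-codon and per-codon-pair tables, keyed by genetic code and
# stop handling
.ng_cache <- new.env(parent = emptyenv())

code_key <- function(code, stop_handling) {
  paste0(paste(names(code), code, sep = ":", collapse = ";"), "#", stop_handling)
}

#' The standard genetic code
#'
#' Named character vector mapping DNA codons to one-letter amino acids,
#' with `*` for stop codons. Any equally shaped table can be supplied to
#' the counting functions for non-standard codes.
#'
#' @return Named character vector of length 64.
#' @export
standard_genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  setNames(as.character(code), names(code))
}

sense_codons <- function(code) names(code)[code != "*"]

split_codons <- function(x) {
  x <- toupper(chartr("Uu", "Tt", x))
  if (nchar(x) %% 3 != 0) abort("sequence length must be divisible by 3")
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

codon_is_clean <- function(codons) {
  vapply(strsplit(codons, ""), function(ch) all(ch %in% NUC), logical(1))
}

#' Prepare an aligned codon sequence pair
#'
#' Splits two equal-length aligned coding sequences into codons and
#' excludes, pairwise, any codon position where either sequence carries a
#' gap or ambiguity character or a stop codon. `r` counts the retained
#' codons.
#'
#' @param seq1,seq2 Aligned nucleotide strings of equal length divisible
#'   by 3 (U is accepted for T).
#' @param code Genetic code table (default [standard_genetic_code()]).
#' @return A list with `codons1`, `codons2` (retained codons) and `r`.
#' @export
codon_pair <- function(seq1, seq2, code = standard_genetic_code()) {
  if (nchar(seq1) != nchar(seq2)) abort("aligned sequences must have equal length")
  c1 <- split_codons(seq1)
  c2 <- split_codons(seq2)
  keep <- codon_is_clean(c1) & codon_is_clean(c2)
  keep[keep] <- code[c1[keep]] != "*" & code[c2[keep]] != "*"
  list(codons1 = c1[keep], codons2 = c2[keep], r = sum(keep))
}

# Fraction of the three possible changes at each codon position that are
# synonymous; stop-creating changes count as nonsynonymous (default) or are
# excluded from the site total.
syn_site_table <- function(code, stop_handling = c("nonsynonymous", "exclude")) {
  stop_handling <- match.arg(stop_handling)
  key <- paste0("sites|", code_key(code, stop_handling))
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  codons <- sense_codons(code)
  s <- n <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    ch <- strsplit(cd, "")[[1]]
    aa <- code[[cd]]
    for (i in 1:3) {
      for (b in setdiff(NUC, ch[i])) {
        mut <- ch; mut[i] <- b
        maa <- code[[paste(mut, collapse = "")]]
        if (maa == aa) {
          s[cd] <- s[cd] + 1 / 3
        } else if (maa != "*" || stop_handling == "nonsynonymous") {
          n[cd] <- n[cd] + 1 / 3
        }
      }
    }
  }
  out <- list(s = s, n = n)
  .ng_cache[[key]] <- out
  out
}

#' Synonymous and nonsynonymous site counts of a codon pair
#'
#' For each codon, the synonymous site count is the proportion of the
#' three alternative nucleotides at each position that leave the encoded
#' amino acid unchanged, summed over the three positions; totals are
#' averaged between the two sequences. Under the default stop handling
#' (`"nonsynonymous"`), `S + N = 3r` exactly.
#'
#' @param pair A [codon_pair()].
#' @param code Genetic code table.
#' @param stop_handling Whether single changes that create a stop codon
#'   count as nonsynonymous (default) or are excluded from the site total.
#' @return A list with `S` and `N`.
#' @export
site_counts <- function(pair, code = standard_genetic_code(),
                        stop_handling = c("nonsynonymous", "exclude")) {
  stop_handling <- match.arg(stop_handling)
  bad <- c(pair$codons1, pair$codons2)[!codon_is_clean(c(pair$codons1, pair$codons2))]
  if (length(bad) > 0) {
    abort(sprintf("retained codon contains a non-ACGT character: %s", bad[1]))
  }
  tab <- syn_site_table(code, stop_handling)
  s1 <- sum(tab$s[pair$codons1]); n1 <- sum(tab$n[pair$codons1])
  s2 <- sum(tab$s[pair$codons2]); n2 <- sum(tab$n[pair$codons2])
  list(S = (s1 + s2) / 2, N = (n1 + n2) / 2)
}

#' Enumerate the substitution pathways between two codons
#'
#' Codons differing at k positions are connected by k! orderings of the
#' single-nucleotide steps (1, 2 or 6 pathways). Each step is classified
#' as synonymous or nonsynonymous; pathways passing through a stop codon
#' are flagged as blocked.
#'
#' @param codon1,codon2 Codon strings over ACGT.
#' @param code Genetic code table.
#' @return A tibble with one row per step: `pathway`, `step`, `from`,
#'   `to`, `synonymous`, `blocked` (pathway-level flag).
#' @export
codon_pathways <- function(codon1, codon2, code = standard_genetic_code()) {
  ch1 <- strsplit(codon1, "")[[1]]
  ch2 <- strsplit(codon2, "")[[1]]
  diff_pos <- which(ch1 != ch2)
  k <- length(diff_pos)
  if (k == 0) {
    return(tibble(pathway = integer(), step = integer(), from = character(),
                  to = character(), synonymous = logical(), blocked = logical()))
  }
  perms <- permutations_of(diff_pos)
  rows <- list()
  for (p in seq_along(perms)) {
    cur <- ch1
    blocked <- FALSE
    steps <- vector("list", k)
    for (s in seq_len(k)) {
      nxt <- cur
      nxt[perms[[p]][s]] <- ch2[perms[[p]][s]]
      from_cd <- paste(cur, collapse = "")
      to_cd <- paste(nxt, collapse = "")
      if (code[[to_cd]] == "*") blocked <- TRUE
      steps[[s]] <- tibble(pathway = p, step = s, from = from_cd, to = to_cd,
                           synonymous = code[[from_cd]] == code[[to_cd]] &&
                             code[[to_cd]] != "*")
      cur <- nxt
    }
    rows[[p]] <- bind_rows(steps) |> mutate(blocked = blocked)
  }
  bind_rows(rows)
}

permutations_of <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# Average synonymous/nonsynonymous differences for one codon pair over the
# admitted (stop-free) pathways. If every pathway is blocked, differences
# are split proportionally to the classification of the direct single-step
# changes that do not create a stop.
diff_counts_codon <- function(codon1, codon2, code) {
  key <- paste0("diff|", codon1, "|", codon2)
  ck <- paste0("diffcache|", code_key(code, "x"))
  cache <- .ng_cache[[ck]]
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .ng_cache[[ck]] <- cache
  }
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  ch1 <- strsplit(codon1, "")[[1]]
  ch2 <- strsplit(codon2, "")[[1]]
  diff_pos <- which(ch1 != ch2)
  k <- length(diff_pos)
  if (k == 0) {
    out <- c(s_d = 0, n_d = 0)
  } else {
    syn_per_path <- numeric()
    for (perm in permutations_of(diff_pos)) {
      cur <- ch1
      blocked <- FALSE
      syn <- 0
      for (pos in perm) {
        from_aa <- code[[paste(cur, collapse = "")]]
        cur[pos] <- ch2[pos]
        to_aa <- code[[paste(cur, collapse = "")]]
        if (to_aa == "*") blocked <- TRUE
        if (from_aa == to_aa && to_aa != "*") syn <- syn + 1
      }
      if (!blocked) syn_per_path <- c(syn_per_path, syn)
    }
    if (length(syn_per_path) > 0) {
      s_d <- mean(syn_per_path)
    } else {
      # every ordering crosses a stop: split by the direct single-step
      # changes that stay sense
      from_aa <- code[[codon1]]
      syn_open <- open <- 0
      for (pos in diff_pos) {
        mut <- ch1; mut[pos] <- ch2[pos]
        to_aa <- code[[paste(mut, collapse = "")]]
        if (to_aa != "*") {
          open <- open + 1
          if (to_aa == from_aa) syn_open <- syn_open + 1
        }
      }
      s_d <- if (open > 0) k * syn_open / open else 0
    }
    out <- c(s_d = s_d, n_d = k - s_d)
  }
  cache[[key]] <- out
  out
}

#' Synonymous and nonsynonymous differences of a codon pair
#'
#' Codon-by-codon pathway enumeration: for each codon with k differing
#' positions, the k! single-step orderings are averaged (stop-crossing
#' pathways excluded), so per codon the synonymous plus nonsynonymous
#' differences equal the number of differing positions.
#'
#' @inheritParams site_counts
#' @return A list with `S_d` and `N_d`.
#' @export
diff_counts <- function(pair, code = standard_genetic_code()) {
  s_d <- n_d <- 0
  for (j in seq_len(pair$r)) {
    d <- diff_counts_codon(pair$codons1[j], pair$codons2[j], code)
    s_d <- s_d + d[["s_d"]]
    n_d <- n_d + d[["n_d"]]
  }
  list(S_d = s_d, N_d = n_d)
}

#' Jukes-Cantor correction
#'
#' Converts an observed difference proportion into substitutions per site,
#' `d = -0.75 * log(1 - 4 p / 3)`; undefined (returned as `NA`) for
#' `p >= 3/4`, where the correction saturates.
#'
#' @param p Proportion(s) of observed differences, in \[0, 1\].
#' @return Numeric vector of corrected distances, `NA` where undefined.
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("`p` must lie in [0, 1]")
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise dN/dS estimation for aligned codon sequence pairs
#'
#' For every row of `pairs`, counts synonymous and nonsynonymous sites and
#' differences, converts the difference proportions with the Jukes-Cantor
#' formula, and classifies the selective pressure: `dN/dS < 1` negative
#' (purifying), `= 1` neutral, `> 1` positive. The ratio is undefined when
#' `d_S` is zero or either correction saturates.
#'
#' @param pairs A data frame with columns `seq1`, `seq2` (aligned
#'   nucleotide strings) and optionally `pair_id`.
#' @param code Genetic code table.
#' @param stop_handling See [site_counts()].
#' @return A tibble with one row per pair: `pair_id`, `r`, `S`, `N`,
#'   `S_d`, `N_d`, `p_s`, `p_n`, `d_s`, `d_n`, `dnds`, `selection_class`.
#' @export
pairwise_rates <- function(pairs, code = standard_genetic_code(),
                           stop_handling = c("nonsynonymous", "exclude")) {
  stop_handling <- match.arg(stop_handling)
  stopifnot(is.data.frame(pairs), all(c("seq1", "seq2") %in% names(pairs)))
  pair_id <- pairs[["pair_id"]] %||% as.character(seq_len(nrow(pairs)))
  rows <- purrr::pmap(list(pairs$seq1, pairs$seq2, pair_id), function(s1, s2, pid) {
    cp <- codon_pair(s1, s2, code)
    if (cp$r == 0) abort(sprintf("pair %s has no retained codons", pid))
    sc <- site_counts(cp, code, stop_handling)
    if (sc$S == 0 || sc$N == 0) {
      abort(sprintf("pair %s is degenerate: S = %g, N = %g", pid, sc$S, sc$N))
    }
    dc <- diff_counts(cp, code)
    p_s <- dc$S_d / sc$S
    p_n <- dc$N_d / sc$N
    d_s <- jukes_cantor(p_s)
    d_n <- jukes_cantor(p_n)
    dnds <- if (is.na(d_s) || is.na(d_n) || d_s == 0) NA_real_ else d_n / d_s
    cls <- if (is.na(dnds)) "undefined"
           else if (dnds < 1) "negative"
           else if (dnds > 1) "positive"
           else "neutral"
    tibble(pair_id = pid, r = cp$r, S = sc$S, N = sc$N,
           S_d = dc$S_d, N_d = dc$N_d, p_s = p_s, p_n = p_n,
           d_s = d_s, d_n = d_n, dnds = dnds, selection_class = cls)
  })
  bind_rows(rows)
}

#' Summarise selection pressure over a set of pairs
#'
#' Empirical cumulative distribution of the defined dN/dS ratios plus the
#' fraction of pairs under negative, neutral and positive selection;
#' undefined ratios are reported separately.
#'
#' @param rates A [pairwise_rates()] result.
#' @return A `selection_summary`: list with `fractions` (one-row tibble)
#'   and `cdf` (tibble `dnds`, `cumulative`).
#' @export
selection_summary <- function(rates) {
  stopifnot(is.data.frame(rates), "dnds" %in% names(rates))
  if (nrow(rates) == 0) abort("empty rates table")
  def <- rates$dnds[!is.na(rates$dnds)]
  if (length(def) == 0) abort("all dN/dS ratios are undefined")
  fractions <- tibble(
    n_pairs = nrow(rates),
    n_defined = length(def),
    n_undefined = sum(is.na(rates$dnds)),
    frac_negative = mean(def < 1),
    frac_neutral = mean(def == 1),
    frac_positive = mean(def > 1)
  )
  s <- sort(def)
  cdf <- tibble(dnds = s, cumulative = seq_along(s) / length(s))
  structure(list(fractions = fractions, cdf = cdf), class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  f <- x$fractions
  cat(sprintf(
    "dN/dS over %d pairs (%d defined): negative %.3f, neutral %.3f, positive %.3f\n",
    f$n_pairs, f$n_defined, f$frac_negative, f$frac_neutral, f$frac_positive))
  invisible(x)
}

#' @rdname selection_summary
#' @param x A `selection_summary`.
#' @param ... Unused.
#' @method tidy selection_summary
#' @export
tidy.selection_summary <- function(x, ...) x$cdf

#' @rdname selection_summary
#' @method glance selection_summary
#' @export
glance.selection_summary <- function(x, ...) x$fractions
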