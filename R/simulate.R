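# Seed-deterministic generators: planted-partition distance matrices that
# emulate the bimodal log-scale structure of sequence-similarity networks,
# and codon sequence pairs evolved under controlled synonymous /
# nonsynonymous substitution regimes.

#' Generate a planted-partition distance matrix
#'
#' Nodes are split into blocks; pairwise distances are drawn log-normally
#' (normal on the log10 scale) with a small intra-block scale and a much
#' larger inter-block scale, emulating the strongly bimodal edge-length
#' structure of E-value networks. A fraction of intra-block pairs can be
#' forced to distance zero to emulate fully conserved groups.
#'
#' @param block_sizes Integer vector of block sizes (default three blocks
#'   of 20).
#' @param intra_mean,intra_sd Mean and sd of intra-block log10 distances
#'   (defaults -120 and 2).
#' @param inter_mean,inter_sd Mean and sd of inter-block log10 distances
#'   (defaults -10 and 2).
#' @param density_within,density_between Probability that a pair gets an
#'   edge at all (default 1).
#' @param zero_frac Fraction of intra-block pairs set to exact zero
#'   distance (default 0).
#' @param seed Integer random seed; identical seeds give identical output.
#' @return A list with `distances` (edge tibble with `attr(, "ids")`) and
#'   `labels` (tibble `id`, `block`).
#' @export
generate_distances <- function(block_sizes = c(20L, 20L, 20L),
                               intra_mean = -120, intra_sd = 2,
                               inter_mean = -10, inter_sd = 2,
                               density_within = 1, density_between = 1,
                               zero_frac = 0, seed = 1L) {
  stopifnot(all(block_sizes >= 1))
  if (inter_mean <= intra_mean) {
    warn("inter-block scale is not larger than intra-block scale; blocks will not separate")
  }
  set.seed(seed)
  n <- sum(block_sizes)
  ids <- sprintf("s%03d", seq_len(n))
  block <- rep(seq_along(block_sizes), block_sizes)
  pairs <- utils::combn(n, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  same <- block[i] == block[j]
  keep <- runif(length(i)) < ifelse(same, density_within, density_between)
  ld <- ifelse(same, rnorm(length(i), intra_mean, intra_sd),
               rnorm(length(i), inter_mean, inter_sd))
  d <- 10^ld
  if (zero_frac > 0) {
    zero <- same & (runif(length(i)) < zero_frac)
    d[zero] <- 0
  }
  edges <- tibble(id1 = ids[i][keep], id2 = ids[j][keep],
                  distance = d[keep]) |>
    canonicalize_edges()
  attr(edges, "ids") <- ids
  list(distances = edges,
       labels = tibble(id = ids, block = block))
}

#' Simulate aligned codon sequence pairs under a substitution regime
#'
#' An ancestral sequence of `r` codons is drawn uniformly over the sense
#' codons of the code; the two pair members then diverge independently:
#' at every nucleotide site, with probability `p_syn` a synonymous
#' single-nucleotide change is applied (if one exists at that site) and
#' with probability `p_nonsyn` a nonsynonymous one, chosen uniformly
#' among the qualifying alternatives. Substitutions are only ever drawn
#' from sense codons, so stop codons never arise. The generating regime
#' (`"negative"` when `p_nonsyn < p_syn`, `"positive"` when
#' `p_nonsyn > p_syn`, else `"neutral"`) is recorded as ground truth.
#'
#' @param n_pairs Number of pairs to generate.
#' @param r Number of codons per sequence (default 300).
#' @param p_syn,p_nonsyn Per-site substitution probabilities
#'   (`p_syn + p_nonsyn <= 1`).
#' @param code Genetic code table.
#' @param seed Integer random seed.
#' @return A tibble with columns `pair_id`, `seq1`, `seq2`, `regime`.
#' @export
generate_codon_pairs <- function(n_pairs, r = 300L, p_syn = 0.06,
                                 p_nonsyn = 0.12,
                                 code = standard_genetic_code(), seed = 1L) {
  stopifnot(r >= 1, p_syn >= 0, p_nonsyn >= 0, p_syn + p_nonsyn <= 1)
  set.seed(seed)
  sense <- sense_codons(code)
  regime <- if (p_nonsyn < p_syn) "negative" else if (p_nonsyn > p_syn) "positive" else "neutral"
  out <- purrr::map(seq_len(n_pairs), function(p) {
    anc <- sample(sense, r, replace = TRUE)
    tibble(pair_id = sprintf("pair%04d", p),
           seq1 = paste(mutate_codons(anc, p_syn, p_nonsyn, code), collapse = ""),
           seq2 = paste(mutate_codons(anc, p_syn, p_nonsyn, code), collapse = ""),
           regime = regime)
  })
  bind_rows(out)
}

# Apply per-site synonymous/nonsynonymous substitutions to a codon vector.
mutate_codons <- function(codons, p_syn, p_nonsyn, code) {
  vapply(codons, function(cd) {
    ch <- strsplit(cd, "")[[1]]
    for (i in 1:3) {
      u <- runif(1)
      want_syn <- u < p_syn
      want_non <- !want_syn && u < p_syn + p_nonsyn
      if (!want_syn && !want_non) next
      cur_aa <- code[[paste(ch, collapse = "")]]
      alts <- setdiff(NUC, ch[i])
      cands <- character()
      for (b in alts) {
        mut <- ch; mut[i] <- b
        mcd <- paste(mut, collapse = "")
        if (code[[mcd]] == "*") next
        syn <- code[[mcd]] == cur_aa
        if ((want_syn && syn) || (want_non && !syn)) cands <- c(cands, b)
      }
      if (length(cands) > 0) ch[i] <- sample(cands, 1)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
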