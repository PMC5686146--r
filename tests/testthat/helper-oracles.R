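# Independent brute-force oracles. These share no code with the package:
# results are recomputed from first principles so that agreement is a real
# cross-check.

# random sparse symmetric distance table over n nodes
rand_dist_table <- function(n, density = 0.4, seed = 1, log_lo = -150, log_hi = -5) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pr <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pr)) < density
  tib <- tibble::tibble(
    id1 = ids[pr[1, keep]],
    id2 = ids[pr[2, keep]],
    distance = 10^stats::runif(sum(keep), log_lo, log_hi)
  )
  attr(tib, "ids") <- ids
  tib
}

# per-row argmin nearest neighbour from a dense matrix, smallest-id ties
oracle_nn <- function(edges, ids) {
  m <- matrix(Inf, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(edges))) {
    m[edges$id1[r], edges$id2[r]] <- edges$distance[r]
    m[edges$id2[r], edges$id1[r]] <- edges$distance[r]
  }
  rows <- list()
  for (id in ids) {
    v <- m[id, ]
    v <- v[names(v) != id]
    if (all(!is.finite(v))) next
    best <- min(v)
    nbr <- sort(names(v)[v == best])[1]
    rows[[id]] <- data.frame(node = id, neighbor = nbr, distance = best)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out <- out[order(out$distance, out$node, out$neighbor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# connected components of an undirected edge list, by repeated sweeps
oracle_components <- function(edges, ids) {
  comp <- stats::setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      a <- comp[[edges[[1]][r]]]; b <- comp[[edges[[2]][r]]]
      if (a != b) {
        comp[comp == max(a, b)] <- min(a, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(comp), comp)
}

# Kruskal minimum spanning forest total weight (recursive find)
oracle_kruskal_weight <- function(edges) {
  ids <- sort(unique(c(edges$id1, edges$id2)))
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  o <- order(edges$distance)
  total <- 0
  for (r in o) {
    ra <- find(edges$id1[r]); rb <- find(edges$id2[r])
    if (ra != rb) {
      parent[[rb]] <- ra
      total <- total + edges$distance[r]
    }
  }
  total
}

# exhaustive-threshold F optimum: try a threshold just below and just above
# every observed minimum log distance
oracle_best_f <- function(min_log, positive) {
  u <- sort(unique(min_log[is.finite(min_log)]))
  cands <- unique(c(u - 1e-9, u + 1e-9, if (length(u)) max(u) + 1 else 0))
  best <- 0
  for (t in cands) {
    pred <- min_log < t
    tp <- sum(pred & positive); fp <- sum(pred & !positive); fn <- sum(!pred & positive)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    if (f > best) best <- f
  }
  best
}

# ---- independent Nei-Gojobori enumeration ----------------------------

.oracle_code <- as.character(Biostrings::GENETIC_CODE)
names(.oracle_code) <- names(Biostrings::GENETIC_CODE)

.oracle_perms <- list(
  "1" = list(1L),
  "2" = list(c(1L, 2L), c(2L, 1L)),
  "3" = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

oracle_codon_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  aa <- .oracle_code[[codon]]
  s <- 0
  for (i in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == ch[i]) next
      mut <- ch; mut[i] <- b
      if (.oracle_code[[paste0(mut[1], mut[2], mut[3])]] == aa) s <- s + 1 / 3
    }
  }
  c(s = s, n = 3 - s)
}

oracle_codon_diffs <- function(c1, c2) {
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  pos <- which(ch1 != ch2)
  k <- length(pos)
  if (k == 0) return(c(s_d = 0, n_d = 0))
  syns <- c()
  for (ord in .oracle_perms[[as.character(k)]]) {
    cur <- ch1; nsyn <- 0; ok <- TRUE
    for (step_pos in pos[ord]) {
      before <- .oracle_code[[paste0(cur[1], cur[2], cur[3])]]
      cur[step_pos] <- ch2[step_pos]
      after <- .oracle_code[[paste0(cur[1], cur[2], cur[3])]]
      if (after == "*") ok <- FALSE
      if (before == after && after != "*") nsyn <- nsyn + 1
    }
    if (ok) syns <- c(syns, nsyn)
  }
  if (length(syns) > 0) {
    s_d <- sum(syns) / length(syns)
  } else {
    open <- 0; syn_open <- 0
    for (p in pos) {
      mut <- ch1; mut[p] <- ch2[p]
      after <- .oracle_code[[paste0(mut[1], mut[2], mut[3])]]
      if (after != "*") {
        open <- open + 1
        if (after == .oracle_code[[c1]]) syn_open <- syn_open + 1
      }
    }
    s_d <- if (open > 0) k * syn_open / open else 0
  }
  c(s_d = s_d, n_d = k - s_d)
}

oracle_ng_pair <- function(seq1, seq2) {
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  c1 <- split3(seq1); c2 <- split3(seq2)
  S1 <- sum(vapply(c1, function(cd) oracle_codon_sites(cd)[["s"]], 1))
  S2 <- sum(vapply(c2, function(cd) oracle_codon_sites(cd)[["s"]], 1))
  diffs <- mapply(function(a, b) oracle_codon_diffs(a, b), c1, c2)
  list(S = (S1 + S2) / 2, N = 3 * length(c1) - (S1 + S2) / 2,
       S_d = sum(diffs["s_d", ]), N_d = sum(diffs["n_d", ]),
       per_codon = diffs)
}

# random sense-codon sequence
rand_codon_seq <- function(r) {
  sense <- names(.oracle_code)[.oracle_code != "*"]
  paste(sample(sense, r, replace = TRUE), collapse = "")
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
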