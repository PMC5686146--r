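ev_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(query = vapply(rows, `[[`, "", 1),
                 subject = vapply(rows, `[[`, "", 2),
                 evalue = vapply(rows, function(r) as.numeric(r[[3]]), 1))
}

test_that("symmetrize takes the geometric mean of the two directions", {
  d <- symmetrize(ev_tbl(list("a", "b", 4e-10), list("b", "a", 1e-10)))
  expect_equal(d$distance, 2e-10)

  # geometric mean must not underflow for small E-values
  d2 <- symmetrize(ev_tbl(list("a", "b", 1e-200), list("b", "a", 1e-200)))
  expect_equal(d2$distance, 1e-200)
})

test_that("mutual zero E-values give a zero distance and one zero group", {
  d <- symmetrize(ev_tbl(list("a", "b", 0), list("b", "a", 0),
                         list("a", "c", 1e-5), list("c", "a", 1e-5)))
  expect_equal(d$distance[d$id1 == "a" & d$id2 == "b"], 0)
  zg <- zero_groups(d)
  expect_equal(zg$zero_group[zg$id == "a"], zg$zero_group[zg$id == "b"])
  expect_false(zg$zero_group[zg$id == "c"] == zg$zero_group[zg$id == "a"])
})

test_that("one-directional hits are dropped or capped per policy", {
  one <- ev_tbl(list("a", "b", 1e-20))
  expect_equal(nrow(symmetrize(one, missing_policy = "drop")), 0)
  capped <- symmetrize(one, missing_policy = "cap", cap_value = 10)
  expect_equal(capped$distance, sqrt(1e-20 * 10))
  expect_error(symmetrize(one, missing_policy = "cap", cap_value = -1), "positive")
})

test_that("E-values above the ceiling are discarded before symmetrization", {
  d <- symmetrize(ev_tbl(list("a", "b", 5), list("b", "a", 1e-30)))
  expect_equal(nrow(d), 0)
  d2 <- symmetrize(ev_tbl(list("a", "b", 5), list("b", "a", 1e-30)),
                   evalue_ceiling = 10)
  expect_equal(d2$distance, sqrt(5e-30))
})

test_that("symmetrize is invariant under transposing the E-value table", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 8
    ids <- letters[1:n]
    pairs <- expand.grid(query = ids, subject = ids, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$query != pairs$subject, ]
    pairs <- pairs[runif(nrow(pairs)) < 0.6, ]
    pairs$evalue <- 10^runif(nrow(pairs), -80, 0)
    tab <- tibble::as_tibble(pairs)
    flipped <- dplyr::rename(tab, query = "subject", subject = "query")
    expect_equal(as.data.frame(symmetrize(tab)),
                 as.data.frame(symmetrize(flipped)))
    # direct-formula check on pairs present in both directions
    d <- symmetrize(tab)
    for (r in seq_len(nrow(d))) {
      e1 <- tab$evalue[tab$query == d$id1[r] & tab$subject == d$id2[r]]
      e2 <- tab$evalue[tab$query == d$id2[r] & tab$subject == d$id1[r]]
      expect_equal(d$distance[r], sqrt(min(e1) * min(e2)), tolerance = 1e-12)
    }
  }
})

test_that("collapsing zero groups takes the minimum cross-pair distance", {
  d <- tibble::tibble(id1 = c("a", "a", "b"), id2 = c("b", "c", "c"),
                      distance = c(0, 1e-5, 1e-7))
  attr(d, "ids") <- c("a", "b", "c")
  cz <- collapse_zero_groups(d)
  expect_equal(nrow(cz$distances), 1)
  expect_equal(cz$distances$distance, 1e-7)
  expect_equal(sort(cz$members$id), c("a", "b", "c"))
  expect_equal(unique(cz$members$node[cz$members$id %in% c("a", "b")]), "a")
})

canonicalize_edges_for_test <- function(d) {
  d <- d[order(d$distance, d$id1, d$id2), c("id1", "id2", "distance")]
  tibble::as_tibble(d)
}

test_that("collapse is the identity for all-singleton matrices", {
  d <- tibble::tibble(id1 = c("a", "b"), id2 = c("b", "c"),
                      distance = c(1e-10, 1e-20))
  attr(d, "ids") <- c("a", "b", "c")
  cz <- collapse_zero_groups(d)
  expect_equal(as.data.frame(cz$distances[, 1:3]),
               as.data.frame(canonicalize_edges_for_test(d)))
  expect_equal(cz$members$node, cz$members$id)
})

test_that("a fully conserved matrix collapses to a single super-node", {
  d <- tibble::tibble(id1 = c("a", "a", "b"), id2 = c("b", "c", "c"),
                      distance = c(0, 0, 0))
  attr(d, "ids") <- c("a", "b", "c")
  cz <- collapse_zero_groups(d)
  expect_equal(nrow(cz$distances), 0)
  expect_equal(unique(cz$members$node), "a")
  expect_equal(nrow(cz$members), 3)
})

test_that("collapsed distances equal the brute-force minimum over cross pairs", {
  for (seed in 1:10) {
    sim <- generate_distances(block_sizes = c(6L, 6L), zero_frac = 0.4,
                              intra_mean = -60, inter_mean = -8, seed = seed)
    d <- sim$distances
    cz <- collapse_zero_groups(d)
    expect_equal(nrow(cz$members), length(attr(d, "ids")))
    grp <- stats::setNames(cz$members$node, cz$members$id)
    for (r in seq_len(nrow(cz$distances))) {
      g1 <- cz$distances$id1[r]; g2 <- cz$distances$id2[r]
      cross <- d[grp[d$id1] != grp[d$id2] &
                   ((grp[d$id1] == g1 & grp[d$id2] == g2) |
                    (grp[d$id1] == g2 & grp[d$id2] == g1)), ]
      expect_equal(cz$distances$distance[r], min(cross$distance))
    }
  }
})
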