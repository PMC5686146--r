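tri_dist <- function(d_ab, d_bc, d_ac) {
  d <- tibble::tibble(id1 = c("a", "b", "a"), id2 = c("b", "c", "c"),
                      distance = c(d_ab, d_bc, d_ac))
  attr(d, "ids") <- c("a", "b", "c")
  d
}

test_that("nearest-neighbour list keeps both directions of a mutual pair", {
  nn <- nearest_neighbor_list(tri_dist(1, 2, 3))
  expect_equal(nn$node, c("a", "b", "c"))
  expect_equal(nn$neighbor, c("b", "a", "b"))
  expect_equal(nn$distance, c(1, 1, 2))
})

test_that("nearest-neighbour list of an edgeless matrix is empty", {
  d <- tibble::tibble(id1 = character(), id2 = character(), distance = double())
  expect_equal(nrow(nearest_neighbor_list(d)), 0)
})

test_that("nearest-neighbour list matches the brute-force argmin oracle", {
  for (seed in 1:25) {
    d <- rand_dist_table(50, density = 0.15, seed = seed)
    nn <- nearest_neighbor_list(d)
    expected <- oracle_nn(d, attr(d, "ids"))
    expect_equal(as.data.frame(nn), expected, tolerance = 1e-15,
                 ignore_attr = TRUE)
  }
})

test_that("cluster growth follows the ascending-distance rules", {
  # chain: core pair (a, b), then c joins
  nn <- nearest_neighbor_list(tri_dist(1, 5, 10))
  lvl <- build_clusters(nn, units = c("a", "b", "c"))
  expect_equal(sum(!is.na(unique(lvl$membership$cluster))), 1)
  core <- lvl$edges[lvl$edges$is_core, ]
  expect_setequal(c(core$u, core$v), c("a", "b"))
  expect_equal(nrow(lvl$edges), 2)  # spanning tree of 3 nodes

  # two well-separated pairs form two clusters
  d <- tibble::tibble(id1 = c("a", "c"), id2 = c("b", "d"), distance = c(1, 2))
  attr(d, "ids") <- c("a", "b", "c", "d")
  lvl2 <- build_clusters(nearest_neighbor_list(d), units = attr(d, "ids"))
  expect_equal(sort(unique(stats::na.omit(lvl2$membership$cluster))),
               c("C1-001", "C1-002"))
})

test_that("clusters equal the connected components of the NN graph", {
  for (seed in 1:25) {
    d <- rand_dist_table(50, density = 0.2, seed = seed + 100)
    nn <- nearest_neighbor_list(d)
    lvl <- build_clusters(nn, units = attr(d, "ids"))
    got <- split(lvl$membership$unit[!lvl$membership$is_outlier],
                 lvl$membership$cluster[!lvl$membership$is_outlier])
    comp <- oracle_components(nn[, c("node", "neighbor")],
                              sort(unique(c(nn$node, nn$neighbor))))
    comp <- Filter(function(x) length(x) >= 2, comp)
    norm <- function(x) sort(vapply(x, function(g) paste(sort(g), collapse = ","), ""))
    expect_equal(unname(norm(got)), unname(norm(comp)))
    # tree property: per-cluster edge count = member count - 1
    sizes <- table(lvl$membership$cluster[!lvl$membership$is_outlier])
    ecnt <- table(lvl$edges$cluster)
    expect_equal(as.integer(ecnt[names(sizes)]), as.integer(sizes) - 1L)
  }
})

test_that("truncation deletes long bonds and splits components", {
  d <- tri_dist(1e-100, 1e-50, 1e-20)
  lvl <- build_clusters(nearest_neighbor_list(d), units = attr(d, "ids"))
  tr <- truncate_clusters(lvl, 1e-80)
  expect_equal(tr$threshold, 1e-80)
  mem <- tr$membership
  expect_setequal(mem$unit[!mem$is_outlier], c("a", "b"))
  expect_equal(mem$unit[mem$is_outlier], "c")
  # all edges below the threshold: level unchanged up to labels
  tr2 <- truncate_clusters(lvl, 1e-10)
  expect_equal(tr2$membership$cluster, lvl$membership$cluster)
  expect_error(truncate_clusters(lvl, -1), "positive")
})

test_that("truncation agrees with brute-force components of the kept edges", {
  for (seed in 1:20) {
    d <- rand_dist_table(30, density = 0.3, seed = seed + 200)
    lvl <- build_clusters(nearest_neighbor_list(d), units = attr(d, "ids"))
    set.seed(seed)
    d_t <- 10^runif(1, -140, -10)
    tr <- truncate_clusters(lvl, d_t)
    kept <- lvl$edges[lvl$edges$distance <= d_t, ]
    comp <- oracle_components(kept[, c("u", "v")], attr(d, "ids"))
    comp_big <- Filter(function(x) length(x) >= 2, comp)
    got <- split(tr$membership$unit[!tr$membership$is_outlier],
                 tr$membership$cluster[!tr$membership$is_outlier])
    norm <- function(x) sort(vapply(x, function(g) paste(sort(g), collapse = ","), ""))
    expect_equal(unname(norm(got)), unname(norm(comp_big)))
    expect_true(all(tr$edges$distance <= d_t))
  }
})

test_that("renormalized distances are the minimum over cross pairs", {
  d <- tibble::tibble(id1 = c("a", "a", "b"), id2 = c("b", "c", "c"),
                      distance = c(1e-100, 1e-6, 1e-9))
  attr(d, "ids") <- c("a", "b", "c")
  lvl <- truncate_clusters(
    build_clusters(nearest_neighbor_list(d), units = attr(d, "ids")), 1e-50)
  ren <- renormalize(lvl, d)
  expect_equal(nrow(ren), 1)
  expect_equal(ren$distance, 1e-9)

  for (seed in 1:15) {
    d <- rand_dist_table(30, density = 0.3, seed = seed + 300)
    lvl <- build_clusters(nearest_neighbor_list(d), units = attr(d, "ids"))
    set.seed(seed)
    lvl <- truncate_clusters(lvl, 10^runif(1, -120, -20))
    ren <- renormalize(lvl, d)
    mem <- lvl$membership
    map <- stats::setNames(ifelse(mem$is_outlier, mem$unit, mem$cluster), mem$unit)
    for (r in seq_len(nrow(ren))) {
      cross <- d[map[d$id1] != map[d$id2] &
                   ((map[d$id1] == ren$id1[r] & map[d$id2] == ren$id2[r]) |
                    (map[d$id1] == ren$id2[r] & map[d$id2] == ren$id1[r])), ]
      expect_equal(ren$distance[r], min(cross$distance))
    }
    # units with no finite cross pair have no edge: everything present is finite
    expect_true(all(is.finite(ren$distance)))
  }
})

test_that("threshold estimation separates bimodal edge lengths and returns none for unimodal", {
  for (seed in 1:15) {
    sim <- generate_distances(intra_mean = -100, intra_sd = 2,
                              inter_mean = -20, inter_sd = 2, seed = seed)
    h <- run_msc(sim$distances, max_levels = 1)
    dt <- h$thresholds$threshold[1]
    expect_gt(dt, 1e-90)
    expect_lt(dt, 1e-30)
  }
  sim1 <- generate_distances(block_sizes = 40L, seed = 5)
  h1 <- run_msc(sim1$distances, max_levels = 1)
  expect_true(is.na(h1$thresholds$threshold[1]))
  expect_error(estimate_threshold(tibble::tibble()), "empty")
})

test_that("planted blocks: level-1 clusters are pure and the hierarchy recovers the blocks", {
  for (seed in 1:10) {
    sim <- generate_distances(seed = seed)
    h <- run_msc(sim$distances)
    blk <- stats::setNames(sim$labels$block, sim$labels$id)
    p1 <- partition_at(h, 1)
    purity <- vapply(split(blk[p1$sequence_id], p1$group),
                     function(x) length(unique(x)) == 1, TRUE)
    expect_true(all(purity))
    pf <- partition_at(h)
    expect_equal(adjusted_rand(pf$group, blk[pf$sequence_id]), 1.0)
  }
})

test_that("hierarchy invariants: nested membership, completeness, trees", {
  sim <- generate_distances(block_sizes = c(15L, 15L, 15L), seed = 42)
  h <- run_msc(sim$distances)
  n <- length(h$ids)
  for (k in seq_along(h$levels)) {
    ak <- h$assignments[h$assignments$level == k, ]
    # every sequence appears exactly once per level
    expect_equal(sort(ak$sequence_id), sort(h$ids))
    lvl <- h$levels[[k]]
    sizes <- table(lvl$membership$cluster[!lvl$membership$is_outlier])
    if (length(sizes) > 0) {
      ecnt <- table(lvl$edges$cluster)
      expect_equal(as.integer(ecnt[names(sizes)]), as.integer(sizes) - 1L)
      expect_true(all(lvl$edges$distance <= lvl$threshold | is.na(lvl$threshold)))
    }
    if (k > 1) {
      # nesting: each level-k unit is a union of level-(k-1) units
      prev <- h$assignments[h$assignments$level == k - 1, ]
      joined <- merge(ak, prev, by = "sequence_id")
      crossed <- tapply(joined$unit.y, joined$unit.x,
                        function(u) length(unique(u)))
      prev_sizes <- tapply(joined$sequence_id, joined$unit.y, length)
      # no level-(k-1) unit is split across two level-k units
      splitcount <- tapply(joined$unit.x, joined$unit.y,
                           function(u) length(unique(u)))
      expect_true(all(splitcount == 1))
    }
  }
})

test_that("a single pair terminates with one cluster and identical reruns match", {
  d <- tibble::tibble(id1 = "a", id2 = "b", distance = 1e-30)
  attr(d, "ids") <- c("a", "b")
  h <- run_msc(d)
  expect_equal(length(h$levels), 1)
  expect_equal(sum(!is.na(unique(h$levels[[1]]$membership$cluster))), 1)

  sim <- generate_distances(seed = 8)
  h1 <- run_msc(sim$distances)
  h2 <- run_msc(sim$distances)
  expect_identical(tidy(h1), tidy(h2))
  expect_identical(h1$thresholds, h2$thresholds)
})

test_that("spanning forest weight matches a brute-force Kruskal oracle", {
  # forced MST of a triangle
  fo <- spanning_forest(tri_dist(1, 2, 3))
  expect_equal(sum(fo$edges$distance), 3)
  expect_equal(nrow(fo$edges), 2)

  # a single node has no edges
  empty <- tibble::tibble(id1 = character(), id2 = character(), distance = double())
  attr(empty, "ids") <- "a"
  expect_equal(nrow(spanning_forest(empty)$edges), 0)

  for (seed in 1:15) {
    d <- rand_dist_table(40, density = 0.4, seed = seed + 400)
    fo <- spanning_forest(d)
    expect_equal(sum(fo$edges$distance), oracle_kruskal_weight(d),
                 tolerance = 1e-12)
  }
})

test_that("degrees and hubs are reported on the coarse-grained forest", {
  sim <- generate_distances(seed = 21)
  h <- run_msc(sim$distances)
  fo <- cluster_forest(h, 1)
  expect_equal(sum(fo$nodes$degree), 2 * nrow(fo$edges))
  stats <- network_stats(h, sim$distances, level = 1)
  expect_true(all(stats$hubs$degree >= 1))
  expect_equal(max(stats$degrees$degree), max(stats$hubs$degree))
})
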