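test_that("site counts follow the 9-change enumeration and conserve S + N = 3r", {
  # single codon against itself: check against the direct enumeration oracle
  for (cd in c("TTT", "ATG", "CTA", "CGG", "TGG")) {
    pair <- codon_pair(cd, cd)
    sc <- site_counts(pair)
    osc <- oracle_codon_sites(cd)
    expect_equal(sc$S, osc[["s"]])
    expect_equal(sc$S + sc$N, 3)
  }
  # random pairs conserve sites exactly
  set.seed(1)
  for (i in 1:20) {
    s1 <- rand_codon_seq(12); s2 <- rand_codon_seq(12)
    pair <- codon_pair(s1, s2)
    sc <- site_counts(pair)
    expect_equal(sc$S + sc$N, 3 * pair$r, tolerance = 1e-12)
  }
})

test_that("gap and ambiguity codons are excluded pairwise", {
  pair <- codon_pair("ATG---AAA", "ATGTTTAAN")
  expect_equal(pair$r, 1)  # middle codon gapped in seq1, last ambiguous in seq2
  expect_equal(pair$codons1, "ATG")
  expect_equal(pair$codons2, "ATG")
  # stop codons are excluded pairwise as well
  expect_equal(codon_pair("ATGTGA", "ATGTGG")$r, 1)
  expect_error(codon_pair("ATG", "ATGAAA"), "equal length")
})

test_that("pathway enumeration yields 1, 2 and 6 orderings", {
  expect_equal(length(unique(codon_pathways("TTT", "TTC")$pathway)), 1)
  expect_equal(length(unique(codon_pathways("TTT", "TCG")$pathway)), 2)
  expect_equal(length(unique(codon_pathways("TTT", "CAG")$pathway)), 6)
  expect_equal(nrow(codon_pathways("ATG", "ATG")), 0)
})

test_that("identical codons give zero differences; diffs conserve the Hamming count", {
  pair <- codon_pair("ATGATG", "ATGATG")
  dc <- diff_counts(pair)
  expect_equal(dc$S_d, 0)
  expect_equal(dc$N_d, 0)

  set.seed(2)
  for (i in 1:20) {
    s1 <- rand_codon_seq(10); s2 <- rand_codon_seq(10)
    pair <- codon_pair(s1, s2)
    dc <- diff_counts(pair)
    hamming <- sum(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
    expect_equal(dc$S_d + dc$N_d, hamming, tolerance = 1e-12)
  }
})

test_that("site and difference counts match the independent enumeration oracle", {
  set.seed(3)
  for (i in 1:100) {
    s1 <- rand_codon_seq(8); s2 <- rand_codon_seq(8)
    pair <- codon_pair(s1, s2)
    sc <- site_counts(pair)
    dc <- diff_counts(pair)
    o <- oracle_ng_pair(s1, s2)
    expect_equal(sc$S, o$S, tolerance = 1e-12)
    expect_equal(sc$N, o$N, tolerance = 1e-12)
    expect_equal(dc$S_d, o$S_d, tolerance = 1e-12)
    expect_equal(dc$N_d, o$N_d, tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction follows the closed form and saturates", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.1), -0.75 * log(1 - 0.4 / 3))
  expect_equal(round(jukes_cantor(0.1), 6), 0.107326)
  expect_true(is.na(jukes_cantor(0.75)))
  expect_true(is.na(jukes_cantor(0.9)))
  expect_equal(jukes_cantor(1e-6) / 1e-6, 1, tolerance = 1e-5)
  expect_error(jukes_cantor(-0.1), "\\[0, 1\\]")
  expect_error(jukes_cantor(1.1), "\\[0, 1\\]")
})

test_that("identical sequences have an undefined ratio; synonymous-only pairs are negative", {
  rt <- pairwise_rates(tibble::tibble(seq1 = "ATGGTGAAA", seq2 = "ATGGTGAAA"))
  expect_equal(rt$d_s, 0)
  expect_equal(rt$d_n, 0)
  expect_true(is.na(rt$dnds))
  expect_equal(rt$selection_class, "undefined")

  syn_only <- generate_codon_pairs(5, r = 50, p_syn = 0.2, p_nonsyn = 0,
                                   seed = 7)
  rt2 <- pairwise_rates(syn_only)
  expect_true(all(rt2$S_d > 0))
  expect_true(all(rt2$dnds < 1))
  expect_true(all(rt2$selection_class == "negative"))
})

test_that("degenerate pairs with no synonymous sites raise a named error", {
  # a codon whose 9 neighbours are all nonsynonymous: TGG (Trp) alone
  expect_error(pairwise_rates(tibble::tibble(seq1 = "TGG", seq2 = "TGG",
                                             pair_id = "w")),
               "degenerate")
})

test_that("selection summary reports class fractions and the CDF", {
  rates <- tibble::tibble(dnds = c(0.5, 2.0, NA, 1.0))
  s <- selection_summary(rates)
  f <- glance(s)
  expect_equal(f$frac_negative, 1 / 3)
  expect_equal(f$frac_positive, 1 / 3)
  expect_equal(f$frac_neutral, 1 / 3)
  expect_equal(f$n_undefined, 1)
  expect_equal(tidy(s)$cumulative, c(1, 2, 3) / 3)

  all_neg <- selection_summary(tibble::tibble(dnds = c(0.1, 0.5, 0.9)))
  expect_equal(glance(all_neg)$frac_negative, 1)
  expect_error(selection_summary(tibble::tibble(dnds = NA_real_)),
               "undefined")
})

test_that("a 70/30 regime mixture is recovered within 5 points", {
  neg <- generate_codon_pairs(105, r = 100, p_syn = 0.12, p_nonsyn = 0.06,
                              seed = 31)
  pos <- generate_codon_pairs(45, r = 100, p_syn = 0.06, p_nonsyn = 0.12,
                              seed = 32)
  rates <- pairwise_rates(dplyr::bind_rows(neg, pos))
  s <- glance(selection_summary(rates))
  expect_equal(s$frac_negative, 0.70, tolerance = 0.05 / 0.70)
})
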