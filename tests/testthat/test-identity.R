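test_that("global alignment handles exact and gapped cases", {
  p <- align_params(match = 1, mismatch = -1, gap_open = 1, gap_extend = 1)
  aln <- nw_align("ACDE", "ACDE", p)
  expect_equal(aln$score, 4)
  expect_equal(aln$aligned_a, "ACDE")
  expect_equal(aln$aligned_b, "ACDE")

  aln <- nw_align("ACDE", "ACE", p)
  expect_equal(aln$aligned_a, "ACDE")
  expect_equal(aln$aligned_b, "AC-E")
  expect_equal(aln$score, 3 - 2)  # 3 matches, one 1-column gap run

  expect_error(nw_align("", "ACDE", p), "empty")
})

test_that("alignment score equals the memoized affine-gap oracle", {
  # the enumeration and memoized oracles agree on tiny instances ...
  set.seed(61)
  sub <- simple_sub(2, -1)
  for (k in 1:10) {
    a <- random_seq(sample(1:4, 1))
    b <- random_seq(sample(1:4, 1))
    expect_equal(oracle_align_score(a, b, sub, 3, 1),
                 enumerate_best_score(a, b, sub, 3, 1))
  }
  # ... and the implementation matches the oracle on longer ones
  for (k in 1:40) {
    a <- random_seq(sample(1:8, 1))
    b <- random_seq(sample(1:8, 1))
    got <- nw_align(a, b, align_params(match = 2, mismatch = -1,
                                       gap_open = 3, gap_extend = 1))$score
    expect_equal(got, oracle_align_score(a, b, sub, 3, 1))
  }
})

test_that("percent identity definitions behave per mode", {
  m <- aa_msa(c(a = "AAAA", b = "AAAA", c = "AAAT", d = "AA--"))
  expect_equal(percent_identity_msa(m, "a", "b"), 100)
  expect_equal(percent_identity_msa(m, "a", "c"), 75)
  expect_equal(percent_identity_msa(m, "a", "d", "pairwise-deletion"), 100)
  expect_equal(percent_identity_msa(m, "a", "d", "alignment-length"), 50)
  expect_equal(percent_identity_msa(m, "a", "d", "shorter-length"), 100)
  expect_error(percent_identity_msa(m, "a", "zz"), "not in alignment")

  # symmetry over random pairs
  set.seed(67)
  rows <- setNames(vapply(1:5, function(i) {
    s <- strsplit(random_seq(60), "")[[1]]
    s[sample(60, 6)] <- "-"
    paste(s, collapse = "")
  }, character(1)), letters[1:5])
  m2 <- aa_msa(rows)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(percent_identity_msa(m2, letters[i], letters[j]),
                 percent_identity_msa(m2, letters[j], letters[i]))
  }
})

test_that("X never counts as an identity match", {
  m <- aa_msa(c(a = "AXAA", b = "AXAA"))
  expect_equal(percent_identity_msa(m, "a", "b"), 75)
})

test_that("comparison counts follow the within/cross formulas", {
  expect_equal(comparison_count(68, within = TRUE), 2278L)
  expect_equal(comparison_count(1, within = TRUE), 0L)
  expect_equal(comparison_count(68, 69), 4692L)
  expect_error(comparison_count(3, 4, within = TRUE), "n1 == n2")
})

test_that("group identity table aggregates means and counts", {
  # two groups of identical duplicates, all cross pairs at one mismatch level
  m <- aa_msa(c(g1a = "AAAAAAAAAA", g1b = "AAAAAAAAAA",
                g2a = "ACCCCCCCCC", g2b = "ACCCCCCCCC"))
  lab <- c(g1a = "I", g1b = "I", g2a = "CRAL_TRIO", g2b = "CRAL_TRIO")
  tab <- group_identity_table(identity_matrix(m), lab)
  get <- function(g1, g2) tab[tab$group1 == g1 & tab$group2 == g2, ]
  expect_equal(get("I", "I")$mean_identity, 100)
  expect_equal(get("I", "I")$n_comparisons, 1L)
  expect_equal(get("CRAL_TRIO", "CRAL_TRIO")$mean_identity, 100)
  expect_equal(get("I", "CRAL_TRIO")$mean_identity, 10)
  expect_equal(get("I", "CRAL_TRIO")$n_comparisons, 4L)
})

test_that("single-group mean identity is the mean of its pairs", {
  # construct 3 sequences of length 10 with pairwise identities 50/60/70
  m <- aa_msa(c(a = "AAAAAAAAAA",
                b = "AAAAAACCCC",  # a-b: 6/10
                c = "AAAAADDDCC")) # a-c: 5/10, b-c: 7/10
  expect_equal(percent_identity_msa(m, "a", "b"), 60)
  expect_equal(percent_identity_msa(m, "a", "c"), 50)
  expect_equal(percent_identity_msa(m, "b", "c"), 70)
  tab <- group_identity_table(identity_matrix(m),
                              c(a = "I", b = "I", c = "I"))
  expect_equal(tab$mean_identity, 60)
  expect_equal(tab$n_comparisons, 3L)
})

test_that("table cell counts always reproduce comparison_count", {
  set.seed(71)
  ids <- sprintf("s%02d", 1:20)
  sizes <- c(I = 7, IIA = 5, CRAL_TRIO = 8)
  lab <- setNames(rep(names(sizes), sizes), ids)
  fake <- matrix(runif(400, 0, 100), 20, 20, dimnames = list(ids, ids))
  fake <- (fake + t(fake)) / 2
  diag(fake) <- 100
  tab <- group_identity_table(fake, lab)
  for (r in seq_len(nrow(tab))) {
    g1 <- tab$group1[r]
    g2 <- tab$group2[r]
    expected <- if (g1 == g2) {
      comparison_count(sizes[[g1]], within = TRUE)
    } else {
      comparison_count(sizes[[g1]], sizes[[g2]])
    }
    expect_equal(tab$n_comparisons[r], expected)
  }
})

test_that("unassigned ids are excluded with a warning", {
  m <- aa_msa(c(a = "AAAA", b = "AAAA", z = "CCCC"))
  lab <- c(a = "I", b = "I", z = "unassigned")
  expect_warning(tab <- group_identity_table(identity_matrix(m), lab),
                 "unassigned")
  expect_equal(nrow(tab), 1L)
  expect_error(group_identity_table(identity_matrix(m), lab[1:2]),
               "unlabeled")
})
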