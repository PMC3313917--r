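test_that("p-distances ignore gapped columns under complete deletion", {
  m <- aa_msa(c(a = "AAAA", b = "AAAA"))
  expect_equal(max(abs(distance_matrix(m))), 0)

  m <- aa_msa(c(a = "AAAA", b = "AATT"))
  expect_equal(distance_matrix(m)["a", "b"], 0.5)

  # gap in one row removes that column for every pair
  m <- aa_msa(c(a = "AAAA", b = "AAAT", c = "AA-A"))
  d <- distance_matrix(m, "complete-deletion")
  expect_equal(d["a", "b"], 1 / 3)  # 3 retained columns, 1 mismatch
  expect_equal(d["a", "c"], 0)

  allgap <- aa_msa(c(a = "A-", b = "-A"))
  expect_error(distance_matrix(allgap, "complete-deletion"),
               "pairwise-deletion")
})

test_that("three-leaf NJ reproduces the three-point formulas", {
  d <- matrix(c(0, 0.2, 0.3,
                0.2, 0, 0.4,
                0.3, 0.4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], 0.05)
  expect_equal(bl[["b"]], 0.15)
  expect_equal(bl[["c"]], 0.25)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers the stated four-leaf additive tree exactly", {
  gen <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.3,D:0.4):0.0);")
  dm <- ape::cophenetic.phylo(gen)
  tr <- nj_tree(dm)
  # path distances reproduce the generating matrix ...
  got <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_lt(max(abs(got - dm)), 1e-9)
  # ... with the AB|CD topology
  expect_equal(unrooted_rf(tr, gen), 0)
})

test_that("NJ reproduces additive path distances on random trees", {
  set.seed(73)
  for (k in 1:20) {
    case <- random_additive_case(sample(4:8, 1))
    tr <- nj_tree(case$dm)
    got <- ape::cophenetic.phylo(tr)[rownames(case$dm), colnames(case$dm)]
    expect_lt(max(abs(got - case$dm)), 1e-9)
    expect_equal(unrooted_rf(tr, case$tree), 0)
  }
})

test_that("NJ agrees with the reference implementation in ape", {
  set.seed(79)
  case <- random_additive_case(7)
  noisy <- case$dm + matrix(runif(49, 0, 0.01), 7, 7)
  noisy <- (noisy + t(noisy)) / 2
  diag(noisy) <- 0
  expect_equal(unrooted_rf(nj_tree(noisy), ape::nj(noisy)), 0)
})

test_that("negative branch estimates are clamped and logged", {
  # violates the triangle inequality: the three-point formula for 'a'
  # gives (0.2 + 0.3 - 0.6) / 2 = -0.05
  d <- matrix(c(0, 0.2, 0.3,
                0.2, 0, 0.6,
                0.3, 0.6, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], 0)
  expect_equal(attr(tr, "negative_deficit"), 0.05)
})

test_that("bootstrap supports are reproducible and saturate on strong signal", {
  set.seed(83)
  # alignment whose informative columns repeat many times: resampling
  # cannot lose the signal, so every true split gets 100
  block <- c(a = "AAAA", b = "AAAC", c = "CCGG", d = "CCGT")
  rows <- setNames(vapply(block, function(s) strrep(s, 25), character(1)),
                   names(block))
  m <- aa_msa(rows)
  cfg <- phylo_config(n_bootstrap = 50, seed = 7)
  tr <- bootstrap_support(m, cfg)
  sup <- suppressWarnings(as.integer(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  tr2 <- bootstrap_support(m, cfg)
  expect_equal(tr$node.label, tr2$node.label)

  tr0 <- bootstrap_support(m, phylo_config(n_bootstrap = 0))
  expect_null(tr0$node.label)
})

test_that("bootstrap supports are invariant to row order", {
  set.seed(89)
  fam <- evolve_family(simulate_tree(6, brlen_mean = 0.1),
                       group_config("I", n = 6, length = 120,
                                    signatures = NULL, motif_start = NULL))
  m <- fam$msa
  cfg <- phylo_config(n_bootstrap = 30, seed = 11)
  t1 <- bootstrap_support(m, cfg)
  perm <- aa_msa(unclass(m)[rev(seq_len(nrow(m))), , drop = FALSE])
  t2 <- bootstrap_support(perm, cfg)
  key <- function(tr) {
    sup <- tr$node.label
    names(sup) <- vapply(seq_along(sup), function(i) i, character(1))
    sort(sup[nzchar(sup)])
  }
  expect_equal(sort(t1$node.label[nzchar(t1$node.label)]),
               sort(t2$node.label[nzchar(t2$node.label)]))
})

test_that("clade collapsing follows the strict mean-leaf-distance rule", {
  tr <- ape::read.tree(text = "((a:0.03,b:0.05):0.2,(c:0.3,d:0.4):0.1,e:0.5);")
  out <- collapse_clades(tr, threshold = 0.05)
  expect_equal(nrow(out$collapsed), 1L)
  expect_equal(out$collapsed$n_leaves, 2L)
  expect_equal(out$collapsed$mean_leaf_distance, 0.04)
  expect_equal(ape::Ntip(out$tree), 4L)  # a+b replaced by one leaf

  # mean exactly at the threshold is NOT collapsed
  tr2 <- ape::read.tree(text = "((a:0.05,b:0.05):0.2,(c:0.3,d:0.4):0.1,e:0.5);")
  out2 <- collapse_clades(tr2, threshold = 0.05)
  expect_equal(nrow(out2$collapsed), 0L)
  expect_equal(ape::Ntip(out2$tree), 5L)

  # zero threshold never collapses
  out3 <- collapse_clades(tr, threshold = 0)
  expect_equal(ape::Ntip(out3$tree), 5L)
})

test_that("collapsed leaf counts conserve the original leaf count", {
  set.seed(97)
  for (k in 1:10) {
    tr <- ape::rtree(12)
    tr$edge.length <- rexp(nrow(tr$edge), 10)
    out <- collapse_clades(tr, threshold = 0.08)
    expect_equal(sum(out$collapsed$n_leaves) +
                   sum(!grepl("^collapsed_", out$tree$tip.label)),
                 12L)
  }
})
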