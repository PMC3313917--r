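test_that("random trees are reproducible with exponential branch lengths", {
  t1 <- simulate_tree(8, brlen_mean = 0.1, seed = 5)
  t2 <- simulate_tree(8, brlen_mean = 0.1, seed = 5)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))

  cherry <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(cherry), 2L)
  expect_error(simulate_tree(1), "at least 2")

  set.seed(151)
  draws <- unlist(lapply(1:150, function(i) {
    simulate_tree(5, brlen_mean = 0.1)$edge.length
  }))
  expect_gt(length(draws), 1000)
  expect_lt(abs(mean(draws) - 0.1) / 0.1, 0.1)  # within 10% of the mean
})

test_that("zero substitution rate copies the root to every leaf", {
  set.seed(157)
  fam <- evolve_family(simulate_tree(6),
                       group_config("I", n = 6, length = 50, rate = 0,
                                    signatures = NULL, motif_start = NULL))
  s <- msa_strings(fam$msa)
  expect_true(all(s == s[1]))
})

test_that("planted signature rates are recovered within binomial error", {
  set.seed(163)
  fam <- evolve_family(simulate_tree(175),
                       group_config("I", n = 175,
                                    signatures = bch_signatures(),
                                    motif_start = 235L))
  m <- unclass(fam$msa)
  h248 <- mean(m[, 248] == "H")
  expect_lt(abs(h248 - 0.983), 0.03)
  for (k in seq_len(nrow(fam$planted))) {
    col <- fam$planted$column[k]
    allowed <- strsplit(fam$planted$allowed[k], "/")[[1]]
    obs <- mean(m[, col] %in% allowed)
    rate <- fam$planted$rate[k]
    expect_lt(abs(obs - rate), 3 * sqrt(rate * (1 - rate) / 175) + 1e-9)
  }
})

test_that("a signature inside the motif window with disjoint sets errors", {
  bad_sig <- signature_set("ref", positions = 240, allowed = list("W"))
  cfg <- group_config("I", n = 4, signatures = bad_sig, motif_start = 235L)
  expect_error(evolve_family(simulate_tree(4), cfg), "disjoint")
})

test_that("within-group identity exceeds cross-group identity", {
  set.seed(167)
  ds <- emit_dataset(sim_config(seed = 11, groups = list(
    group_config("I", n = 12, signatures = bch_signatures(),
                 motif_start = 235L),
    group_config("CRAL_TRIO", n = 12,
                 signatures = cral_trio_signatures()))))
  tab <- group_identity_table(identity_matrix(ds$msa), ds$labels)
  within <- tab$mean_identity[tab$group1 == tab$group2]
  cross <- tab$mean_identity[tab$group1 != tab$group2]
  expect_true(all(outer(within, cross, `>`)))
})

test_that("dataset emission is deterministic and self-consistent", {
  cfg <- sim_config(seed = 23, groups = list(
    group_config("I", n = 8, signatures = bch_signatures(),
                 motif_start = 235L),
    group_config("CRAL_TRIO", n = 8,
                 signatures = cral_trio_signatures())))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_dataset(cfg, d1)
  emit_dataset(cfg, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }

  # emitted files parse cleanly and agree with each other
  recs <- read_fasta(file.path(d1, "sequences.fasta"))
  msa_fa <- read_msa(file.path(d1, "alignment.afa"))
  msa_cl <- read_msa(file.path(d1, "alignment.aln"), "clustal")
  expect_equal(msa_fa, msa_cl)
  expect_setequal(recs$id, rownames(msa_fa))
  labs <- read_labels(file.path(d1, "labels.tsv"), ids = recs$id)
  expect_setequal(unique(labs), c("I", "CRAL_TRIO"))
  introns <- read_introns(file.path(d1, "introns.tsv"))
  expect_true(all(introns$id %in% recs$id))
  for (g in c("I", "CRAL_TRIO")) {
    tr <- read_newick(file.path(d1, "truth", paste0("tree_", g, ".nwk")))
    expect_setequal(tr$tip.label, names(labs)[labs == g])
  }
})

test_that("NJ with bootstrap recovers the true tree from strong signal", {
  # fixed 8-leaf balanced tree with internal branches long enough to
  # leave tens of substitutions per branch over the domain
  nwk <- paste0("(((L1:0.05,L2:0.05):0.08,(L3:0.05,L4:0.05):0.08):0.1,",
                "((L5:0.05,L6:0.05):0.08,(L7:0.05,L8:0.05):0.08):0.1);")
  set.seed(173)
  cfg <- group_config("I", n = 8, length = 297, tree = nwk, rate = 1,
                      signatures = NULL, motif_start = NULL)
  fam <- evolve_family(ape::read.tree(text = nwk), cfg)
  true_tree <- fam$tree
  boot <- bootstrap_support(fam$msa, phylo_config(n_bootstrap = 100, seed = 3))
  expect_equal(unrooted_rf(boot, true_tree), 0)
  sup <- suppressWarnings(as.integer(boot$node.label))
  expect_gte(mean(sup[!is.na(sup)]), 90)
})

test_that("gap injection produces rows the gap screen rejects", {
  set.seed(179)
  fam <- evolve_family(simulate_tree(6),
                       group_config("I", n = 6, length = 200,
                                    signatures = NULL, motif_start = NULL))
  mut <- inject_gap_runs(fam$msa, ids = c("I_001", "I_002"), run_length = 35)
  out <- gap_screen(mut, screen_config(max_gap_run = 30))
  expect_setequal(out$discarded, c("I_001", "I_002"))
})
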