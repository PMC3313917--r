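test_that("motif notation compiles to explicit residue sets", {
  p <- compile_pattern("(R/K)")
  expect_length(p$sets, 1L)
  expect_setequal(p$sets[[1]], c("R", "K"))

  expect_error(compile_pattern("z"), "unknown symbol 'z' at position 1")
  expect_error(compile_pattern("A(R/"), "unclosed")

  lit <- compile_pattern("RNs")
  expect_equal(lit$sets[[1]], "R")
  expect_setequal(lit$sets[[3]], c("A", "T", "G", "S"))
})

test_that("the hallmark motif expands to its 16 documented positions", {
  pat <- hallmark_motif()
  expect_length(pat$sets, 16L)
  expect_equal(pat$sets[[14]], "H")
  expect_equal(pat$sets[[6]], "N")
  expect_equal(pat$sets[[7]], "L")
  expect_setequal(pat$sets[[2]], c("R", "K"))
  expect_setequal(pat$sets[[9]], AA20)  # wildcard position
  expect_setequal(pat$sets[[3]], c("L", "I", "V", "F", "M", "Y", "W"))
})

test_that("anchoring the invariant N at BNIP-2 240 places H248 and P249", {
  pat <- hallmark_motif()
  n_pos <- 6L   # pattern position of the invariant N
  start <- 240L - (n_pos - 1L)
  expect_equal(start, 235L)
  expect_equal(start + 14L - 1L, 248L)  # H at pattern position 14
  expect_equal(pat$sets[[14]], "H")
  expect_equal(start + 15L - 1L, 249L)  # P at pattern position 15
  expect_equal(pat$sets[[15]], "P")
})

test_that("scanning finds hand-checkable hits and respects violations", {
  pat <- hallmark_motif()
  hits <- scan_motif("RKLRKNLKALIVFHPA", pat)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$violations, 0L)
  expect_equal(hits$rk_patch, "RKRKK")

  expect_equal(nrow(scan_motif(strrep("G", 100), pat)), 0L)
  expect_equal(nrow(scan_motif("RKL", pat)), 0L)  # shorter than pattern

  # one violating position (G at the invariant N) needs tolerance 1
  mut <- "RKLRKGLKALIVFHPA"
  expect_equal(nrow(scan_motif(mut, pat, max_violations = 0)), 0L)
  h1 <- scan_motif(mut, pat, max_violations = 1)
  expect_equal(h1$violations, 1L)
  expect_equal(h1$violated_positions, "6")

  # X never matches, not even the wildcard position
  xmut <- "RKLRKNLKXLIVFHPA"
  expect_equal(nrow(scan_motif(xmut, pat, max_violations = 0)), 0L)
  expect_equal(nrow(scan_motif(xmut, pat, max_violations = 1)), 1L)
})

test_that("scan equals the brute-force window checker on random input", {
  set.seed(109)
  pat <- compile_pattern("R(R/K)hxNs")
  for (k in 1:25) {
    s <- random_seq(sample(20:500, 1))
    for (mv in 0:2) {
      got <- scan_motif(s, pat, max_violations = mv)$start
      expect_equal(got, brute_scan_starts(s, pat$sets, mv))
    }
  }
})

test_that("raising the violation tolerance never loses hits", {
  set.seed(113)
  pat <- hallmark_motif()
  for (k in 1:10) {
    s <- random_seq(300)
    counts <- vapply(0:4, function(mv) {
      nrow(scan_motif(s, pat, max_violations = mv))
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("classifier labels synthetic families correctly", {
  set.seed(127)
  bch <- evolve_family(simulate_tree(40, brlen_mean = 0.04),
                       group_config("I", n = 40,
                                    signatures = bch_signatures(),
                                    motif_start = 235L))
  cral <- evolve_family(simulate_tree(40, brlen_mean = 0.04),
                        group_config("CRAL_TRIO", n = 40,
                                     signatures = cral_trio_signatures()))
  cls_b <- classify_domain(bch$msa)
  cls_c <- classify_domain(cral$msa)
  expect_gte(mean(cls_b$label == "BCH"), 0.95)
  expect_gte(mean(cls_c$label == "CRAL_TRIO"), 0.95)
})

test_that("a half-matching sequence lands in the BCH-like band", {
  # construct a 297-residue row matching 5/9 BCH and 4/8 CRAL positions
  set.seed(131)
  resv <- strsplit(random_seq(297), "")[[1]]
  bch <- bch_signatures()
  cral <- cral_trio_signatures()
  for (k in seq_along(bch$positions)) {
    resv[bch$positions[k]] <- if (k <= 5) bch$allowed[[k]][1] else "G"
  }
  for (k in seq_along(cral$positions)) {
    if (cral$positions[k] %in% bch$positions) next
    resv[cral$positions[k]] <- if (k <= 4) cral$allowed[[k]][1] else "W"
  }
  m <- aa_msa(matrix(resv, nrow = 1, dimnames = list("amb", NULL)))
  cls <- classify_domain(m)
  expect_gte(cls$bch_score, 0.4)
  expect_lt(cls$bch_score, 0.6)
  expect_gte(cls$cral_score, 0.4)
  expect_lt(cls$cral_score, 0.6)
  expect_equal(cls$label, "BCH-like")
})

test_that("BCH is never called without a hallmark hit", {
  set.seed(137)
  # plant all BCH signature residues but no motif window
  fam <- evolve_family(simulate_tree(30, brlen_mean = 0.04),
                       group_config("I", n = 30,
                                    signatures = bch_signatures(),
                                    motif_start = NULL))
  cls <- classify_domain(fam$msa)
  expect_true(all(cls$label[!cls$hallmark_hit] != "BCH"))
  expect_true(all(!cls$hallmark_hit | cls$label == "BCH"))
})
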