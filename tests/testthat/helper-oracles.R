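# Independent reference implementations used to cross-check the package.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(len) paste(sample(AA20, len, replace = TRUE),
                                  collapse = "")

# --- alignment score oracles ------------------------------------------

# Literal enumeration of every global alignment (all interleavings of
# matches and gaps), scoring gap runs as open + len * extend.  Only
# feasible for very short sequences; used to validate the memoized
# oracle below.
enumerate_best_score <- function(a, b, sub, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, score + sub[av[i], bv[j]], "M")
    }
    if (i <= length(av)) {
      gap_cost <- ext + if (last == "U") 0 else open
      rec(i + 1, j, score - gap_cost, "U")
    }
    if (j <= length(bv)) {
      gap_cost <- ext + if (last == "L") 0 else open
      rec(i, j + 1, score - gap_cost, "L")
    }
  }
  rec(1, 1, 0, "start")
  best
}

# Memoized top-down recursion over (i, j, last-move), an independent
# coding of the affine-gap optimum.
oracle_align_score <- function(a, b, sub, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    key <- paste(i, j, last)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, sub[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(av)) {
      cost <- ext + if (last == "U") 0 else open
      best <- max(best, rec(i + 1, j, "U") - cost)
    }
    if (j <= length(bv)) {
      cost <- ext + if (last == "L") 0 else open
      best <- max(best, rec(i, j + 1, "L") - cost)
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "start")
}

simple_sub <- function(match = 2, mismatch = -1) {
  m <- matrix(mismatch, 20, 20, dimnames = list(AA20, AA20))
  diag(m) <- match
  m
}

# --- motif scan oracle ------------------------------------------------

brute_scan_starts <- function(seq_str, sets, max_violations) {
  res <- strsplit(seq_str, "")[[1]]
  L <- length(sets)
  out <- integer(0)
  if (length(res) < L) return(out)
  for (s in seq_len(length(res) - L + 1)) {
    v <- 0
    for (p in seq_len(L)) {
      r <- res[s + p - 1]
      if (!(r %in% sets[[p]]) || r == "X") v <- v + 1
    }
    if (v <= max_violations) out <- c(out, s)
  }
  out
}

# --- phylogeny helpers ------------------------------------------------

# Random binary tree with strictly positive branch lengths and the
# additive distance matrix of its leaf-to-leaf path lengths.
random_additive_case <- function(n_leaves, min_bl = 0.05, max_bl = 0.5) {
  tr <- ape::rtree(n_leaves, br = NULL)
  tr$edge.length <- runif(nrow(tr$edge), min_bl, max_bl)
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
  list(tree = tr, dm = dm)
}

unrooted_rf <- function(t1, t2) {
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)))
}
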