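#' Phylogeny configuration
#'
#' @param n_bootstrap number of bootstrap replicates (default 1000, the
#'   conventional choice for assessing branch robustness; 0 disables
#'   supports).
#' @param collapse_threshold clades whose average leaf distance is
#'   strictly below this are collapsed in the display step (default
#'   0.05).
#' @param gap_mode `"complete-deletion"` (default; every column
#'   containing any gap is removed before distances) or
#'   `"pairwise-deletion"`.
#' @param seed integer seed for bootstrap resampling.
#' @return a list of class `phylo_config`.
#' @export
phylo_config <- function(n_bootstrap = 1000L, collapse_threshold = 0.05,
                         gap_mode = c("complete-deletion",
                                      "pairwise-deletion"),
                         seed = 1L) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(n_bootstrap >= 0, collapse_threshold >= 0)
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 collapse_threshold = collapse_threshold,
                 gap_mode = gap_mode, seed = as.integer(seed)),
            class = "phylo_config")
}

# Columns retained under complete deletion (no gap in any row).
ungapped_columns <- function(msa) {
  which(colSums(unclass(msa) == GAP_CHAR) == 0L)
}

#' p-distance matrix from an alignment
#'
#' Distances are `1 - identity fraction` over compared columns.  Under
#' `complete-deletion` every column containing a gap in any row is
#' removed first (distances for all pairs use the same column set);
#' under `pairwise-deletion` each pair uses the columns where neither
#' row is gapped.  `X` never counts as identical.
#'
#' @param msa an [aa_msa()] with at least two rows.
#' @param gap_mode see [phylo_config()].
#' @return symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(msa, gap_mode = c("complete-deletion",
                                              "pairwise-deletion")) {
  gap_mode <- match.arg(gap_mode)
  if (nrow(msa) < 2) stop_bch("need at least 2 rows for distances")
  ids <- rownames(msa)
  m <- unclass(msa)
  if (gap_mode == "complete-deletion") {
    keep <- ungapped_columns(msa)
    if (length(keep) == 0L) {
      stop_bch("complete deletion removed every column; ",
               "consider gap_mode = 'pairwise-deletion'")
    }
    m <- m[, keep, drop = FALSE]
    n <- length(ids)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        same <- m[i, ] == m[j, ] & m[i, ] != "X"
        d[i, j] <- d[j, i] <- 1 - sum(same) / ncol(m)
      }
    }
    d
  } else {
    n <- length(ids)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        both <- m[i, ] != GAP_CHAR & m[j, ] != GAP_CHAR
        if (!any(both)) {
          stop_bch("incomparable pair under pairwise deletion: '",
                   ids[i], "' and '", ids[j], "'")
        }
        same <- m[i, both] == m[j, both] & m[i, both] != "X"
        d[i, j] <- d[j, i] <- 1 - sum(same) / sum(both)
      }
    }
    d
  }
}

#' Neighbor-Joining tree
#'
#' Standard agglomerative Neighbor-Joining on a distance matrix using
#' the Q criterion.  Ties in Q are broken by the lexicographically
#' smallest index pair, so the result is deterministic.  Estimated
#' negative branch lengths are clamped to zero; the total clamped
#' deficit is recorded in the `negative_deficit` attribute.
#'
#' @param dm square symmetric distance matrix with at least 3 ids.
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  ids <- rownames(dm)
  n <- length(ids)
  if (n < 3) stop_bch("Neighbor-Joining needs at least 3 sequences")
  deficit <- 0
  clamp <- function(x) {
    bad <- x < 0
    deficit <<- deficit + sum(-x[bad])
    x[bad] <- 0
    x
  }
  # active nodes carried as partial Newick fragments
  node <- ids
  D <- dm
  while (length(node) > 3) {
    r <- length(node)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    # lexicographically smallest (i, j), i < j, among Q minima
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]
    j <- cand[1, 2]
    bi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    bl <- clamp(c(bi, bj))
    new_node <- sprintf("(%s:%s,%s:%s)", node[i], format(bl[1], digits = 15),
                        node[j], format(bl[2], digits = 15))
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    node <- c(node[keep], new_node)
    rownames(D) <- colnames(D) <- NULL
  }
  # three remaining nodes: star join with the three-point formulas
  la <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 node[1], format(la, digits = 15),
                 node[2], format(lb, digits = 15),
                 node[3], format(lc, digits = 15))
  tree <- ape::read.tree(text = txt)
  attr(tree, "negative_deficit") <- deficit
  tree
}

# Canonical bipartitions of an unrooted tree: for every internal edge,
# the leaf-label set on the side NOT containing the alphabetically first
# label, as a single collapsed string.
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= ntip) next  # trivial split
    side <- desc[[ch]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2 || length(side) > ntip - 2) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Bootstrap supports for a Neighbor-Joining tree
#'
#' Builds the full-data NJ tree, then resamples the retained columns
#' with replacement `n_bootstrap` times, rebuilding the tree for each
#' replicate.  The support of an internal split is the percentage of
#' replicate trees containing it.  Under `complete-deletion` the gapped
#' columns are removed once, before resampling, so every replicate
#' draws from the same retained column set.
#'
#' @param msa an [aa_msa()].
#' @param config a [phylo_config()]; `config$seed` makes the resampling
#'   reproducible.
#' @return the full-data [ape::phylo] tree; when `n_bootstrap > 0` its
#'   `node.label` holds integer percent supports (root label empty).
#' @export
bootstrap_support <- function(msa, config = phylo_config()) {
  m <- unclass(msa)
  if (config$gap_mode == "complete-deletion") {
    keep <- ungapped_columns(msa)
    if (length(keep) == 0L) stop_bch("complete deletion removed every column")
    m <- m[, keep, drop = FALSE]
  }
  base_msa <- aa_msa(m)
  full <- nj_tree(distance_matrix(base_msa, config$gap_mode))
  if (config$n_bootstrap == 0L) return(full)
  splits <- tree_splits(full)
  counts <- setNames(integer(length(splits)), splits)
  set.seed(config$seed)
  for (b in seq_len(config$n_bootstrap)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_msa <- aa_msa(m[, cols, drop = FALSE])
    rep_tree <- nj_tree(distance_matrix(rep_msa, config$gap_mode))
    hit <- splits %in% tree_splits(rep_tree)
    counts[hit] <- counts[hit] + 1L
  }
  support <- round(100 * counts / config$n_bootstrap)
  # attach supports to the matching internal nodes
  ntip <- length(full$tip.label)
  anchor <- sort(full$tip.label)[1]
  desc <- vector("list", ntip + full$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- full$tip.label[i]
  for (e in ape::postorder(full)) {
    p <- full$edge[e, 1]
    desc[[p]] <- c(desc[[p]], desc[[full$edge[e, 2]]])
  }
  labels <- character(full$Nnode)
  for (node in seq(ntip + 1, ntip + full$Nnode)) {
    side <- desc[[node]]
    if (anchor %in% side) side <- setdiff(full$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) {
      labels[node - ntip] <- as.character(support[[key]])
    }
  }
  full$node.label <- labels
  full
}

# distance from an internal node to each of its descendant leaves
node_leaf_distances <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  dist <- vector("list", ntip + nnode)
  count <- integer(ntip + nnode)
  for (i in seq_len(ntip)) {
    dist[[i]] <- 0
    count[i] <- 1L
  }
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    dist[[p]] <- c(dist[[p]], dist[[ch]] + tree$edge.length[e])
    count[p] <- count[p] + count[ch]
  }
  list(dist = dist, count = count)
}

#' Collapse low-divergence clades into counted leaves
#'
#' Every maximal internal node whose mean path length to its descendant
#' leaves is strictly below `threshold` is replaced by a single leaf
#' whose label records the number of leaves it absorbed
#' (`"collapsed_<k>_<n>leaves"`).  "Maximal" means no ancestor of the
#' node also qualifies; the rule is applied from the root down.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param threshold collapse threshold on the mean leaf distance.
#' @return list with `tree` (collapsed [ape::phylo]) and `collapsed`
#'   (data frame `label`, `n_leaves`, `mean_leaf_distance`).
#' @export
collapse_clades <- function(tree, threshold = 0.05) {
  ntip <- length(tree$tip.label)
  nld <- node_leaf_distances(tree)
  mean_d <- vapply(seq_len(ntip + tree$Nnode),
                   function(k) mean(nld$dist[[k]]), numeric(1))
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- setNames(tree$edge.length, tree$edge[, 2])
  report <- data.frame(label = character(0), n_leaves = integer(0),
                       mean_leaf_distance = numeric(0),
                       stringsAsFactors = FALSE)
  counter <- 0L
  root <- ntip + 1L
  rec <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    if (node != root && mean_d[node] < threshold) {
      counter <<- counter + 1L
      label <- sprintf("collapsed_%d_%dleaves", counter, nld$count[node])
      report <<- rbind(report, data.frame(
        label = label, n_leaves = nld$count[node],
        mean_leaf_distance = mean_d[node], stringsAsFactors = FALSE))
      return(label)
    }
    parts <- vapply(kids[[as.character(node)]], function(ch) {
      paste0(rec(ch), ":", format(elen[[as.character(ch)]], digits = 15))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(rec(root), ";")
  out <- ape::read.tree(text = txt)
  list(tree = out, collapsed = report)
}
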