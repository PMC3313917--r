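#' Alignment scoring parameters
#'
#' Either a named substitution matrix (`"BLOSUM62"`, taken from
#' \pkg{Biostrings}) or a simple match/mismatch scheme.  Gap penalties
#' are positive costs under an affine model: a gap run of length L
#' costs `gap_open + L * gap_extend`.
#'
#' @param matrix name of a substitution matrix, or a numeric matrix
#'   with residue dimnames; ignored when `match` is given.
#' @param match,mismatch scores for a simple scheme (both or neither).
#' @param gap_open,gap_extend non-negative gap penalties.
#' @return a list of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", match = NULL, mismatch = NULL,
                         gap_open = 10, gap_extend = 0.5) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  if (!is.null(match)) {
    stopifnot(!is.null(mismatch))
    sub <- base::matrix(mismatch, 21, 21,
                        dimnames = list(AA_WITH_X, AA_WITH_X))
    diag(sub) <- match
  } else if (is.character(matrix)) {
    sub <- named_submatrix(matrix)
  } else {
    stopifnot(is.matrix(matrix))
    sub <- matrix[AA_WITH_X, AA_WITH_X]
  }
  structure(list(sub = sub, gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

.submat_cache <- new.env(parent = emptyenv())

named_submatrix <- function(name) {
  if (!is.null(.submat_cache[[name]])) return(.submat_cache[[name]])
  e <- new.env()
  data(list = name, package = "Biostrings", envir = e)
  full <- get(name, envir = e)
  sub <- full[AA_WITH_X, AA_WITH_X]
  .submat_cache[[name]] <- sub
  sub
}

encode_residues <- function(s) {
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], AA_WITH_X)
  if (anyNA(idx)) stop_bch("illegal residue at position ", which(is.na(idx))[1])
  idx
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment under affine-gap scoring with deterministic
#' tie-breaking in the traceback (diagonal preferred, then a gap in the
#' second sequence, then a gap in the first).
#'
#' @param a,b residue strings, or single-row [seq_set()] entries.
#' @param params an [align_params()].
#' @return list of class `pairwise_alignment`: `score`, `aligned_a`,
#'   `aligned_b`.
#' @export
nw_align <- function(a, b, params = align_params()) {
  a <- as_residue_string(a)
  b <- as_residue_string(b)
  if (!nzchar(a) || !nzchar(b)) stop_bch("cannot align an empty sequence")
  res <- .nw_align_cpp(encode_residues(a), encode_residues(b),
                       params$sub, params$gap_open, params$gap_extend)
  decode <- function(idx) {
    v <- AA_WITH_X[pmax(idx, 1L)]
    v[idx == 0L] <- GAP_CHAR
    paste(v, collapse = "")
  }
  structure(list(score = res$score,
                 aligned_a = decode(res$a_idx),
                 aligned_b = decode(res$b_idx)),
            class = "pairwise_alignment")
}

as_residue_string <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x$residues
  } else {
    toupper(as.character(x))
  }
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment, score ", format(x$score), "\n",
      x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity between two alignment rows
#'
#' The default `pairwise-deletion` mode counts matches over columns
#' where neither row is gapped.  `shorter-length` divides matches by
#' the shorter ungapped sequence length and `alignment-length` by the
#' full column count.  `X` never counts as a match.
#'
#' @param msa an [aa_msa()].
#' @param id1,id2 row ids.
#' @param mode identity denominator, see Details.
#' @return percent identity in `[0, 100]`.
#' @export
percent_identity_msa <- function(msa, id1, id2,
                                 mode = c("pairwise-deletion",
                                          "shorter-length",
                                          "alignment-length")) {
  mode <- match.arg(mode)
  for (id in c(id1, id2)) {
    if (!id %in% rownames(msa)) stop_bch("id not in alignment: ", id)
  }
  r1 <- msa[id1, ]
  r2 <- msa[id2, ]
  both <- r1 != GAP_CHAR & r2 != GAP_CHAR
  matches <- sum(r1 == r2 & both & r1 != "X")
  denom <- switch(mode,
    "pairwise-deletion" = sum(both),
    "shorter-length" = min(sum(r1 != GAP_CHAR), sum(r2 != GAP_CHAR)),
    "alignment-length" = length(r1))
  if (denom == 0L) {
    stop_bch("incomparable pair: no shared ungapped columns between '",
             id1, "' and '", id2, "'")
  }
  100 * matches / denom
}

#' All-pairs identity matrix from an alignment
#'
#' @param msa an [aa_msa()].
#' @inheritParams percent_identity_msa
#' @return symmetric numeric matrix of percent identities with a
#'   diagonal of 100.
#' @export
identity_matrix <- function(msa, mode = "pairwise-deletion") {
  ids <- rownames(msa)
  n <- length(ids)
  v <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        v[i, j] <- v[j, i] <- percent_identity_msa(msa, ids[i], ids[j], mode)
      }
    }
  }
  v
}

#' Number of pairwise comparisons within or across groups
#'
#' @param n1,n2 group sizes.
#' @param within if `TRUE`, `n1` must equal `n2` and the count is
#'   `n1 * (n1 - 1) / 2`; otherwise the cross count `n1 * n2`.
#' @return integer comparison count.
#' @export
comparison_count <- function(n1, n2 = n1, within = FALSE) {
  stopifnot(n1 >= 0, n2 >= 0)
  if (within) {
    if (n1 != n2) stop_bch("within-group count requires n1 == n2")
    as.integer(n1 * (n1 - 1) / 2)
  } else {
    as.integer(n1 * n2)
  }
}

#' Group-wise mean identity and comparison counts
#'
#' Summarizes an all-pairs identity matrix into the lower-triangular
#' group table: for every group pair the mean percent identity over all
#' between- (or within-) group sequence pairs, with the number of
#' comparisons.  Unassigned ids are excluded with a warning.
#'
#' @param identity a square identity matrix from [identity_matrix()].
#' @param labels named character vector `id -> group`.
#' @return data frame of class `group_identity_table` with columns
#'   `group1`, `group2`, `mean_identity`, `n_comparisons`.
#' @export
group_identity_table <- function(identity, labels) {
  ids <- rownames(identity)
  unlabeled <- setdiff(ids, names(labels))
  if (length(unlabeled)) {
    stop_bch("unlabeled id(s) in identity matrix: ",
             paste(unlabeled, collapse = ", "))
  }
  lab <- labels[ids]
  drop <- lab == "unassigned"
  if (any(drop)) {
    warning("excluding ", sum(drop), " unassigned id(s): ",
            paste(ids[drop], collapse = ", "), call. = FALSE)
    ids <- ids[!drop]
    lab <- lab[!drop]
    identity <- identity[ids, ids, drop = FALSE]
  }
  groups <- intersect(GROUP_LABELS, unique(lab))
  empty <- setdiff(setdiff(GROUP_LABELS, "unassigned"), groups)
  out <- NULL
  for (gi in seq_along(groups)) {
    for (gj in seq_len(gi)) {
      g1 <- groups[gj]
      g2 <- groups[gi]
      i1 <- which(lab == g1)
      i2 <- which(lab == g2)
      if (g1 == g2) {
        if (length(i1) < 2) {
          vals <- numeric(0)
        } else {
          m <- identity[i1, i1, drop = FALSE]
          vals <- m[upper.tri(m)]
        }
        n_cmp <- comparison_count(length(i1), within = TRUE)
      } else {
        vals <- as.vector(identity[i1, i2, drop = FALSE])
        n_cmp <- comparison_count(length(i1), length(i2))
      }
      out <- rbind(out, data.frame(
        group1 = g1, group2 = g2,
        mean_identity = if (length(vals)) mean(vals) else NA_real_,
        n_comparisons = n_cmp, stringsAsFactors = FALSE))
    }
  }
  structure(out, class = c("group_identity_table", "data.frame"),
            omitted_groups = empty)
}
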