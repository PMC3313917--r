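#' Per-column conservation profile
#'
#' For every alignment column: the occupancy (fraction of rows that are
#' not gaps), the residue frequency vector over the 20 amino acids
#' (gaps and `X` excluded), and the majority residue with its fraction.
#' Columns with no countable residue are flagged as undefined.
#'
#' @param msa an [aa_msa()].
#' @param pseudocount added to every residue count before normalizing
#'   (default 0: raw frequencies, as used for the published logos).
#' @return a list of class `conservation_profile`: `freq` (20 x n_cols
#'   matrix), `occupancy`, `majority`, `majority_fraction`, `defined`.
#' @export
column_frequencies <- function(msa, pseudocount = 0) {
  m <- unclass(msa)
  nc <- ncol(m)
  freq <- matrix(0, nrow = 20, ncol = nc,
                 dimnames = list(AA_ALPHABET, NULL))
  occupancy <- numeric(nc)
  majority <- rep(NA_character_, nc)
  majority_fraction <- rep(NA_real_, nc)
  defined <- logical(nc)
  for (j in seq_len(nc)) {
    col <- m[, j]
    occupancy[j] <- mean(col != GAP_CHAR)
    res <- col[col %in% AA_ALPHABET]
    counts <- table(factor(res, levels = AA_ALPHABET)) + pseudocount
    tot <- sum(counts)
    if (tot > 0) {
      f <- as.numeric(counts) / tot
      freq[, j] <- f
      defined[j] <- TRUE
      top <- which.max(f)
      majority[j] <- AA_ALPHABET[top]
      majority_fraction[j] <- f[top]
    }
  }
  structure(list(freq = freq, occupancy = occupancy, majority = majority,
                 majority_fraction = majority_fraction, defined = defined),
            class = "conservation_profile")
}

#' Sequence-logo information content
#'
#' Per-column information content in bits, `IC = log2(20) - H` where
#' `H` is the Shannon entropy of the column's residue frequencies.
#' Letter heights are `frequency * IC`, optionally scaled by column
#' occupancy.  Undefined (all-gap) columns get zero heights.
#'
#' @param profile a [column_frequencies()] result.
#' @param scale_by_occupancy multiply heights by column occupancy.
#' @return a list of class `logo_matrix`: `heights` (20 x n_cols, bits)
#'   and `ic` (per-column total, bits).
#' @export
information_content <- function(profile, scale_by_occupancy = FALSE) {
  max_bits <- log2(20)
  nc <- ncol(profile$freq)
  ic <- numeric(nc)
  heights <- matrix(0, nrow = 20, ncol = nc,
                    dimnames = dimnames(profile$freq))
  for (j in seq_len(nc)) {
    if (!profile$defined[j]) next
    f <- profile$freq[, j]
    nz <- f > 0
    h <- -sum(f[nz] * log2(f[nz]))
    ic[j] <- max_bits - h
    heights[, j] <- f * ic[j]
    if (scale_by_occupancy) heights[, j] <- heights[, j] * profile$occupancy[j]
  }
  structure(list(heights = heights, ic = ic), class = "logo_matrix")
}

#' Map reference residue positions to alignment columns
#'
#' Converts 1-based residue positions in the (ungapped) reference
#' sequence to 1-based alignment columns via the reference row's gap
#' structure.
#'
#' @param msa an [aa_msa()] containing the reference row.
#' @param ref_id reference row id.
#' @param positions 1-based residue positions in the ungapped reference.
#' @return integer vector of 1-based alignment columns.
#' @export
map_reference_positions <- function(msa, ref_id, positions) {
  if (!ref_id %in% rownames(msa)) {
    stop_bch("reference id not in alignment: ", ref_id)
  }
  row <- msa[ref_id, ]
  res_cols <- which(row != GAP_CHAR)
  bad <- positions < 1 | positions > length(res_cols)
  if (any(bad)) {
    stop_bch("position(s) beyond reference length (", length(res_cols),
             "): ", paste(positions[bad], collapse = ", "))
  }
  res_cols[positions]
}

#' Construct a signature set
#'
#' A signature set is a list of diagnostic residue positions, numbered
#' in a reference protein's coordinates, each with its allowed residue
#' set and (optionally) the conservation fraction expected in the
#' domain family.
#'
#' @param ref_id reference sequence id the positions are numbered in.
#' @param positions strictly increasing 1-based reference positions.
#' @param allowed list of non-empty character vectors of allowed
#'   residues, one per position.
#' @param expected optional numeric vector of expected conservation
#'   fractions.
#' @param offset numbering offset: alignment-relative residue index =
#'   `position - offset`.  Zero when the reference row is numbered from
#'   its own first residue.
#' @return a list of class `signature_set`.
#' @export
signature_set <- function(ref_id, positions, allowed, expected = NULL,
                          offset = 0L) {
  stopifnot(length(positions) == length(allowed),
            is.null(expected) || length(expected) == length(positions))
  if (any(diff(positions) <= 0)) {
    stop_bch("signature positions must be strictly increasing")
  }
  if (any(lengths(allowed) == 0)) stop_bch("empty allowed residue set")
  structure(list(ref_id = ref_id, positions = as.integer(positions),
                 allowed = lapply(allowed, toupper),
                 expected = expected, offset = as.integer(offset)),
            class = "signature_set")
}

#' BCH-domain signature residues
#'
#' The diagnostic residue positions conserved across BCH domains,
#' numbered in the human BNIP-2 protein (NCBI NP_004321), with the
#' conservation fractions observed over 175 BCH domain sequences:
#' (R/N)165 0.901, P176 0.873, (H/N)212 0.890, P221 0.878,
#' (K/R)238 0.928, (K/R)239 0.873, N240 0.879, H248 0.983,
#' (K/R)271 0.995.
#'
#' @param offset numbering offset to apply (see [signature_set()]);
#'   default 0 keeps full-protein BNIP-2 numbering.
#' @return a [signature_set()].
#' @export
bch_signatures <- function(offset = 0L) {
  signature_set(
    ref_id = "NP_004321",
    positions = c(165, 176, 212, 221, 238, 239, 240, 248, 271),
    allowed = list(c("R", "N"), "P", c("H", "N"), "P", c("K", "R"),
                   c("K", "R"), "N", "H", c("K", "R")),
    expected = c(0.901, 0.873, 0.890, 0.878, 0.928, 0.873, 0.879,
                 0.983, 0.995),
    offset = offset)
}

#' CRAL_TRIO-domain signature residues
#'
#' Diagnostic residue positions conserved across CRAL_TRIO domains,
#' numbered in yeast Sec14p (NCBI NP_013796): E152 0.841, D178 0.942,
#' P206 0.913, P218 0.899, (K/R)239 0.855, P261 0.812, G265 0.898,
#' G266 0.970.
#'
#' @inheritParams bch_signatures
#' @return a [signature_set()].
#' @export
cral_trio_signatures <- function(offset = 0L) {
  signature_set(
    ref_id = "NP_013796",
    positions = c(152, 178, 206, 218, 239, 261, 265, 266),
    allowed = list("E", "D", "P", "P", c("K", "R"), "P", "G", "G"),
    expected = c(0.841, 0.942, 0.913, 0.899, 0.855, 0.812, 0.898, 0.970),
    offset = offset)
}

# Resolve signature positions to alignment columns.  When the reference
# row is present its gap structure is used; otherwise the alignment is
# taken to be in reference coordinates (position - offset = column),
# which holds for ungapped synthetic alignments.
signature_columns <- function(msa, sig) {
  pos <- sig$positions - sig$offset
  if (sig$ref_id %in% rownames(msa)) {
    map_reference_positions(msa, sig$ref_id, pos)
  } else {
    if (any(pos < 1 | pos > ncol(msa))) {
      stop_bch("signature positions unmappable: reference '", sig$ref_id,
               "' absent and positions fall outside the alignment")
    }
    as.integer(pos)
  }
}

#' Observed conservation of signature residues per group
#'
#' For every signature position and group label: the fraction of
#' occupied rows (non-gap at the mapped column) whose residue is in the
#' position's allowed set.  The full table is always returned; the
#' `reported` column marks the values that clear `report_threshold`
#' (the published table prints only values above 50%).
#'
#' @param msa an [aa_msa()].
#' @param sig a [signature_set()].
#' @param labels named character vector `id -> group`; rows without a
#'   label are skipped.
#' @param report_threshold fractions at or below this are flagged as
#'   suppressed in the thresholded report (default 0.5).
#' @return data frame with columns `position`, `allowed`, `group`,
#'   `n_occupied`, `observed`, `expected`, `reported`.
#' @export
signature_conservation <- function(msa, sig, labels,
                                   report_threshold = 0.5) {
  cols <- signature_columns(msa, sig)
  ids <- intersect(rownames(msa), names(labels))
  lab <- labels[ids]
  groups <- intersect(GROUP_LABELS, unique(lab))
  out <- NULL
  for (k in seq_along(sig$positions)) {
    col <- msa[ids, cols[k]]
    for (g in groups) {
      sel <- lab == g
      occ <- col[sel][col[sel] != GAP_CHAR]
      obs <- if (length(occ)) {
        mean(occ %in% sig$allowed[[k]] & occ != "X")
      } else {
        NA_real_
      }
      out <- rbind(out, data.frame(
        position = sig$positions[k],
        allowed = paste(sig$allowed[[k]], collapse = "/"),
        group = g, n_occupied = length(occ), observed = obs,
        expected = if (is.null(sig$expected)) NA_real_ else sig$expected[k],
        reported = !is.na(obs) && obs > report_threshold,
        stringsAsFactors = FALSE))
    }
  }
  out
}
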