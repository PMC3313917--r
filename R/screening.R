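#' Screening configuration
#'
#' Dataset-curation thresholds: minimum sequence length (sequences below
#' ~100 residues are unlikely to fold into a complete domain), greedy
#' redundancy clustering level, and the long-gap rules used to drop
#' fragmentary alignment rows.
#'
#' @param min_length minimum residue count kept (default 100; strictly
#'   shorter sequences are discarded).
#' @param redundancy_threshold percent identity at which sequences are
#'   grouped as redundant (default 95).
#' @param max_gap_run an alignment row is dropped when its longest
#'   internal gap run spans at least this many columns (default 30).
#' @param max_gap_fraction an alignment row is dropped when its overall
#'   gap fraction exceeds this value (default 0.5).
#' @return a list of class `screen_config`.
#' @export
screen_config <- function(min_length = 100L, redundancy_threshold = 95,
                          max_gap_run = 30L, max_gap_fraction = 0.5) {
  stopifnot(min_length >= 1, redundancy_threshold > 0,
            redundancy_threshold <= 100, max_gap_run >= 1,
            max_gap_fraction > 0, max_gap_fraction <= 1)
  structure(list(min_length = as.integer(min_length),
                 redundancy_threshold = redundancy_threshold,
                 max_gap_run = as.integer(max_gap_run),
                 max_gap_fraction = max_gap_fraction),
            class = "screen_config")
}

#' Minimum-length filter
#'
#' @param records a [seq_set()].
#' @param config a [screen_config()].
#' @return list with `kept` (a `seq_set`, or zero-row data frame) and
#'   `discarded` (data frame `id`, `rule`, `value`).
#' @export
length_filter <- function(records, config = screen_config()) {
  len <- nchar(records$residues)
  keep <- len >= config$min_length
  discarded <- data.frame(id = records$id[!keep],
                          rule = rep("min_length", sum(!keep)),
                          value = len[!keep], stringsAsFactors = FALSE)
  kept <- records[keep, , drop = FALSE]
  list(kept = kept, discarded = discarded)
}

# Longest run of gaps not touching either end of the row.
longest_internal_gap_run <- function(row) {
  n <- length(row)
  is_gap <- row == GAP_CHAR
  if (!any(is_gap)) return(0L)
  r <- rle(is_gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  internal <- r$values & starts > 1L & ends < n
  if (!any(internal)) 0L else max(r$lengths[internal])
}

#' Long-gap screen for alignment rows
#'
#' A row is discarded when its longest internal gap run reaches
#' `max_gap_run` columns, or when its total gap fraction exceeds
#' `max_gap_fraction`.  Terminal gap runs (incomplete ends) are exempt
#' from the run rule but still count toward the fraction.
#'
#' @param msa an [aa_msa()].
#' @param config a [screen_config()].
#' @return list with `kept` and `discarded` ids, and a `log` data frame
#'   (`id`, `rule`, `value`) for the discarded rows.
#' @export
gap_screen <- function(msa, config = screen_config()) {
  runs <- apply(unclass(msa), 1, longest_internal_gap_run)
  frac <- rowMeans(unclass(msa) == GAP_CHAR)
  drop_run <- runs >= config$max_gap_run
  drop_frac <- frac > config$max_gap_fraction
  drop <- drop_run | drop_frac
  log <- rbind(
    data.frame(id = rownames(msa)[drop_run],
               rule = rep("max_gap_run", sum(drop_run)),
               value = runs[drop_run], stringsAsFactors = FALSE),
    data.frame(id = rownames(msa)[drop_frac & !drop_run],
               rule = rep("max_gap_fraction", sum(drop_frac & !drop_run)),
               value = round(frac[drop_frac & !drop_run], 4),
               stringsAsFactors = FALSE))
  list(kept = rownames(msa)[!drop], discarded = rownames(msa)[drop],
       log = log[order(log$id), , drop = FALSE])
}

#' CD-hit-style pairwise identity
#'
#' Percent identity between two unaligned sequences, computed as the
#' number of identical aligned residue pairs after global alignment,
#' divided by the length of the shorter sequence.  `X` never counts as
#' a match.
#'
#' @param a,b residue strings.
#' @param params alignment scoring, see [align_params()].
#' @return percent identity in `[0, 100]`.
#' @export
cdhit_identity <- function(a, b, params = align_params()) {
  aln <- nw_align(a, b, params)
  pa <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  pb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  matches <- sum(pa == pb & pa != GAP_CHAR & pa != "X")
  100 * matches / min(nchar(a), nchar(b))
}

#' Greedy redundancy clustering
#'
#' Sequences are sorted by descending length (ties broken by id) and
#' processed in order: each joins the first existing cluster whose
#' representative shares at least `redundancy_threshold` percent
#' identity (per [cdhit_identity()]), otherwise it founds a new cluster
#' with itself as representative.  Representatives are therefore always
#' the longest member of their cluster.
#'
#' @param records a [seq_set()].
#' @param config a [screen_config()].
#' @param params alignment scoring passed to [cdhit_identity()].
#' @return list of class `clustering`: each element has `representative`
#'   and `members` (ids, representative included).
#' @export
greedy_cluster <- function(records, config = screen_config(),
                           params = align_params()) {
  if (nrow(records) == 0L) stop_bch("no records to cluster")
  ord <- order(-nchar(records$residues), records$id)
  records <- records[ord, , drop = FALSE]
  reps <- character(0)
  rep_seq <- character(0)
  members <- list()
  for (k in seq_len(nrow(records))) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (cdhit_identity(rep_seq[ci], records$residues[k], params) >=
          config$redundancy_threshold) {
        members[[ci]] <- c(members[[ci]], records$id[k])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, records$id[k])
      rep_seq <- c(rep_seq, records$residues[k])
      members[[length(reps)]] <- records$id[k]
    }
  }
  structure(Map(function(r, m) list(representative = r, members = m),
                reps, members),
            class = "clustering", names = reps)
}

#' Apply the full screening stage
#'
#' Length filter on the unaligned records, then greedy redundancy
#' clustering.  By default all cluster members are retained (the
#' curation this mirrors kept redundant members in the final dataset);
#' set `keep = "representatives"` to reduce each cluster to its
#' representative.
#'
#' @param records a [seq_set()].
#' @param config a [screen_config()].
#' @param keep `"members"` (default) or `"representatives"`.
#' @param params alignment scoring for clustering.
#' @return list with `kept` (`seq_set`), `clusters`, and `log` (discard
#'   log data frame).
#' @export
screen_records <- function(records, config = screen_config(),
                           keep = c("members", "representatives"),
                           params = align_params()) {
  keep <- match.arg(keep)
  lf <- length_filter(records, config)
  if (nrow(lf$kept) == 0L) {
    return(list(kept = lf$kept, clusters = NULL, log = lf$discarded))
  }
  cl <- greedy_cluster(lf$kept, config, params)
  kept_ids <- if (keep == "members") {
    unlist(lapply(cl, `[[`, "members"), use.names = FALSE)
  } else {
    names(cl)
  }
  log <- lf$discarded
  dropped <- setdiff(lf$kept$id, kept_ids)
  if (length(dropped)) {
    log <- rbind(log, data.frame(id = dropped, rule = "redundancy",
                                 value = config$redundancy_threshold,
                                 stringsAsFactors = FALSE))
  }
  list(kept = lf$kept[lf$kept$id %in% kept_ids, , drop = FALSE],
       clusters = cl, log = log)
}
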