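#' Secondary-structure template
#'
#' An ordered set of labeled secondary-structure elements (`strand`,
#' `helix`, `loop`) with 1-based inclusive residue ranges in a named
#' reference coordinate system.  Elements must be non-overlapping and
#' ascending; coverage may have holes.
#'
#' @param name element names.
#' @param kind element kinds (`strand`, `helix`, `loop`).
#' @param start,end 1-based inclusive residue coordinates.
#' @return data frame of class `ss_template`.
#' @export
ss_template <- function(name, kind, start, end) {
  kind <- match.arg(kind, c("strand", "helix", "loop"), several.ok = TRUE)
  x <- data.frame(name = name, kind = kind, start = as.integer(start),
                  end = as.integer(end), stringsAsFactors = FALSE)
  if (nrow(x) == 0L) stop_bch("empty secondary-structure template")
  if (any(x$end < x$start)) stop_bch("element end before start")
  if (is.unsorted(x$start, strictly = TRUE) ||
      any(x$start[-1] <= x$end[-nrow(x)])) {
    stop_bch("template elements must be ascending and non-overlapping")
  }
  class(x) <- c("ss_template", "data.frame")
  x
}

#' Default BCH-domain secondary-structure template
#'
#' The structural core of the BCH domain comprises three pairs of
#' alternating alpha-helices and parallel beta-strands enclosing a
#' hydrophobic cavity, flanked by N- and C-terminal strands (betaN,
#' betaC).  No experimental structure fixes the residue ranges, so this
#' template carries placeholder ranges spanning a 173-residue domain,
#' with contiguous loops between elements; supply real ranges (e.g.
#' from a predicted model) via [read_ss_template()] for real data.  All
#' computation is template-relative.
#'
#' @return an [ss_template()].
#' @export
default_ss_template <- function() {
  core <- data.frame(
    name = c("betaN", "alpha1", "beta1", "alpha2", "beta2", "alpha3",
             "beta3", "betaC"),
    kind = c("strand", "helix", "strand", "helix", "strand", "helix",
             "strand", "strand"),
    start = c(8L, 22L, 50L, 64L, 92L, 106L, 134L, 150L),
    end = c(14L, 42L, 56L, 84L, 98L, 126L, 140L, 156L),
    stringsAsFactors = FALSE)
  # interleave loops over the remaining coordinates of the 173-residue span
  rows <- NULL
  prev_end <- 0L
  for (k in seq_len(nrow(core))) {
    if (core$start[k] > prev_end + 1L) {
      rows <- rbind(rows, data.frame(
        name = sprintf("loop%d", k - 1L), kind = "loop",
        start = prev_end + 1L, end = core$start[k] - 1L,
        stringsAsFactors = FALSE))
    }
    rows <- rbind(rows, core[k, ])
    prev_end <- core$end[k]
  }
  rows <- rbind(rows, data.frame(name = "loopC", kind = "loop",
                                 start = prev_end + 1L, end = 173L,
                                 stringsAsFactors = FALSE))
  ss_template(rows$name, rows$kind, rows$start, rows$end)
}

#' Read a secondary-structure template TSV
#'
#' Columns: `name`, `kind`, `start`, `end`.
#'
#' @param path input path.
#' @return an [ss_template()].
#' @export
read_ss_template <- function(path) {
  tab <- read_table_tsv(path)
  need <- c("name", "kind", "start", "end")
  if (!all(need %in% names(tab))) {
    stop_bch("template must have columns: ", paste(need, collapse = ", "))
  }
  ss_template(tab$name, tab$kind, tab$start, tab$end)
}

#' Read an intron-position table TSV
#'
#' Columns: `id` (gene/protein), `group`, `position` (amino-acid
#' position of the insertion), `phase` (0, 1 or 2).
#'
#' @param path input path.
#' @return a validated data frame.
#' @export
read_introns <- function(path) {
  tab <- read_table_tsv(path)
  need <- c("id", "group", "position", "phase")
  if (!all(need %in% names(tab))) {
    stop_bch("intron table must have columns: ", paste(need, collapse = ", "))
  }
  validate_introns(tab)
}

validate_introns <- function(tab) {
  if (nrow(tab) && any(tab$position < 1)) stop_bch("intron position < 1")
  if (nrow(tab) && !all(tab$phase %in% 0:2)) {
    stop_bch("intron phase must be 0, 1 or 2")
  }
  tab
}

#' Map intron positions onto secondary-structure elements
#'
#' Each intron is assigned the element containing its amino-acid
#' position.  Boundary rule: an intron at the last residue of a
#' non-loop element that is directly followed by a loop is assigned to
#' that following loop (it falls between structural elements).
#' Positions outside the template span are flagged (`in_span = FALSE`),
#' not dropped.  Introns landing in beta-strands are additionally
#' flagged: in curated BCH data no intron insertions are seen in
#' strands, so a strand hit usually marks an annotation problem.
#'
#' @param introns an intron table (see [read_introns()]).
#' @param template an [ss_template()].
#' @return list with `annotated` (intron table plus `element`, `kind`,
#'   `in_span`, `strand_flag`), `counts_by_kind`, and
#'   `counts_by_group_kind`.
#' @export
map_introns <- function(introns, template) {
  if (!inherits(template, "ss_template")) template <- ss_template(
    template$name, template$kind, template$start, template$end)
  introns <- validate_introns(introns)
  n <- nrow(introns)
  element <- rep(NA_character_, n)
  kind <- rep(NA_character_, n)
  in_span <- rep(FALSE, n)
  for (k in seq_len(n)) {
    pos <- introns$position[k]
    hit <- which(template$start <= pos & pos <= template$end)
    if (!length(hit)) next
    hit <- hit[1]
    if (pos == template$end[hit] && template$kind[hit] != "loop" &&
        hit < nrow(template) && template$kind[hit + 1] == "loop") {
      hit <- hit + 1L
    }
    element[k] <- template$name[hit]
    kind[k] <- template$kind[hit]
    in_span[k] <- TRUE
  }
  annotated <- cbind(introns,
                     data.frame(element = element, kind = kind,
                                in_span = in_span,
                                strand_flag = !is.na(kind) & kind == "strand",
                                stringsAsFactors = FALSE))
  kinds <- c("strand", "helix", "loop")
  counts_by_kind <- vapply(kinds, function(kk) {
    sum(annotated$in_span & annotated$kind == kk)
  }, integer(1))
  groups <- unique(annotated$group)
  counts_by_group_kind <- if (length(groups)) {
    do.call(rbind, lapply(groups, function(g) {
      sel <- annotated$group == g & annotated$in_span
      data.frame(group = g,
                 strand = sum(annotated$kind[sel] == "strand"),
                 helix = sum(annotated$kind[sel] == "helix"),
                 loop = sum(annotated$kind[sel] == "loop"),
                 out_of_span = sum(annotated$group == g & !annotated$in_span),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(group = character(0), strand = integer(0),
               helix = integer(0), loop = integer(0),
               out_of_span = integer(0))
  }
  list(annotated = annotated, counts_by_kind = counts_by_kind,
       counts_by_group_kind = counts_by_group_kind)
}

#' Per-group intron spectrum over element kinds
#'
#' Fractions of in-span introns per element kind within each group;
#' fractions sum to one within a group (groups with no in-span introns
#' are omitted).
#'
#' @param annotated the `annotated` table from [map_introns()].
#' @return data frame with columns `group`, `kind`, `fraction`.
#' @export
element_spectrum <- function(annotated) {
  kinds <- c("strand", "helix", "loop")
  groups <- unique(annotated$group[annotated$in_span])
  out <- NULL
  for (g in groups) {
    sel <- annotated$group == g & annotated$in_span
    tot <- sum(sel)
    for (kk in kinds) {
      out <- rbind(out, data.frame(
        group = g, kind = kk,
        fraction = sum(annotated$kind[sel] == kk) / tot,
        stringsAsFactors = FALSE))
    }
  }
  out %||% data.frame(group = character(0), kind = character(0),
                      fraction = numeric(0))
}
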