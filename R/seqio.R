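#' Construct a protein sequence set
#'
#' A `seq_set` is the package's container for unaligned protein
#' sequences: a data frame with columns `id`, `description` and
#' `residues`.  Residues are uppercase letters from the 20 amino-acid
#' alphabet plus `X` (unknown residue).  Ids must be unique and contain
#' no whitespace.
#'
#' @param id character vector of unique, whitespace-free identifiers.
#' @param residues character vector of residue strings.
#' @param description optional free-text descriptions.
#' @return a data frame of class `seq_set`.
#' @export
seq_set <- function(id, residues, description = "") {
  x <- data.frame(id = as.character(id),
                  description = rep_len(as.character(description), length(id)),
                  residues = toupper(as.character(residues)),
                  stringsAsFactors = FALSE)
  class(x) <- c("seq_set", "data.frame")
  validate_seq_set(x)
}

validate_seq_set <- function(x) {
  if (nrow(x) == 0L) stop_bch("sequence set is empty")
  if (anyDuplicated(x$id)) {
    dup <- unique(x$id[duplicated(x$id)])
    stop_bch("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  }
  if (any(grepl("[[:space:]]", x$id))) {
    stop_bch("sequence ids must not contain whitespace: ",
             paste(x$id[grepl("[[:space:]]", x$id)], collapse = ", "))
  }
  for (k in seq_len(nrow(x))) {
    r <- x$residues[k]
    if (!nzchar(r)) stop_bch("empty sequence for id '", x$id[k], "'")
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% AA_WITH_X)
    if (length(bad)) {
      stop_bch("illegal residue '", ch[bad[1]], "' at position ", bad[1],
               " in sequence '", x$id[k], "'")
    }
  }
  x
}

#' @export
print.seq_set <- function(x, ...) {
  cat("Protein sequence set: ", nrow(x), " sequences, lengths ",
      min(nchar(x$residues)), "-", max(nchar(x$residues)), "\n", sep = "")
  invisible(x)
}

#' Read a protein FASTA file
#'
#' Lowercase residues are uppercased and trailing `*` stop characters
#' are stripped before validation.  Duplicate ids, empty files and
#' residues outside the 20-letter amino-acid alphabet (plus `X`) are
#' errors.
#'
#' @param path path to a FASTA file.
#' @return a [seq_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_bch("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop_bch("empty FASTA file: ", path)
  nm <- names(set)
  id <- sub("[[:space:]].*$", "", nm)
  desc <- ifelse(grepl("[[:space:]]", nm),
                 sub("^[^[:space:]]+[[:space:]]+", "", nm), "")
  res <- toupper(as.character(set))
  res <- sub("\\*+$", "", res)
  seq_set(id, res, desc)
}

#' Write a sequence set to FASTA
#'
#' @param x a [seq_set()].
#' @param path output path.
#' @param width line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  x <- validate_seq_set(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(x))) {
    hdr <- if (nzchar(x$description[k])) {
      paste(x$id[k], x$description[k])
    } else {
      x$id[k]
    }
    writeLines(paste0(">", hdr), con)
    r <- x$residues[k]
    starts <- seq(1L, nchar(r), by = width)
    writeLines(substring(r, starts, pmin(starts + width - 1L, nchar(r))), con)
  }
  invisible(path)
}

#' Construct a multiple sequence alignment
#'
#' An `aa_msa` is a character matrix (one row per sequence, one column
#' per alignment position) with unique row names.  `-` is the gap
#' character; `.` on input is converted to `-`.  Ungapping any row must
#' yield a valid protein sequence.
#'
#' @param x a named character vector of equal-length gapped strings, or
#'   a character matrix of single residues with row names.
#' @return a matrix of class `aa_msa`.
#' @export
aa_msa <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else {
    if (is.null(names(x))) stop_bch("alignment rows must be named")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      bad <- names(x)[lens != max(lens)]
      stop_bch("alignment rows have unequal lengths (ragged): ",
               paste(bad, collapse = ", "))
    }
    m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(m) <- names(x)
  }
  m[m == "."] <- GAP_CHAR
  m <- toupper(m)
  m[m == tolower(GAP_CHAR)] <- GAP_CHAR
  validate_msa(m)
}

validate_msa <- function(m) {
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop_bch("alignment rows must have unique names")
  }
  if (ncol(m) == 0L) stop_bch("alignment has zero columns")
  bad <- !(m %in% c(AA_WITH_X, GAP_CHAR))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop_bch("illegal alignment character '", m[bad][1], "' in row '",
             rownames(m)[idx[1]], "' column ", idx[2])
  }
  if (any(apply(m, 1, function(r) all(r == GAP_CHAR)))) {
    stop_bch("alignment contains an all-gap row")
  }
  class(m) <- c("aa_msa", class(m))
  m
}

#' @export
print.aa_msa <- function(x, ...) {
  cat("Protein alignment:", nrow(x), "sequences x", ncol(x), "columns\n")
  invisible(x)
}

#' Collapse alignment rows back to gapped strings
#'
#' @param msa an [aa_msa()].
#' @return named character vector of gapped strings.
#' @export
msa_strings <- function(msa) {
  setNames(apply(unclass(msa), 1, paste, collapse = ""), rownames(msa))
}

#' Ungap one alignment row into a plain residue string
#'
#' @param msa an [aa_msa()].
#' @param id row id.
#' @return residue string without gaps.
#' @export
ungapped_row <- function(msa, id) {
  if (!id %in% rownames(msa)) stop_bch("id not in alignment: ", id)
  r <- msa[id, ]
  paste(r[r != GAP_CHAR], collapse = "")
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA and Clustal dialects.  Clustal conservation
#' lines are ignored; `.` gaps are normalized to `-`.
#'
#' @param path path to the alignment file.
#' @param dialect `"aligned-fasta"` or `"clustal"`.
#' @return an [aa_msa()].
#' @export
read_msa <- function(path, dialect = c("aligned-fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_bch("no such file: ", path)
  if (dialect == "aligned-fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop_bch("empty alignment file: ", path)
    nm <- sub("[[:space:]].*$", "", names(set))
    aa_msa(setNames(as.character(set), nm))
  } else {
    aa_msa(parse_clustal(path))
  }
}

# Minimal Clustal parser: header line, then interleaved blocks of
# "<name> <chunk> [cumulative count]"; conservation lines (leading
# whitespace) and blank lines are skipped.  Handles any block count,
# including the single-block files some writers emit.
parse_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^CLUSTAL", lines[1])) {
    stop_bch("not a Clustal file (missing CLUSTAL header): ", path)
  }
  lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s", lines)]
  if (!length(lines)) stop_bch("empty Clustal alignment: ", path)
  m <- regmatches(lines, regexec("^(\\S+)\\s+(\\S+)", lines))
  chunks <- list()
  for (hit in m) {
    if (length(hit) < 3) stop_bch("malformed Clustal line")
    nm <- hit[2]
    chunks[[nm]] <- c(chunks[[nm]], hit[3])
  }
  setNames(vapply(chunks, paste, character(1), collapse = ""),
           names(chunks))
}

#' Write an alignment as aligned FASTA
#'
#' @param msa an [aa_msa()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  s <- msa_strings(msa)
  writeLines(as.vector(rbind(paste0(">", names(s)), s)), path)
  invisible(path)
}

#' Write an alignment in Clustal format
#'
#' Emits interleaved 60-column blocks under a standard Clustal header.
#' No conservation line is written (readers ignore it).
#'
#' @param msa an [aa_msa()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa_clustal <- function(msa, path) {
  s <- msa_strings(msa)
  nm <- format(names(s), width = max(nchar(names(s))) + 3L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("CLUSTAL W (2.0) multiple sequence alignment", "", ""), con)
  width <- 60L
  for (start in seq(1L, nchar(s[1]), by = width)) {
    chunk <- substring(s, start, min(start + width - 1L, nchar(s[1])))
    writeLines(paste0(nm, chunk), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write a data frame as a TSV with header
#'
#' @param rows a data frame (possibly zero rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(rows, path) {
  if (!is.data.frame(rows)) stop_bch("rows must be a data frame")
  ok <- tryCatch({
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop_bch("cannot write table to '", path, "': ",
                            conditionMessage(ok))
  invisible(path)
}

#' Read a TSV written by [write_table_tsv()]
#'
#' @param path input path.
#' @return a data frame.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop_bch("no such file: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a group-label table
#'
#' A two-column TSV (`id`, `group`) mapping sequence ids to the closed
#' group vocabulary `I, IIA, IIB, III, NF1, RhoGEF, CRAL_TRIO,
#' unassigned`.
#'
#' @param path input path.
#' @param ids optional vector of known sequence ids; labeled ids absent
#'   from it are an error.
#' @return named character vector `id -> group`.
#' @export
read_labels <- function(path, ids = NULL) {
  tab <- read_table_tsv(path)
  if (!all(c("id", "group") %in% names(tab))) {
    stop_bch("label table must have columns 'id' and 'group'")
  }
  labeling(setNames(tab$group, tab$id), ids = ids)
}

#' Validate a group labeling
#'
#' @param labels named character vector `id -> group`.
#' @param ids optional universe of sequence ids the labels must refer to.
#' @return the validated named vector.
#' @export
labeling <- function(labels, ids = NULL) {
  bad <- setdiff(unique(labels), GROUP_LABELS)
  if (length(bad)) {
    stop_bch("unknown group label(s): ", paste(bad, collapse = ", "),
             " (allowed: ", paste(GROUP_LABELS, collapse = ", "), ")")
  }
  if (!is.null(ids)) {
    missing <- setdiff(names(labels), ids)
    if (length(missing)) {
      stop_bch("labeled id(s) absent from sequence set: ",
               paste(missing, collapse = ", "))
    }
  }
  labels
}

# ---- Newick -----------------------------------------------------------

format_brlen <- function(x) sprintf("%.6f", x)

#' Write a tree to Newick
#'
#' Branch lengths are written with six decimals; integer bootstrap
#' supports (if present in `tree$node.label`) become internal-node
#' labels.
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop_bch("tree must be a 'phylo' object")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  lab <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    nl <- tree$node.label
    if (is.null(nl)) return("")
    l <- nl[node - ntip]
    if (is.na(l) || identical(l, "NA")) "" else as.character(l)
  }
  rec <- function(node) {
    e <- kids[[as.character(node)]]
    if (is.null(e)) return(lab(node))
    parts <- vapply(e, function(ei) {
      child <- tree$edge[ei, 2]
      sub <- rec(child)
      if (!is.null(tree$edge.length)) {
        paste0(sub, ":", format_brlen(tree$edge.length[ei]))
      } else {
        sub
      }
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")", lab(node))
  }
  txt <- paste0(rec(root), ";")
  ok <- tryCatch({ writeLines(txt, path); TRUE }, error = function(e) e)
  if (!isTRUE(ok)) stop_bch("cannot write Newick to '", path, "': ",
                            conditionMessage(ok))
  invisible(path)
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()]; numeric internal-node labels
#' are kept as character bootstrap supports in `node.label`.
#'
#' @param path input path.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_bch("no such file: ", path)
  ape::read.tree(path)
}
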