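#' Per-group simulation settings
#'
#' Describes one synthetic domain family: how many sequences, how long,
#' the tree they evolve on, the substitution intensity, which signature
#' residues are planted at which conservation rates, whether the
#' hallmark motif window is planted (BCH-type groups only), and the
#' intron policy.
#'
#' The synthetic domain is laid out directly in the signature set's
#' reference numbering (alignment column = reference position -
#' offset), so the published positions fall inside the domain without a
#' mapping step.
#'
#' @param name group label from the closed vocabulary (see
#'   [labeling()]).
#' @param n number of sequences (tree leaves).
#' @param length domain length in residues (default 297, the length of
#'   the trimmed alignment block the real analysis retained).
#' @param tree fixed Newick string, or `NULL` to draw a random tree.
#' @param brlen_mean mean of the exponential branch-length distribution
#'   for random trees (substitutions per site per branch).
#' @param rate per-site substitution rate per unit branch length.
#' @param signatures a [signature_set()] with expected conservation
#'   rates, planted per leaf; `NULL` plants nothing.
#' @param motif_start 1-based start of the hallmark motif window, or
#'   `NULL` for families without the motif.
#' @param decoy_signatures a [signature_set()] of the *opposing*
#'   family's diagnostic positions, planted at the low `decoy_rate`:
#'   in the published conservation table every such position sits
#'   below the 50% reporting threshold in the other family, so a
#'   faithful family must not conserve them by ancestral drift.
#'   Positions colliding with this group's own signatures or motif
#'   window are skipped.
#' @param decoy_rate conservation rate for decoy positions; the
#'   default `NULL` uses each position's background expectation
#'   `length(allowed) / 20`, i.e. no signal above chance.
#' @param motif_pattern compiled pattern planted in the window.
#' @param background residue sampling weights (length 20; default
#'   uniform).
#' @param introns_per_gene introns drawn per sequence.
#' @param intron_kinds element kinds introns may fall in (e.g.
#'   `"helix"` for animal-like, `"loop"` for plant-like policies).
#' @return a list of class `group_config`.
#' @export
group_config <- function(name, n, length = 297L, tree = NULL,
                         brlen_mean = 0.04, rate = 1,
                         signatures = NULL, motif_start = NULL,
                         decoy_signatures = NULL, decoy_rate = NULL,
                         motif_pattern = hallmark_motif(),
                         background = rep(1 / 20, 20),
                         introns_per_gene = 2L,
                         intron_kinds = "helix") {
  stopifnot(n >= 1, length >= 1, rate >= 0, brlen_mean > 0,
            length(background) == 20, all(background >= 0))
  if (!is.null(signatures)) {
    pos <- signatures$positions - signatures$offset
    if (any(pos < 1 | pos > length)) {
      stop_bch("signature positions fall outside the domain length")
    }
    if (!is.null(signatures$expected) &&
        any(signatures$expected < 0 | signatures$expected > 1)) {
      stop_bch("signature rates must be in [0, 1]")
    }
  }
  if (!is.null(motif_start)) {
    if (motif_start < 1 ||
        motif_start + length(motif_pattern$sets) - 1L > length) {
      stop_bch("motif window does not fit the domain length")
    }
  }
  structure(list(name = name, n = as.integer(n), length = as.integer(length),
                 tree = tree, brlen_mean = brlen_mean, rate = rate,
                 signatures = signatures, motif_start = motif_start,
                 decoy_signatures = decoy_signatures,
                 decoy_rate = decoy_rate,
                 motif_pattern = motif_pattern,
                 background = background / sum(background),
                 introns_per_gene = as.integer(introns_per_gene),
                 intron_kinds = intron_kinds),
            class = "group_config")
}

#' Full simulation configuration
#'
#' @param seed integer seed; all randomness in [emit_dataset()] derives
#'   from it.
#' @param groups list of [group_config()]s.
#' @param template an [ss_template()] used for intron placement.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L, groups, template = default_ss_template()) {
  stopifnot(length(groups) >= 1)
  structure(list(seed = as.integer(seed), groups = groups,
                 template = template),
            class = "sim_config")
}

#' Default simulation: the study's dataset structure
#'
#' Emulates the real dataset the analysis was built on: a BCH family of
#' 175 sequences (group label `I`) carrying the hallmark motif window
#' anchored at BNIP-2 residue 235 and the BCH signature residues at
#' their published conservation rates, and a CRAL_TRIO family of 69
#' sequences carrying the Sec14p-anchored signatures at their published
#' rates and no motif.  Each family additionally plants the *other*
#' family's signature positions at background conservation
#' (`length(allowed) / 20` per position), mirroring the published
#' table where cross-family signatures sit below the 50% reporting
#' threshold.
#' Both families are 297 residues long (the trimmed alignment block
#' length).  Intron policy: helix insertions
#' for the animal-like BCH group, loop insertions for the plant-like
#' policy illustrated on the CRAL_TRIO family; no strand insertions.
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
default_sim_config <- function(seed = 42L) {
  sim_config(seed = seed, groups = list(
    group_config("I", n = 175L, signatures = bch_signatures(),
                 decoy_signatures = cral_trio_signatures(),
                 motif_start = 235L, intron_kinds = "helix"),
    group_config("CRAL_TRIO", n = 69L, signatures = cral_trio_signatures(),
                 decoy_signatures = bch_signatures(),
                 motif_start = NULL, intron_kinds = "loop")))
}

#' Simulate a random binary tree
#'
#' Random topology (recursive random splitting, via [ape::rtree()])
#' with independent exponential branch lengths.
#'
#' @param n number of leaves (>= 2).
#' @param brlen_mean mean branch length.
#' @param seed optional seed for reproducibility.
#' @return an [ape::phylo] tree with tips `t1..tn`.
#' @export
simulate_tree <- function(n, brlen_mean = 0.04, seed = NULL) {
  if (n < 2) stop_bch("need at least 2 leaves")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rtree(n, br = NULL)
  tree$edge.length <- rexp(nrow(tree$edge), rate = 1 / brlen_mean)
  tree
}

sample_background <- function(k, background) {
  sample(AA_ALPHABET, k, replace = TRUE, prob = background)
}

#' Evolve a sequence family on a tree
#'
#' A root sequence drawn from the background frequencies is propagated
#' along the tree; on each branch every site substitutes independently
#' with probability `1 - exp(-rate * branch_length)`, substituted sites
#' being resampled from the background (a simple resampling model, not
#' a named empirical matrix).  Evolution is indel-free, so the leaf
#' matrix is its own true alignment.
#'
#' After evolution, per-leaf and independently of the tree:
#' * the hallmark motif window (if configured) is planted by drawing
#'   each window position from its allowed residue class;
#' * each signature position is planted at its target conservation
#'   rate by exact count: `round(rate_k * n)` randomly chosen leaves
#'   receive a residue from the allowed set (restricted to the motif
#'   class when the position sits inside the motif window; disjoint
#'   sets are a configuration error), the rest a residue from outside
#'   the allowed set, so the realized conservation equals the
#'   configured rate up to rounding.
#'
#' @param tree an [ape::phylo] tree whose tip count equals `config$n`.
#' @param config a [group_config()].
#' @return list of class `sim_family`: `msa` (true alignment, rows
#'   named `<group>_<k>`), `labels`, `tree` (tips renamed to match),
#'   `planted` (data frame of planted signature columns and rates),
#'   `motif_window` (start/end or `NULL`).
#' @export
evolve_family <- function(tree, config) {
  ntip <- length(tree$tip.label)
  if (ntip != config$n) stop_bch("tree has ", ntip, " leaves, config wants ",
                                 config$n)
  L <- config$length
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample_background(L, config$background)
  # preorder: parents before children
  for (e in rev(ape::postorder(tree))) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    p_sub <- 1 - exp(-config$rate * tree$edge.length[e])
    s <- seqs[[p]]
    mask <- runif(L) < p_sub
    if (any(mask)) s[mask] <- sample_background(sum(mask), config$background)
    seqs[[ch]] <- s
  }
  ids <- sprintf("%s_%03d", config$name, seq_len(ntip))
  m <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(m) <- ids
  motif_window <- NULL
  motif_sets <- NULL
  if (!is.null(config$motif_start)) {
    sets <- config$motif_pattern$sets
    motif_window <- c(start = config$motif_start,
                      end = config$motif_start + length(sets) - 1L)
    motif_sets <- sets
    for (p in seq_along(sets)) {
      col <- config$motif_start + p - 1L
      m[, col] <- sample(sets[[p]], ntip, replace = TRUE)
    }
  }
  planted <- NULL
  own_cols <- integer(0)
  plant_set <- function(sig, rates, role, skip_cols = integer(0)) {
    for (k in seq_along(sig$positions)) {
      col <- sig$positions[k] - sig$offset
      if (col %in% skip_cols) next
      allowed <- sig$allowed[[k]]
      in_window <- !is.null(motif_window) && col >= motif_window["start"] &&
        col <= motif_window["end"]
      if (in_window && role == "decoy") next
      if (in_window) {
        pat_set <- motif_sets[[col - motif_window["start"] + 1L]]
        match_set <- intersect(allowed, pat_set)
        if (!length(match_set)) {
          stop_bch("signature at position ", sig$positions[k],
                   " lies inside the motif window with a disjoint ",
                   "residue set")
        }
      } else {
        match_set <- allowed
      }
      miss_set <- setdiff(AA_ALPHABET, allowed)
      # exact-count planting: the family carries round(rate * n) allowed
      # residues at this column, so the realized conservation equals the
      # configured rate up to rounding (rather than a Bernoulli draw
      # whose extremes can stray several standard errors)
      n_match <- round(rates[k] * ntip)
      is_match <- rep(FALSE, ntip)
      if (n_match > 0) is_match[sample.int(ntip, n_match)] <- TRUE
      if (any(is_match)) {
        m[is_match, col] <<- sample(match_set, sum(is_match), replace = TRUE)
      }
      if (any(!is_match)) {
        m[!is_match, col] <<- sample(miss_set, sum(!is_match), replace = TRUE)
      }
      planted <<- rbind(planted, data.frame(
        group = config$name, position = sig$positions[k], column = col,
        allowed = paste(allowed, collapse = "/"), rate = rates[k],
        role = role, stringsAsFactors = FALSE))
    }
  }
  if (!is.null(config$signatures)) {
    sig <- config$signatures
    plant_set(sig, sig$expected %||% rep(1, length(sig$positions)),
              role = "signature")
    own_cols <- sig$positions - sig$offset
  }
  if (!is.null(config$decoy_signatures)) {
    dec <- config$decoy_signatures
    dec_rates <- config$decoy_rate %||% (lengths(dec$allowed) / 20)
    plant_set(dec, rep_len(dec_rates, length(dec$positions)),
              role = "decoy", skip_cols = own_cols)
  }
  tree$tip.label <- ids
  structure(list(msa = aa_msa(m),
                 labels = setNames(rep(config$name, ntip), ids),
                 tree = tree, planted = planted,
                 motif_window = motif_window),
            class = "sim_family")
}

draw_introns <- function(ids, group, template, kinds, per_gene) {
  elig <- which(template$kind %in% kinds)
  if (!length(elig) || per_gene == 0L) {
    return(data.frame(id = character(0), group = character(0),
                      position = integer(0), phase = integer(0)))
  }
  rows <- NULL
  for (id in ids) {
    el <- sample(elig, per_gene, replace = TRUE)
    pos <- vapply(el, function(e) {
      # the last residue of a non-loop element maps to the following
      # loop under the boundary rule, so draw strictly inside it
      hi <- if (template$kind[e] == "loop") template$end[e] else
        max(template$start[e], template$end[e] - 1L)
      as.integer(sample(seq(template$start[e], hi), 1))
    }, integer(1))
    rows <- rbind(rows, data.frame(
      id = id, group = group, position = pos,
      phase = sample(0:2, per_gene, replace = TRUE),
      stringsAsFactors = FALSE))
  }
  rows
}

#' Generate and write a full synthetic dataset
#'
#' Simulates every configured family from `config$seed`, stacks them
#' into one alignment (families must share the same domain length), and
#' writes the cross-consistent file set: unaligned FASTA, aligned FASTA
#' and its Clustal twin, label and intron TSVs, the secondary-structure
#' template, per-group true trees (Newick), the planted-rate table and
#' a JSON metadata bundle.  Output is byte-identical for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed); `NULL` skips file
#'   output and returns the in-memory objects only.
#' @return list of class `sim_dataset`: `msa`, `records`, `labels`,
#'   `introns`, `families` (per-group [evolve_family()] results),
#'   `template`, and `paths` when files were written.
#' @export
emit_dataset <- function(config = default_sim_config(), dir = NULL) {
  set.seed(config$seed)
  families <- list()
  for (g in config$groups) {
    tree <- if (is.null(g$tree)) {
      simulate_tree(g$n, g$brlen_mean)
    } else {
      ape::read.tree(text = g$tree)
    }
    families[[g$name]] <- evolve_family(tree, g)
  }
  lens <- vapply(families, function(f) ncol(f$msa), integer(1))
  if (length(unique(lens)) != 1L) {
    stop_bch("all families must share the same domain length to stack")
  }
  big <- do.call(rbind, lapply(families, function(f) unclass(f$msa)))
  msa <- aa_msa(big)
  labels <- do.call(c, unname(lapply(families, `[[`, "labels")))
  records <- seq_set(rownames(msa),
                     vapply(rownames(msa), function(id) ungapped_row(msa, id),
                            character(1)))
  introns <- do.call(rbind, lapply(seq_along(config$groups), function(k) {
    g <- config$groups[[k]]
    draw_introns(names(families[[g$name]]$labels), g$name,
                 config$template, g$intron_kinds, g$introns_per_gene)
  }))
  planted <- do.call(rbind, lapply(families, `[[`, "planted"))
  rownames(planted) <- NULL
  out <- structure(list(msa = msa, records = records, labels = labels,
                        introns = introns, families = families,
                        planted = planted, template = config$template,
                        seed = config$seed),
                   class = "sim_dataset")
  if (!is.null(dir)) {
    dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(dir, "sequences.fasta"),
      msa_fasta = file.path(dir, "alignment.afa"),
      msa_clustal = file.path(dir, "alignment.aln"),
      labels = file.path(dir, "labels.tsv"),
      introns = file.path(dir, "introns.tsv"),
      template = file.path(dir, "ss_template.tsv"),
      planted = file.path(dir, "truth", "planted_rates.tsv"),
      meta = file.path(dir, "truth", "meta.json"))
    write_fasta(records, paths$fasta)
    write_msa_fasta(msa, paths$msa_fasta)
    write_msa_clustal(msa, paths$msa_clustal)
    write_table_tsv(data.frame(id = names(labels), group = unname(labels)),
                    paths$labels)
    write_table_tsv(introns, paths$introns)
    write_table_tsv(as.data.frame(config$template), paths$template)
    write_table_tsv(planted, paths$planted)
    for (g in names(families)) {
      p <- file.path(dir, "truth", paste0("tree_", g, ".nwk"))
      write_newick(families[[g]]$tree, p)
      paths[[paste0("tree_", g)]] <- p
    }
    meta <- list(seed = config$seed,
                 groups = lapply(config$groups, function(g) {
                   list(name = g$name, n = g$n, length = g$length,
                        rate = g$rate, brlen_mean = g$brlen_mean,
                        motif_start = g$motif_start,
                        introns_per_gene = g$introns_per_gene,
                        intron_kinds = g$intron_kinds)
                 }))
    jsonlite::write_json(meta, paths$meta, auto_unbox = TRUE, pretty = TRUE)
    out$paths <- paths
  }
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic domain dataset:", nrow(x$msa), "sequences x",
      ncol(x$msa), "columns;",
      length(unique(x$labels)), "groups;",
      nrow(x$introns), "introns; seed", x$seed, "\n")
  invisible(x)
}

#' Inject gap runs into alignment rows
#'
#' Test mutator for the gap-screening and complete-deletion code paths:
#' replaces an internal stretch of residues with gaps in the chosen
#' rows.  The alignment stays rectangular.
#'
#' @param msa an [aa_msa()].
#' @param ids rows to mutate.
#' @param run_length gap run length in columns.
#' @param start 1-based start column of the run (default: centered).
#' @return the mutated [aa_msa()].
#' @export
inject_gap_runs <- function(msa, ids, run_length = 35L, start = NULL) {
  m <- unclass(msa)
  if (is.null(start)) start <- max(2L, (ncol(m) - run_length) %/% 2L)
  stopifnot(start > 1L, start + run_length - 1L < ncol(m))
  for (id in ids) {
    if (!id %in% rownames(m)) stop_bch("id not in alignment: ", id)
    m[id, start:(start + run_length - 1L)] <- GAP_CHAR
  }
  aa_msa(m)
}
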