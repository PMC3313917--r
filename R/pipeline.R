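#' Load a pipeline configuration
#'
#' A pipeline configuration is a plain list (or a YAML file holding
#' one) with the entries:
#'
#' * `seed` — integer, drives every random stage;
#' * `input` — either `simulate: true` (the default synthetic dataset
#'   is generated into the output directory) or paths `fasta`, `msa`,
#'   `labels`, and optionally `introns`, `template`;
#' * `screen` — arguments for [screen_config()];
#' * `phylo` — arguments for [phylo_config()] (default bootstrap count
#'   here is 100 to keep the stage responsive; raise it for final
#'   trees);
#' * `classify` — arguments for [classify_thresholds()].
#'
#' Referenced paths must exist at invocation.
#'
#' @param config a list or the path to a YAML file.
#' @return validated configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_bch("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$input <- config$input %||% list(simulate = TRUE)
  if (!isTRUE(config$input$simulate)) {
    required <- c("fasta", "msa", "labels")
    for (field in required) {
      if (is.null(config$input[[field]])) {
        stop_bch("config error: input$", field, " is required when not ",
                 "simulating")
      }
    }
    for (field in required) {
      p <- config$input[[field]]
      if (!file.exists(p)) {
        stop_bch("config error: input$", field, " file not found: ", p)
      }
    }
  }
  config
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_bch("stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Orders the stages as in the original analysis: screen the sequences,
#' compute the group identity table, build the bootstrapped
#' Neighbor-Joining tree with clade collapsing, write conservation and
#' signature tables, classify every sequence, and map introns onto the
#' secondary-structure template.  All outputs land in `out_dir`
#' together with a `manifest.tsv` listing every artifact with its row
#' count.  Deterministic for a fixed seed.
#'
#' @param config see [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- NULL
  note <- function(path, n_rows) {
    manifest <<- rbind(manifest, data.frame(
      file = basename(path), n_rows = n_rows, stringsAsFactors = FALSE))
  }

  if (isTRUE(config$input$simulate)) {
    ds <- run_stage("simulate", {
      emit_dataset(default_sim_config(config$seed),
                   file.path(out_dir, "dataset"))
    })
    records <- ds$records
    msa <- ds$msa
    labels <- ds$labels
    introns <- ds$introns
    template <- ds$template
  } else {
    records <- run_stage("read", read_fasta(config$input$fasta))
    msa <- run_stage("read", read_msa(config$input$msa))
    labels <- run_stage("read", read_labels(config$input$labels,
                                            ids = rownames(msa)))
    introns <- if (!is.null(config$input$introns)) {
      run_stage("read", read_introns(config$input$introns))
    }
    template <- if (!is.null(config$input$template)) {
      run_stage("read", read_ss_template(config$input$template))
    } else {
      default_ss_template()
    }
  }

  scr_cfg <- do.call(screen_config, config$screen %||% list())
  scr <- run_stage("screen", {
    lf <- length_filter(records, scr_cfg)
    gs <- gap_screen(msa[rownames(msa) %in% lf$kept$id, , drop = FALSE],
                     scr_cfg)
    log <- rbind(lf$discarded,
                 if (nrow(gs$log)) gs$log else NULL)
    list(kept = gs$kept, log = log)
  })
  p <- file.path(out_dir, "screen_log.tsv")
  write_table_tsv(scr$log, p)
  note(p, nrow(scr$log))
  msa <- msa[scr$kept, , drop = FALSE]
  class(msa) <- c("aa_msa", class(msa))
  labels <- labels[intersect(names(labels), scr$kept)]

  idt <- run_stage("identity", {
    group_identity_table(identity_matrix(msa), labels)
  })
  p <- file.path(out_dir, "group_identity.tsv")
  write_table_tsv(as.data.frame(idt), p)
  note(p, nrow(idt))

  ph_cfg <- do.call(phylo_config,
                    utils::modifyList(list(n_bootstrap = 100L,
                                           seed = config$seed),
                                      config$phylo %||% list()))
  tree <- run_stage("tree", bootstrap_support(msa, ph_cfg))
  p <- file.path(out_dir, "tree.nwk")
  write_newick(tree, p)
  note(p, 1L)
  coll <- run_stage("tree", collapse_clades(tree, ph_cfg$collapse_threshold))
  p <- file.path(out_dir, "tree_collapsed.nwk")
  write_newick(coll$tree, p)
  note(p, 1L)
  p <- file.path(out_dir, "collapse_report.tsv")
  write_table_tsv(coll$collapsed, p)
  note(p, nrow(coll$collapsed))

  logo <- run_stage("logo", {
    prof <- column_frequencies(msa)
    lm <- information_content(prof)
    data.frame(column = seq_along(lm$ic), occupancy = prof$occupancy,
               majority = prof$majority,
               majority_fraction = prof$majority_fraction,
               ic_bits = lm$ic, stringsAsFactors = FALSE)
  })
  p <- file.path(out_dir, "logo.tsv")
  write_table_tsv(logo, p)
  note(p, nrow(logo))

  sigs <- run_stage("signatures", {
    rbind(cbind(set = "BCH",
                signature_conservation(msa, bch_signatures(), labels)),
          cbind(set = "CRAL_TRIO",
                signature_conservation(msa, cral_trio_signatures(), labels)))
  })
  p <- file.path(out_dir, "signature_conservation.tsv")
  write_table_tsv(sigs, p)
  note(p, nrow(sigs))

  cls_th <- do.call(classify_thresholds, config$classify %||% list())
  cls <- run_stage("classify", classify_domain(msa, thresholds = cls_th))
  p <- file.path(out_dir, "classification.tsv")
  write_table_tsv(cls, p)
  note(p, nrow(cls))

  if (!is.null(introns) && nrow(introns)) {
    im <- run_stage("introns", map_introns(introns, template))
    p <- file.path(out_dir, "introns_annotated.tsv")
    write_table_tsv(im$annotated, p)
    note(p, nrow(im$annotated))
    spec <- element_spectrum(im$annotated)
    p <- file.path(out_dir, "intron_spectrum.tsv")
    write_table_tsv(spec, p)
    note(p, nrow(spec))
  }

  p <- file.path(out_dir, "manifest.tsv")
  write_table_tsv(manifest, p)
  invisible(manifest)
}
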