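#' Run a full classification workflow from a configuration list
#'
#' Wires the package modules into the two end-to-end workflows (`stepwise`
#' cascade and `reference_based` subtraction), plus `simulate` and
#' `assess_only`, writing machine-readable artifacts to `out_dir`:
#' classification TSV, per-stage count JSON, metrics JSON (when truth
#' labels are available), count/RPKM TSVs (when quantification is
#' requested), and a run log. Re-running with the same config reproduces
#' all outputs byte for byte.
#'
#' Config fields (paths unless noted): `workflow` (one of `"stepwise"`,
#' `"reference_based"`, `"assess_only"`, `"simulate"`); `out_dir`;
#' `reads`, `reads2` (FASTA/FASTQ); `ref_a`, `ref_b`, `genus_refs`,
#' `family_db`; `taxonomy` (TSV subject_id/family) with `family_labels`
#' (named vector family -> species); `preset` (stage-1 preset name,
#' default `"ci_lenient"`); `truth` (TSV read_id/label); `predicted`
#' (classification TSV, `assess_only`); `positive_label`; `quantify`
#' (logical); `seed` and simulator fields (`simulate`; passed to
#' [sim_config()]).
#'
#' @param config a named list as described above.
#' @return (invisibly) a named list of the artifact paths written.
#' @export
run_pipeline <- function(config) {
  wf <- config$workflow %||% stop("config error: workflow is required")
  out_dir <- config$out_dir %||% stop("config error: out_dir is required")
  if (!wf %in% c("stepwise", "reference_based", "assess_only", "simulate"))
    stop("config error: unknown workflow '", wf, "'")
  config <- config[!vapply(config, is.null, logical(1))]
  need <- switch(wf,
    stepwise = c("reads", "ref_a", "ref_b"),
    reference_based = c("reads", "ref_b"),
    assess_only = c("truth", "predicted"),
    simulate = "seed")
  missing_keys <- setdiff(need, names(config))
  if (length(missing_keys) > 0)
    stop("config error: missing ", paste(missing_keys, collapse = ", "))
  for (key in intersect(names(config),
                        c("reads", "reads2", "ref_a", "ref_b", "genus_refs",
                          "family_db", "taxonomy", "truth", "predicted")))
    if (!file.exists(config[[key]]))
      stop("config error: ", key, " path does not exist: ", config[[key]])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) message("[duosplit] ", ...)
  artifacts <- list()
  labels <- config$labels %||% c("species_a", "species_b")

  if (wf == "simulate") {
    sim_args <- config[intersect(names(config), names(formals(sim_config)))]
    cfg <- do.call(sim_config, sim_args)
    log("simulating transcriptomes (seed ", cfg$seed, ")")
    tx <- simulate_transcriptomes(cfg)
    rd <- simulate_reads(tx, cfg)
    paths <- list(
      contigs_a = file.path(out_dir, "contigs_a.fasta"),
      contigs_b = file.path(out_dir, "contigs_b.fasta"),
      genus_refs = file.path(out_dir, "genus_refs.fasta"),
      family_db = file.path(out_dir, "family_db.fasta"),
      taxonomy = file.path(out_dir, "taxonomy.tsv"),
      truth = file.path(out_dir, "truth.tsv"),
      reads = file.path(out_dir, "reads.fastq"))
    write_sequences(tx$contigs_a, paths$contigs_a)
    write_sequences(tx$contigs_b, paths$contigs_b)
    write_sequences(tx$genus_refs, paths$genus_refs)
    write_sequences(tx$family_db, paths$family_db)
    tax <- tx$taxonomy
    writeLines(c("subject_id\tfamily",
                 paste(names(tax$subject_family),
                       unname(tax$subject_family), sep = "\t")),
               paths$taxonomy)
    writeLines(c("read_id\tlabel",
                 paste(rd$truth$read_id, rd$truth$species, sep = "\t")),
               paths$truth)
    write_sequences(rd$reads, paths$reads, format = "fastq")
    artifacts <- paths
  } else if (wf == "stepwise") {
    reads <- read_sequences(config$reads)
    if (!is.null(config$reads2))
      reads <- rbind(reads, read_sequences(config$reads2))
    refs_a <- read_sequences(config$ref_a)
    refs_b <- read_sequences(config$ref_b)
    genus <- if (!is.null(config$genus_refs))
      read_sequences(config$genus_refs) else NULL
    famdb <- if (!is.null(config$family_db))
      read_sequences(config$family_db) else NULL
    tax <- NULL
    if (!is.null(config$taxonomy)) {
      tt <- read_tsv_strict(config$taxonomy, c("subject_id", "family"))
      fam_labels <- config$family_labels %||%
        stats::setNames(labels, unique(tt$family))
      tax <- taxonomy_map(tt, fam_labels)
    }
    preset <- config$preset %||% "ci_lenient"
    cfg <- cascade_config(params_stage1 = mapping_params(preset),
                          genus_target_label = labels[1])
    log("classifying ", nrow(reads), " reads (stepwise, preset ", preset, ")")
    cls <- run_cascade(reads, refs_a, refs_b, genus, famdb, tax,
                       config = cfg, labels = labels)
    artifacts$classification <- file.path(out_dir, "classification.tsv")
    write_classification(cls, artifacts$classification)
    artifacts$stage_counts <- file.path(out_dir, "stage_counts.json")
    write_metrics(as.list(attr(cls, "stage_counts")), artifacts$stage_counts)
    if (!is.null(config$truth)) {
      tr <- read_tsv_strict(config$truth, c("read_id", "label"))
      rep_ <- assess_report(tr, cls, positive_label = labels[1])
      artifacts$metrics <- file.path(out_dir, "metrics.json")
      write_metrics(metrics_of(rep_), artifacts$metrics)
      log(sprintf("assessment AUC %.3f", rep_$auc))
    }
    if (isTRUE(config$quantify)) {
      for (side in 1:2) {
        own <- if (side == 1) refs_a else refs_b
        other <- if (side == 1) refs_b else refs_a
        ids <- cls$read_id[cls$label == labels[side]]
        cnt <- count_per_contig(reads[match(ids, reads$id), , drop = FALSE],
                                own, other,
                                regime = config$regime %||% "separate")
        tagg <- c("a", "b")[side]
        artifacts[[paste0("counts_", tagg)]] <-
          file.path(out_dir, paste0("counts_", tagg, ".tsv"))
        write_counts(cnt, artifacts[[paste0("counts_", tagg)]])
        if (attr(cnt, "total_mapped") > 0) {
          artifacts[[paste0("rpkm_", tagg)]] <-
            file.path(out_dir, paste0("rpkm_", tagg, ".tsv"))
          rp <- rpkm_table(cnt)
          writeLines(c("contig_id\trpkm",
                       paste(rp$contig_id, fmt_num(rp$rpkm), sep = "\t")),
                     artifacts[[paste0("rpkm_", tagg)]])
        }
      }
    }
  } else if (wf == "reference_based") {
    reads <- read_sequences(config$reads)
    if (!is.null(config$reads2))
      reads <- rbind(reads, read_sequences(config$reads2))
    host <- read_sequences(config$ref_b)
    preset <- config$preset %||% "ci_lenient"
    log("classifying ", nrow(reads), " reads (reference-based)")
    cls <- reference_based_classify(reads, host, mapping_params(preset),
                                    labels = labels)
    artifacts$classification <- file.path(out_dir, "classification.tsv")
    write_classification(cls, artifacts$classification)
    if (!is.null(config$truth)) {
      tr <- read_tsv_strict(config$truth, c("read_id", "label"))
      rep_ <- assess_report(tr, cls, positive_label = labels[1])
      artifacts$metrics <- file.path(out_dir, "metrics.json")
      write_metrics(metrics_of(rep_), artifacts$metrics)
    }
  } else { # assess_only
    tr <- read_tsv_strict(config$truth, c("read_id", "label"))
    pred <- read_classification(config$predicted)
    rep_ <- assess_report(tr, pred,
                          positive_label = config$positive_label %||%
                            labels[1])
    artifacts$metrics <- file.path(out_dir, "metrics.json")
    write_metrics(metrics_of(rep_), artifacts$metrics)
    log(sprintf("assessment AUC %.3f", rep_$auc))
  }

  # run log: thresholds and versions for reproducibility
  logpath <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    paste("duosplit", as.character(utils::packageVersion("duosplit"))),
    paste("workflow:", wf),
    paste("preset:", config$preset %||% "ci_lenient"),
    paste("seed:", config$seed %||% "NA")), logpath)
  artifacts$run_log <- logpath
  log("done: ", length(artifacts), " artifacts in ", out_dir)
  invisible(artifacts)
}
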