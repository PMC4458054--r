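#' Taxonomy map for the family-vote stage
#'
#' Associates every subject of the family-labelled database with a family
#' token, and family tokens with species labels. The mapping must be total
#' over the database and the two species must belong to distinct families.
#'
#' @param subject_family named character vector (or two-column data.frame
#'   `subject_id`, `family`) mapping database subjects to family tokens.
#' @param family_species named character vector mapping family tokens to
#'   species labels (families without an entry never yield a label).
#' @return an object of class `taxonomy_map`.
#' @export
taxonomy_map <- function(subject_family, family_species) {
  if (is.data.frame(subject_family)) {
    stopifnot(all(c("subject_id", "family") %in% names(subject_family)))
    subject_family <- stats::setNames(subject_family$family,
                                      subject_family$subject_id)
  }
  stopifnot(is.character(subject_family), !is.null(names(subject_family)),
            is.character(family_species), !is.null(names(family_species)))
  if (anyDuplicated(names(subject_family)))
    stop("duplicate subject_id in taxonomy map")
  labs <- unname(family_species)
  if (length(labs) >= 2 && anyDuplicated(labs))
    stop("the two species must map to distinct families")
  structure(list(subject_family = subject_family,
                 family_species = family_species),
            class = "taxonomy_map")
}

#' Cascade configuration
#'
#' @param params_stage1 [mapping_params()] for the species-contig stage
#'   (default preset `ci_lenient`).
#' @param params_stage2 [mapping_params()] for the same-genus stage
#'   (default preset `genus`).
#' @param top_k number of top database hits required to vote unanimously at
#'   stage 3 (default 5; hits tied with the k-th are included; with fewer
#'   than `top_k` hits, unanimity of all available hits is required).
#' @param genus_target_label species label assigned by the genus stage
#'   (the side that possesses genus-level references; default
#'   `"species_a"`, the parasite in the motivating design).
#' @param stage3_max_evalue e-value gate for hits entering the family vote
#'   (default 1e-5).
#' @return an object of class `cascade_config`.
#' @export
cascade_config <- function(params_stage1 = mapping_params("ci_lenient"),
                           params_stage2 = mapping_params("genus"),
                           top_k = 5, genus_target_label = "species_a",
                           stage3_max_evalue = 1e-5) {
  stopifnot(top_k >= 1)
  structure(list(params_stage1 = params_stage1,
                 params_stage2 = params_stage2, top_k = top_k,
                 genus_target_label = genus_target_label,
                 stage3_max_evalue = stage3_max_evalue),
            class = "cascade_config")
}

# One classification record as a single-row data.frame.
class_record <- function(read_id, label, stage, best = NULL) {
  data.frame(read_id = read_id, label = label, stage = stage,
             best_hit_id = if (is.null(best)) NA_character_ else best$sseqid,
             evalue = if (is.null(best)) NA_real_ else best$evalue,
             identity = if (is.null(best)) NA_real_ else best$pident,
             stringsAsFactors = FALSE)
}

best_of <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  sort_hits(hits)[1, , drop = FALSE]
}

#' Stage 1: unique mapping to one species' contig set
#'
#' A read with at least one passing hit against one species' contigs and
#' none against the other is assigned to that species. Passing hits in both
#' sets make the read `ambiguous` (it does not proceed to later stages);
#' no passing hit leaves it `unclassified` and eligible for stage 2.
#'
#' @param read_id the read's id.
#' @param hits_a,hits_b hits of this read against the two contig sets.
#' @param params [mapping_params()] applied to both hit sets.
#' @param labels species labels for the two reference sets.
#' @return a one-row classification record.
#' @export
stage1_unique <- function(read_id, hits_a, hits_b,
                          params = mapping_params("ci_lenient"),
                          labels = c("species_a", "species_b")) {
  pa <- hits_a[passes_predicate(hits_a, params), , drop = FALSE]
  pb <- hits_b[passes_predicate(hits_b, params), , drop = FALSE]
  if (nrow(pa) > 0 && nrow(pb) == 0)
    class_record(read_id, labels[1], "1", best_of(pa))
  else if (nrow(pb) > 0 && nrow(pa) == 0)
    class_record(read_id, labels[2], "1", best_of(pb))
  else if (nrow(pa) > 0 && nrow(pb) > 0)
    class_record(read_id, "ambiguous", "1", best_of(rbind(pa, pb)))
  else
    class_record(read_id, "unclassified", "none")
}

#' Stage 2: same-genus unigene rescue
#'
#' Reads left unclassified by stage 1 are searched against unigene sets of
#' the same genus as the target species; any passing hit assigns the read
#' to that species. Only the species with genus-level references benefits
#' from this stage.
#'
#' @param read_id the read's id.
#' @param genus_hits hits of this read against the genus unigene sets.
#' @param params [mapping_params()] (default preset `genus`).
#' @param target_label species label assigned on success.
#' @return a one-row classification record.
#' @export
stage2_genus <- function(read_id, genus_hits,
                         params = mapping_params("genus"),
                         target_label = "species_a") {
  pg <- genus_hits[passes_predicate(genus_hits, params), , drop = FALSE]
  if (nrow(pg) > 0) class_record(read_id, target_label, "2", best_of(pg))
  else class_record(read_id, "unclassified", "none")
}

#' Stage 3: family-level top-k unanimity vote
#'
#' The top `min(top_k, n)` database hits (hits tied with the k-th by
#' (e-value, bitscore) included) are mapped to family tokens through the
#' taxonomy; if all belong to one family and that family carries a species
#' label, the read is assigned to it, otherwise it stays unclassified.
#'
#' @param read_id the read's id.
#' @param db_hits hits against the family-labelled database, sorted by
#'   (evalue asc, bitscore desc).
#' @param taxonomy a [taxonomy_map()].
#' @param top_k vote size (default 5).
#' @return a one-row classification record.
#' @export
stage3_family_vote <- function(read_id, db_hits, taxonomy, top_k = 5) {
  stopifnot(inherits(taxonomy, "taxonomy_map"))
  if (is.null(db_hits) || nrow(db_hits) == 0)
    return(class_record(read_id, "unclassified", "none"))
  db_hits <- sort_hits(db_hits)
  k <- min(top_k, nrow(db_hits))
  kth <- db_hits[k, ]
  tied <- db_hits$evalue == kth$evalue & db_hits$bitscore == kth$bitscore
  take <- seq_len(nrow(db_hits)) <= k | tied
  top <- db_hits[take, , drop = FALSE]
  unknown <- setdiff(top$sseqid, names(taxonomy$subject_family))
  if (length(unknown) > 0)
    stop("subject missing from taxonomy map: ", unknown[1])
  fams <- unique(unname(taxonomy$subject_family[top$sseqid]))
  if (length(fams) == 1 && fams %in% names(taxonomy$family_species))
    class_record(read_id, unname(taxonomy$family_species[fams]), "3",
                 best_of(top))
  else class_record(read_id, "unclassified", "none")
}

split_by_read <- function(hits) {
  if (nrow(hits) == 0) return(stats::setNames(vector("list", 0), character(0)))
  split(hits, factor(hits$qseqid, levels = unique(hits$qseqid)))
}

#' Run the three-stage stepwise classification cascade
#'
#' Every read receives exactly one label in `{species_a, species_b,
#' ambiguous, unclassified}`; stage outputs are disjoint and a read
#' labelled at one stage is never re-examined later. Stage 2 runs only when
#' `genus_refs` is non-empty, stage 3 only when `family_db` and `taxonomy`
#' are supplied. Per-stage counts are attached as attribute
#' `stage_counts`.
#'
#' @param reads read data.frame (`id`, `sequence`); ids must be unique.
#' @param refs_a,refs_b species-specific contig sets.
#' @param genus_refs optional genus-level unigene set (for the
#'   `genus_target_label` side).
#' @param family_db optional family-labelled database.
#' @param taxonomy [taxonomy_map()] for `family_db`.
#' @param config [cascade_config()].
#' @param labels species labels for `refs_a` and `refs_b`.
#' @return classification data.frame with columns `read_id`, `label`,
#'   `stage`, `best_hit_id`, `evalue`, `identity`, one row per input read,
#'   in input order.
#' @export
run_cascade <- function(reads, refs_a, refs_b, genus_refs = NULL,
                        family_db = NULL, taxonomy = NULL,
                        config = cascade_config(),
                        labels = c("species_a", "species_b")) {
  stopifnot(inherits(config, "cascade_config"))
  reads <- as_seqdf(reads)
  if (anyDuplicated(reads$id))
    stop("duplicate read id: ", reads$id[duplicated(reads$id)][1])

  # stage 1: unique mapping onto either species' contigs
  hits_a <- align_reads(reads, refs_a)
  hits_b <- align_reads(reads, refs_b)
  pa <- hits_a[passes_predicate(hits_a, config$params_stage1), , drop = FALSE]
  pb <- hits_b[passes_predicate(hits_b, config$params_stage1), , drop = FALSE]
  in_a <- reads$id %in% pa$qseqid
  in_b <- reads$id %in% pb$qseqid
  label <- rep("unclassified", nrow(reads))
  stage <- rep("none", nrow(reads))
  label[in_a & !in_b] <- labels[1]
  label[in_b & !in_a] <- labels[2]
  label[in_a & in_b] <- "ambiguous"
  stage[in_a | in_b] <- "1"
  best <- rep(list(NULL), nrow(reads))
  bests1 <- lapply(split_by_read(rbind(pa, pb)), best_of)
  idx <- match(names(bests1), reads$id)
  best[idx] <- bests1

  # stage 2: same-genus unigenes (asymmetric rescue)
  open <- which(label == "unclassified")
  n1 <- c(sum(label == labels[1]), sum(label == labels[2]),
          sum(label == "ambiguous"))
  if (length(open) > 0 && !is.null(genus_refs) &&
      nrow(as_seqdf(genus_refs)) > 0) {
    gh <- align_reads(reads[open, , drop = FALSE], genus_refs)
    pg <- gh[passes_predicate(gh, config$params_stage2), , drop = FALSE]
    hit2 <- open[reads$id[open] %in% pg$qseqid]
    label[hit2] <- config$genus_target_label
    stage[hit2] <- "2"
    bests2 <- lapply(split_by_read(pg), best_of)
    best[match(names(bests2), reads$id)] <- bests2
  }
  n2 <- sum(stage == "2")

  # stage 3: family-database unanimity vote
  open <- which(label == "unclassified")
  if (length(open) > 0 && !is.null(family_db) &&
      nrow(as_seqdf(family_db)) > 0) {
    if (is.null(taxonomy)) stop("family_db requires a taxonomy map")
    fh <- align_reads(reads[open, , drop = FALSE], family_db)
    fh <- fh[fh$evalue <= config$stage3_max_evalue, , drop = FALSE]
    recs <- lapply(split_by_read(fh), function(h)
      stage3_family_vote(h$qseqid[1], h, taxonomy, config$top_k))
    for (r in recs) {
      i <- match(r$read_id, reads$id)
      if (r$label != "unclassified") {
        label[i] <- r$label
        stage[i] <- r$stage
        best[[i]] <- data.frame(sseqid = r$best_hit_id, evalue = r$evalue,
                                pident = r$identity,
                                stringsAsFactors = FALSE)
      }
    }
  }
  n3 <- sum(stage == "3")

  out <- data.frame(
    read_id = reads$id, label = label, stage = stage,
    best_hit_id = vapply(best, function(b)
      if (is.null(b)) NA_character_ else b$sseqid, character(1)),
    evalue = vapply(best, function(b)
      if (is.null(b)) NA_real_ else b$evalue, numeric(1)),
    identity = vapply(best, function(b)
      if (is.null(b)) NA_real_ else b$pident, numeric(1)),
    stringsAsFactors = FALSE)
  attr(out, "stage_counts") <- c(
    stage1_a = n1[1], stage1_b = n1[2], stage1_ambiguous = n1[3],
    stage2 = n2, stage3 = n3,
    unclassified = sum(out$label == "unclassified"))
  out
}

#' Select read pairs with identical mate classification
#'
#' A pair is selected iff both mates carry the same species label; pairs
#' with an ambiguous, unclassified, or missing mate are rejected.
#'
#' @param table classification data.frame.
#' @param species_labels the two species labels.
#' @return character vector of selected read ids (both mates of every
#'   selected pair).
#' @export
reconcile_pairs <- function(table,
                            species_labels = c("species_a", "species_b")) {
  key <- pair_key(table$read_id)
  sel <- unlist(lapply(split(seq_len(nrow(table)), key), function(i) {
    if (length(i) != 2) return(integer(0))
    l <- table$label[i]
    if (l[1] == l[2] && l[1] %in% species_labels) i else integer(0)
  }), use.names = FALSE)
  table$read_id[sort(sel)]
}

#' Reference-based (subtraction) classification
#'
#' The single-reference alternative to the stepwise cascade: reads with a
#' passing hit against the host reference are assigned to the host; all
#' remaining reads are assumed to come from the parasite. The output is a
#' two-way partition with no ambiguous or unclassified reads, which is
#' precisely why host-parasite homologs are systematically misassigned to
#' the host by this approach.
#'
#' @param reads read data.frame.
#' @param host_reference host transcript set (non-empty).
#' @param params [mapping_params()] (default preset `ci_lenient`).
#' @param labels `c(parasite, host)` species labels.
#' @return classification data.frame (stage `"reference"` throughout).
#' @export
reference_based_classify <- function(reads, host_reference,
                                     params = mapping_params("ci_lenient"),
                                     labels = c("species_a", "species_b")) {
  reads <- as_seqdf(reads)
  host_reference <- as_seqdf(host_reference)
  if (nrow(host_reference) == 0) stop("host reference is empty")
  if (anyDuplicated(reads$id))
    stop("duplicate read id: ", reads$id[duplicated(reads$id)][1])
  hits <- align_reads(reads, host_reference)
  ph <- hits[passes_predicate(hits, params), , drop = FALSE]
  mapped <- reads$id %in% ph$qseqid
  bests <- lapply(split_by_read(ph), best_of)
  out <- data.frame(read_id = reads$id,
                    label = ifelse(mapped, labels[2], labels[1]),
                    stage = "reference", best_hit_id = NA_character_,
                    evalue = NA_real_, identity = NA_real_,
                    stringsAsFactors = FALSE)
  idx <- match(names(bests), reads$id)
  out$best_hit_id[idx] <- vapply(bests, function(b) b$sseqid, character(1))
  out$evalue[idx] <- vapply(bests, function(b) b$evalue, numeric(1))
  out$identity[idx] <- vapply(bests, function(b) b$pident, numeric(1))
  out
}
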