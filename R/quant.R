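#' Count reads per contig under separate or merged mapping
#'
#' Reads are aligned (internally, with the `expression` preset by default)
#' and each passing read contributes one count to exactly one contig, its
#' best hit; ties at the best score go to the lexicographically smallest
#' contig id.
#'
#' Under the `separate` regime, reads are mapped against their own
#' species' contig set only. Under the `merged` regime, reads are mapped
#' against the union of both sets and any read whose best hit lands on the
#' other species' contigs is excluded entirely from the table. When no
#' cross-species homology exists the two regimes coincide.
#'
#' @param reads read data.frame (reads already classified to the species
#'   that owns `refs_own`).
#' @param refs_own the species' own contig set.
#' @param refs_other the other species' contig set (required for
#'   `regime = "merged"`).
#' @param regime `"separate"` or `"merged"`.
#' @param params [mapping_params()] gate (default preset `expression`).
#' @return data.frame with columns `contig_id`, `length_bp`, `count`, one
#'   row per contig of `refs_own` (zero counts included), with attributes
#'   `total_mapped` (= sum of counts) and `n_excluded` (merged-regime
#'   exclusions).
#' @export
count_per_contig <- function(reads, refs_own, refs_other = NULL,
                             regime = c("separate", "merged"),
                             params = mapping_params("expression")) {
  regime <- match.arg(regime)
  reads <- as_seqdf(reads)
  refs_own <- as_seqdf(refs_own)
  if (regime == "merged") {
    if (is.null(refs_other)) stop("merged regime requires refs_other")
    refs_other <- as_seqdf(refs_other)
    targets <- rbind(refs_own[, c("id", "sequence")],
                     refs_other[, c("id", "sequence")])
  } else {
    targets <- refs_own
  }
  hits <- align_reads(reads, targets)
  hits <- hits[passes_predicate(hits, params), , drop = FALSE]
  counts <- stats::setNames(rep(0, nrow(refs_own)), refs_own$id)
  n_excluded <- 0L
  if (nrow(hits) > 0) {
    # best hit per read; sort_hits ties go to the smallest subject id
    best <- do.call(rbind, lapply(split_by_read(hits), function(h)
      h[1, c("qseqid", "sseqid")]))
    if (regime == "merged") {
      wrong <- best$sseqid %in% refs_other$id
      n_excluded <- sum(wrong)
      best <- best[!wrong, , drop = FALSE]
    }
    tab <- table(best$sseqid)
    counts[names(tab)] <- as.numeric(tab)
  }
  out <- data.frame(contig_id = refs_own$id,
                    length_bp = nchar(refs_own$sequence),
                    count = unname(counts), stringsAsFactors = FALSE)
  attr(out, "total_mapped") <- sum(out$count)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count * 1e9 / (contig_length_bp * total_mapped)`.
#'
#' @param count reads assigned to the contig.
#' @param contig_length_bp contig length in bp (>= 1).
#' @param total_mapped total reads counted in the library (>= 1).
#' @return numeric RPKM value(s).
#' @export
rpkm <- function(count, contig_length_bp, total_mapped) {
  if (any(contig_length_bp < 1)) stop("contig_length_bp must be >= 1")
  if (any(total_mapped < 1)) stop("total_mapped must be >= 1")
  stopifnot(all(count >= 0))
  count * 1e9 / (as.numeric(contig_length_bp) * as.numeric(total_mapped))
}

#' Expression table from a counts table
#'
#' @param counts a [count_per_contig()] table.
#' @param total_mapped total mapped reads (default: the table's
#'   `total_mapped` attribute).
#' @return data.frame with columns `contig_id`, `rpkm`.
#' @export
rpkm_table <- function(counts, total_mapped = NULL) {
  total_mapped <- total_mapped %||% attr(counts, "total_mapped")
  data.frame(contig_id = counts$contig_id,
             rpkm = rpkm(counts$count, counts$length_bp, total_mapped),
             stringsAsFactors = FALSE)
}
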