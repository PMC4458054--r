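#' Mapping-threshold presets
#'
#' A `mapping_params` object bundles the thresholds a hit must satisfy to
#' count as a mapping. The named presets reproduce the threshold sets used
#' throughout the stepwise-classification workflow:
#'
#' * `ci_lenient` — match length >= 90 bp, e-value <= 1e-20, <= 1 mismatch,
#'   <= 1 gap opening. Stage-1 preset for 101 bp libraries.
#' * `genus` — match length >= 90 bp, e-value <= 1e-20, identity >= 90%.
#'   Stage-2 preset (same-genus unigene search).
#' * `strict_exact` — match length equal to the full read length, no
#'   mismatches, no gaps.
#' * `cg_stage1` — as `ci_lenient` with match length >= 67 bp, for shorter
#'   (74 bp) libraries.
#' * `contaminant` — e-value <= 1e-5 only (rRNA/tRNA pre-filter).
#' * `expression` — match length >= 90 bp, <= 1 mismatch, <= 1 gap opening,
#'   no e-value gate (read counting for RPKM).
#'
#' Unset thresholds (`NA`) are ignored by [passes_predicate()]. The "gap"
#' threshold counts gap openings, not gapped columns.
#'
#' @param name preset name, or `"custom"` with explicit thresholds.
#' @param min_match_length minimum aligned length in bp (`NA` = no gate).
#' @param exact_length if `TRUE`, require the aligned length to equal the
#'   full read length.
#' @param max_mismatches maximum mismatch count.
#' @param max_gaps maximum number of gap openings.
#' @param max_evalue maximum e-value.
#' @param min_identity minimum percent identity.
#' @return an object of class `mapping_params`.
#' @export
mapping_params <- function(name = c("ci_lenient", "genus", "strict_exact",
                                    "cg_stage1", "contaminant", "expression",
                                    "custom"),
                           min_match_length = NA, exact_length = FALSE,
                           max_mismatches = NA, max_gaps = NA,
                           max_evalue = NA, min_identity = NA) {
  name <- match.arg(name)
  p <- switch(name,
    ci_lenient = list(min_match_length = 90, exact_length = FALSE,
                      max_mismatches = 1, max_gaps = 1,
                      max_evalue = 1e-20, min_identity = NA),
    genus = list(min_match_length = 90, exact_length = FALSE,
                 max_mismatches = NA, max_gaps = NA,
                 max_evalue = 1e-20, min_identity = 90),
    strict_exact = list(min_match_length = NA, exact_length = TRUE,
                        max_mismatches = 0, max_gaps = 0,
                        max_evalue = NA, min_identity = NA),
    cg_stage1 = list(min_match_length = 67, exact_length = FALSE,
                     max_mismatches = 1, max_gaps = 1,
                     max_evalue = 1e-20, min_identity = NA),
    contaminant = list(min_match_length = NA, exact_length = FALSE,
                       max_mismatches = NA, max_gaps = NA,
                       max_evalue = 1e-5, min_identity = NA),
    expression = list(min_match_length = 90, exact_length = FALSE,
                      max_mismatches = 1, max_gaps = 1,
                      max_evalue = NA, min_identity = NA),
    custom = list(min_match_length = min_match_length,
                  exact_length = exact_length,
                  max_mismatches = max_mismatches, max_gaps = max_gaps,
                  max_evalue = max_evalue, min_identity = min_identity))
  thr <- unlist(p[c("min_match_length", "max_mismatches", "max_gaps",
                    "max_evalue", "min_identity")])
  if (any(!is.na(thr) & thr < 0)) stop("thresholds must be non-negative")
  structure(c(list(name = name), p), class = "mapping_params")
}

#' @export
print.mapping_params <- function(x, ...) {
  cat("mapping_params <", x$name, ">\n", sep = "")
  for (f in setdiff(names(x), "name"))
    cat("  ", f, ": ", format(x[[f]]), "\n", sep = "")
  invisible(x)
}

# Bits per unit of raw alignment score. With match +1 this yields ~2 bits
# per matched base, so that the e-value gates (1e-20, 1e-5) are reachable
# by the match lengths they are meant to gate (a 90 bp perfect match scores
# ~180 bits; E ~ 1e-40 against a megabase database).
.BITS_PER_SCORE <- 2

#' Expectation value of an alignment score
#'
#' A simplified database-scaled e-value: `E = m * n * 2^(-bitscore)` with
#' `m` the query length and `n` the total database length. It is monotone
#' decreasing in the bitscore and linear in the database size, which is all
#' the hard e-value gates of the mapping presets require of it.
#'
#' @param bitscore normalized alignment score in bits.
#' @param query_len query length in bp.
#' @param database_len total database length in bp.
#' @return numeric e-value (>= 0).
#' @export
evalue_of <- function(bitscore, query_len, database_len) {
  stopifnot(all(is.finite(query_len) & query_len >= 1),
            all(is.finite(database_len) & database_len >= 1))
  as.numeric(query_len) * as.numeric(database_len) * 2^(-bitscore)
}

#' Align reads against a reference set
#'
#' A seed-and-extend local aligner: exact 11-mer seeding on both strands,
#' followed by a full affine-gap Smith-Waterman pass over the seed window
#' (scoring: match +1, mismatch -2, gap of length L costs 5 + 2L; N never
#' matches). One hit is reported per (read, subject, strand): the best local
#' alignment found, provided its raw score reaches `min_score`. Reads
#' shorter than the seed are reported unaligned. Subject coordinates are on
#' the forward subject; query coordinates are on the forward read; `strand`
#' records the orientation.
#'
#' @param reads data.frame with `id` and `sequence` columns (e.g. from
#'   [read_sequences()]), or a named character vector.
#' @param targets reference sequences, same accepted forms.
#' @param seed_len exact seed length (default 11).
#' @param min_score minimum raw score of a reported hit (default
#'   `seed_len`).
#' @param pad window padding around the seed diagonal, bp.
#' @return data.frame of hits with columns `qseqid`, `sseqid`, `strand`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `gapcols`, `qstart`,
#'   `qend`, `sstart`, `send`, `score`, `qlen`, `bitscore`, `evalue`,
#'   sorted by query then (evalue asc, bitscore desc, sseqid asc).
#' @export
align_reads <- function(reads, targets, seed_len = 11, min_score = seed_len,
                        pad = 30) {
  reads <- as_seqdf(reads)
  targets <- as_seqdf(targets)
  empty <- empty_hits()
  if (nrow(reads) == 0 || nrow(targets) == 0) return(empty)
  hits <- cpp_align_batch(reads$id, toupper(reads$sequence),
                          targets$id, toupper(targets$sequence),
                          as.integer(seed_len), as.integer(pad),
                          as.integer(pad), as.integer(min_score))
  if (nrow(hits) == 0) return(empty)
  dblen <- sum(nchar(targets$sequence))
  hits$bitscore <- .BITS_PER_SCORE * hits$score
  hits$evalue <- evalue_of(hits$bitscore, hits$qlen, dblen)
  sort_hits(hits)
}

# Canonical hit ordering: query, then e-value ascending, bitscore
# descending, subject id ascending (deterministic tie-break).
sort_hits <- function(hits) {
  o <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid,
             method = "radix")
  out <- hits[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             strand = character(0), pident = numeric(0), length = integer(0),
             mismatch = integer(0), gapopen = integer(0), gapcols = integer(0),
             qstart = integer(0), qend = integer(0), sstart = integer(0),
             send = integer(0), score = integer(0), qlen = integer(0),
             bitscore = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

as_seqdf <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    if (anyDuplicated(x$id))
      stop("duplicate sequence id: ", x$id[duplicated(x$id)][1])
    return(x)
  }
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequence vectors must be named")
    return(data.frame(id = names(x), sequence = unname(x),
                      stringsAsFactors = FALSE))
  }
  stop("unsupported sequence container: ", class(x)[1])
}

#' Test hits against a threshold preset
#'
#' Returns, for each hit, whether every configured threshold of `params` is
#' satisfied. Unset (`NA`) thresholds are ignored. Exact-length presets
#' compare the aligned length against the read length (taken from the
#' `qlen` column when present, else from `read_length`).
#'
#' @param hits hit data.frame as returned by [align_reads()] or
#'   [read_outfmt6()].
#' @param params a [mapping_params()] object.
#' @param read_length read length(s) for exact-length presets when `hits`
#'   lacks a `qlen` column (scalar or per-hit vector).
#' @return logical vector, one element per hit row.
#' @export
passes_predicate <- function(hits, params, read_length = NULL) {
  stopifnot(inherits(params, "mapping_params"))
  n <- nrow(hits)
  if (n == 0) return(logical(0))
  ok <- rep(TRUE, n)
  if (!is.na(params$min_match_length))
    ok <- ok & hits$length >= params$min_match_length
  if (isTRUE(params$exact_length)) {
    qlen <- hits$qlen %||% read_length
    if (is.null(qlen))
      stop("exact-length preset requires a qlen column or read_length")
    ok <- ok & hits$length == qlen
  }
  if (!is.na(params$max_mismatches))
    ok <- ok & hits$mismatch <= params$max_mismatches
  if (!is.na(params$max_gaps))
    ok <- ok & hits$gapopen <= params$max_gaps
  if (!is.na(params$max_evalue))
    ok <- ok & hits$evalue <= params$max_evalue
  if (!is.na(params$min_identity))
    ok <- ok & hits$pident >= params$min_identity
  ok
}

.outfmt6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                   "bitscore")

#' Read and write 12-column tabular alignments (BLAST outfmt 6)
#'
#' Externally produced alignments in the standard 12-column tabular format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`) can be substituted for the internal engine. On write,
#' minus-strand hits are emitted with `sstart > send` (the tabular
#' convention); on read, such rows are normalized back to ascending subject
#' coordinates with `strand = "-"`.
#'
#' @param hits hit data.frame.
#' @param path file path.
#' @return `read_outfmt6()` returns a hit data.frame (without `score`,
#'   `gapcols`, `qlen`, which only the internal engine provides).
#' @export
write_outfmt6 <- function(hits, path) {
  s1 <- ifelse(hits$strand == "-", hits$send, hits$sstart)
  s2 <- ifelse(hits$strand == "-", hits$sstart, hits$send)
  body <- paste(hits$qseqid, hits$sseqid, fmt_num(hits$pident), hits$length,
                hits$mismatch, hits$gapopen, hits$qstart, hits$qend,
                s1, s2, fmt_num(hits$evalue), fmt_num(hits$bitscore),
                sep = "\t")
  writeLines(body, path)
  invisible(path)
}

#' @rdname write_outfmt6
#' @export
read_outfmt6 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- empty_hits()
    return(out[setdiff(names(out), c("score", "gapcols", "qlen"))])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad) > 0)
    stop("malformed row at line ", bad[1], " of ", path,
         ": expected 12 columns, found ", nf[bad[1]])
  m <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(m) <- .outfmt6_cols
  for (col in c("pident", "evalue", "bitscore")) m[[col]] <- as.numeric(m[[col]])
  for (col in c("length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send")) m[[col]] <- as.integer(m[[col]])
  m$strand <- ifelse(m$sstart > m$send, "-", "+")
  flip <- m$strand == "-"
  tmp <- m$sstart[flip]
  m$sstart[flip] <- m$send[flip]
  m$send[flip] <- tmp
  sort_hits(m)
}
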