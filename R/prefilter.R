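#' Filter accounting report
#'
#' Bookkeeping for read-level pre-filters. `output_count` always equals
#' `input_count` minus the removals, so every input record is accounted for
#' exactly once. Counts are in units of the records the filter operates on
#' (reads for [contaminant_filter()], pairs for [pair_span_filter()] and
#' [polya_trim_min_len()]).
#'
#' @param input_count records presented to the filter.
#' @param removed_contaminant records removed by the contaminant filter.
#' @param removed_short_span pairs removed for short estimated span.
#' @param removed_short_read pairs removed because a mate fell below the
#'   minimum length after poly-A trimming.
#' @param trimmed_polya reads from which a poly-A/leading-T run was trimmed.
#' @return a list of class `filter_report`.
#' @export
filter_report <- function(input_count, removed_contaminant = 0,
                          removed_short_span = 0, removed_short_read = 0,
                          trimmed_polya = 0) {
  out <- list(input_count = input_count,
              removed_contaminant = removed_contaminant,
              removed_short_span = removed_short_span,
              removed_short_read = removed_short_read,
              trimmed_polya = trimmed_polya,
              output_count = input_count - removed_contaminant -
                removed_short_span - removed_short_read)
  stopifnot(out$output_count >= 0)
  class(out) <- "filter_report"
  out
}

#' Remove reads matching a contaminant database
#'
#' Reads with at least one alignment at e-value <= `max_evalue` against the
#' contaminant set (e.g. plant rRNA/tRNA sequences) are removed; surviving
#' reads keep their input order.
#'
#' @param reads read data.frame (`id`, `sequence`).
#' @param contaminant_db contaminant sequences (data.frame or named vector).
#' @param max_evalue removal threshold (default 1e-5).
#' @return list with `reads` (kept) and `report` ([filter_report]).
#' @export
contaminant_filter <- function(reads, contaminant_db, max_evalue = 1e-5) {
  reads <- as_seqdf(reads)
  contaminant_db <- as_seqdf(contaminant_db)
  if (nrow(contaminant_db) == 0) stop("contaminant database is empty")
  if (nrow(reads) == 0)
    return(list(reads = reads, report = filter_report(0)))
  hits <- align_reads(reads, contaminant_db)
  bad_ids <- unique(hits$qseqid[hits$evalue <= max_evalue])
  keep <- !(reads$id %in% bad_ids)
  list(reads = reads[keep, , drop = FALSE],
       report = filter_report(nrow(reads),
                              removed_contaminant = sum(!keep)))
}

#' Remove read pairs with short estimated fragment span
#'
#' The fragment span of a pair is estimated as `len(r1) + len(r2) -
#' overlap`, where `overlap` is the longest suffix-prefix match (at least
#' `min_overlap` bp, at most `max_mismatches` mismatches) between read 1 and
#' the reverse complement of read 2; pairs whose mates do not overlap get
#' span `len(r1) + len(r2)`. Pairs spanning less than `min_span` bp are
#' removed.
#'
#' @param pairs list with read data.frames `r1` and `r2`, row-aligned.
#' @param min_span minimum span in bp (default 175).
#' @param min_overlap minimum mate overlap considered (default 10 bp).
#' @param max_mismatches mismatches tolerated in the overlap (default 2).
#' @return list with `pairs` (kept, same structure) and `report`.
#' @export
pair_span_filter <- function(pairs, min_span = 175, min_overlap = 10,
                             max_mismatches = 2) {
  stopifnot(is.list(pairs), all(c("r1", "r2") %in% names(pairs)),
            nrow(pairs$r1) == nrow(pairs$r2))
  n <- nrow(pairs$r1)
  if (n == 0) return(list(pairs = pairs, report = filter_report(0)))
  s1 <- toupper(pairs$r1$sequence)
  s2rc <- rc(toupper(pairs$r2$sequence))
  ov <- vapply(seq_len(n), function(i) {
    cpp_overlap_len(s1[i], s2rc[i], as.integer(min_overlap),
                    as.integer(max_mismatches))
  }, integer(1))
  span <- nchar(s1) + nchar(pairs$r2$sequence) - ov
  keep <- span >= min_span
  list(pairs = list(r1 = pairs$r1[keep, , drop = FALSE],
                    r2 = pairs$r2[keep, , drop = FALSE]),
       report = filter_report(n, removed_short_span = sum(!keep)))
}

# Length of the maximal terminal A-run (3' end), allowing at most one non-A
# interruption; 0 when the qualifying run is shorter than min_run.
terminal_a_run <- function(seq, min_run = 10) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  run1 <- 0
  i <- n
  while (i >= 1 && chars[i] == "A") { run1 <- run1 + 1; i <- i - 1 }
  run2 <- 0
  if (i >= 2 && chars[i] != "A") { # one interruption allowed
    j <- i - 1
    while (j >= 1 && chars[j] == "A") { run2 <- run2 + 1; j <- j - 1 }
  }
  total <- if (run2 > 0) run1 + 1 + run2 else run1
  if (run2 > 0 && total >= min_run) total
  else if (run1 >= min_run) run1
  else 0L
}

# Kept region [start, end] of a sequence after poly-A trimming.
polya_bounds <- function(s, min_run = 10) {
  end <- nchar(s) - terminal_a_run(s, min_run)
  trimmed <- substr(s, 1, end)
  # leading T run = the poly-A tail seen on the opposite strand
  revc <- chartr("TA", "AT",
                 paste(rev(strsplit(trimmed, "", fixed = TRUE)[[1]]),
                       collapse = ""))
  start <- 1L + terminal_a_run(revc, min_run)
  c(start = as.integer(start), end = as.integer(end))
}

#' Trim poly-A tails from a read sequence
#'
#' Removes a maximal terminal run of A (3' end) and a maximal leading run
#' of T (5' end, the reverse-complemented tail) of at least `min_run` bases,
#' tolerating at most one interrupting non-A (non-T) base within the run.
#'
#' @param seq character vector of sequences.
#' @param min_run minimum run length to trigger trimming (default 10).
#' @return character vector of trimmed sequences.
#' @export
trim_polya <- function(seq, min_run = 10) {
  seq <- toupper(seq)
  vapply(seq, function(s) {
    b <- polya_bounds(s, min_run)
    substr(s, b["start"], b["end"])
  }, character(1), USE.NAMES = FALSE)
}

#' Poly-A trimming with minimum-length pair discard
#'
#' Trims poly-A tails ([trim_polya()]) from both mates, then discards pairs
#' in which one or both reads are shorter than `min_read_len` after
#' trimming. Qualities, when present, are clipped alongside the sequence.
#'
#' @param pairs list with read data.frames `r1` and `r2`, row-aligned.
#' @param min_read_len minimum surviving read length (default 75 bp).
#' @param min_run minimum poly-A run length (default 10).
#' @return list with `pairs` (trimmed and kept) and `report`.
#' @export
polya_trim_min_len <- function(pairs, min_read_len = 75, min_run = 10) {
  stopifnot(is.list(pairs), all(c("r1", "r2") %in% names(pairs)),
            nrow(pairs$r1) == nrow(pairs$r2))
  n <- nrow(pairs$r1)
  if (n == 0) return(list(pairs = pairs, report = filter_report(0)))
  trim_one <- function(df) {
    old <- toupper(df$sequence)
    bounds <- vapply(old, polya_bounds, c(start = 1L, end = 1L),
                     min_run = min_run, USE.NAMES = FALSE)
    df$sequence <- substr(old, bounds[1, ], bounds[2, ])
    if (!is.null(df$quality))
      df$quality <- substr(df$quality, bounds[1, ], bounds[2, ])
    df
  }
  r1 <- trim_one(pairs$r1)
  r2 <- trim_one(pairs$r2)
  trimmed <- sum(nchar(r1$sequence) < nchar(pairs$r1$sequence)) +
    sum(nchar(r2$sequence) < nchar(pairs$r2$sequence))
  keep <- nchar(r1$sequence) >= min_read_len &
    nchar(r2$sequence) >= min_read_len
  list(pairs = list(r1 = r1[keep, , drop = FALSE],
                    r2 = r2[keep, , drop = FALSE]),
       report = filter_report(n, removed_short_read = sum(!keep),
                              trimmed_polya = trimmed))
}
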