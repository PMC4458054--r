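#' Longest open reading frame of a contig
#'
#' Scans all six frames (+1, +2, +3, -1, -2, -3, in that tie-break order)
#' under the standard genetic code. The longest full-length ORF — an ATG
#' followed in frame by a stop codon (TAA/TAG/TGA), length counted
#' inclusive of the stop — is returned when one exists; otherwise the
#' longest open stretch bounded by stops and/or the sequence ends, with
#' `has_start`/`has_stop` flags set accordingly. Ties are broken by the
#' lowest frame index, then the smallest start. Coordinates are 1-based
#' inclusive on the contig's forward strand.
#'
#' @param sequence a single DNA sequence (character scalar).
#' @param min_len_bp minimum ORF length in bp; `NULL` is returned when the
#'   longest ORF is shorter (default 0).
#' @param id optional contig id carried into the result.
#' @return a one-row data.frame with columns `contig_id`, `frame`, `start`,
#'   `end`, `length_bp`, `has_start`, `has_stop`, `full_length`, or `NULL`.
#' @export
longest_orf <- function(sequence, min_len_bp = 0, id = NA_character_) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 3) stop("sequence must be at least 3 bp")
  frames <- list(`1` = sequence, `2` = sequence, `3` = sequence,
                 `-1` = rc(sequence), `-2` = rc(sequence),
                 `-3` = rc(sequence))
  offsets <- c(1, 2, 3, 1, 2, 3)
  stops <- c("TAA", "TAG", "TGA")
  best_full <- NULL
  best_open <- NULL
  for (fi in seq_along(frames)) {
    s <- frames[[fi]]
    off <- offsets[fi]
    nc <- (L - off + 1) %/% 3
    if (nc < 1) next
    starts_nt <- off + 3 * (seq_len(nc) - 1)
    codons <- substring(s, starts_nt, starts_nt + 2)
    is_stop <- codons %in% stops
    is_atg <- codons == "ATG"
    stop_idx <- which(is_stop)
    # full-length ORFs: first ATG after the previous stop, up to each stop
    prev <- 0
    for (si in stop_idx) {
      window <- which(is_atg[(prev + 1):si])
      if (length(window) > 0) {
        a <- prev + window[1]
        len <- (si - a + 1) * 3
        if (is.null(best_full) || len > best_full$len)
          best_full <- list(fi = fi, c1 = a, c2 = si, len = len,
                            has_start = TRUE, has_stop = TRUE)
      }
      prev <- si
    }
    # open stretches bounded by stops/ends (terminating stop included)
    bounds_lo <- c(1, stop_idx + 1)
    bounds_hi <- c(stop_idx, nc)
    keep <- bounds_lo <= bounds_hi
    for (k in which(keep)) {
      c1 <- bounds_lo[k]
      c2 <- bounds_hi[k]
      len <- (c2 - c1 + 1) * 3
      if (is.null(best_open) || len > best_open$len)
        best_open <- list(fi = fi, c1 = c1, c2 = c2, len = len,
                          has_start = is_atg[c1],
                          has_stop = is_stop[c2])
    }
  }
  pick <- best_full %||% best_open
  if (is.null(pick) || pick$len < min_len_bp) return(NULL)
  off <- offsets[pick$fi]
  nt1 <- off + 3 * (pick$c1 - 1)
  nt2 <- off + 3 * pick$c2 - 1
  if (pick$fi <= 3) {
    frame <- pick$fi
    start <- nt1
    end <- nt2
  } else {
    frame <- -(pick$fi - 3)
    start <- L - nt2 + 1
    end <- L - nt1 + 1
  }
  data.frame(contig_id = id, frame = frame, start = start, end = end,
             length_bp = pick$len, has_start = pick$has_start,
             has_stop = pick$has_stop,
             full_length = pick$has_start && pick$has_stop,
             stringsAsFactors = FALSE)
}

#' Annotate the longest ORF of every contig
#'
#' Applies [longest_orf()] to each contig; contigs whose longest ORF is
#' shorter than `min_len_bp` are dropped (the full-length-transcript
#' screen for assembled contig sets uses 200 bp).
#'
#' @param contigs contig data.frame (`id`, `sequence`).
#' @param min_len_bp minimum ORF length in bp (default 200).
#' @return data.frame of ORF annotations, one row per kept contig.
#' @export
annotate_orfs <- function(contigs, min_len_bp = 200) {
  contigs <- as_seqdf(contigs)
  rows <- lapply(seq_len(nrow(contigs)), function(i)
    longest_orf(contigs$sequence[i], min_len_bp, id = contigs$id[i]))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(contig_id = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      length_bp = integer(0), has_start = logical(0),
                      has_stop = logical(0), full_length = logical(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
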