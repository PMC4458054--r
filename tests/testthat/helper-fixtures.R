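# Shared fixture builders and independent oracles. Everything is generated
# in code under fixed seeds; no fixture files.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute k distinct positions with a different base
mutate_at_rate <- function(s, k) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# insert or delete 1-3 bases at a random interior position
random_indel <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  p <- sample(length(ch) - 4, 1) + 1
  if (runif(1) < 0.5) {
    ch <- ch[-(p:(p + sample(1:3, 1) - 1))]
  } else {
    ch <- append(ch, sample(c("A", "C", "G", "T"), sample(1:3, 1), TRUE),
                 after = p)
  }
  paste(ch, collapse = "")
}

# Independent local-alignment oracle: full (unbanded) Smith-Waterman via
# Biostrings dynamic programming, same scoring scheme as the engine.
.sw_submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                       mismatch = -2,
                                                       baseOnly = TRUE)
sw_oracle_score <- function(query, target) {
  max(
    Biostrings::score(Biostrings::pairwiseAlignment(
      query, target, type = "local", substitutionMatrix = .sw_submat,
      gapOpening = 5, gapExtension = 2)),
    Biostrings::score(Biostrings::pairwiseAlignment(
      rc(query), target, type = "local", substitutionMatrix = .sw_submat,
      gapOpening = 5, gapExtension = 2)))
}

# Brute-force six-frame ORF oracle: enumerate every frame and codon range.
orf_oracle <- function(sequence) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  stops <- c("TAA", "TAG", "TGA")
  best_full <- NULL
  best_open <- NULL
  frames <- c(rep(list(sequence), 3), rep(list(rc(sequence)), 3))
  for (fi in 1:6) {
    off <- c(1, 2, 3, 1, 2, 3)[fi]
    s <- frames[[fi]]
    nc <- (L - off + 1) %/% 3
    if (nc < 1) next
    codons <- substring(s, off + 3 * (0:(nc - 1)), off + 3 * (0:(nc - 1)) + 2)
    # full-length: every ATG, scan forward to the first stop
    for (a in which(codons == "ATG")) {
      rest <- which(codons[a:nc] %in% stops)
      if (length(rest) > 0) {
        len <- rest[1] * 3
        if (is.null(best_full) || len > best_full) best_full <- len
      }
    }
    # open stretches bounded by stops/ends (terminating stop included)
    is_stop <- codons %in% stops
    lo <- c(1, which(is_stop) + 1)
    hi <- c(which(is_stop), nc)
    for (k in seq_along(lo)) {
      if (lo[k] > hi[k]) next
      len <- (hi[k] - lo[k] + 1) * 3
      if (is.null(best_open) || len > best_open) best_open <- len
    }
  }
  list(full = best_full, open = best_open)
}

# Small two-species fixture: one shared gene (diverged copy), one private
# gene per species. Returns reference sets plus reads of known origin.
tiny_system <- function(seed = 11, gene_len = 600, ortho_identity = 85) {
  set.seed(seed)
  shared_a <- rand_dna(gene_len)
  shared_b <- mutate_at_rate(shared_a,
                             round(gene_len * (100 - ortho_identity) / 100))
  priv_a <- rand_dna(gene_len)
  priv_b <- rand_dna(gene_len)
  list(
    refs_a = data.frame(id = c("A_shared", "A_priv"),
                        sequence = c(shared_a, priv_a),
                        stringsAsFactors = FALSE),
    refs_b = data.frame(id = c("B_shared", "B_priv"),
                        sequence = c(shared_b, priv_b),
                        stringsAsFactors = FALSE))
}

# a hit row with the columns passes_predicate() consults
hit_row <- function(length, mismatch = 0, gapopen = 0, evalue = 1e-40,
                    pident = 100, qlen = 100, sseqid = "s1",
                    qseqid = "q1", bitscore = 2 * length) {
  data.frame(qseqid = qseqid, sseqid = sseqid, strand = "+",
             pident = pident, length = length, mismatch = mismatch,
             gapopen = gapopen, gapcols = 0, qstart = 1, qend = length,
             sstart = 1, send = length, score = length, qlen = qlen,
             bitscore = bitscore, evalue = evalue, stringsAsFactors = FALSE)
}
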