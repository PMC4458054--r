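#' Read sequences from FASTA or FASTQ
#'
#' Sequences are returned as a plain data frame, one row per record, with
#' sequences upper-cased. Record order is preserved. Duplicate ids are a
#' hard error.
#'
#' @param path path to an (uncompressed or gzipped) FASTA/FASTQ file.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (default: decide from the
#'   file extension, falling back to the first character of the file).
#' @return a data.frame with columns `id`, `description`, `sequence` and,
#'   for FASTQ input, `quality` (Sanger/Phred+33 strings).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("fq", "fastq")) "fastq" else
      if (ext %in% c("fa", "fasta", "fna", "ffn")) "fasta" else {
        first <- substr(readLines(path, n = 1L), 1, 1)
        if (identical(first, "@")) "fastq" else "fasta"
      }
  }
  if (format == "fasta") {
    set <- Biostrings::readDNAStringSet(path, format = "fasta")
    nm <- names(set)
    id <- sub("\\s.*$", "", nm)
    desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
    dup <- id[duplicated(id)]
    if (length(dup) > 0)
      stop("duplicate sequence id: ", dup[1])
    out <- data.frame(id = id, description = desc,
                      sequence = toupper(as.character(set)),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  # FASTQ: four-line records, validated explicitly so contract violations
  # are reported with their record number.
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: number of lines (", length(lines),
         ") is not a multiple of 4")
  n <- length(lines) %/% 4
  hdr <- lines[seq(1, by = 4, length.out = n)]
  seqs <- toupper(lines[seq(2, by = 4, length.out = n)])
  plus <- lines[seq(3, by = 4, length.out = n)]
  qual <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0)
    stop("malformed FASTQ record ", bad[1])
  mism <- which(nchar(seqs) != nchar(qual))
  if (length(mism) > 0)
    stop("FASTQ record ", mism[1],
         ": sequence and quality lengths differ (",
         nchar(seqs[mism[1]]), " vs ", nchar(qual[mism[1]]), ")")
  nm <- substring(hdr, 2)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  dup <- id[duplicated(id)]
  if (length(dup) > 0) stop("duplicate sequence id: ", dup[1])
  data.frame(id = id, description = desc, sequence = seqs, quality = qual,
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param records data.frame as returned by [read_sequences()]; for FASTQ a
#'   `quality` column is required (missing qualities default to "I").
#' @param path output path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  nm <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  if (format == "fasta") {
    out <- as.vector(rbind(paste0(">", nm), records$sequence))
  } else {
    qual <- records$quality %||% strrep("I", nchar(records$sequence))
    qual[is.na(qual)] <- strrep("I", nchar(records$sequence))[is.na(qual)]
    out <- as.vector(rbind(paste0("@", nm), records$sequence, "+", qual))
  }
  writeLines(out, path)
  invisible(path)
}

# Strict TSV reader: single header line with exactly the expected columns,
# every data row must have the same number of fields; violations name the
# offending line.
read_tsv_strict <- function(path, expected_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file: ", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, expected_cols))
    stop("unexpected header in ", path, ": ", lines[1])
  if (length(lines) == 1)
    return(stats::setNames(
      as.data.frame(matrix(character(0), 0, length(expected_cols)),
                    stringsAsFactors = FALSE), expected_cols))
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(expected_cols))
  if (length(bad) > 0)
    stop("malformed row at line ", bad[1] + 1L, " of ", path, ": expected ",
         length(expected_cols), " columns, found ", nf[bad[1]])
  out <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(out) <- expected_cols
  out
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

.classification_cols <- c("read_id", "label", "stage", "best_hit_id",
                          "evalue", "identity")

#' Read and write classification tables
#'
#' The on-disk format is a UTF-8 TSV with one header line and columns
#' `read_id`, `label`, `stage`, `best_hit_id`, `evalue`, `identity`.
#' Floats are serialized with 6 significant digits.
#'
#' @param table data.frame with the columns above (as produced by
#'   [run_cascade()] or [reference_based_classify()]).
#' @param path file path.
#' @return `read_classification()` returns the table; `write_classification()`
#'   returns `path` invisibly.
#' @export
write_classification <- function(table, path) {
  stopifnot(all(.classification_cols %in% names(table)))
  if (anyDuplicated(table$read_id))
    stop("duplicate read_id in classification table: ",
         table$read_id[duplicated(table$read_id)][1])
  body <- paste(table$read_id, table$label, table$stage,
                ifelse(is.na(table$best_hit_id), "NA", table$best_hit_id),
                fmt_num(table$evalue), fmt_num(table$identity), sep = "\t")
  writeLines(c(paste(.classification_cols, collapse = "\t"), body), path)
  invisible(path)
}

#' @rdname write_classification
#' @export
read_classification <- function(path) {
  out <- read_tsv_strict(path, .classification_cols)
  out$best_hit_id[out$best_hit_id == "NA"] <- NA_character_
  num <- function(x) as.numeric(replace(x, x == "NA", NA_character_))
  out$evalue <- num(out$evalue)
  out$identity <- num(out$identity)
  if (anyDuplicated(out$read_id))
    stop("duplicate read_id in classification table: ",
         out$read_id[duplicated(out$read_id)][1])
  out
}

.counts_cols <- c("contig_id", "length_bp", "count")

#' Read and write per-contig count tables
#'
#' TSV with columns `contig_id`, `length_bp`, `count`. The total number of
#' counted reads is carried as attribute `total_mapped` (recomputed as the
#' column sum when reading).
#'
#' @param table counts data.frame (see [count_per_contig()]).
#' @param path file path.
#' @export
write_counts <- function(table, path) {
  stopifnot(all(.counts_cols %in% names(table)))
  body <- paste(table$contig_id, table$length_bp, table$count, sep = "\t")
  writeLines(c(paste(.counts_cols, collapse = "\t"), body), path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  out <- read_tsv_strict(path, .counts_cols)
  out$length_bp <- as.integer(out$length_bp)
  out$count <- as.numeric(out$count)
  attr(out, "total_mapped") <- sum(out$count)
  out
}

#' Read and write flat metrics reports
#'
#' Metrics (confusion-matrix cells, rates, AUC, ...) are stored as a flat
#' JSON object mapping metric names to numbers.
#'
#' @param metrics named list (or named numeric vector) of scalars.
#' @param path file path.
#' @export
write_metrics <- function(metrics, path) {
  metrics <- as.list(metrics)
  stopifnot(length(metrics) == 0 || !is.null(names(metrics)))
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Derive the pair key of a read id
#'
#' Strips one trailing mate suffix: `/1` or `/2`, an underscore variant
#' `_1`/`_2`, or an Illumina-style ` 1...`/` 2...` comment. Reads whose ids
#' do not carry such a suffix keep their id as key.
#'
#' @param id character vector of read ids.
#' @return character vector of pair keys.
#' @export
pair_key <- function(id) {
  out <- sub(" [12](:.*)?$", "", id)
  sub("[/_][12]$", "", out)
}

#' Mate number of a read id
#'
#' @param id character vector of read ids.
#' @return integer vector: 1, 2, or NA when no mate suffix is present.
#' @export
mate_of <- function(id) {
  m <- regmatches(id, regexpr("([/_][12]$)|( [12](:.*)?$)", id))
  res <- rep(NA_integer_, length(id))
  has <- grepl("([/_][12]$)|( [12](:.*)?$)", id)
  res[has] <- as.integer(substr(sub("^[/_ ]", "",
    regmatches(id, regexpr("([/_][12]$)|( [12](:[^ ]*)?$)", id))), 1, 1))
  res
}
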