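#' Simulation configuration
#'
#' Describes a synthetic two-species system with the statistical structure
#' the classifier faces: two transcriptomes sharing orthologous genes at
#' tunable identity plus species-specific genes, a same-genus proxy
#' reference for the parasite side, a family-labelled database covering
#' both sides, and error-bearing reads mixed at a parasite-biased ratio
#' (the default 16.8:1 reflects the ~16.8-fold higher RNA yield per mg of
#' parasite tissue).
#'
#' @param seed master seed (mandatory; every output object consumes its own
#'   stream derived from it, so e.g. adding genes does not perturb reads).
#' @param n_genes_shared genes with an ortholog in both species.
#' @param n_genes_private_a,n_genes_private_b species-specific genes.
#' @param gene_length length range in bp, sampled uniformly (default
#'   300-3000).
#' @param ortholog_identity per-gene ortholog identity range in percent,
#'   sampled uniformly (default 75-95).
#' @param genus_divergence percent divergence of the genus-proxy reference
#'   from the parasite genes (default 5).
#' @param family_divergence percent divergence of family-database entries
#'   from the species' genes (default 10).
#' @param read_length read length in bp (default 100).
#' @param error_rate per-base substitution error rate (default 0.005).
#' @param paired emit read pairs (default FALSE).
#' @param fragment_mean,fragment_sd fragment-length sampler for paired
#'   reads (normal, default mean 300 sd 50).
#' @param mix_ratio expected parasite:host read ratio (default 16.8).
#' @param n_reads total reads to emit (default 10000).
#' @param labels species labels `c(parasite, host)`.
#' @param families family tokens for the database entries of the two
#'   species.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed, n_genes_shared = 60, n_genes_private_a = 20,
                       n_genes_private_b = 20, gene_length = c(300, 3000),
                       ortholog_identity = c(75, 95), genus_divergence = 5,
                       family_divergence = 10, read_length = 100,
                       error_rate = 0.005, paired = FALSE,
                       fragment_mean = 300, fragment_sd = 50,
                       mix_ratio = 16.8, n_reads = 10000,
                       labels = c("species_a", "species_b"),
                       families = c("family_a", "family_b")) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(all(ortholog_identity > 0), all(ortholog_identity <= 100),
            genus_divergence >= 0, family_divergence >= 0,
            error_rate >= 0, error_rate < 1, mix_ratio > 0,
            read_length >= 1, length(gene_length) == 2,
            gene_length[1] <= gene_length[2])
  structure(list(seed = as.integer(seed), n_genes_shared = n_genes_shared,
                 n_genes_private_a = n_genes_private_a,
                 n_genes_private_b = n_genes_private_b,
                 gene_length = gene_length,
                 ortholog_identity = ortholog_identity,
                 genus_divergence = genus_divergence,
                 family_divergence = family_divergence,
                 read_length = read_length, error_rate = error_rate,
                 paired = paired, fragment_mean = fragment_mean,
                 fragment_sd = fragment_sd, mix_ratio = mix_ratio,
                 n_reads = n_reads, labels = labels, families = families),
            class = "sim_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute k distinct positions with a different base; the realized
# global identity to the input is exactly 100 * (L - k) / L.
mutate_seq <- function(seq, k) {
  if (k == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

diverge_set <- function(seqs, percent) {
  vapply(seqs, function(s) {
    mutate_seq(s, round(nchar(s) * percent / 100))
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a pair of transcriptomes with shared orthologs
#'
#' Emits the full reference structure of the stepwise workflow: the two
#' species' contig sets, a genus-proxy unigene set (diverged copies of the
#' parasite genes), a family-labelled database (diverged copies of both
#' species' genes under two family tokens) with its [taxonomy_map()], and
#' a gene-level ground-truth table. Shared genes realize their sampled
#' target identity exactly up to rounding (substitutions at distinct
#' positions), hence within 2 percentage points. Deterministic given the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return list with `contigs_a`, `contigs_b`, `genus_refs`, `family_db`
#'   (sequence data.frames), `taxonomy`, and `genes` (gene_id, species,
#'   shared flag, target and realized ortholog identity).
#' @export
simulate_transcriptomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_sh <- config$n_genes_shared
  n_pa <- config$n_genes_private_a
  n_pb <- config$n_genes_private_b

  set.seed(derive_seed(config$seed, "genes"))
  len_sh <- sample(config$gene_length[1]:config$gene_length[2], n_sh,
                   replace = TRUE)
  len_pa <- sample(config$gene_length[1]:config$gene_length[2], n_pa,
                   replace = TRUE)
  len_pb <- sample(config$gene_length[1]:config$gene_length[2], n_pb,
                   replace = TRUE)
  sh_a <- vapply(len_sh, rand_dna, character(1))
  pa <- vapply(len_pa, rand_dna, character(1))
  pb <- vapply(len_pb, rand_dna, character(1))
  id_target <- if (n_sh > 0)
    runif(n_sh, config$ortholog_identity[1], config$ortholog_identity[2])
  else numeric(0)
  ksub <- round(len_sh * (100 - id_target) / 100)
  sh_b <- vapply(seq_len(n_sh), function(i) mutate_seq(sh_a[i], ksub[i]),
                 character(1))
  id_real <- if (n_sh > 0) 100 * (len_sh - ksub) / len_sh else numeric(0)

  prefix_ids <- function(prefix, ids)
    if (length(ids) > 0) paste0(prefix, ids) else character(0)
  ids_sh <- sprintf("gs%03d", seq_len(n_sh))
  ids_pa <- sprintf("ga%03d", seq_len(n_pa))
  ids_pb <- sprintf("gb%03d", seq_len(n_pb))
  contigs_a <- data.frame(id = c(prefix_ids("ctgA_", ids_sh),
                                 prefix_ids("ctgA_", ids_pa)),
                          sequence = c(sh_a, pa), stringsAsFactors = FALSE)
  contigs_b <- data.frame(id = c(prefix_ids("ctgB_", ids_sh),
                                 prefix_ids("ctgB_", ids_pb)),
                          sequence = c(sh_b, pb), stringsAsFactors = FALSE)

  set.seed(derive_seed(config$seed, "genus"))
  genus_refs <- data.frame(
    id = prefix_ids("genus_", c(ids_sh, ids_pa)),
    sequence = diverge_set(c(sh_a, pa), config$genus_divergence),
    stringsAsFactors = FALSE)

  set.seed(derive_seed(config$seed, "family"))
  fam_a <- data.frame(
    id = prefix_ids("famA_", c(ids_sh, ids_pa)),
    sequence = diverge_set(c(sh_a, pa), config$family_divergence),
    stringsAsFactors = FALSE)
  fam_b <- data.frame(
    id = prefix_ids("famB_", c(ids_sh, ids_pb)),
    sequence = diverge_set(c(sh_b, pb), config$family_divergence),
    stringsAsFactors = FALSE)
  family_db <- rbind(fam_a, fam_b)
  taxonomy <- taxonomy_map(
    stats::setNames(c(rep(config$families[1], nrow(fam_a)),
                      rep(config$families[2], nrow(fam_b))), family_db$id),
    stats::setNames(config$labels, config$families))

  genes <- data.frame(
    gene_id = c(ids_sh, ids_pa, ids_pb),
    species = c(rep("both", n_sh), rep(config$labels[1], n_pa),
                rep(config$labels[2], n_pb)),
    shared = c(rep(TRUE, n_sh), rep(FALSE, n_pa + n_pb)),
    identity_target = c(id_target, rep(NA_real_, n_pa + n_pb)),
    identity_realized = c(id_real, rep(NA_real_, n_pa + n_pb)),
    stringsAsFactors = FALSE)

  list(contigs_a = contigs_a, contigs_b = contigs_b,
       genus_refs = genus_refs, family_db = family_db,
       taxonomy = taxonomy, genes = genes, config = config)
}

apply_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  k <- rbinom(length(seq), nchar(seq), error_rate)
  need <- which(k > 0)
  for (i in need) seq[i] <- mutate_seq(seq[i], k[i])
  seq
}

#' Simulate ground-truth-labelled reads from a simulated transcriptome pair
#'
#' Reads are drawn uniformly along uniformly chosen genes of each species,
#' on both strands, with per-species counts following the configured
#' parasite:host mix ratio in expectation and i.i.d. substitution errors at
#' the configured rate. Every read carries its truth label. Deterministic
#' given the config seed.
#'
#' @param tx result of [simulate_transcriptomes()].
#' @param config a [sim_config()] (default: the one stored in `tx`).
#' @return for single-end configs, a list with `reads` (read data.frame
#'   with `truth_label` column) and `truth` (read_id, species, gene_id,
#'   position, strand); for paired configs additionally mate-split `r1`
#'   and `r2` data.frames.
#' @export
simulate_reads <- function(tx, config = tx$config) {
  stopifnot(inherits(config, "sim_config"))
  rl <- config$read_length
  src <- list(tx$contigs_a, tx$contigs_b)
  minlen <- min(nchar(src[[1]]$sequence), nchar(src[[2]]$sequence))
  if (rl > minlen)
    stop("read_length (", rl, ") exceeds the shortest gene (", minlen, ")")
  set.seed(derive_seed(config$seed, "reads"))
  n <- config$n_reads
  p_a <- config$mix_ratio / (1 + config$mix_ratio)
  species_idx <- ifelse(runif(n) < p_a, 1L, 2L)
  gene_row <- integer(n)
  for (s in 1:2) {
    w <- which(species_idx == s)
    gene_row[w] <- sample.int(nrow(src[[s]]), length(w), replace = TRUE)
  }
  gene_id <- ifelse(species_idx == 1, src[[1]]$id[gene_row],
                    src[[2]]$id[gene_row])
  gene_seq <- ifelse(species_idx == 1, src[[1]]$sequence[gene_row],
                     src[[2]]$sequence[gene_row])
  glen <- nchar(gene_seq)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  truth_label <- config$labels[species_idx]

  if (!config$paired) {
    pos <- 1L + floor(runif(n) * (glen - rl + 1))
    raw <- substr(gene_seq, pos, pos + rl - 1)
    raw[strand == "-"] <- rc(raw[strand == "-"])
    seqs <- apply_errors(raw, config$error_rate)
    ids <- sprintf("r%06d", seq_len(n))
    reads <- data.frame(id = ids, description = "", sequence = seqs,
                        quality = strrep("I", rl),
                        truth_label = truth_label, stringsAsFactors = FALSE)
    truth <- data.frame(read_id = ids, species = truth_label,
                        gene_id = gene_id, position = pos, strand = strand,
                        stringsAsFactors = FALSE)
    return(list(reads = reads, truth = truth))
  }

  # paired: fragment on the chosen strand, r1 from its 5' end, r2 the
  # reverse complement of its 3' end
  frag <- pmax(rl, pmin(glen,
    round(rnorm(n, config$fragment_mean, config$fragment_sd))))
  pos <- 1L + floor(runif(n) * (glen - frag + 1))
  frag_seq <- substr(gene_seq, pos, pos + frag - 1)
  frag_seq[strand == "-"] <- rc(frag_seq[strand == "-"])
  r1 <- substr(frag_seq, 1, rl)
  r2 <- rc(substr(frag_seq, frag - rl + 1, frag))
  r1 <- apply_errors(r1, config$error_rate)
  r2 <- apply_errors(r2, config$error_rate)
  key <- sprintf("r%06d", seq_len(n))
  mk <- function(seqs, mate) data.frame(
    id = paste0(key, "/", mate), description = "", sequence = seqs,
    quality = strrep("I", rl), truth_label = truth_label,
    stringsAsFactors = FALSE)
  truth <- data.frame(read_id = rep(key, 2),
                      species = rep(truth_label, 2),
                      gene_id = rep(gene_id, 2),
                      position = rep(pos, 2),
                      strand = rep(strand, 2), stringsAsFactors = FALSE)
  truth$read_id <- c(paste0(key, "/1"), paste0(key, "/2"))
  r1df <- mk(r1, 1)
  r2df <- mk(r2, 2)
  list(reads = rbind(r1df, r2df), r1 = r1df, r2 = r2df, truth = truth)
}
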