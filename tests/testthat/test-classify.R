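test_that("stage 1 assigns uniquely mapped reads and flags double hits", {
  sys <- tiny_system(seed = 11, ortho_identity = 85)
  read_a <- substr(sys$refs_a$sequence[2], 101, 200)  # private A gene
  read_b <- substr(sys$refs_b$sequence[2], 101, 200)  # private B gene
  reads <- data.frame(id = c("ra", "rb", "rnone"),
                      sequence = c(read_a, read_b, rand_dna(100)),
                      stringsAsFactors = FALSE)
  set.seed(99)
  cls <- run_cascade(reads, sys$refs_a, sys$refs_b)
  expect_equal(cls$label, c("species_a", "species_b", "unclassified"))
  expect_equal(cls$stage, c("1", "1", "none"))

  # identical gene copies in both sets -> passing hits on both -> ambiguous
  both <- rbind(sys$refs_a,
                data.frame(id = "A_dup", sequence = sys$refs_b$sequence[2]))
  cls2 <- run_cascade(reads[2, , drop = FALSE], both, sys$refs_b)
  expect_equal(cls2$label, "ambiguous")
  expect_equal(cls2$stage, "1")
})

test_that("per-read stage operations follow the cascade rules", {
  lenient <- mapping_params("ci_lenient")
  h_a <- rbind(hit_row(100, sseqid = "a1"), hit_row(95, sseqid = "a2"))
  none <- hit_row(100)[0, ]
  r <- stage1_unique("r1", h_a, none, lenient)
  expect_equal(r$label, "species_a")
  expect_equal(r$stage, "1")
  r <- stage1_unique("r1", h_a, hit_row(100, sseqid = "b1"), lenient)
  expect_equal(r$label, "ambiguous")
  r <- stage1_unique("r1", none, none, lenient)
  expect_equal(r$label, "unclassified")

  r <- stage2_genus("r1", hit_row(95, pident = 93, evalue = 1e-25))
  expect_equal(r$label, "species_a")
  expect_equal(r$stage, "2")
  r <- stage2_genus("r1", hit_row(95, pident = 85, evalue = 1e-25))
  expect_equal(r$label, "unclassified")
  r <- stage2_genus("r1", hit_row(95)[0, ])
  expect_equal(r$label, "unclassified")
})

test_that("the family vote requires unanimity of the top hits", {
  tax <- taxonomy_map(
    c(cv1 = "Convolvulaceae", cv2 = "Convolvulaceae", cv3 = "Convolvulaceae",
      cv4 = "Convolvulaceae", cv5 = "Convolvulaceae", cv6 = "Convolvulaceae",
      ba1 = "Balsaminaceae", ba2 = "Balsaminaceae", ba3 = "Balsaminaceae"),
    c(Convolvulaceae = "species_a", Balsaminaceae = "species_b"))
  mk <- function(ids, evalues) do.call(rbind, Map(function(s, e)
    hit_row(100, sseqid = s, evalue = e, bitscore = -log10(e)), ids, evalues))

  # five unanimous hits
  r <- stage3_family_vote("r1", mk(paste0("cv", 1:5), 10^-(50:46)), tax)
  expect_equal(r$label, "species_a")
  expect_equal(r$stage, "3")
  # 4 + 1 in the top five: no unanimity
  r <- stage3_family_vote("r1", mk(c(paste0("cv", 1:4), "ba1"),
                                   10^-(50:46)), tax)
  expect_equal(r$label, "unclassified")
  # fewer than five hits: unanimity of all available hits suffices
  r <- stage3_family_vote("r1", mk(paste0("ba", 1:3), 10^-(50:48)), tax)
  expect_equal(r$label, "species_b")
  # a tie at rank five pulls the tied hit into the vote
  hits <- mk(c(paste0("cv", 1:5), "ba1"),
             c(10^-(50:47), 1e-46, 1e-46))
  r <- stage3_family_vote("r1", hits, tax)
  expect_equal(r$label, "unclassified")
  # unknown subjects are a hard error naming the subject
  expect_error(stage3_family_vote("r1", mk("zz9", 1e-30), tax), "zz9")
})

test_that("cascade output is a partition and stages are disjoint", {
  cfg <- sim_config(seed = 101, n_genes_shared = 12, n_genes_private_a = 4,
                    n_genes_private_b = 4, gene_length = c(300, 800),
                    ortholog_identity = c(75, 90), n_reads = 800)
  tx <- simulate_transcriptomes(cfg)
  rd <- simulate_reads(tx, cfg)
  cls <- run_cascade(rd$reads[, c("id", "sequence")], tx$contigs_a,
                     tx$contigs_b, tx$genus_refs, tx$family_db, tx$taxonomy)
  expect_equal(nrow(cls), 800)
  expect_setequal(cls$read_id, rd$reads$id)
  tab <- table(factor(cls$label, c("species_a", "species_b", "ambiguous",
                                   "unclassified")))
  expect_equal(sum(tab), 800)
  # labelled reads always carry a deciding stage
  expect_true(all(cls$stage[cls$label %in%
                              c("species_a", "species_b")] != "none"))
  counts <- attr(cls, "stage_counts")
  expect_equal(unname(sum(counts)), 800)
})

test_that("reads matching only the genus proxy are rescued at stage 2", {
  set.seed(61)
  sys <- tiny_system(seed = 61)
  # a parasite gene absent from the stage-1 contigs, present (diverged 5%)
  # in the genus unigene set
  novel <- rand_dna(700)
  genus <- data.frame(id = "genus_novel",
                      sequence = mutate_at_rate(novel, 35),
                      stringsAsFactors = FALSE)
  reads <- data.frame(id = "r1", sequence = substr(novel, 201, 300),
                      stringsAsFactors = FALSE)
  cls <- run_cascade(reads, sys$refs_a, sys$refs_b, genus_refs = genus)
  expect_equal(cls$label, "species_a")
  expect_equal(cls$stage, "2")
})

test_that("identical inputs give byte-identical classification tables", {
  cfg <- sim_config(seed = 71, n_genes_shared = 8, n_genes_private_a = 3,
                    n_genes_private_b = 3, gene_length = c(300, 600),
                    n_reads = 300)
  tx <- simulate_transcriptomes(cfg)
  rd <- simulate_reads(tx, cfg)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  for (fp in c(f1, f2)) {
    cls <- run_cascade(rd$reads[, c("id", "sequence")], tx$contigs_a,
                       tx$contigs_b, tx$genus_refs, tx$family_db,
                       tx$taxonomy)
    write_classification(cls, fp)
  }
  expect_identical(readLines(f1), readLines(f2))
})

test_that("pair reconciliation keeps only pairs with identical labels", {
  tab <- data.frame(
    read_id = c("p1/1", "p1/2", "p2/1", "p2/2", "p3/1", "p3/2",
                "p4/1", "p4/2", "solo/1"),
    label = c("species_a", "species_a", "species_a", "species_b",
              "species_a", "unclassified", "species_b", "species_b",
              "species_a"),
    stage = "1", best_hit_id = NA, evalue = NA, identity = NA,
    stringsAsFactors = FALSE)
  sel <- reconcile_pairs(tab)
  expect_setequal(sel, c("p1/1", "p1/2", "p4/1", "p4/2"))
})

test_that("duplicate read ids abort the cascade", {
  sys <- tiny_system()
  reads <- data.frame(id = c("r1", "r1"),
                      sequence = rep(substr(sys$refs_a$sequence[1], 1, 100), 2),
                      stringsAsFactors = FALSE)
  expect_error(run_cascade(reads, sys$refs_a, sys$refs_b), "duplicate")
})

test_that("reference-based subtraction misassigns host-homologous reads", {
  set.seed(83)
  # host gene; the parasite ortholog differs only outside a conserved core
  host_gene <- rand_dna(600)
  core <- substr(host_gene, 201, 320)
  flanks_mut <- paste0(mutate_at_rate(substr(host_gene, 1, 200), 30),
                       core,
                       mutate_at_rate(substr(host_gene, 321, 600), 42))
  host_ref <- data.frame(id = "host1", sequence = host_gene,
                         stringsAsFactors = FALSE)
  # read from the conserved core of the PARASITE ortholog
  parasite_read <- substr(flanks_mut, 201, 300)
  # read from a parasite-only gene
  private_read <- substr(rand_dna(500), 101, 200)
  reads <- data.frame(id = c("homolog", "private"),
                      sequence = c(parasite_read, private_read),
                      stringsAsFactors = FALSE)
  cls <- reference_based_classify(reads, host_ref)
  expect_equal(cls$stage, c("reference", "reference"))
  # the homologous parasite read is swallowed by the host bin ...
  expect_equal(cls$label[cls$read_id == "homolog"], "species_b")
  # ... while unmapped reads fall through to the parasite bin
  expect_equal(cls$label[cls$read_id == "private"], "species_a")
  # and a host read maps home correctly
  cls2 <- reference_based_classify(
    data.frame(id = "h", sequence = substr(host_gene, 401, 500),
               stringsAsFactors = FALSE), host_ref)
  expect_equal(cls2$label, "species_b")
})

test_that("stepwise classification beats reference-based subtraction", {
  cfg <- sim_config(seed = 131, n_genes_shared = 15, n_genes_private_a = 5,
                    n_genes_private_b = 5, gene_length = c(300, 1000),
                    ortholog_identity = c(85, 95), n_reads = 1500,
                    mix_ratio = 4)
  tx <- simulate_transcriptomes(cfg)
  rd <- simulate_reads(tx, cfg)
  reads <- rd$reads[, c("id", "sequence")]
  truth <- stats::setNames(rd$truth$species, rd$truth$read_id)
  step <- run_cascade(reads, tx$contigs_a, tx$contigs_b, tx$genus_refs,
                      tx$family_db, tx$taxonomy)
  refb <- reference_based_classify(reads, tx$contigs_b)
  mis <- function(cls) {
    pred <- stats::setNames(cls$label, cls$read_id)
    sum(pred %in% c("species_a", "species_b") &
          pred != truth[names(pred)])
  }
  expect_lte(mis(step), mis(refb))
  expect_gt(mis(refb), 0)
})
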