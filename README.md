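# duosplit

Stepwise classification of mixed-species RNA-Seq reads.

## The problem

Tissue at the infection site of a parasitic plant — the region where the
haustorium grows into the host stem — cannot be dissected into pure
parasite and pure host material. RNA-Seq libraries made from it contain
reads from two species at once, typically two non-model plants without
reference genomes. Before parasite and host expression can be profiled
simultaneously, every read must be assigned to its source species, and
the error rate of that assignment must be measured. `duosplit` is for
researchers analysing such dual-species (host–parasite, graft,
xenograft-style) bulk RNA-Seq data without reference genomes.

## The method

Reads are classified by a three-stage cascade of local-alignment
searches, each stage consuming only the reads the previous one left
unclassified:

1. **Species contigs** — map against contig sets assembled from
   single-species ("not-in-contact") samples of either plant; a read
   uniquely mapped (match ≥ 90 bp, e ≤ 1e-20, ≤ 1 mismatch, ≤ 1 gap) to
   one species' set is assigned to that species.
2. **Same-genus unigenes** — map the remainder against congeneric
   unigene sets (match ≥ 90 bp, e ≤ 1e-20, identity ≥ 90%); hits assign
   the read to the species with genus-level resources (the parasite).
3. **Family vote** — the top 5 hits in a family-labelled database must
   unanimously belong to one family for the read to be assigned.

Assignment quality is estimated by competitive mapping of single-species
reads against the union of both reference sets. With the parasite
library positive, TPR = TP/(TP+FN), FPR = FP/(FP+TN), and the AUC of the
hard binary assignment is the trapezoid through the operating point:

    AUC = (1 + TPR − FPR) / 2

Per-contig counts (separate or merged mapping regime, with cross-species
exclusion) and RPKM = count·10⁹/(length·total) quantify expression from
the classified reads; a six-frame ORF scan grades contigs for
full-length transcripts; and a ground-truth simulator generates complete
synthetic two-species systems so that every stage is testable without
external downloads.

## Worked example

Simulate a parasite–host mixture (16.8:1 read ratio, orthologs at 75–90%
identity, 0.5% sequencing error), classify it, and assess the result
against the simulator's ground truth:

```r
library(duosplit)

cfg <- sim_config(seed = 7, n_reads = 4000, ortholog_identity = c(75, 90))
tx  <- simulate_transcriptomes(cfg)
rd  <- simulate_reads(tx, cfg)

cls <- run_cascade(rd$reads[, c("id", "sequence")],
                   tx$contigs_a, tx$contigs_b,
                   tx$genus_refs, tx$family_db, tx$taxonomy)
attr(cls, "stage_counts")
#>         stage1_a         stage1_b stage1_ambiguous           stage2
#>             3475              205                0              281
#>           stage3     unclassified
#>               27               12

assess_report(setNames(rd$truth$species, rd$truth$read_id),
              cls, positive_label = "species_a")
#> confusion_matrix (positive = species_a )
#>   tp 3,770  fn 0
#>   fp 0  tn 218
#>   misclassification: a 0%  b 0%
#>   mapped fraction:   a 99.81%  b 97.76%
#>   AUC 1.000  (excluded reads: 12)
```

Most reads are settled at stage 1 against the species contigs; reads
carrying two or more sequencing errors fail the 1-mismatch gate and are
rescued by the genus (stage 2, parasite only) and family-vote (stage 3)
searches. The assessment compares predicted labels with the simulator's
truth: no read ended up on the wrong species, 12 stayed unclassified, and
the single-point AUC is 1.000.

The same metric machinery reproduces worked examples from published
read-assignment contingency tables:

```r
cm <- confusion_matrix(tp = 73819654, fn = 442526,
                       fp = 271929, tn = 71471262)
round(auc_single_point(cm), 3)
#> [1] 0.995
round(misclassification_rate(442526, 114056994), 2)
#> [1] 0.39
```

A thin command-line wrapper with `simulate`, `prefilter`, `classify`,
`assess`, `quantify`, `annotate` and `run` subcommands is installed at
`inst/cli/duosplit.R` (run it with `Rscript`).

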