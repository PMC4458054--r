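---
title: "Stepwise classification of mixed-species RNA-Seq reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise classification of mixed-species RNA-Seq reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duosplit)
```

## The problem

When a parasitic plant inserts its haustorium into a host stem, the
interface tissue cannot be dissected into pure parasite and pure host
material: every RNA-Seq library made from it is a mixture of reads from two
species, often both without a reference genome. Before any expression
analysis can be trusted, each read must be assigned to its source species,
and the error of that assignment must be measured. `duosplit` implements a
reference-free solution built entirely from local-alignment searches
against progressively broader reference sets, together with the
competitive-mapping framework used to quantify how often reads end up on
the wrong side.

## The classification cascade

`run_cascade()` assigns each read one of four labels — the two species,
`ambiguous`, or `unclassified` — in three sequential stages. Each stage
consumes only the reads the previous stage left unclassified, so stage
outputs are disjoint and the four label counts always sum to the input
count.

1. **Species contigs.** Reads are mapped against contig sets assembled from
   single-species ("not-in-contact") samples of each plant. A read with at
   least one passing hit on one set and none on the other is assigned to
   that species. The default gate (`ci_lenient`) requires a match of at
   least 90 bp at e-value ≤ 1e-20 with at most 1 mismatch and 1 gap
   opening; for shorter 74 bp libraries the `cg_stage1` preset lowers the
   length gate to 67 bp.
2. **Same-genus unigenes.** Unclassified reads are searched against
   unigene sets from congeneric species. This stage is asymmetric: in the
   motivating design only the parasite has usable genus-level resources,
   so any passing hit (≥ 90 bp, e-value ≤ 1e-20, identity ≥ 90%) assigns
   the read to the parasite. The identity gate replaces the mismatch cap
   because genus-level references are expected to diverge by several
   percent from the sequenced species.
3. **Family-level vote.** Remaining reads are searched against a database
   whose entries carry family labels. The top five hits (ties with the
   fifth included) must all belong to one family; if that family maps to
   one of the two species, the read is assigned accordingly, otherwise it
   stays unclassified.

For paired libraries, `reconcile_pairs()` then keeps exactly the pairs
whose two mates received the same species label.

The package also implements the obvious alternative,
`reference_based_classify()`: map everything against the single available
(host) reference and call every unmapped read "parasite". Its failure mode
is structural — any parasite read from a gene conserved between the two
species maps to the host reference and is silently absorbed into the host
bin — and the test suite demonstrates on simulated mixtures that the
cascade misassigns no more reads than subtraction does.

### Decisions where the procedure is underdetermined

Several corner cases are not fixed by the verbal description of the
method; the package resolves them as follows, and treats each choice as
configuration:

* Reads whose stage-1 hits pass the gate in **both** species' contig sets
  are labelled `ambiguous` and are *not* forwarded to stage 2: the later
  stages are defined for reads that could not be mapped, not for reads
  mapped too well. Their count is reported in the `stage_counts`
  attribute.
* "Uniquely mapped" is interpreted across species sets (≥ 1 passing hit
  in one set, 0 in the other). Multi-mapping within one species is
  allowed — transcript sets assembled de novo contain many near-duplicate
  contigs, and demanding single-locus hits would discard most reads.
* At stage 3, when fewer than five hits exist, unanimity of all available
  hits (at least one) is required; hits tied with the fifth by
  (e-value, bitscore) join the vote.
* Pair reconciliation is strict: (species, unclassified) pairs are
  rejected, not rescued by the labelled mate.
* Read ids must be unique; a duplicate is a hard error rather than a
  silent overwrite.

## The alignment engine

Searches are performed by an internal seed-and-extend aligner
(`align_reads()`): exact 11-mer seeding on both strands, seeds clustered
by diagonal, and a full affine-gap Smith–Waterman pass (Gotoh) over a band
covering the seed diagonals plus an 8-column margin. Within that band the
dynamic program is exact, so for seeded alignments the reported statistics
equal those of an unrestricted optimal local alignment of the read against
the reported subject interval — a property the test suite checks against
an independent full-DP oracle on a thousand random instances. Reads
shorter than the seed, or sharing no 11-mer with any target, are reported
unaligned.

Numerical choices, all fixed in one place and documented here because no
external search tool is involved:

* Scoring: match +1, mismatch −2, a gap of length L costs 5 + 2L. `N`
  never matches anything.
* Bit score = 2 × raw score, i.e. roughly two bits per matched base,
  comparable to a nucleotide search with this match/mismatch ratio. With
  this scaling a 90 bp perfect match scores 180 bits and clears the
  1e-20 e-value gate against megabase-scale databases, which is exactly
  the regime the presets are designed for.
* E-value: the simplified database-scaled form
  `E = m · n · 2^(−bitscore)` (`evalue_of()`), with m the read length and
  n the total reference length. The thresholds in the workflow (1e-20,
  1e-5) act as hard gates, so an order-consistent surrogate is
  sufficient; fitted Karlin–Altschul parameters would change no decision
  the package makes. All e-value gates are inclusive (≤).
* The "gap" threshold of a preset counts gap *openings*, the tabular
  alignment convention.
* Hits are ordered by (e-value ascending, bitscore descending, subject id
  ascending); the lexicographic final key makes every downstream
  tie-break deterministic.

Externally produced alignments in the standard 12-column tabular format
can be substituted for the engine via `read_outfmt6()`; because word
size, scoring and e-value parameterization of external tools differ, the
package reproduces the *contract* of such searches, not their bit-exact
output.

## Quality assessment

`competitive_map()` maps reads of known origin against the union of both
species' references and assigns each read by the better hit, comparing
e-value first, then identity, then bitscore (the two quantities are
reported together by the underlying searches; e-value is compared first
because every preset gates on it). Reads equal on all three are
`ambiguous` and excluded from the confusion matrix (their count is
reported alongside), mirroring tables that report only correctly-mapped
and cross-mapped reads.

With the parasite library positive: TPR = TP/(TP+FN), FPR = FP/(FP+TN),
and the area under the ROC curve of a hard binary assignment is the
trapezoid through the single operating point,

AUC = (1 + TPR − FPR) / 2,

implemented in `auc_single_point()`. `auc_from_scores()` integrates the
full threshold sweep of a continuous margin score and reduces exactly to
the single-point formula for hard ±1 margins; both routes are compared in
the tests, and the sweep version is additionally cross-checked against an
independent ROC implementation (pROC). Per-library misclassification
rates and mapped fractions are expressed as percent of the library's
*total* read count, including unmapped reads.

## Quantification

`count_per_contig()` counts each passing read (preset `expression`:
≥ 90 bp, ≤ 1 mismatch, ≤ 1 gap opening, no e-value gate) once, at its
best hit; ties go to the lexicographically smallest contig id. Two
regimes reproduce the two mapping designs used around the cascade:
`separate` maps a species' reads only against its own contigs, `merged`
maps against the union and *excludes* any read whose best hit lands on
the other species' contigs. As cross-species homology vanishes the two
tables converge — the robustness property behind using either design
interchangeably. `rpkm()` computes
`count × 10^9 / (length_bp × total_mapped)`. Multi-mapped reads within a
species are counted once at the best hit; fractional allocation was
deliberately left out because every downstream consumer in this workflow
(count-based DE tools) expects integer counts.

## Pre-filters

`contaminant_filter()` drops reads matching an rRNA/tRNA set at e-value
≤ 1e-5. `pair_span_filter()` removes pairs spanning less than 175 bp —
"span" is interpreted as the estimated fragment length
`len(r1) + len(r2) − overlap`, with the overlap the longest suffix-prefix
match (≥ 10 bp, ≤ 2 mismatches) between read 1 and the reverse complement
of read 2; the 175 bp default equals the assembler insert size used with
these libraries. Summed aligned length was the other defensible reading
of "span"; the fragment-length interpretation was chosen because the
threshold value is an insert length. `polya_trim_min_len()` clips
terminal poly-A (and leading poly-T) runs of at least 10 bases, tolerating
one interrupting base, and discards pairs with a mate shorter than 75 bp
afterwards; run length and interruption tolerance are package choices, as
poly-A trimmers differ and no parameters were specified for this step.
Every filter returns a `filter_report` whose removals reconcile exactly
with the input count, and all filters are idempotent.

## ORF annotation

`longest_orf()` scans all six frames under the standard genetic code and
prefers the longest full-length ORF (ATG … stop, length counted inclusive
of the stop codon); only when no frame contains one does it fall back to
the longest open stretch bounded by stops or sequence ends. Alternative
start codons are not considered — a documented simplification relative to
dedicated ORF predictors, sufficient for the full-length flag and the
200 bp length filter used to grade contig sets.

## The simulator

`simulate_transcriptomes()` and `simulate_reads()` generate the complete
study structure with ground truth: two transcriptomes sharing orthologs,
a genus-proxy reference, a family-labelled database, and labelled reads.
Divergence is applied as substitutions at distinct random positions, so a
gene pair's realized identity equals its target exactly up to rounding —
a deliberate restriction that keeps the ground-truth identity
interpretable; gapped alignment is exercised separately in the aligner
tests through explicit indel fixtures. Defaults, chosen once as the
conditions the method is meant to face:

| parameter | default | rationale |
|---|---|---|
| genes (shared / private per species) | 60 / 20 / 20 | enough genes that reads multi-map realistically, small enough for desk-scale runs |
| gene length | 300–3000 bp | typical assembled-transcript range |
| ortholog identity | uniform 75–95% | the coding-sequence identity band where cross-mapping is a real risk |
| genus divergence | 5% | congeneric transcript divergence |
| family divergence | 10% | confamilial divergence, distinct from the genus level |
| read length | 100 bp | HiSeq 101 bp libraries |
| substitution error | 0.5% | typical raw Illumina error |
| parasite:host mix | 16.8 : 1 | measured ~16.8-fold higher RNA yield per mg of parasite tissue |
| reads | 10,000 | desk-scale while keeping binomial noise on 1%-level rates small |

Each output object draws from its own random stream derived from the
master seed, so changing the number of genes does not perturb the reads.

What the simulator does **not** emulate: realistic expression-level
distributions (genes are sampled uniformly), quality-score-dependent
error profiles, indel sequencing errors, splice variants, assembly
artifacts (chimeric or fragmented contigs), and incomplete reference
sets other than by explicit configuration. Passing the recovery tests
therefore shows that the cascade's logic and thresholds behave correctly
under controlled homology and error — not that real libraries will reach
the same rates; on real data, reference completeness and assembly quality
dominate.

The end-to-end tests run the cascade on a default-condition simulation
(10,000 reads, ortholog identity capped at 90%, fixed seed) and assert
that at least 95% of reads are labelled, that under 1% of reads are
misclassified, and that the truth-vs-label AUC exceeds 0.99; the same
suite verifies the dose–response expectation that misclassification does
not decrease as ortholog identity rises.

## Known limitations

* The e-value surrogate is order-consistent but not calibrated; absolute
  e-values are not comparable to those of external search tools, only the
  pass/fail decisions at the preset gates are meaningful.
* The banded refinement can miss alignments whose optimal path drifts
  more than the band margin away from every seed diagonal; for read-scale
  queries with ≤ 3 bp indels this does not occur in practice (and is
  checked against the full-DP oracle in the tests).
* Stage 3 is only as good as the taxonomy labelling of the database; a
  subject missing from the taxonomy is a hard error by design.
* AUC is reported for the binary two-species problem; multi-species
  mixtures are out of scope.
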