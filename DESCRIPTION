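Package: duosplit
Title: Stepwise Classification of Mixed-Species RNA-Seq Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference-free deconvolution of bulk RNA-Seq reads sequenced
    from tissue where two plant species are physically intermingled, such as
    the haustorial interface between a parasitic plant and its host. Reads
    are assigned to their source species by a three-stage cascade of local
    alignment searches (species-specific contigs, same-genus unigene sets,
    then a family-labelled database vote), with an accompanying
    competitive-mapping framework that estimates misclassification rates and
    ROC AUC, RPKM quantification under separate and merged mapping regimes,
    minimal six-frame ORF annotation, and a ground-truth-labelled simulator
    of mixed two-species transcriptome read sets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    withr,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
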