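test_that("an exact substring yields a perfect forward hit", {
  set.seed(5)
  t <- rand_dna(1200)
  q <- substr(t, 301, 400)
  h <- align_reads(c(read1 = q), c(ctg1 = t))
  expect_equal(nrow(h), 1)
  expect_equal(h$pident, 100)
  expect_equal(h$length, 100L)
  expect_equal(h$mismatch, 0L)
  expect_equal(h$gapopen, 0L)
  expect_equal(h$strand, "+")
  expect_equal(c(h$sstart, h$send), c(301L, 400L))
})

test_that("the reverse complement of a query gives the strand-flipped hit", {
  set.seed(5)
  t <- rand_dna(1200)
  q <- substr(t, 301, 400)
  h_fwd <- align_reads(c(r = q), c(ctg1 = t))
  h_rev <- align_reads(c(r = rc(q)), c(ctg1 = t))
  expect_equal(h_rev$strand, "-")
  for (col in c("pident", "length", "mismatch", "gapopen", "sstart",
                "send", "score"))
    expect_equal(h_rev[[col]], h_fwd[[col]])
})

test_that("queries sharing no seed with any target are unaligned", {
  h <- align_reads(c(r = strrep("A", 100)), c(t1 = strrep("G", 1000)))
  expect_equal(nrow(h), 0)
  # reads shorter than the seed are reported unaligned, not an error
  h2 <- align_reads(c(r = "ACGTACGT"), c(t1 = strrep("ACGT", 100)))
  expect_equal(nrow(h2), 0)
  # empty target set
  h3 <- align_reads(c(r = strrep("ACGT", 30)),
                    data.frame(id = character(0), sequence = character(0)))
  expect_equal(nrow(h3), 0)
})

test_that("e-values follow the database-scaled formula", {
  expect_equal(evalue_of(20, 100, 1000), 100 * 1000 * 2^-20)
  expect_lt(abs(evalue_of(20, 100, 1000) - 0.09537), 1e-4)
  # monotone decreasing in bitscore, linear in database length
  expect_true(all(diff(evalue_of(seq(10, 100, 10), 100, 1e6)) < 0))
  expect_equal(evalue_of(30, 100, 2e6), 2 * evalue_of(30, 100, 1e6))
  expect_equal(evalue_of(Inf, 100, 1e6), 0)
})

test_that("threshold presets gate hits as configured", {
  lenient <- mapping_params("ci_lenient")
  expect_true(passes_predicate(hit_row(95, mismatch = 1, evalue = 1e-30),
                               lenient))
  expect_false(passes_predicate(hit_row(89, mismatch = 0, evalue = 1e-40),
                                lenient))
  expect_false(passes_predicate(hit_row(95, mismatch = 2, evalue = 1e-30),
                                lenient))
  expect_false(passes_predicate(hit_row(95, mismatch = 0, evalue = 1e-10),
                                lenient))

  strict <- mapping_params("strict_exact")
  expect_true(passes_predicate(hit_row(100, mismatch = 0, qlen = 100),
                               strict))
  expect_false(passes_predicate(hit_row(100, mismatch = 1, qlen = 100),
                                strict))
  expect_false(passes_predicate(hit_row(99, mismatch = 0, qlen = 100),
                                strict))

  genus <- mapping_params("genus")
  expect_true(passes_predicate(hit_row(95, pident = 93, evalue = 1e-25),
                               genus))
  expect_false(passes_predicate(hit_row(95, pident = 85, evalue = 1e-25),
                                genus))

  expect_true(passes_predicate(hit_row(40, evalue = 1e-6),
                               mapping_params("contaminant")))
  expect_true(passes_predicate(hit_row(95, mismatch = 1, evalue = 1),
                               mapping_params("expression")))
})

test_that("strict_exact passes imply ci_lenient passes (stringency)", {
  set.seed(17)
  targets <- data.frame(id = paste0("t", 1:4),
                        sequence = vapply(rep(1500, 4), rand_dna,
                                          character(1)),
                        stringsAsFactors = FALSE)
  reads <- do.call(rbind, lapply(1:60, function(i) {
    src <- sample(4, 1)
    st <- sample(1400, 1)
    q <- substr(targets$sequence[src], st, st + 99)
    k <- sample(0:2, 1)
    if (k > 0) q <- mutate_at_rate(q, k)
    data.frame(id = paste0("r", i), sequence = q, stringsAsFactors = FALSE)
  }))
  hits <- align_reads(reads, targets)
  strict <- passes_predicate(hits, mapping_params("strict_exact"))
  lenient <- passes_predicate(hits, mapping_params("ci_lenient"))
  expect_gt(sum(strict), 0)
  expect_true(all(lenient[strict]))
})

test_that("engine statistics match the full DP oracle on random instances", {
  set.seed(23)
  for (i in 1:60) {
    tlen <- sample(400:2000, 1)
    t <- rand_dna(tlen)
    ql <- sample(60:200, 1)
    st <- sample(tlen - ql, 1)
    q <- mutate_at_rate(substr(t, st, st + ql - 1), rbinom(1, ql, 0.04))
    if (runif(1) < 0.3) q <- random_indel(q)
    if (runif(1) < 0.5) q <- rc(q)
    h <- align_reads(c(r = q), c(t1 = t))
    eng <- if (nrow(h) > 0) max(h$score) else 0
    expect_equal(eng, sw_oracle_score(q, t))
    if (nrow(h) > 0) {
      b <- h[which.max(h$score), ]
      # reported statistics are internally consistent with the score
      matches <- b$length - b$mismatch - b$gapcols
      expect_equal(b$score,
                   matches - 2 * b$mismatch - 5 * b$gapopen - 2 * b$gapcols)
      expect_equal(b$pident, 100 * matches / b$length)
    }
  }
})

test_that("hit ordering is deterministic with lexicographic tie-break", {
  set.seed(9)
  g <- rand_dna(500)
  targets <- data.frame(id = c("zeta", "alpha"), sequence = c(g, g),
                        stringsAsFactors = FALSE)
  h <- align_reads(c(r = substr(g, 101, 200)), targets)
  expect_equal(h$sseqid[1], "alpha")
})

test_that("tabular alignments round-trip through outfmt 6", {
  set.seed(31)
  t <- rand_dna(800)
  q1 <- substr(t, 101, 200)
  h <- align_reads(data.frame(id = c("q1", "q2"),
                              sequence = c(q1, rc(q1)),
                              stringsAsFactors = FALSE),
                   c(s1 = t))
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_outfmt6(h, fp)
  back <- read_outfmt6(fp)
  expect_equal(back$strand, h$strand)
  expect_equal(back$sstart, h$sstart)
  expect_equal(back$send, h$send)
  expect_equal(back$length, h$length)
  # malformed rows are rejected with a line number
  writeLines(c(readLines(fp), "q3\ts1\t100"), fp)
  expect_error(read_outfmt6(fp), "line 3")
})
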