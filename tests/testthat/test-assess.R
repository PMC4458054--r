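test_that("competitive choice follows the e-value/identity/bitscore order", {
  a <- hit_row(100, evalue = 1e-50)
  b <- hit_row(100, evalue = 1e-30)
  expect_equal(competitive_choice(a, b), "species_a")
  expect_equal(competitive_choice(b, a), "species_b")
  # equal e-values: identity decides
  a2 <- hit_row(100, evalue = 1e-40, pident = 99)
  b2 <- hit_row(100, evalue = 1e-40, pident = 97)
  expect_equal(competitive_choice(a2, b2), "species_a")
  # identical hits on both sides are ambiguous
  expect_equal(competitive_choice(a, a), "ambiguous")
  # single-sided and empty cases
  expect_equal(competitive_choice(a, NULL), "species_a")
  expect_equal(competitive_choice(NULL, b), "species_b")
  expect_equal(competitive_choice(NULL, NULL), "unclassified")
  # bitscore is the final tie-breaker before ambiguity
  a3 <- hit_row(100, evalue = 1e-40, pident = 99, bitscore = 210)
  b3 <- hit_row(100, evalue = 1e-40, pident = 99, bitscore = 200)
  expect_equal(competitive_choice(a3, b3), "species_a")
})

test_that("confusion matrices count the four outcomes correctly", {
  truth <- c(r1 = "species_a", r2 = "species_a", r3 = "species_a",
             r4 = "species_b", r5 = "species_b", r6 = "species_b")
  pred <- c(r1 = "species_a", r2 = "species_b", r3 = "unclassified",
            r4 = "species_b", r5 = "species_a", r6 = "species_b")
  cm <- confusion_from_labels(truth, pred, "species_a")
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(1, 1, 1, 2))
  expect_equal(cm$n_excluded, 1)
  # all-correct predictions
  cm0 <- confusion_from_labels(truth, truth, "species_a")
  expect_equal(c(cm0$fn, cm0$fp), c(0, 0))
  # wholesale label swap exchanges tp<->fn and tn<->fp
  swapped <- ifelse(truth == "species_a", "species_b", "species_a")
  names(swapped) <- names(truth)
  cms <- confusion_from_labels(truth, swapped, "species_a")
  expect_equal(c(cms$tp, cms$fn, cms$fp, cms$tn),
               c(0, cm0$tp + cm0$fn, cm0$tn + cm0$fp, 0))
  # id mismatches are a hard error
  expect_error(confusion_from_labels(truth, pred[-1], "species_a"),
               "ids do not match")
})

test_that("misclassification rates are percent of the library total", {
  expect_equal(misclassification_rate(25, 1000), 2.5)
  expect_equal(misclassification_rate(0, 10), 0)
  expect_error(misclassification_rate(1, 0), "library_total")
})

test_that("single-point AUC is the trapezoid through the operating point", {
  cm <- confusion_matrix(tp = 90, fn = 10, fp = 5, tn = 95)
  expect_equal(auc_single_point(cm), (1 + 0.9 - 0.05) / 2)
  expect_equal(auc_single_point(confusion_matrix(50, 0, 0, 50)), 1.0)
  expect_error(auc_single_point(confusion_matrix(0, 0, 5, 5)), "degenerate")
})

test_that("threshold-sweep AUC equals single-point AUC for hard labels", {
  set.seed(7)
  for (i in 1:25) {
    n_pos <- sample(20:200, 1)
    n_neg <- sample(20:200, 1)
    truth <- c(rep("species_a", n_pos), rep("species_b", n_neg))
    names(truth) <- paste0("r", seq_along(truth))
    pred_pos <- runif(n_pos) < runif(1, 0.5, 1)
    pred_neg <- runif(n_neg) < runif(1, 0, 0.5)
    margin <- c(ifelse(pred_pos, 1, -1), ifelse(pred_neg, 1, -1))
    names(margin) <- names(truth)
    cm <- confusion_matrix(tp = sum(pred_pos), fn = sum(!pred_pos),
                           fp = sum(pred_neg), tn = sum(!pred_neg))
    if (length(unique(margin)) < 2) next
    expect_equal(auc_from_scores(truth, margin, "species_a"),
                 auc_single_point(cm))
  }
})

test_that("sweep AUC is invariant under monotone score transforms and
           agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  n <- 300
  truth <- ifelse(runif(n) < 0.4, "species_a", "species_b")
  names(truth) <- paste0("r", 1:n)
  scores <- rnorm(n, mean = ifelse(truth == "species_a", 1, -0.5))
  names(scores) <- names(truth)
  a1 <- auc_from_scores(truth, scores, "species_a")
  a2 <- auc_from_scores(truth, exp(scores), "species_a")
  a3 <- auc_from_scores(truth, rank(scores), "species_a")
  expect_equal(a1, a2)
  expect_equal(a1, a3)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth == "species_a", predictor = unname(scores),
    direction = "<", quiet = TRUE)))
  expect_equal(a1, ref, tolerance = 1e-12)
  # degenerate cases
  expect_warning(flat <- auc_from_scores(truth,
    stats::setNames(rep(1, n), names(truth)), "species_a"), "constant")
  expect_equal(flat, 0.5)
  sep <- stats::setNames(ifelse(truth == "species_a", 2, 1) + runif(n, 0, .5),
                         names(truth))
  expect_equal(auc_from_scores(truth, sep, "species_a"), 1.0)
})

test_that("assessment recovers a known corruption rate of the labels", {
  set.seed(19)
  n <- 4000
  eps <- 0.03
  truth <- ifelse(runif(n) < 0.5, "species_a", "species_b")
  names(truth) <- paste0("r", 1:n)
  flip <- runif(n) < eps
  pred <- ifelse(flip, ifelse(truth == "species_a", "species_b", "species_a"),
                 truth)
  names(pred) <- names(truth)
  rep_ <- assess_report(truth, pred, "species_a")
  # binomial sampling error: 3 sd on eps with ~n/2 draws per library
  tol <- 3 * sqrt(eps * (1 - eps) / (n / 2)) * 100
  expect_lt(abs(rep_$misclassification_rate_a - 100 * eps), tol)
  expect_lt(abs(rep_$misclassification_rate_b - 100 * eps), tol)
  expect_equal(rep_$mapped_fraction_a + rep_$misclassification_rate_a, 100)
})

test_that("competitive mapping assigns single-species reads to their side", {
  set.seed(29)
  sys <- tiny_system(seed = 29, ortho_identity = 80)
  reads <- data.frame(
    id = c("a1", "a2", "b1"),
    sequence = c(substr(sys$refs_a$sequence[1], 51, 150),
                 substr(sys$refs_a$sequence[2], 201, 300),
                 substr(sys$refs_b$sequence[1], 301, 400)),
    stringsAsFactors = FALSE)
  cm <- competitive_map(reads, sys$refs_a, sys$refs_b)
  expect_equal(cm$label, c("species_a", "species_a", "species_b"))
  expect_true(all(cm$margin[1:2] > 0))
  expect_lt(cm$margin[3], 0)
})
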