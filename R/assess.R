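#' Competitive binary choice between two best hits
#'
#' Given a read's best passing hit against each species' reference set,
#' assign the read to the species with the better mapping score. The
#' comparator orders by e-value (ascending), then identity (descending),
#' then bitscore (descending); hits equal on all three give `ambiguous`,
#' no hit on either side gives `unclassified`.
#'
#' @param best_hit_a,best_hit_b one-row hit data.frames or `NULL`.
#' @param labels species labels for the two sides.
#' @return a single label string.
#' @export
competitive_choice <- function(best_hit_a, best_hit_b,
                               labels = c("species_a", "species_b")) {
  ha <- !is.null(best_hit_a) && nrow(best_hit_a) > 0
  hb <- !is.null(best_hit_b) && nrow(best_hit_b) > 0
  if (ha && !hb) return(labels[1])
  if (hb && !ha) return(labels[2])
  if (!ha && !hb) return("unclassified")
  if (best_hit_a$evalue != best_hit_b$evalue)
    return(if (best_hit_a$evalue < best_hit_b$evalue) labels[1] else labels[2])
  if (best_hit_a$pident != best_hit_b$pident)
    return(if (best_hit_a$pident > best_hit_b$pident) labels[1] else labels[2])
  if (best_hit_a$bitscore != best_hit_b$bitscore)
    return(if (best_hit_a$bitscore > best_hit_b$bitscore) labels[1]
           else labels[2])
  "ambiguous"
}

#' Competitive mapping of reads against two reference sets
#'
#' Maps every read against both species' references, filters hits by
#' `params`, and assigns each read by [competitive_choice()] on its best
#' hit per side. The signed comparator margin (bitscore of the best A-side
#' hit minus bitscore of the best B-side hit; a missing side contributes 0)
#' is returned alongside for threshold-sweep ROC analysis.
#'
#' @param reads read data.frame.
#' @param refs_a,refs_b the two reference sets.
#' @param params [mapping_params()] gate (default preset `ci_lenient`).
#' @param labels species labels.
#' @return data.frame with columns `read_id`, `label`, `margin`.
#' @export
competitive_map <- function(reads, refs_a, refs_b,
                            params = mapping_params("ci_lenient"),
                            labels = c("species_a", "species_b")) {
  reads <- as_seqdf(reads)
  ha <- align_reads(reads, refs_a)
  hb <- align_reads(reads, refs_b)
  pa <- ha[passes_predicate(ha, params), , drop = FALSE]
  pb <- hb[passes_predicate(hb, params), , drop = FALSE]
  ba <- lapply(split_by_read(pa), best_of)
  bb <- lapply(split_by_read(pb), best_of)
  lab <- character(nrow(reads))
  margin <- numeric(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    a <- ba[[reads$id[i]]]
    b <- bb[[reads$id[i]]]
    lab[i] <- competitive_choice(a, b, labels)
    margin[i] <- (if (is.null(a)) 0 else a$bitscore) -
      (if (is.null(b)) 0 else b$bitscore)
  }
  data.frame(read_id = reads$id, label = lab, margin = margin,
             stringsAsFactors = FALSE)
}

#' Read-level confusion matrix from truth and predicted labels
#'
#' With species A positive: a truth-A read predicted A is a true positive,
#' predicted B a false negative; a truth-B read predicted A is a false
#' positive, predicted B a true negative. Reads predicted `ambiguous` or
#' `unclassified` are excluded from the matrix and counted separately.
#'
#' @param truth,predicted named character vectors (names = read ids) or
#'   data.frames with `read_id` and `label` columns. Ids must coincide.
#' @param positive_label the species counted as positive.
#' @return an object of class `confusion_matrix` with fields `tp`, `fn`,
#'   `fp`, `tn`, `positive_label`, `n_excluded`.
#' @export
confusion_from_labels <- function(truth, predicted, positive_label) {
  truth <- as_labelvec(truth)
  predicted <- as_labelvec(predicted)
  if (!setequal(names(truth), names(predicted)) ||
      length(truth) != length(predicted))
    stop("truth and predicted read ids do not match")
  predicted <- predicted[names(truth)]
  species <- unique(truth)
  stopifnot(positive_label %in% species, length(species) == 2)
  negative_label <- setdiff(species, positive_label)
  scored <- predicted %in% species
  t <- truth[scored]
  p <- predicted[scored]
  structure(list(
    tp = sum(t == positive_label & p == positive_label),
    fn = sum(t == positive_label & p == negative_label),
    fp = sum(t == negative_label & p == positive_label),
    tn = sum(t == negative_label & p == negative_label),
    positive_label = positive_label,
    n_excluded = sum(!scored)), class = "confusion_matrix")
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fn,fp,tn read counts.
#' @param positive_label the positive species token.
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn, positive_label = "species_a") {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 positive_label = positive_label, n_excluded = 0L),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix (positive =", x$positive_label, ")\n")
  cat(sprintf("  tp %s  fn %s\n  fp %s  tn %s\n",
              format(x$tp, big.mark = ","), format(x$fn, big.mark = ","),
              format(x$fp, big.mark = ","), format(x$tn, big.mark = ",")))
  invisible(x)
}

as_labelvec <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("read_id", "label") %in% names(x)))
    return(stats::setNames(x$label, x$read_id))
  }
  stopifnot(is.character(x), !is.null(names(x)))
  x
}

#' Misclassification rate as percent of a library
#'
#' @param cross_mapped number of reads of the library mapped to the other
#'   species' references.
#' @param library_total total number of reads in the library (including
#'   unmapped reads).
#' @return percent, `100 * cross_mapped / library_total`.
#' @export
misclassification_rate <- function(cross_mapped, library_total) {
  if (any(library_total < 1)) stop("library_total must be >= 1")
  stopifnot(all(cross_mapped >= 0), all(cross_mapped <= library_total))
  100 * cross_mapped / library_total
}

#' ROC AUC of a single operating point
#'
#' The area under the ROC curve through (0,0), (FPR, TPR), (1,1) by
#' trapezoidal integration: `AUC = (1 + TPR - FPR) / 2` with
#' `TPR = tp/(tp+fn)` and `FPR = fp/(fp+tn)`. This is the AUC of a hard
#' binary assignment such as the competitive-mapping choice.
#'
#' @param cm a [confusion_matrix()].
#' @return numeric AUC in `[0, 1]`.
#' @export
auc_single_point <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn < 1 || cm$fp + cm$tn < 1)
    stop("degenerate confusion matrix: empty positive or negative margin")
  tpr <- cm$tp / (cm$tp + cm$fn)
  fpr <- cm$fp / (cm$fp + cm$tn)
  (1 + tpr - fpr) / 2
}

#' ROC AUC from continuous assignment scores
#'
#' Trapezoidal integration of the ROC curve over the full threshold sweep
#' of a per-read margin score (higher = more confidently positive). For a
#' hard binary margin this reduces exactly to [auc_single_point()] on the
#' corresponding confusion matrix.
#'
#' @param truth named character vector (or data.frame) of true species
#'   labels.
#' @param scores named numeric vector of margin scores (same read ids).
#' @param positive_label the positive species token.
#' @return numeric AUC in `[0, 1]`; constant scores with mixed truth give
#'   0.5 with a warning.
#' @export
auc_from_scores <- function(truth, scores, positive_label) {
  truth <- as_labelvec(truth)
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (!setequal(names(truth), names(scores)))
    stop("truth and score read ids do not match")
  scores <- scores[names(truth)]
  pos <- truth == positive_label
  if (!any(pos) || all(pos))
    stop("need at least one positive and one negative read")
  if (length(unique(scores)) == 1) {
    warning("constant scores: AUC undefined, returning 0.5")
    return(0.5)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  p <- pos[o]
  # cumulative counts at each unique threshold (ties collapsed)
  last <- which(diff(s) != 0)
  idx <- c(last, length(s))
  tpr <- c(0, cumsum(p)[idx] / sum(pos))
  fpr <- c(0, cumsum(!p)[idx] / sum(!pos))
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Full assessment report for a binary read assignment
#'
#' Summarizes a competitive-mapping (or cascade) assignment against known
#' read origins: the confusion matrix, per-library cross-mapping
#' (misclassification) rates and correctly-mapped fractions as percent of
#' each library's total reads, and the single-operating-point ROC AUC.
#'
#' @param truth,predicted labels as in [confusion_from_labels()].
#' @param positive_label the positive species (library "a").
#' @param library_totals optional named totals `c(a = ..., b = ...)`;
#'   default: the number of truth reads of each species (reads excluded
#'   from the matrix still count towards their library total).
#' @return a list of class `assessment_report` with fields `confusion`,
#'   `misclassification_rate_a/b`, `mapped_fraction_a/b`, `auc`,
#'   `n_excluded`.
#' @export
assess_report <- function(truth, predicted, positive_label,
                          library_totals = NULL) {
  truth <- as_labelvec(truth)
  cm <- confusion_from_labels(truth, predicted, positive_label)
  negative_label <- setdiff(unique(truth), positive_label)
  if (is.null(library_totals))
    library_totals <- c(a = sum(truth == positive_label),
                        b = sum(truth == negative_label))
  out <- list(
    confusion = cm,
    misclassification_rate_a = misclassification_rate(cm$fn,
                                                      library_totals[["a"]]),
    misclassification_rate_b = misclassification_rate(cm$fp,
                                                      library_totals[["b"]]),
    mapped_fraction_a = 100 * cm$tp / library_totals[["a"]],
    mapped_fraction_b = 100 * cm$tn / library_totals[["b"]],
    auc = auc_single_point(cm),
    n_excluded = cm$n_excluded)
  class(out) <- "assessment_report"
  out
}

#' @export
print.assessment_report <- function(x, ...) {
  print(x$confusion)
  cat(sprintf("  misclassification: a %.4g%%  b %.4g%%\n",
              x$misclassification_rate_a, x$misclassification_rate_b))
  cat(sprintf("  mapped fraction:   a %.4g%%  b %.4g%%\n",
              x$mapped_fraction_a, x$mapped_fraction_b))
  cat(sprintf("  AUC %.3f  (excluded reads: %d)\n", x$auc,
              as.integer(x$n_excluded)))
  invisible(x)
}

#' Flatten an assessment report to a named metrics list
#'
#' @param report an [assess_report()] result.
#' @return named list suitable for [write_metrics()].
#' @export
metrics_of <- function(report) {
  stopifnot(inherits(report, "assessment_report"))
  cm <- report$confusion
  list(tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn,
       tpr = cm$tp / (cm$tp + cm$fn), fpr = cm$fp / (cm$fp + cm$tn),
       misclassification_rate_a = report$misclassification_rate_a,
       misclassification_rate_b = report$misclassification_rate_b,
       mapped_fraction_a = report$mapped_fraction_a,
       mapped_fraction_b = report$mapped_fraction_b,
       auc = report$auc, n_excluded = report$n_excluded)
}
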