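#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth Vectors of `"positive"`/`"negative"` (or
#'   logical / `"true"`/`"false"`) calls of equal length.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(predicted, truth) {
  p <- .as_positive(predicted)
  t <- .as_positive(truth)
  stopifnot(length(p) == length(t))
  c(TP = sum(p & t), FP = sum(p & !t), TN = sum(!p & !t), FN = sum(!p & t))
}

#' Classification metrics from confusion counts
#'
#' Sensitivity, specificity, accuracy, F1 and Matthews correlation
#' coefficient. An MCC whose denominator vanishes is 0 by convention; an
#' undefined F1 (no positive calls and no positives) is 0 with a warning.
#'
#' @param counts Named vector with `TP`, `FP`, `TN`, `FN` (as from
#'   [confusion_counts()]), or the predicted labels when `truth` is given.
#' @param truth Optional true labels; when given, `counts` is taken as
#'   predicted labels.
#' @return Named numeric vector `c(sens, spec, acc, f1, mcc)`.
#' @export
classification_metrics <- function(counts, truth = NULL) {
  if (!is.null(truth)) counts <- confusion_counts(counts, truth)
  if (any(counts < 0)) stop("negative confusion counts")
  TP <- as.numeric(counts["TP"]); FP <- as.numeric(counts["FP"])
  TN <- as.numeric(counts["TN"]); FN <- as.numeric(counts["FN"])
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  acc <- (TP + TN) / (TP + FP + TN + FN)
  if (TP + FP + FN == 0) {
    warning("F1 undefined (no positives anywhere); returning 0")
    f1 <- 0
  } else {
    f1 <- 2 * TP / (2 * TP + FP + FN)
  }
  denom <- sqrt((TP + FP)) * sqrt((TP + FN)) * sqrt((TN + FP)) * sqrt((TN + FN))
  mcc <- if (denom == 0) 0 else (TP * TN - FP * FN) / denom
  c(sens = sens, spec = spec, acc = acc, f1 = f1, mcc = mcc)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score (ties grouped) and accumulates the ROC
#' curve; AUC by the trapezoid rule. For scaled predictor scores the
#' positive class scores low, which is the default orientation.
#'
#' @param scores Numeric scores.
#' @param labels True labels.
#' @param positives_low If `TRUE` (default) lower scores indicate the
#'   positive class, as on the scaled axis.
#' @return List: `curve` (data frame `fpr`, `tpr`, one row per threshold)
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels, positives_low = TRUE) {
  pos <- .as_positive(labels)
  if (!any(pos) || all(pos)) stop("ROC requires both classes")
  s <- if (positives_low) -as.numeric(scores) else as.numeric(scores)
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; pos <- pos[ord]
  # group ties: cumulative counts at the end of each tie block
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(pos)[last]
  fp <- cumsum(!pos)[last]
  tpr <- c(0, tp / sum(pos))
  fpr <- c(0, fp / sum(!pos))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Per-class overlap and coverage of predictor pairs
#'
#' For the chosen class, a pair's overlap is the fraction of class
#' samples that both predictors call correctly and its coverage the
#' fraction at least one calls correctly; with three or more predictors
#' the all-inclusive coverage (any predictor correct) is also reported.
#' Overlap and coverage obey the inclusion-exclusion identity
#' `overlap + coverage = recall_A + recall_B`.
#'
#' @param calls Logical matrix (rows = samples, one column per predictor):
#'   `TRUE` where the predictor calls the sample positive. Or a character
#'   matrix of `"positive"`/`"negative"`.
#' @param labels True labels, length `nrow(calls)`.
#' @param class `"positive"` (default) or `"negative"`: which class the
#'   fractions are computed over.
#' @return List of class `overlap_coverage`: `class`, `recall` (per
#'   predictor), `pairwise` (data frame with `pair`, `overlap`,
#'   `coverage`), `all_inclusive` (`NA` for fewer than 3 predictors).
#' @export
overlap_coverage <- function(calls, labels, class = c("positive", "negative")) {
  class <- match.arg(class)
  if (is.character(calls)) calls <- matrix(.as_positive(calls), nrow = nrow(calls),
                                           dimnames = dimnames(calls))
  pos <- .as_positive(labels)
  in_class <- if (class == "positive") pos else !pos
  if (!sum(in_class)) stop("no samples in class ", class)
  # a call is correct when it matches the class under consideration
  correct <- if (class == "positive") calls[in_class, , drop = FALSE]
             else !calls[in_class, , drop = FALSE]
  n <- sum(in_class)
  preds <- colnames(correct)
  if (is.null(preds)) preds <- paste0("p", seq_len(ncol(correct)))
  recall <- colSums(correct) / n
  names(recall) <- preds
  pairs <- utils::combn(seq_len(ncol(correct)), 2)
  pw <- apply(pairs, 2, function(ij) {
    a <- correct[, ij[1]]; b <- correct[, ij[2]]
    c(overlap = sum(a & b) / n, coverage = sum(a | b) / n)
  })
  pairwise <- data.frame(pair = apply(pairs, 2, function(ij)
                           paste(preds[ij], collapse = "+")),
                         overlap = pw["overlap", ], coverage = pw["coverage", ])
  all_inc <- if (ncol(correct) >= 3) sum(rowSums(correct) > 0) / n else NA_real_
  structure(list(class = class, recall = recall, pairwise = pairwise,
                 all_inclusive = all_inc),
            class = "overlap_coverage")
}

#' @export
print.overlap_coverage <- function(x, ...) {
  cat("overlap/coverage for", x$class, "samples\n")
  cat("per-predictor recall:\n")
  print(round(x$recall, 3))
  print(transform(x$pairwise, overlap = round(overlap, 3),
                  coverage = round(coverage, 3)))
  if (!is.na(x$all_inclusive))
    cat("all-inclusive coverage:", round(x$all_inclusive, 3), "\n")
  invisible(x)
}

#' Default-cutoff calls of the individual predictors
#'
#' Applies the scaled default cutoffs with the strictly-below convention:
#' a predictor calls a record positive when its scaled score is below the
#' predictor's scaled default cutoff.
#'
#' @param records Scaled records data frame.
#' @param predictors Predictor ids (default: all with scaled columns).
#' @return Logical matrix of calls (columns named by predictor).
#' @export
default_cutoff_calls <- function(records, predictors = NULL) {
  cut <- scaled_default_cutoffs()
  if (is.null(predictors))
    predictors <- intersect(predictor_ids(),
                            sub("^scaled_", "", grep("^scaled_", names(records),
                                                     value = TRUE)))
  m <- sapply(predictors, function(p) records[[paste0("scaled_", p)]] < cut[p])
  matrix(m, nrow = nrow(records), dimnames = list(NULL, predictors))
}
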