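# Binary-classification metrics for aggregation predictors: confusion
# counts at a strict score threshold, accuracy, Matthews correlation
# coefficient, per-class precisions, and threshold-free ROC/AUC.

#' Confusion counts at a score threshold
#'
#' Scores strictly above the threshold are called aggregation-prone
#' (positive); a score exactly equal to the threshold is called negative.
#'
#' @param scores Numeric propensity scores in \[0, 1\].
#' @param labels True labels: the package's label factor, 0/1, or logical
#'   (`TRUE`/1/`"aggregating"` = positive).
#' @param threshold Decision threshold, default 0.5.
#' @return A one-row tibble with columns `tp`, `fn`, `fp`, `tn`.
#' @export
#' @examples
#' confusion_counts(c(0.9, 0.1), c(1, 0))
confusion_counts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` differ in length", call. = FALSE)
  }
  pos <- as_positive(labels)
  call_pos <- scores > threshold
  tibble::tibble(
    tp = sum(call_pos & pos),
    fn = sum(!call_pos & pos),
    fp = sum(call_pos & !pos),
    tn = sum(!call_pos & !pos)
  )
}

check_counts <- function(counts) {
  need <- setdiff(c("tp", "fn", "fp", "tn"), names(counts))
  if (length(need) > 0) {
    stop("counts need column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tot <- counts$tp + counts$fn + counts$fp + counts$tn
  if (any(tot <= 0)) {
    stop("confusion counts sum to zero", call. = FALSE)
  }
  if (any(c(counts$tp, counts$fn, counts$fp, counts$tn) < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  invisible(counts)
}

#' Accuracy from confusion counts
#'
#' @param counts A data frame with columns `tp`, `fn`, `fp`, `tn`
#'   (vectorized over rows).
#' @return Numeric accuracy, `(tp + tn) / total`.
#' @export
accuracy <- function(counts) {
  check_counts(counts)
  with(counts, (tp + tn) / (tp + fn + fp + tn))
}

#' Matthews correlation coefficient from confusion counts
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, in \[-1, 1\]:
#' +1 is a perfect prediction, 0 an average random one, -1 a perfectly
#' inverted one. When any factor of the denominator is zero the value is
#' defined as 0 (the usual convention).
#'
#' @inheritParams accuracy
#' @return Numeric MCC.
#' @export
mcc <- function(counts) {
  check_counts(counts)
  with(counts, {
    den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    num <- tp * tn - fp * fn
    ifelse(den2 == 0, 0, num / sqrt(den2))
  })
}

#' Per-class precisions from confusion counts
#'
#' Positive precision `tp / (tp + fp)` and negative precision
#' `tn / (tn + fn)`. A zero denominator yields 0 for that side, with a
#' warning.
#'
#' @inheritParams accuracy
#' @return A tibble with columns `precision_pos`, `precision_neg`.
#' @export
class_precisions <- function(counts) {
  check_counts(counts)
  pp_den <- counts$tp + counts$fp
  np_den <- counts$tn + counts$fn
  if (any(pp_den == 0) || any(np_den == 0)) {
    warning("precision with empty call set; returning 0 for that class",
            call. = FALSE)
  }
  tibble::tibble(
    precision_pos = ifelse(pp_den == 0, 0, counts$tp / pp_den),
    precision_neg = ifelse(np_den == 0, 0, counts$tn / np_den)
  )
}

#' Augment confusion counts with all reported metrics
#'
#' Adds `accuracy`, `mcc`, `precision_pos` and `precision_neg` columns,
#' vectorized over rows — convenient for recomputing a whole results
#' table of confusion counts in one `mutate`-style call.
#'
#' @inheritParams accuracy
#' @return The input tibble with four metric columns appended.
#' @export
classification_metrics <- function(counts) {
  counts <- tibble::as_tibble(counts)
  dplyr::bind_cols(
    counts,
    tibble::tibble(accuracy = accuracy(counts), mcc = mcc(counts)),
    class_precisions(counts)
  )
}

#' ROC curve over all score thresholds
#'
#' Sweeps the decision threshold over every distinct score and records the
#' false-positive rate (1 - specificity) and true-positive rate
#' (sensitivity) at each, from (0, 0) to (1, 1). Tied scores move the
#' curve diagonally in one step.
#'
#' @inheritParams confusion_counts
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` differ in length", call. = FALSE)
  }
  pos <- as_positive(labels)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tibble::tibble(
    threshold = c(Inf, s[last_of_tie]),
    tpr = c(0, cumsum(p)[last_of_tie] / n_pos),
    fpr = c(0, cumsum(!p)[last_of_tie] / n_neg)
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_curve()]. Because tied scores contribute
#' diagonal segments, this equals the Mann-Whitney statistic: the fraction
#' of (positive, negative) pairs ranked concordantly, ties counted 1/2.
#'
#' @inheritParams confusion_counts
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  cur <- roc_curve(scores, labels)
  sum(diff(cur$fpr) * (utils::head(cur$tpr, -1) + utils::tail(cur$tpr, -1)) / 2)
}
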