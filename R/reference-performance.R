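# Published evaluation counts for the ProA predictors, shipped so that
# the reported metrics can be recomputed from raw confusion counts with
# this package's metric functions.

#' Published confusion counts for the ProA predictors
#'
#' Raw confusion counts (TP, FN, FP, TN) from the published evaluation of
#' the ProA aggregation predictors on the AP1 peptide dataset and the
#' SignalP 2.0 signal-peptide/anchor sets:
#'
#' * `"lopo"` — leave-one-protein-out cross-validation of ProA-SVM
#'   (7-feature subset) and ProA-RF (10-feature subset) on AP1.
#' * `"roc_fpr02"` — AP1 classification with the decision threshold set
#'   at a false-positive rate of 0.2 on the ROC curve, for the two ProA
#'   predictors and five external comparators (Zyggregator, AGGRESCAN,
#'   FoldAmyloid, TANGO, PAGE).
#' * `"signal_peptides"` — ProA models applied unchanged to the four
#'   SignalP 2.0 sets (eukaryotic signal peptides and anchors,
#'   Gram-positive and Gram-negative bacterial signal peptides) and their
#'   totals.
#'
#' Pass rows to [classification_metrics()] to recompute accuracy, MCC and
#' class precisions from the counts.
#'
#' @return A tibble with columns `predictor`, `evaluation`, `dataset`,
#'   `tp`, `fn`, `fp`, `tn`.
#' @export
#' @examples
#' proa_reference_counts() |>
#'   dplyr::filter(evaluation == "lopo") |>
#'   classification_metrics()
proa_reference_counts <- function() {
  tibble::tribble(
    ~predictor, ~evaluation, ~dataset, ~tp, ~fn, ~fp, ~tn,
    "ProA-SVM", "lopo", "AP1", 148, 36, 38, 132,
    "ProA-RF", "lopo", "AP1", 146, 38, 41, 129,
    "ProA-RF", "roc_fpr02", "AP1", 154, 30, 34, 136,
    "ProA-SVM", "roc_fpr02", "AP1", 144, 40, 34, 136,
    "ZYGGREGATOR", "roc_fpr02", "AP1", 139, 45, 34, 136,
    "AGGRESCAN", "roc_fpr02", "AP1", 123, 61, 34, 136,
    "FoldAmyloid", "roc_fpr02", "AP1", 116, 68, 34, 136,
    "TANGO", "roc_fpr02", "AP1", 98, 86, 34, 136,
    "PAGE", "roc_fpr02", "AP1", 96, 88, 34, 136,
    "ProA-SVM", "signal_peptides", "EUKSIG", 1022, 103, 189, 936,
    "ProA-SVM", "signal_peptides", "EUKANC", 55, 12, 10, 56,
    "ProA-SVM", "signal_peptides", "GRAM+SIG", 118, 51, 33, 136,
    "ProA-SVM", "signal_peptides", "GRAM-SIG", 286, 64, 73, 277,
    "ProA-SVM", "signal_peptides", "total", 1481, 230, 305, 1405,
    "ProA-RF", "signal_peptides", "EUKSIG", 896, 229, 297, 828,
    "ProA-RF", "signal_peptides", "EUKANC", 60, 7, 9, 57,
    "ProA-RF", "signal_peptides", "GRAM+SIG", 127, 42, 38, 131,
    "ProA-RF", "signal_peptides", "GRAM-SIG", 290, 60, 104, 246,
    "ProA-RF", "signal_peptides", "total", 1373, 338, 448, 1262
  )
}
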