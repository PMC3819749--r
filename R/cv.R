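# Cross-validation machinery: seeded k-fold splits, leave-one-protein-out
# splits grouped by source protein, and nested cross-validation in which
# every tuning decision is made inside the outer-training data only.

#' Seeded k-fold split
#'
#' Randomly partitions `1:n` into `k` folds whose sizes differ by at most
#' one. Folds are unstratified: the split is a plain seeded shuffle.
#'
#' @param n Number of samples.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Integer seed for the shuffle.
#' @return A tibble with columns `fold`, `train` (list of integer index
#'   vectors) and `test` (list), with attributes `scheme = "kfold"` and
#'   `seed`.
#' @export
kfold_splits <- function(n, k = 10, seed = 1) {
  if (k > n) stop("k must not exceed n", call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  idx <- withr::with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  test_sets <- split(idx, rep(seq_len(k), times = sizes))
  out <- tibble::tibble(
    fold = seq_len(k),
    train = purrr::map(test_sets, ~ sort(setdiff(idx, .x))),
    test = purrr::map(test_sets, sort)
  )
  structure(out, scheme = "kfold", seed = seed)
}

#' Leave-one-protein-out split
#'
#' One fold per distinct `protein_group`: the fold's test set is every
#' peptide from that protein (all de novo peptides, group `"de_novo"`,
#' form a single fold together) and its training set is every other
#' peptide. No protein contributes to both sides of any fold, so
#' within-protein similarity cannot leak between training and test.
#'
#' @param peptides A data frame with a `protein_group` column.
#' @return A tibble with columns `fold`, `group`, `train`, `test`, with
#'   attribute `scheme = "lopo"`.
#' @export
lopo_splits <- function(peptides) {
  grp <- peptides$protein_group
  if (is.null(grp) || any(is.na(grp) | !nzchar(grp))) {
    stop("every peptide needs a non-empty protein_group", call. = FALSE)
  }
  groups <- unique(grp)
  out <- tibble::tibble(
    fold = seq_along(groups),
    group = groups,
    train = purrr::map(groups, ~ which(grp != .x)),
    test = purrr::map(groups, ~ which(grp == .x))
  )
  structure(out, scheme = "lopo", seed = NA_integer_)
}

#' Nested cross-validation of a propensity predictor
#'
#' For each outer fold, fits the predictor on the outer-training rows
#' only — including any hyperparameter tuning, which uses an inner k-fold
#' split of the outer-training data — then scores the held-out rows.
#' Pooled out-of-fold scores give the confusion counts, accuracy, MCC,
#' class precisions and AUC.
#'
#' @param data An encoded dataset from [encode_peptides()] with a `label`
#'   column.
#' @param features Character vector of feature columns to use.
#' @param method `"svm"` (linear kernel, cost tuned by inner CV) or
#'   `"rf"` (500-tree random forest).
#' @param folds Optional fold assignment (e.g. [lopo_splits()]); default
#'   is a seeded `k_outer`-fold split.
#' @param k_outer,k_inner Outer and inner fold counts.
#' @param threshold Decision threshold for the pooled confusion counts.
#' @param seed Integer seed governing folds and model fitting.
#' @param ... Passed to [train_propensity()] (e.g. `cost_grid`, `ntree`).
#' @return A `cv_result` object: list with `scores` (tibble of row, fold,
#'   score, label), `counts`, `metrics` (one row), `auc`, `folds`,
#'   `scheme`, `seed`.
#' @export
nested_cv <- function(data, features, method = c("svm", "rf"),
                      folds = NULL, k_outer = 10, k_inner = 10,
                      threshold = 0.5, seed = 1, ...) {
  method <- match.arg(method)
  if (is.null(folds)) folds <- kfold_splits(nrow(data), k_outer, seed = seed)
  scores <- purrr::map_dfr(seq_len(nrow(folds)), function(i) {
    tr <- folds$train[[i]]
    te <- folds$test[[i]]
    model <- train_propensity(
      data[tr, , drop = FALSE], features, method = method,
      inner_k = k_inner, seed = seed + i, ...
    )
    tibble::tibble(
      row = te,
      fold = folds$fold[i],
      score = predict(model, data[te, , drop = FALSE]),
      positive = as_positive(data$label[te])
    )
  })
  counts <- confusion_counts(scores$score, scores$positive, threshold)
  structure(
    list(
      scores = scores,
      counts = counts,
      metrics = classification_metrics(counts),
      auc = roc_auc(scores$score, scores$positive),
      folds = folds,
      scheme = attr(folds, "scheme"),
      seed = seed
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("# ", x$scheme, " cross-validation (", nrow(x$folds), " folds)\n",
      sep = "")
  print(x$metrics)
  cat("AUC:", format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a cross-validation result
#'
#' @param x A `cv_result` from [nested_cv()].
#' @param ... Unused.
#' @return A one-row tibble: scheme, fold count, pooled confusion counts,
#'   accuracy, MCC, class precisions and AUC.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(scheme = x$scheme, n_folds = nrow(x$folds)),
    x$metrics,
    tibble::tibble(auc = x$auc)
  )
}

#' Per-fold metrics of a cross-validation result
#'
#' @param x A `cv_result` from [nested_cv()].
#' @param threshold Decision threshold for fold-level counts.
#' @param ... Unused.
#' @return A tibble with one row per fold and its confusion counts and
#'   metrics.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, threshold = 0.5, ...) {
  x$scores |>
    dplyr::group_by(.data$fold) |>
    dplyr::reframe(confusion_counts(.data$score, .data$positive, threshold)) |>
    classification_metrics()
}
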