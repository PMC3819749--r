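# The two deployed propensity predictors: a linear soft-margin SVM with
# sigmoid probability calibration and a 500-tree random forest scoring by
# tree-vote fraction. Both emit propensities in [0, 1]; the positive class
# is "aggregating" throughout.

#' Train an aggregation-propensity predictor
#'
#' Fits one of the two deployed predictors on an encoded peptide dataset,
#' restricted to a frozen feature subset:
#'
#' * `"svm"` — linear-kernel soft-margin SVM. When `cost` is `NULL` the
#'   cost parameter C is tuned over `cost_grid` by an inner `inner_k`-fold
#'   cross-validation of the training data (smallest cost wins ties).
#'   Scores are class probabilities from the standard sigmoid (Platt)
#'   calibration fitted on the training data.
#' * `"rf"` — random forest of `ntree` trees with `floor(sqrt(M))`
#'   candidate variables per split (M = number of features). Scores are
#'   the fraction of trees voting for the positive class.
#'
#' @param data An encoded dataset from [encode_peptides()] with a `label`
#'   column containing both classes.
#' @param features Character vector of feature (scale id) columns; the
#'   fitted model refuses prediction data missing any of them.
#' @param method `"svm"` or `"rf"`.
#' @param cost Fixed SVM cost; `NULL` (default) tunes over `cost_grid`.
#' @param cost_grid Candidate costs for inner-CV tuning.
#' @param inner_k Folds for inner tuning.
#' @param ntree Number of random-forest trees.
#' @param seed Integer seed; fitting is deterministic given data and seed.
#' @return A `propensity_model` object.
#' @export
train_propensity <- function(data, features, method = c("svm", "rf"),
                             cost = NULL,
                             cost_grid = c(0.25, 0.5, 1, 2, 4, 8),
                             inner_k = 10, ntree = 500, seed = 1) {
  method <- match.arg(method)
  miss <- setdiff(features, names(data))
  if (length(miss) > 0) {
    stop("feature column(s) absent from data: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(features) == 0) stop("empty feature subset", call. = FALSE)
  y <- factor(
    ifelse(as_positive(data$label), "aggregating", "non_aggregating"),
    levels = c("non_aggregating", "aggregating")
  )
  if (dplyr::n_distinct(y) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  x <- as.matrix(data[, features, drop = FALSE])

  tuning <- NULL
  fit <- withr::with_seed(seed, {
    if (method == "svm") {
      if (is.null(cost)) {
        tuning <- tune_svm_cost(x, y, cost_grid, inner_k, seed)
        cost <- tuning$cost[which.min(tuning$cv_error)]
      }
      e1071::svm(
        x, y,
        kernel = "linear", cost = cost, scale = FALSE, probability = TRUE
      )
    } else {
      randomForest::randomForest(
        x, y,
        ntree = ntree, mtry = max(1L, floor(sqrt(ncol(x))))
      )
    }
  })
  structure(
    list(
      method = method,
      features = features,
      fit = fit,
      cost = if (method == "svm") cost else NULL,
      ntree = if (method == "rf") ntree else NULL,
      tuning = tuning,
      seed = seed,
      n_train = nrow(x)
    ),
    class = "propensity_model"
  )
}

# inner-CV error over the cost grid; ties broken toward smaller cost
tune_svm_cost <- function(x, y, cost_grid, inner_k, seed = 1) {
  k <- min(inner_k, nrow(x))
  folds <- kfold_splits(nrow(x), k, seed = seed)
  err <- vapply(sort(cost_grid), function(cc) {
    fold_err <- vapply(seq_len(nrow(folds)), function(i) {
      tr <- folds$train[[i]]
      te <- folds$test[[i]]
      if (dplyr::n_distinct(y[tr]) < 2) return(NA_real_)
      f <- e1071::svm(x[tr, , drop = FALSE], y[tr],
                      kernel = "linear", cost = cc, scale = FALSE)
      mean(predict(f, x[te, , drop = FALSE]) != y[te])
    }, numeric(1))
    mean(fold_err, na.rm = TRUE)
  }, numeric(1))
  tibble::tibble(cost = sort(cost_grid), cv_error = err)
}

#' Predict aggregation propensities
#'
#' @param object A `propensity_model`.
#' @param newdata A data frame containing the model's feature columns, or
#'   a numeric matrix/vector with matching (named) columns.
#' @param ... Unused.
#' @return Numeric propensity scores in \[0, 1\], one per row.
#' @export
predict.propensity_model <- function(object, newdata, ...) {
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list(NULL, names(newdata)))
  }
  nm <- colnames(newdata)
  miss <- setdiff(object$features, nm)
  if (length(miss) > 0) {
    stop("prediction data missing feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  storage.mode(x) <- "double"
  if (object$method == "svm") {
    p <- attr(
      predict(object$fit, x, probability = TRUE),
      "probabilities"
    )[, "aggregating"]
  } else {
    p <- predict(object$fit, x, type = "prob")[, "aggregating"]
  }
  unname(pmin(1, pmax(0, p)))
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("# Aggregation propensity predictor (",
      if (x$method == "svm") "linear SVM" else "random forest", ")\n",
      sep = "")
  cat("Features (", length(x$features), "): ",
      paste(utils::head(x$features, 8), collapse = ", "),
      if (length(x$features) > 8) ", ...", "\n", sep = "")
  if (x$method == "svm") cat("Cost:", x$cost, "\n")
  if (x$method == "rf") cat("Trees:", x$ntree, "\n")
  invisible(x)
}

#' Per-feature terms of a fitted predictor
#'
#' For the linear SVM, the weight of each feature in the decision
#' function (and its square, the RFE ranking criterion); for the random
#' forest, the mean decrease in Gini impurity.
#'
#' @param x A `propensity_model`.
#' @param ... Unused.
#' @return A tibble with `term` and `weight`/`importance` columns.
#' @method tidy propensity_model
#' @export
tidy.propensity_model <- function(x, ...) {
  if (x$method == "svm") {
    w <- drop(t(x$fit$coefs) %*% x$fit$SV)
    tibble::tibble(term = x$features, weight = unname(w[x$features]),
                   weight_sq = unname(w[x$features])^2)
  } else {
    imp <- randomForest::importance(x$fit)[, "MeanDecreaseGini"]
    tibble::tibble(term = x$features, importance = unname(imp[x$features]))
  }
}

#' One-row summary of a fitted predictor
#'
#' @param x A `propensity_model`.
#' @param ... Unused.
#' @return A one-row tibble with method, subset size, hyperparameters,
#'   training size and seed.
#' @method glance propensity_model
#' @export
glance.propensity_model <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_features = length(x$features),
    cost = ifelse(is.null(x$cost), NA_real_, x$cost),
    ntree = ifelse(is.null(x$ntree), NA_integer_, x$ntree),
    n_train = x$n_train,
    seed = x$seed
  )
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load a fitted predictor
#'
#' Persists the model together with its frozen feature subset and a
#' format-version stamp; loading refuses archives written under an
#' incompatible format version.
#'
#' @param model A `propensity_model`.
#' @param path Archive path (`.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored `propensity_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "propensity_model"))
  saveRDS(list(format_version = MODEL_FORMAT_VERSION, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format_version, MODEL_FORMAT_VERSION)) {
    stop("incompatible model archive (format version mismatch)",
         call. = FALSE)
  }
  obj$model
}
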