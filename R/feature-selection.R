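# The two wrapper feature-selection methods: SVM recursive feature
# elimination (rank by squared weight of a linear maximum-margin
# classifier, drop the lowest-ranked, re-fit) and iterative random-forest
# elimination (rank by mean decrease in Gini impurity, drop the least
# important 20% per loop, track out-of-bag error). Both produce an
# elimination trace from which a working subset is chosen by the
# first-significant-minimum rule.

new_elim_trace <- function(df, method, seed) {
  structure(
    df,
    method = method, seed = seed,
    class = c("elim_trace", class(tibble::tibble()))
  )
}

elim_setup <- function(data, features) {
  if (is.null(features)) features <- feature_names(data)
  if (length(features) < 2) {
    stop("need at least 2 features to eliminate", call. = FALSE)
  }
  y <- factor(
    ifelse(as_positive(data$label), "aggregating", "non_aggregating"),
    levels = c("non_aggregating", "aggregating")
  )
  if (dplyr::n_distinct(y) < 2) {
    stop("labels contain a single class", call. = FALSE)
  }
  list(x = as.matrix(data[, features, drop = FALSE]), y = y,
       features = features)
}

# number of features to drop this iteration: one at a time when
# drop_frac is NULL, else keep floor(n * (1 - drop_frac)), dropping
# at least one
n_drop <- function(n_current, drop_frac) {
  if (is.null(drop_frac)) return(1L)
  max(1L, n_current - as.integer(floor(n_current * (1 - drop_frac))))
}

# indices of the m least-important features; ties eliminated in reverse
# collection order (last column first) for determinism
drop_order <- function(importance, positions, m) {
  ord <- order(importance, -positions)
  ord[seq_len(m)]
}

#' Subset-size schedule of an elimination run
#'
#' The sequence of surviving-feature counts an elimination produces:
#' one-at-a-time when `drop_frac` is `NULL`, otherwise keeping
#' `floor(n * (1 - drop_frac))` (at least one feature dropped per
#' iteration) down to a single feature.
#'
#' @param n_start Starting number of features.
#' @param drop_frac `NULL` or the per-iteration drop fraction.
#' @return Integer vector of subset sizes, starting at `n_start` and
#'   ending at 1.
#' @export
#' @examples
#' elimination_sizes(560, 0.2)[1:3] # 560 448 358
elimination_sizes <- function(n_start, drop_frac = NULL) {
  sizes <- as.integer(n_start)
  while (sizes[length(sizes)] > 1L) {
    cur <- sizes[length(sizes)]
    sizes <- c(sizes, cur - n_drop(cur, drop_frac))
  }
  sizes
}

#' SVM recursive feature elimination
#'
#' Starting from the full feature set, repeatedly fits a linear
#' maximum-margin classifier, ranks features by their squared weight in
#' the decision function, and removes the lowest-ranked feature (or, with
#' `drop_frac`, the lowest-ranked block) until one feature remains. Each
#' iteration records the k-fold cross-validated classification error of
#' the current subset; the fold split is fixed once per trace so error
#' differences across iterations reflect the subsets, not fold noise.
#' Equal-weight ties are eliminated in reverse collection order.
#'
#' @param data Encoded dataset from [encode_peptides()] with a `label`
#'   column containing both classes.
#' @param features Feature columns to start from; default all features of
#'   `data`.
#' @param drop_frac `NULL` for one-at-a-time elimination (the default), or
#'   a fraction in (0, 1) to drop that share of surviving features per
#'   iteration (geometric schedule, useful at hundreds of features).
#' @param cost SVM cost, fixed during the elimination loop.
#' @param k Folds for the per-iteration error estimate.
#' @param seed Integer seed (fold split).
#' @return An `elim_trace`: tibble with `iteration`, `n_features`,
#'   `features` (list column), `error`, `dispersion` (standard error of
#'   the fold-mean error),
#'   attributes `method = "svm_rfe"` and `seed`.
#' @export
svm_rfe <- function(data, features = NULL, drop_frac = NULL, cost = 1,
                    k = 10, seed = 1) {
  st <- elim_setup(data, features)
  folds <- kfold_splits(nrow(st$x), min(k, nrow(st$x)), seed = seed)
  cv_error <- function(cols) {
    fold_err <- vapply(seq_len(nrow(folds)), function(i) {
      tr <- folds$train[[i]]
      te <- folds$test[[i]]
      if (dplyr::n_distinct(st$y[tr]) < 2) return(NA_real_)
      f <- e1071::svm(st$x[tr, cols, drop = FALSE], st$y[tr],
                      kernel = "linear", cost = cost, scale = FALSE)
      mean(predict(f, st$x[te, cols, drop = FALSE]) != st$y[te])
    }, numeric(1))
    ok <- sum(!is.na(fold_err))
    c(mean(fold_err, na.rm = TRUE),
      stats::sd(fold_err, na.rm = TRUE) / sqrt(max(ok, 1)))
  }

  current <- st$features
  rows <- list()
  it <- 0L
  repeat {
    it <- it + 1L
    err <- cv_error(current)
    rows[[it]] <- tibble::tibble(
      iteration = it, n_features = length(current),
      features = list(current), error = err[1], dispersion = err[2]
    )
    if (length(current) == 1L) break
    fit <- e1071::svm(st$x[, current, drop = FALSE], st$y,
                      kernel = "linear", cost = cost, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)[current]
    m <- n_drop(length(current), drop_frac)
    out <- drop_order(w^2, match(current, st$features), m)
    current <- current[-out]
  }
  new_elim_trace(dplyr::bind_rows(rows), "svm_rfe", seed)
}

#' Iterative random-forest importance elimination
#'
#' Builds an initial forest of `ntree_build` trees, then repeatedly drops
#' the `drop_frac` least important features — importance being the mean
#' decrease in Gini node impurity — and refits a smaller forest of
#' `ntree_iter` trees, recording each forest's out-of-bag (OOB) error.
#' With `recompute = TRUE` (default) importances are re-estimated from
#' each refitted forest; otherwise the initial ranking is reused
#' throughout. The recorded dispersion is the binomial standard error of
#' the OOB error.
#'
#' @inheritParams svm_rfe
#' @param ntree_build Trees in the initial forest (default 500).
#' @param ntree_iter Trees in each refitted forest (default 200).
#' @param drop_frac Fraction of surviving features dropped per loop
#'   (default 0.2); at least one is always dropped.
#' @param recompute Recompute importances after each refit.
#' @return An `elim_trace` with `method = "rf_is"`; errors are OOB error
#'   rates.
#' @export
rf_importance_selection <- function(data, features = NULL,
                                    ntree_build = 500, ntree_iter = 200,
                                    drop_frac = 0.2, recompute = TRUE,
                                    seed = 1) {
  st <- elim_setup(data, features)
  n <- nrow(st$x)
  fit_forest <- function(cols, ntree) {
    randomForest::randomForest(
      st$x[, cols, drop = FALSE], st$y,
      ntree = ntree, mtry = max(1L, floor(sqrt(length(cols)))),
      importance = FALSE # MeanDecreaseGini is always available
    )
  }

  withr::with_seed(seed, {
    current <- st$features
    fit <- fit_forest(current, ntree_build)
    imp <- randomForest::importance(fit)[, "MeanDecreaseGini"]
    rows <- list()
    it <- 0L
    repeat {
      it <- it + 1L
      oob <- unname(fit$err.rate[fit$ntree, "OOB"])
      rows[[it]] <- tibble::tibble(
        iteration = it, n_features = length(current),
        features = list(current), error = oob,
        dispersion = sqrt(oob * (1 - oob) / n)
      )
      if (length(current) == 1L) break
      m <- n_drop(length(current), drop_frac)
      out <- drop_order(unname(imp[current]),
                        match(current, st$features), m)
      current <- current[-out]
      fit <- fit_forest(current, ntree_iter)
      if (recompute) {
        imp <- randomForest::importance(fit)[, "MeanDecreaseGini"]
      }
    }
    new_elim_trace(dplyr::bind_rows(rows), "rf_is", seed)
  })
}

#' Choose the working subset from an elimination trace
#'
#' Formalizes the "first significant minimum" of the error-versus-size
#' curve: the smallest subset whose error is within `c_sd` dispersions of
#' the global minimum error (dispersion taken at the global-minimum
#' iteration). With `c_sd = 0` this is simply the smallest subset
#' attaining the minimum error.
#'
#' @param trace An `elim_trace`.
#' @param c_sd Dispersion multiplier (default 1).
#' @return A `feature_subset` object: list with `features`, `size`,
#'   `method`, `c_sd` and the `trace`.
#' @export
choose_subset <- function(trace, c_sd = 1) {
  if (nrow(trace) == 0) stop("empty elimination trace", call. = FALSE)
  i_min <- which.min(trace$error)
  disp <- trace$dispersion[i_min]
  if (is.na(disp)) disp <- 0
  limit <- trace$error[i_min] + c_sd * disp
  ok <- which(trace$error <= limit)
  pick <- ok[which.min(trace$n_features[ok])]
  structure(
    list(
      features = trace$features[[pick]],
      size = trace$n_features[pick],
      method = attr(trace, "method"),
      c_sd = c_sd,
      trace = trace
    ),
    class = "feature_subset"
  )
}

#' @export
print.feature_subset <- function(x, ...) {
  cat("# Selected feature subset (", x$method, ", c_sd = ", x$c_sd, "): ",
      x$size, " feature(s)\n", sep = "")
  cat(paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / read an elimination trace as JSON lines
#'
#' One JSON object per iteration (`iteration`, `n_features`, `features`,
#' `error`, `dispersion`, plus `method` and `seed`).
#'
#' @param trace An `elim_trace`.
#' @param path Output path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` the
#'   restored `elim_trace`.
#' @export
write_trace <- function(trace, path) {
  lines <- purrr::map_chr(seq_len(nrow(trace)), function(i) {
    jsonlite::toJSON(
      list(
        iteration = trace$iteration[i],
        n_features = trace$n_features[i],
        features = trace$features[[i]],
        error = trace$error[i],
        dispersion = trace$dispersion[i],
        method = attr(trace, "method"),
        seed = attr(trace, "seed")
      ),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  recs <- purrr::map(readLines(path, warn = FALSE), jsonlite::fromJSON)
  df <- tibble::tibble(
    iteration = purrr::map_int(recs, "iteration"),
    n_features = purrr::map_int(recs, "n_features"),
    features = purrr::map(recs, "features"),
    error = purrr::map_dbl(recs, "error"),
    dispersion = purrr::map_dbl(recs, ~ {
      d <- .x$dispersion
      if (is.null(d)) NA_real_ else d
    })
  )
  new_elim_trace(df, recs[[1]]$method, recs[[1]]$seed)
}

#' Feature subsets of the published ProA predictors
#'
#' The frozen physicochemical-property subsets behind the two deployed
#' ProA predictors: the 7 AAindex scales selected by SVM-RFE and the 10
#' scales (9 AAindex plus the Zyggregator-derived aggregation propensity
#' `X15925383`) selected by RF-IS on the AP1 peptide aggregation dataset.
#' Their union holds 16 distinct properties — dominated by hydrophobicity
#' and secondary-structure propensities — and the two methods agree on
#' `ROSM880105` (hydrophilicity of polar side chains).
#'
#' @return A tibble with columns `method` (`"svm_rfe"`/`"rf_is"`),
#'   `scale_id` and `description`.
#' @export
#' @examples
#' dplyr::count(proa_subsets(), method)
proa_subsets <- function() {
  tibble::tribble(
    ~method, ~scale_id, ~description,
    "svm_rfe", "ROSM880105", "Hydrophilicity of polar amino-acid side chains",
    "svm_rfe", "RICJ880117", "Relative preference in alpha helices",
    "svm_rfe", "VENT840101", "Hydrophobicity (bitter taste of L-amino acids)",
    "svm_rfe", "ROBB760110", "Conformational preference, middle of turn",
    "svm_rfe", "PONP800105", "Surrounding hydrophobicity in beta-sheet",
    "svm_rfe", "ZIMJ680101", "Hydrophobicity by statistical methods",
    "svm_rfe", "PRAM820103", "Shape and surface features of globular proteins",
    "rf_is",   "GUYH850101", "Partition energy",
    "rf_is",   "VHEG790101", "Transfer free energy to lipophilic phase",
    "rf_is",   "ROSM880105", "Hydrophilicity of polar amino-acid side chains",
    "rf_is",   "CASG920101", "Hydrophobicity from native protein structures",
    "rf_is",   "PONP800107", "Accessibility reduction ratio",
    "rf_is",   "WILM950102", "Hydrophobicity coefficient in RP-HPLC",
    "rf_is",   "X15925383",  "Aggregation propensity (Zyggregator P_agg, pH 7)",
    "rf_is",   "LEVM780102", "Normalized frequency of beta-sheet",
    "rf_is",   "PALJ810111", "Normalized frequency of beta-sheet",
    "rf_is",   "PRAM900103", "Relative frequency of beta-sheet in signal and nascent peptides"
  )
}
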