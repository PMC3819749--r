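# ggplot2 views of the three result types: elimination traces (error vs
# subset size), propensity profiles with called regions, and ROC curves.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an elimination trace
#'
#' Error (classification or out-of-bag) against the number of surviving
#' features, on a reversed log axis so elimination runs left to right,
#' with a ribbon of one dispersion unit where available.
#'
#' @param object An `elim_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot elim_trace
#' @export
autoplot.elim_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n_features, y = .data$error))
  if (any(!is.na(df$dispersion))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$error - .data$dispersion,
        ymax = .data$error + .data$dispersion
      ),
      alpha = 0.2
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(trans = "reverse") +
    ggplot2::labs(
      x = "Number of features",
      y = if (identical(attr(object, "method"), "rf_is")) {
        "Out-of-bag error"
      } else {
        "Cross-validated classification error"
      },
      title = paste0(
        "Feature elimination (",
        if (identical(attr(object, "method"), "rf_is")) "RF-IS" else "SVM-RFE",
        ")"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a propensity profile
#'
#' Per-residue propensity against sequence position, one panel per
#' protein, with the decision threshold and the called regions shaded.
#'
#' @param object A `propensity_profile`.
#' @param threshold Threshold line and region calling (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot propensity_profile
#' @export
autoplot.propensity_profile <- function(object, threshold = 0.5, ...) {
  df <- tibble::as_tibble(object)
  regions <- call_regions(object, threshold = threshold)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$score))
  if (nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(
        xmin = .data$start - 0.5, xmax = .data$end + 0.5,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$id), ncol = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Residue position", y = "Aggregation propensity",
      title = paste0("Sliding-window propensity profile (window ",
                     attr(object, "window"), ")")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve from out-of-fold scores
#'
#' @param x A `cv_result` from [nested_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_roc <- function(x, ...) {
  cur <- roc_curve(x$scores$score, x$scores$positive)
  ggplot2::ggplot(cur, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (%s CV), AUC = %.4f", x$scheme, x$auc)
    ) +
    ggplot2::theme_minimal()
}
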