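# broom-style accessors for fitted objects -------------------------------

#' Tidy the per-class metric panel of a cross-validated kNN fit
#'
#' @param x A `fall_knn_cv` object from [cross_validate()] or
#'   [fit_fall_knn()].
#' @param ... Unused.
#' @return A tibble with one row per (class, metric): columns `class`,
#'   `metric`, `value`.
#' @method tidy fall_knn_cv
#' @export
tidy.fall_knn_cv <- function(x, ...) {
  tidyr::pivot_longer(x$metrics$per_class, -"class",
                      names_to = "metric", values_to = "value")
}

#' One-row summary of a cross-validated kNN fit
#'
#' @inheritParams tidy.fall_knn_cv
#' @return A one-row tibble: `source`, `k`, `n_folds`, `n`, `accuracy`,
#'   `mcc`.
#' @method glance fall_knn_cv
#' @export
glance.fall_knn_cv <- function(x, ...) {
  cmt <- x$confusion
  tibble::tibble(
    source = x$source,
    k = x$k,
    n_folds = x$n_folds,
    n = cmt$tp + cmt$fn + cmt$fp + cmt$tn,
    accuracy = x$metrics$accuracy,
    mcc = x$metrics$mcc
  )
}

#' Plot the K-selection error curve of a fitted kNN classifier
#'
#' @param object A `fall_knn_cv` from [fit_fall_knn()] with `k = "auto"`,
#'   or any `fall_knn_cv` (falls back to a single point at its K).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fall_knn_cv
#' @export
autoplot.fall_knn_cv <- function(object, ...) {
  curve <- object$k_curve %||%
    tibble::tibble(k = object$k, accuracy = object$metrics$accuracy,
                   error = 1 - object$metrics$accuracy)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = curve[curve$k == object$k, ],
                        colour = "red", size = 3) +
    ggplot2::scale_x_continuous(breaks = curve$k) +
    ggplot2::labs(x = "K neighbors", y = "cross-validated error rate",
                  title = sprintf("K selection (%s source); chosen K = %d",
                                  object$source, object$k)) +
    ggplot2::theme_minimal()
}
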