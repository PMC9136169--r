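# Diagnostic plots --------------------------------------------------------

#' Plot a segmented gait trial
#'
#' Shows the filtered left/right series of one source with the detected
#' heel strikes marked, the visual analogue of checking the segmentation by
#' eye.
#'
#' @param trial One-row cohort tibble.
#' @param source Signal source to display.
#' @param ... Passed to [preprocess_trial()].
#' @return A ggplot object.
#' @export
plot_trial <- function(trial, source = "rss", ...) {
  fs <- trial$fs[[1]]
  sig <- trial$signal[[1]]
  sig_f <- sig
  for (col in c("lx", "ly", "lz", "rx", "ry", "rz")) {
    sig_f[[col]] <- lowpass_filter(sig[[col]], fs)
  }
  df <- tibble::tibble(
    t_s = rep(sig$t_s, 2),
    side = rep(c("left", "right"), each = nrow(sig)),
    value = c(source_series(sig_f, source, "left"),
              source_series(sig_f, source, "right"))
  )
  strikes <- dplyr::bind_rows(
    tibble::tibble(side = "left",
                   t_s = sig$t_s[detect_heel_strikes(sig_f$lx, fs)]),
    tibble::tibble(side = "right",
                   t_s = sig$t_s[detect_heel_strikes(sig_f$rx, fs)])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(data = strikes, ggplot2::aes(xintercept = .data$t_s),
                        colour = "red", linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~side, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = sprintf("%s acceleration (g)", source),
                  title = sprintf("%s %s: filtered signal and heel strikes",
                                  trial$participant_id[[1]], trial$trial_id[[1]])) +
    ggplot2::theme_minimal()
}

#' Plot the four NCC series of one trial
#'
#' One panel per comparison (LL, LR, RR, RL), the standard view of gait
#' stability (same-side) and symmetry (cross-side) over the sliding shift.
#'
#' @inheritParams plot_trial
#' @return A ggplot object.
#' @export
plot_ncc_series <- function(trial, source = "rss", ...) {
  pre <- preprocess_trial(trial, source = source, ...)
  sets <- build_ncc_sets(pre$left, pre$right)
  sets$kind <- factor(sets$kind, levels = c("LL", "LR", "RR", "RL"))
  ggplot2::ggplot(sets, ggplot2::aes(x = .data$t, y = .data$ncc)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~kind, ncol = 2) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "shift t (normalized samples)", y = "NCC coefficient",
                  title = sprintf("%s %s: NCC series (%s source)",
                                  trial$participant_id[[1]],
                                  trial$trial_id[[1]], source)) +
    ggplot2::theme_minimal()
}

#' Line chart of the gait-pattern feature distribution by class
#'
#' Plots each trial's 8-feature vector as one line across the feature axis,
#' colored by class, showing how the mean and variability features separate
#' recurrent fallers from non-fallers.
#'
#' @param features Feature tibble from [extract_gait_features()].
#' @return A ggplot object.
#' @export
plot_gait_features <- function(features) {
  long <- tidyr::pivot_longer(features, dplyr::all_of(gait_feature_names()),
                              names_to = "feature", values_to = "value")
  long$feature <- factor(long$feature, levels = gait_feature_names())
  long$id <- paste(long$participant_id, long$trial_id)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = .data$value,
                                     group = .data$id,
                                     colour = factor(.data$gait_label))) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_colour_manual(values = c(`0` = "#d95f02", `1` = "#1b9e77"),
                                 labels = c(`0` = "recurrent faller",
                                            `1` = "non-faller"),
                                 name = NULL) +
    ggplot2::labs(x = NULL, y = "feature value",
                  title = "Gait-pattern features by class") +
    ggplot2::theme_minimal()
}

#' Plot the K-selection error curve
#'
#' @param fit A `fall_knn_cv` object; see [autoplot.fall_knn_cv()].
#' @return A ggplot object.
#' @export
plot_k_selection <- function(fit) autoplot(fit)
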