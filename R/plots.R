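# ggplot2 views of the pipeline's objects.

#' @importFrom ggplot2 ggplot aes geom_line geom_tile geom_col facet_wrap
#'   facet_grid labs scale_fill_gradient2 position_dodge geom_errorbar
#'   theme_minimal
NULL

#' Plot an angle trace
#'
#' @param object an [angle_trace()].
#' @param ... unused.
#' @return a ggplot: the three DoF angles against time.
#' @export
autoplot.angle_trace <- function(object, ...) {
  df <- as_tibble(as.data.frame(object))
  df$time_s <- (seq_len(nrow(df)) - 1) / rate_hz(object)
  long <- tidyr::pivot_longer(df, dplyr::all_of(c("alpha1", "alpha2",
                                                  "alpha3")),
                              names_to = "dof", values_to = "angle_deg")
  ggplot(long, aes(x = .data$time_s, y = .data$angle_deg)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~dof, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = "angle (deg)") +
    theme_minimal()
}

#' Plot a multichannel EMG recording
#'
#' @param object an [emg_recording()].
#' @param max_points cap on plotted samples per channel (thinned evenly).
#' @param ... unused.
#' @return a ggplot with one facet per channel.
#' @export
autoplot.emg_recording <- function(object, max_points = 20000, ...) {
  df <- as_tibble(as.data.frame(object))
  df$time_s <- (seq_len(nrow(df)) - 1) / rate_hz(object)
  if (nrow(df) > max_points) {
    df <- df[unique(as.integer(round(
      seq(1, nrow(df), length.out = max_points)))), ]
  }
  long <- tidyr::pivot_longer(df, -dplyr::all_of("time_s"),
                              names_to = "channel", values_to = "amplitude")
  ggplot(long, aes(x = .data$time_s, y = .data$amplitude)) +
    geom_line(linewidth = 0.2) +
    facet_wrap(~channel, ncol = 1, strip.position = "right") +
    labs(x = "time (s)", y = "EMG (a.u.)") +
    theme_minimal()
}

#' Heatmap of the normalized position-generalization matrix
#'
#' @param object a `wrist_eval` from [run_pipeline()].
#' @param ... unused.
#' @return a ggplot: training x testing position tiles of mean normalized
#'   R^2, one facet per scenario (diagonal = 1 by construction).
#' @export
autoplot.wrist_eval <- function(object, ...) {
  pm <- object$position_matrix
  ggplot(pm, aes(x = .data$test_pos, y = .data$train_pos,
                 fill = .data$mean_r2_norm)) +
    geom_tile() +
    scale_fill_gradient2(midpoint = 1, limits = c(0, NA),
                         name = "R² / intra") +
    facet_wrap(~scenario) +
    labs(x = "testing position", y = "training position") +
    theme_minimal()
}

#' Bar chart of the positional-pooling effect
#'
#' @param x a `wrist_eval` from [run_pipeline()].
#' @return a ggplot comparing mean single-position and pooled-training
#'   R^2 per scenario.
#' @export
plot_pooling_comparison <- function(x) {
  stopifnot(inherits(x, "wrist_eval"))
  long <- tidyr::pivot_longer(
    x$pooling, dplyr::all_of(c("mean_single_pct", "mean_pooled_pct")),
    names_to = "training", values_to = "r2_pct")
  long$training <- ifelse(long$training == "mean_pooled_pct", "pooled",
                          "single position")
  ggplot(long, aes(x = .data$scenario, y = .data$r2_pct,
                   fill = .data$training)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "multivariate R² (%)") +
    theme_minimal()
}
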