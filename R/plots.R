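#' Plot a phase map
#'
#' Tile map of the instantaneous phase (or amplitude) at one sample, in
#' display orientation (row 1 on top).
#'
#' @param pms A [phase_map_series].
#' @param at Sample index (default 1).
#' @param what `"phase"` or `"amplitude"`.
#' @return A ggplot object.
#' @export
plot_phase_map <- function(pms, at = 1, what = c("phase", "amplitude")) {
  what <- match.arg(what)
  d <- tidy(pms, at = at)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                       fill = .data[[what]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = 1:8) +
    ggplot2::scale_x_continuous(breaks = 1:8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("t = %.3f s", d$t[1]), x = NULL, y = NULL)
  if (what == "phase") {
    p <- p + ggplot2::scale_fill_gradientn(
      colours = c("#2166ac", "#f7f7f7", "#b2182b", "#f7f7f7", "#2166ac"),
      limits = c(-pi, pi), name = "phase (rad)")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.phase_map_series <- function(object, at = 1, ...) {
  plot_phase_map(object, at = at)
}

#' @exportS3Method ggplot2::autoplot
autoplot.reference_library <- function(object, ...) {
  d <- as_tibble(object) %>%
    tidyr::pivot_longer(c("rho_44", "rho_14", "rho_41"),
                        names_to = "origin", values_to = "rho")
  ggplot2::ggplot(d, ggplot2::aes(.data$template_id, .data$rho,
                                  colour = .data$origin)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(-0.3, 0.3), linetype = 2,
                        colour = "grey40") +
    ggplot2::facet_wrap(~kind, scales = "free_x") +
    ggplot2::labs(x = "wave type", y = expression(rho[c]),
                  title = "Reference-library fingerprints (chance zone dashed)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.wave_count_timecourse <- function(object, ...) {
  sig <- object %>% filter(.data$significant)
  ggplot2::ggplot(object, ggplot2::aes(.data$t_rel, .data$mean_count)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = sig,
                        ggplot2::aes(y = min(object$mean_count) - 0.02),
                        shape = 16, size = 0.8, colour = "red") +
    ggplot2::geom_vline(xintercept = c(0, 0.5, 1, 3), linetype = 3) +
    ggplot2::labs(x = "time from fixation (s)", y = "mean wave count",
                  title = "Wave-count timecourse (dots: p < 0.01 vs baseline)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.rho_histograms <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 0.3
  sig <- object %>% filter(.data$significant)
  ggplot2::ggplot(object, ggplot2::aes(.data$bin_mid)) +
    ggplot2::annotate("rect", xmin = -thr, xmax = thr, ymin = -Inf,
                      ymax = Inf, alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = .data$prop_baseline),
                       colour = "#b2182b") +
    ggplot2::geom_line(ggplot2::aes(y = .data$prop_epoch),
                       colour = "#1b7837") +
    ggplot2::geom_point(data = sig, ggplot2::aes(y = 0), colour = "blue",
                        size = 0.8) +
    ggplot2::facet_wrap(~epoch) +
    ggplot2::labs(x = expression(rho[c]), y = "proportion of instants",
                  title = "Epoch (green) vs baseline (red) correlation histograms")
}

#' @exportS3Method ggplot2::autoplot
autoplot.bias_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_mid)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$d_positive), colour = "#b2182b") +
    ggplot2::geom_line(ggplot2::aes(y = .data$d_negative), colour = "#2166ac") +
    ggplot2::geom_vline(xintercept = c(0, 0.5, 1, 3), linetype = 3) +
    ggplot2::labs(x = "time from fixation (s)",
                  y = "exceedance fraction - baseline",
                  title = "Direction bias (red: positive, blue: negative)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.direction_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$bin_mid_deg, .data$prop)) +
    ggplot2::geom_col(width = diff(object$bin_mid_deg[1:2]),
                      fill = "#4393c3") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, 45)) +
    ggplot2::labs(x = NULL, y = "proportion",
                  title = "Wave direction histogram")
}

#' @exportS3Method ggplot2::autoplot
autoplot.standing_wave_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$phase_sd, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = attr(object, "cutoff"), linetype = 2) +
    ggplot2::labs(x = "phase circular SD (rad)", y = "instants",
                  title = "Standing vs traveling phase variance")
}
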