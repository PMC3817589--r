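#' Plot a gridded CTD section
#'
#' Tile plot of a bin-averaged parameter over sites (along-fjord order) and
#' depth, depth increasing downwards as in an oceanographic section.
#'
#' @param grid Output of [grid_section()].
#' @param parameter Which parameter to draw (default: first present).
#' @return A ggplot object.
#' @export
plot_section <- function(grid, parameter = NULL) {
  stop_not_df(grid, "grid")
  parameter <- parameter %||% as.character(grid$parameter[1])
  df <- grid[grid$parameter == parameter, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$bin_centre_m,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "Site (along fjord)", y = "Depth (m)",
                  fill = parameter,
                  title = sprintf("Section: %s", parameter)) +
    ggplot2::theme_minimal()
}

#' Plot a binned quantity against depth per site
#'
#' Depth-profile scatter of one per-bin column, one colour per site, depth
#' increasing downwards, with an optional horizontal line at the break.
#'
#' @param bins An `rov_bins` tibble from [bin_frames()].
#' @param var Column to plot (default `"abundance"`).
#' @param break_depth_m Optional break depth to mark.
#' @return A ggplot object.
#' @export
plot_depth_bins <- function(bins, var = "abundance", break_depth_m = NULL) {
  stop_not_df(bins, "bins")
  require_cols(bins, c("bin_centre_m", var), "bins")
  p <- ggplot2::ggplot(bins, ggplot2::aes(x = .data[[var]],
                                          y = .data$bin_centre_m,
                                          colour = .data$site)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = var, y = "Depth (m)", colour = "Site") +
    ggplot2::theme_minimal()
  if (!is.null(break_depth_m)) {
    p <- p + ggplot2::geom_hline(yintercept = break_depth_m,
                                 linetype = "dotted", colour = "red")
  }
  p
}

#' Autoplot a break test
#'
#' Shows the per-bin values above and below the break as jittered points
#' with group means, the visual counterpart of the rank-sum/permutation
#' comparison.
#'
#' @param object A `break_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.break_test <- function(object, ...) {
  df <- tibble::tibble(
    group = factor(rep(c("above break", "below break"),
                       c(object$n_above, object$n_below)),
                   levels = c("above break", "below break")),
    value = c(object$above, object$below))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "red") +
    ggplot2::labs(
      y = object$response, x = NULL,
      title = sprintf("%s split at %g m (perm. p = %.3g)",
                      object$response, object$break_depth_m,
                      object$permutation$p_value)) +
    ggplot2::theme_minimal()
}
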