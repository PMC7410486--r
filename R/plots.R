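#' Plot an abundance series
#'
#' Trajectories of all species on a log10 abundance axis.
#'
#' @param object an `abundance_series`.
#' @param max_species at most this many species (highest mean abundance) are
#'   drawn. Default 30.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.abundance_series <- function(object, max_species = 30, ...) {
  mu <- colMeans(series_matrix(object))
  keep <- names(sort(mu, decreasing = TRUE))[seq_len(min(max_species, length(mu)))]
  long <- tidyr::pivot_longer(object[, c("time", keep)], -"time",
                              names_to = "species", values_to = "abundance")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$abundance,
                                     group = .data$species,
                                     color = .data$species)) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "abundance")
}

#' Plot a rank abundance profile
#'
#' @param profile a tibble from [rank_abundance()].
#' @return A ggplot object (log10 abundance vs rank).
#' @export
plot_rank_abundance <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$rank, .data$mean_abundance)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "mean abundance")
}

#' Plot noise color against mean abundance
#'
#' @param colors a tibble from [noise_color()].
#' @return A ggplot object.
#' @export
plot_noise_color <- function(colors) {
  ggplot2::ggplot(colors, ggplot2::aes(.data$mean_abundance, .data$slope,
                                       color = .data$color)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_color_manual(values = c(white = "grey70", pink = "pink3",
                                           brown = "tan4", black = "black")) +
    ggplot2::labs(x = "mean abundance", y = "PSD slope (noise color)")
}

#' Plot the difference-scaling fit
#'
#' @param object a `diff_scaling` object.
#' @param ... unused.
#' @return A ggplot object of log-log jump size vs mean abundance with the
#'   fitted line.
#' @export
autoplot.diff_scaling <- function(object, ...) {
  d <- dplyr::filter(object$data, .data$mean_abundance > 0,
                     .data$mean_abs_diff > 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$mean_abundance, .data$mean_abs_diff)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean abundance", y = "mean |successive difference|",
                  subtitle = sprintf("slope = %.2f", object$slope))
}

#' Plot a noise-color calibration curve
#'
#' @param object a `color_calibration` object.
#' @param ... unused.
#' @return A ggplot object: mean fitted slope (with dispersion ribbon) and
#'   the monotone fit against log10(g dt).
#' @export
autoplot.color_calibration <- function(object, ...) {
  tbl <- object$table
  ggplot2::ggplot(tbl, ggplot2::aes(.data$log10_gdt, .data$mean_slope)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_slope - .data$sd_slope,
                                      ymax = .data$mean_slope + .data$sd_slope),
                         alpha = 0.2) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_slope)) +
    ggplot2::labs(x = "log10(g * delta_t)", y = "PSD slope (noise color)")
}
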