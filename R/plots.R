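#' Plot a time-course report
#'
#' Mean nerve-fiber density per day with SD error bars, the standard
#' presentation of an innervation time course.
#'
#' @param object An [timecourse_report()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.innerva_timecourse <- function(object, ...) {
  s <- object$summaries
  ggplot2::ggplot(s, ggplot2::aes(x = .data$day, y = .data$mean_density)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_density - .data$sd_density,
      ymax = .data$mean_density + .data$sd_density)) +
    ggplot2::labs(x = "day post-wounding",
                  y = expression("nerve fiber density (pixels/mm"^2 * ")"),
                  title = sprintf("Innervation time course (%s)",
                                  object$compartment)) +
    ggplot2::theme_minimal()
}

#' Plot the density vs re-epithelialization correlation
#'
#' Per-day mean density against per-day mean re-epithelialization percentage
#' with the OLS fit and its coefficient of determination.
#'
#' @param report An [timecourse_report()] result.
#' @return A ggplot object.
#' @export
plot_density_correlation <- function(report) {
  stopifnot(inherits(report, "innerva_timecourse"))
  j <- report$joint
  ggplot2::ggplot(j, ggplot2::aes(x = .data$mean_percent,
                                  y = .data$mean_density)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::annotate("text", x = min(j$mean_percent), y = max(j$mean_density),
                      hjust = 0, vjust = 1,
                      label = sprintf("R^2 == %.3f", report$fit$r_squared),
                      parse = TRUE) +
    ggplot2::labs(x = "re-epithelialization (%)",
                  y = expression("mean nerve fiber density (pixels/mm"^2 * ")")) +
    ggplot2::theme_minimal()
}

#' Display a synthetic section
#'
#' Renders the red (PGP9.5) channel as a raster, optionally outlining the
#' ground-truth fiber mask.
#'
#' @param object A [generate_section()] result.
#' @param show_truth Overlay ground-truth fiber pixels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synthetic_section <- function(object, show_truth = FALSE, ...) {
  px <- get_channel(object$image, "pgp95_red")$pixels
  df <- tibble::tibble(
    row = rep(seq_len(nrow(px)), times = ncol(px)),
    col = rep(seq_len(ncol(px)), each = nrow(px)),
    intensity = as.vector(px))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "red") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (show_truth) {
    tr <- which(object$fiber_mask, arr.ind = TRUE)
    p <- p + ggplot2::annotate("point", x = tr[, 2], y = -tr[, 1],
                               size = 0.1, colour = "white", alpha = 0.3)
  }
  p
}
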