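# ggplot2 visualisations -------------------------------------------------------

#' Plot a rosette ROI over its intensity image
#'
#' @param object A [rosette_roi()].
#' @param channel Optional [image_channel()] to underlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rosette_roi <- function(object, channel = NULL, ...) {
  px <- object$grid$pixel_size_um
  lab <- matrix(NA_character_, nrow(object$body), ncol(object$body))
  lab[object$body] <- "Body"
  lab[object$ribbon] <- "Ribbon"
  d <- tibble(
    x = rep(seq_len(ncol(lab)) - 0.5, each = nrow(lab)) * px,
    y = rep(seq_len(nrow(lab)) - 0.5, times = ncol(lab)) * px,
    roi = as.vector(lab),
    intensity = if (is.null(channel)) NA_real_ else as.vector(channel$data)
  )
  pl <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y))
  if (!is.null(channel))
    pl <- pl + ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white")
  pl +
    ggplot2::geom_raster(data = dplyr::filter(d, !is.na(.data$roi)),
                         ggplot2::aes(alpha = .data$roi),
                         fill = "tomato") +
    ggplot2::scale_alpha_manual(values = c(Body = 0.35, Ribbon = 0.7),
                                name = "ROI") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)")
}

#' Bar/jitter plot of a colocalization report
#'
#' @param object An `oq_coloc_report` from [coloc_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.oq_coloc_report <- function(object, ...) {
  d <- dplyr::filter(object$table, .data$channel_a == "target")
  ggplot2::ggplot(d, ggplot2::aes(.data$region, .data$percent)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey80",
                          colour = "grey30") +
    ggplot2::geom_jitter(width = 0.1, size = 1) +
    ggplot2::facet_wrap(~ channel_b) +
    ggplot2::labs(y = "TVC (% of target volume)", x = NULL)
}

#' Group comparison plot for a report
#'
#' Boxplot of the grouped measurements behind an ANOVA/Tukey report.
#'
#' @param object An `oq_group_report` from [group_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.oq_group_report <- function(object, ...) {
  d <- object$anova$data
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, size = 1, alpha = 0.6) +
    ggplot2::labs(
      x = NULL, y = "value",
      subtitle = sprintf("one-way ANOVA: F(%d, %d) = %.3g, p = %.3g",
                         object$anova$df_between, object$anova$df_within,
                         object$anova$statistic, object$anova$p_value))
}
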