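# ggplot2 visualizations for the main result types.

raster_df <- function(m, value = "value") {
  d <- dim(m)
  out <- tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1])
  )
  out[[value]] <- as.vector(m)
  out
}

#' @describeIn fit_biexponential Decay histogram with the fitted model
#'   overlaid on a log-count scale.
#' @param object,x A fitted object.
#' @param ... Ignored.
#' @method autoplot biexp_fit
#' @export
autoplot.biexp_fit <- function(object, ...) {
  d <- tibble(
    t_ns = bin_centers(object$hist),
    counts = object$hist$counts,
    fitted = object$fitted
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_ns)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$counts), size = 0.6,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "#d55e00") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time (ns)", y = "photon counts",
      title = sprintf("tau1 = %.3g ns, tau2 = %.3g ns (%s)",
                      object$tau1_ns, object$tau2_ns, object$flag)
    )
}

#' @describeIn decay_histogram Bar plot of counts over time.
#' @param object,x A decay histogram.
#' @param ... Ignored.
#' @method autoplot decay_histogram
#' @export
autoplot.decay_histogram <- function(object, ...) {
  d <- tibble(t_ns = bin_centers(object), counts = object$counts)
  ggplot2::ggplot(d, ggplot2::aes(.data$t_ns, .data$counts)) +
    ggplot2::geom_col(width = object$bin_width_ns) +
    ggplot2::labs(x = "time (ns)", y = "photon counts")
}

#' @describeIn segment_er Label image rendered with one color per class.
#' @param object,x A segmentation.
#' @param ... Ignored.
#' @method autoplot er_segmentation
#' @export
autoplot.er_segmentation <- function(object, ...) {
  d <- raster_df(object$label_image)
  d$class <- factor(c("background", "tubule", "sheet")[d$value + 1L],
                    levels = c("background", "tubule", "sheet"))
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(background = "grey15",
                                          tubule = "#2e6f40",
                                          sheet = "#e69f00")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}

#' @describeIn orientation_field Axial angle map (0-90 degrees from
#'   vertical), masked pixels only.
#' @param object,x An orientation field.
#' @param ... Ignored.
#' @method autoplot orientation_field
#' @export
autoplot.orientation_field <- function(object, ...) {
  d <- raster_df(object$angle_image, "angle_deg")
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data$angle_deg)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 90), na.value = "grey10") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "angle (deg)")
}

#' @describeIn fit_lifetime_map Long-lifetime map with gated pixels blank.
#' @param object,x A lifetime map.
#' @param ... Ignored.
#' @method autoplot lifetime_map
#' @export
autoplot.lifetime_map <- function(object, ...) {
  d <- raster_df(object$tau1_image, "tau1_ns")
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data$tau1_ns)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey10") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "tau1 (ns)")
}

#' @describeIn soce_trace Trace with phase boundaries marked.
#' @param object,x A SOCE trace.
#' @param ... Ignored.
#' @method autoplot soce_trace
#' @export
autoplot.soce_trace <- function(object, ...) {
  pm <- attr(object, "phase_marks")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$time_s, .data$F)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = unname(pm), linetype = "dashed",
                        color = "grey50") +
    ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)")
}
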