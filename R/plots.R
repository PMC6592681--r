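#' Plot an angular histogram of division angles
#'
#' @param hist Data frame from [angular_histogram()] (or a numeric vector
#'   of angles, binned at 10 degrees).
#' @return A ggplot object.
#' @export
plot_angular_histogram <- function(hist) {
  if (is.numeric(hist)) hist <- angular_histogram(hist)
  mid <- (hist$bin_start + hist$bin_end) / 2
  df <- data.frame(mid = mid, count = hist$count)
  ggplot2::ggplot(df, ggplot2::aes(x = mid, y = count)) +
    ggplot2::geom_col(width = diff(mid[1:2]) * 0.92, fill = "grey35") +
    ggplot2::scale_x_continuous(breaks = seq(0, 90, 30), limits = c(0, 90)) +
    ggplot2::labs(x = "division angle (deg)", y = "divisions") +
    ggplot2::theme_minimal()
}

#' Rose plot of cell polarity axes
#'
#' Axial data are mirrored across 180 degrees for display, the usual
#' rose-diagram convention for nematic polarity.
#'
#' @param cells Data frame with `axis_deg` (and `magnitude` if weighted).
#' @param bin_width_deg Bin width in degrees.
#' @param weighted Weight bins by per-cell magnitude.
#' @param mean_line Draw the tissue average magnitude/direction.
#' @return A ggplot object.
#' @export
plot_rose <- function(cells, bin_width_deg = 15, weighted = FALSE,
                      mean_line = TRUE) {
  rh <- rose_histogram(cells, bin_width_deg, weighted)
  df <- rbind(
    data.frame(mid = (rh$bin_start + rh$bin_end) / 2, weight = rh$weight),
    data.frame(mid = (rh$bin_start + rh$bin_end) / 2 + 180, weight = rh$weight)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = mid, y = weight)) +
    ggplot2::geom_col(width = bin_width_deg * 0.95, fill = "grey40") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 330, 30)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (mean_line && nrow(cells)) {
    tp <- tissue_polarity(cells)
    r <- tp$magnitude / max(cells$magnitude, 1e-12) * max(df$weight)
    seg <- data.frame(x = c(tp$axis_deg, tp$axis_deg + 180), xend = c(tp$axis_deg, tp$axis_deg + 180),
                      y = 0, yend = r)
    p <- p + ggplot2::geom_segment(data = seg,
                                   ggplot2::aes(x = x, xend = xend, y = y, yend = yend),
                                   color = "red", linewidth = 1)
  }
  p
}

#' Height:width ratio versus division angle
#'
#' @param per_event Data frame from [hertwig_alignment()] (`$per_event`).
#' @return A ggplot object.
#' @export
plot_hw_vs_angle <- function(per_event) {
  df <- per_event
  df$category <- factor(df$category,
                        levels = c("planar", "oblique", "perpendicular"))
  ggplot2::ggplot(df, ggplot2::aes(x = category, y = hw_ratio,
                                   color = angle_deg)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          color = "black", linewidth = 0.3) +
    ggplot2::labs(x = "division orientation", y = "interphase H:W",
                  color = "angle (deg)") +
    ggplot2::theme_minimal()
}
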