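# Plot builders: tolerance-range plots, Bland-Altman, paired boxplot,
# QQ plot, and contour-overlay figures. All return ggplot objects.

#' Tolerance-range plot of per-parameter biases
#'
#' Grey bars show the tolerance ranges, red segments the 95% confidence
#' intervals through the mean difference, light blue dots the individual
#' case differences.
#'
#' @param object A `cmr_bias` / `cmr_bias_table` tibble.
#' @param diffs Optional per-case difference table (`parameter`, `diff`)
#'   for the dot swarm.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cmr_bias <- function(object, diffs = NULL, ...) {
  b <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(b, ggplot2::aes(x = .data$parameter))
  if (any(!is.na(b$tolerance_half_width))) {
    p <- p + ggplot2::geom_linerange(
      data = b[!is.na(b$tolerance_half_width), ],
      ggplot2::aes(ymin = -.data$tolerance_half_width,
                   ymax = .data$tolerance_half_width),
      linewidth = 8, colour = "grey80")
  }
  if (!is.null(diffs)) {
    p <- p + ggplot2::geom_jitter(
      data = diffs, ggplot2::aes(y = .data$diff),
      width = 0.12, height = 0, size = 0.8, colour = "lightblue3")
  }
  p +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ci_low,
                                         ymax = .data$ci_high),
                            colour = "red", linewidth = 1) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_diff), colour = "red",
                        size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "reader1 - reader2 difference",
                  title = "Bias 95% CI vs tolerance range") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cmr_study <- function(object, ...) {
  autoplot.cmr_bias(object$bias, diffs = object$diffs, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' @param pairs Data frame with `v1`, `v2` (and optionally `case_id`).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(pairs, title = "Bland-Altman") {
  ba <- bland_altman(pairs)
  ggplot2::ggplot(ba$points, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "red") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of readers", y = "reader1 - reader2",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Paired boxplot with per-case connecting segments
#'
#' Each case appears as a segment from its reader-1 to its reader-2
#' value; near-vertical segments are small deviations, flatter segments
#' larger ones.
#'
#' @inheritParams plot_bland_altman
#' @return A ggplot object.
#' @export
plot_paired <- function(pairs, title = "Paired values") {
  pd <- plot_data(pairs)$paired
  long <- tidyr::pivot_longer(pd, c("v1", "v2"), names_to = "reader",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$reader, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_line(ggplot2::aes(group = .data$case_id), colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "value", title = title) +
    ggplot2::theme_minimal()
}

#' Normal QQ plot of paired differences
#'
#' @inheritParams plot_bland_altman
#' @return A ggplot object.
#' @export
plot_qq <- function(pairs, title = "QQ plot of differences") {
  qq <- plot_data(pairs)$qq
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$theoretical, y = .data$sample)) +
    ggplot2::geom_point() +
    ggplot2::geom_qq_line(data = tibble::tibble(sample = qq$sample),
                          ggplot2::aes(sample = .data$sample),
                          inherit.aes = FALSE) +
    ggplot2::labs(x = "normal quantiles", y = "difference quantiles",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Contour overlay figure for one slice
#'
#' Rasterises both readers' regions for a contour type and colours
#' reader-1-only pixels red, reader-2-only blue, and agreement green.
#'
#' @param pair A [pair_cases()] result.
#' @param slice_index,phase Which slice to draw.
#' @param ctype Contour type (including `"myo"`).
#' @param res Raster resolution in pixel units.
#' @return A ggplot object.
#' @export
plot_contour_overlay <- function(pair, slice_index, phase, ctype = "lv_endo",
                                 res = 0.5) {
  i <- which(pair$slice_index == slice_index & pair$phase == phase)
  if (!length(i)) stop("no such slice in pair", call. = FALSE)
  r1 <- slice_region(pair$slice_r1[[i[1]]], ctype)
  r2 <- slice_region(pair$slice_r2[[i[1]]], ctype)
  pts <- do.call(rbind, c(as_region(r1), as_region(r2)))
  if (is.null(pts)) stop("both readers lack contour '", ctype, "'", call. = FALSE)
  xr <- range(pts[, 1]) + c(-2, 2); yr <- range(pts[, 2]) + c(-2, 2)
  gx <- seq(xr[1], xr[2], by = res); gy <- seq(yr[1], yr[2], by = res)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  m1 <- if (is.null(r1)) rep(FALSE, nrow(grid)) else point_in_region(grid, r1)
  m2 <- if (is.null(r2)) rep(FALSE, nrow(grid)) else point_in_region(grid, r2)
  cls <- dplyr::case_when(m1 & m2 ~ "agreement", m1 ~ "reader1", m2 ~ "reader2",
                          TRUE ~ NA_character_)
  df <- tibble::tibble(col = grid[, 1], row = grid[, 2], class = cls)
  df <- df[!is.na(df$class), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(reader1 = "red", reader2 = "blue",
                                          agreement = "green3")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice %d %s: %s", slice_index, phase, ctype),
                  x = "col", y = "row") +
    ggplot2::theme_minimal()
}
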