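#' Four-model overlay figure for one biomarker
#'
#' Reproduces the standard diagnostic overlay: observations coloured by
#' diagnostic group, horizontal per-group mean segments, the global robust
#' regression line, the two-regime robust fit split at the combined
#' change-point (vertical dashed line), and the robust lowess curve.
#'
#' @param table cohort table.
#' @param biomarker biomarker column.
#' @param result a `biomarker_result` for that biomarker (supplies the
#'   change-point and lowess curve).
#' @return a ggplot object.
#' @export
plot_biomarker_fit <- function(table, biomarker, result) {
  ok <- is.finite(table$camcog) & is.finite(table[[biomarker]])
  dat <- data.frame(camcog = table$camcog[ok], y = table[[biomarker]][ok],
                    group = table$group[ok])
  cp <- result$changepoint$combined

  grp_means <- do.call(rbind, lapply(split(dat, dat$group), function(d) {
    if (nrow(d) == 0) return(NULL)
    data.frame(group = d$group[1], xmin = min(d$camcog),
               xmax = max(d$camcog), mean = mean(d$y))
  }))

  global <- mm_regression(dat$camcog, dat$y)
  gl <- data.frame(camcog = range(dat$camcog))
  gl$y <- global$coefficients[1] + global$coefficients[2] * gl$camcog

  seg_line <- function(sel) {
    d <- dat[sel, ]
    if (nrow(d) < 3 || length(unique(d$camcog)) < 2) return(NULL)
    fit <- mm_regression(d$camcog, d$y)
    xr <- range(d$camcog)
    data.frame(camcog = xr,
               y = fit$coefficients[1] + fit$coefficients[2] * xr)
  }
  seg_above <- seg_line(dat$camcog > cp)
  seg_below <- seg_line(dat$camcog <= cp)

  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$camcog, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$group), alpha = 0.6) +
    ggplot2::scale_shape_manual(values = c("non-demented" = 16, "AD" = 0)) +
    ggplot2::geom_segment(data = grp_means,
                          ggplot2::aes(x = .data$xmin, xend = .data$xmax,
                                       y = .data$mean, yend = .data$mean),
                          colour = "blue", linetype = "dotdash",
                          inherit.aes = FALSE) +
    ggplot2::geom_line(data = gl, colour = "darkgreen",
                       linetype = "dotted") +
    ggplot2::geom_line(data = result$lowess,
                       ggplot2::aes(y = .data$fit),
                       colour = "red", linetype = "dashed") +
    ggplot2::geom_vline(xintercept = cp, linetype = "dashed") +
    ggplot2::labs(x = "CAMCOG score", y = paste0(biomarker, " (pg/mL)"),
                  title = sprintf("%s: change-point at CAMCOG %.1f",
                                  biomarker, cp)) +
    ggplot2::theme_minimal()
  if (!is.null(seg_above))
    p <- p + ggplot2::geom_line(data = seg_above, colour = "black",
                                linewidth = 0.9)
  if (!is.null(seg_below))
    p <- p + ggplot2::geom_line(data = seg_below, colour = "black",
                                linewidth = 0.9)
  p
}
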