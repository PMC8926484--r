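# ggplot2 displays for the main result types. Plots are deliberately plain:
# one readable default each, themeable by the caller.

#' @export
autoplot.herbqc_calibration <- function(object, n_points = 50, ...) {
  grid <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    m <- exp(seq(log(object$range_low_ug[i]), log(object$range_high_ug[i]),
                 length.out = n_points))
    tibble(marker = object$marker[i], mass_ug = m,
           area = exp(object$intercept[i] + object$slope[i] * log(m)))
  })
  ggplot2::ggplot(grid, ggplot2::aes(.data$mass_ug, .data$area,
                                     colour = .data$marker)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "injected mass (µg)", y = "peak area",
                  colour = "marker",
                  title = "Log-log calibration curves")
}

#' @export
autoplot.sqfm_eval <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$p_m_pct, .data$s_m,
                                   label = .data$batch,
                                   colour = factor(.data$grade))) +
    ggplot2::geom_vline(xintercept = 100, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(size = .data$alpha)) +
    ggplot2::geom_text(vjust = -1, show.legend = FALSE) +
    ggplot2::labs(x = "macro-quantitative similarity P_m (%)",
                  y = "macro-qualitative similarity S_m",
                  colour = "grade", size = "α",
                  title = "SQFM evaluation of batches")
}

#' @export
autoplot.batch_hca <- function(object, ...) {
  seg <- dendrogram_segments(object$hclust)
  labs <- tibble(x = seq_along(object$hclust$order),
                 label = object$labels[object$hclust$order])
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = labs$x, labels = labs$label) +
    ggplot2::labs(x = NULL, y = "merge height",
                  title = sprintf("HCA of batches (%s, %s linkage)",
                                  object$distance, object$linkage))
}

# x-position and segment set of an hclust tree, computed from merge/height.
dendrogram_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- numeric(n)
  leaf_x[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_y <- hc$height
  pos <- function(i) if (i < 0) c(leaf_x[-i], 0) else c(node_x[i], node_y[i])
  segs <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    a <- pos(hc$merge[i, 1]); b <- pos(hc$merge[i, 2])
    node_x[i] <- (a[1] + b[1]) / 2
    segs[[i]] <- tibble(
      x = c(a[1], b[1], a[1]), y = c(a[2], b[2], hc$height[i]),
      xend = c(a[1], b[1], b[1]), yend = c(hc$height[i], hc$height[i], hc$height[i]))
  }
  dplyr::bind_rows(segs)
}

#' Plot batch fingerprints as area profiles
#'
#' Line profile of common-peak areas per batch; a quick visual of scale and
#' shape differences between batches.
#'
#' @param fm A [fingerprint_matrix()].
#' @param log_area Plot areas on a log scale (default TRUE).
#' @return A ggplot object.
#' @export
plot_fingerprints <- function(fm, log_area = TRUE) {
  fm <- fingerprint_matrix(fm)
  long <- tidyr::pivot_longer(as_tibble(fm), -"batch_id",
                              names_to = "peak", values_to = "area")
  long$peak <- as.integer(sub("^p", "", long$peak))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$peak, .data$area,
                                          colour = .data$batch_id)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = unique(long$peak)) +
    ggplot2::labs(x = "common peak", y = "area", colour = "batch",
                  title = "Common-peak fingerprints")
  if (log_area) p <- p + ggplot2::scale_y_log10()
  p
}
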