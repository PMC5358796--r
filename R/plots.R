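#' Plot an angle histogram
#'
#' Column chart of the binned local-angle distribution of an interface.
#'
#' @param object An `angle_histogram` from [angle_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.angle_histogram <- function(object, ...) {
  mid <- (object$lower_deg + object$upper_deg) / 2
  df <- tibble::tibble(mid = mid, probability = object$probability,
                       width = object$upper_deg - object$lower_deg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$probability)) +
    ggplot2::geom_col(width = df$width * 0.9, fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = object$lower_deg) +
    ggplot2::labs(x = "local angle (degrees)", y = "probability",
                  title = "Distribution of local angles at the BCI") +
    ggplot2::theme_minimal()
}

#' Plot an angle-level co-occurrence matrix
#'
#' Heat map of the ALCM: mass near the diagonal means consecutive
#' interface pixels share similar orientations (high homogeneity).
#'
#' @param object An `alcm` matrix from [alcm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.alcm <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$probability <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "angle bin", y = "angle bin",
                  title = "Angle-level co-occurrence matrix") +
    ggplot2::theme_minimal()
}

#' Bar chart of a per-grade summary
#'
#' Mean +/- SE bars by subchondral bone grade, the standard presentation
#' of per-grade thickness and OARSI results.
#'
#' @param summary A tibble from [summarize_by_grade()].
#' @param ylab Axis label for the summarised measure.
#' @return A ggplot object.
#' @export
plot_grade_summary <- function(summary, ylab = "mean") {
  ggplot2::ggplot(summary, ggplot2::aes(x = factor(.data$bone_grade),
                                        y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::labs(x = "subchondral bone grade", y = ylab) +
    ggplot2::theme_minimal()
}

#' Descriptor-versus-OARSI regression plot
#'
#' Scatter of an interface descriptor against OARSI cartilage grade with
#' the fitted least-squares line.
#'
#' @param table A study-table tibble.
#' @param descriptor `"entropy_bits"` or `"homogeneity"`.
#' @return A ggplot object.
#' @export
plot_descriptor_regression <- function(table,
                                       descriptor = c("entropy_bits",
                                                      "homogeneity")) {
  descriptor <- match.arg(descriptor)
  df <- table[!is.na(table[[descriptor]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$oarsi,
                                   y = .data[[descriptor]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "OARSI grade", y = descriptor) +
    ggplot2::theme_minimal()
}
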