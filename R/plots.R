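#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a contact probability decay curve
#'
#' @param object A `ps_curve`.
#' @param ... Unused.
#' @return A ggplot (log-log P(s) vs genomic distance).
#' @export
autoplot.ps_curve <- function(object, ...) {
  dat <- object[object$valid & !is.na(object$p) & object$p > 0, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$s_mid, y = .data$p)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::scale_x_log10(labels = label_bp) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "genomic distance s",
      y = "contact probability P(s)"
    ) +
    ggplot2::theme_classic()
}

#' Plot a P(s) derivative curve
#'
#' Raw log-log slope (points) and its smoothed version (line), optionally
#' annotated with loop- and layer-size estimates.
#'
#' @param object A `deriv_curve`.
#' @param estimate Optional `loop_layer_estimate` to annotate.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.deriv_curve <- function(object, estimate = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$s_mid)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$slope_raw),
      size = 0.8, alpha = 0.5
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$slope_smooth), linewidth = 0.7) +
    ggplot2::scale_x_log10(labels = label_bp) +
    ggplot2::labs(
      x = "genomic distance s",
      y = "d log10 P(s) / d log10 s"
    ) +
    ggplot2::theme_classic()
  if (!is.null(estimate)) {
    p <- p +
      ggplot2::geom_vline(
        xintercept = c(estimate$loop_size, estimate$layer_size),
        linetype = "dotted"
      ) +
      ggplot2::annotate("text",
        x = estimate$loop_size, y = max(object$slope_smooth),
        label = "loop", hjust = -0.2, size = 3
      ) +
      ggplot2::annotate("text",
        x = estimate$layer_size, y = max(object$slope_smooth),
        label = "layer", hjust = -0.2, size = 3
      )
  }
  p
}

#' Plot per-mass focus counts
#'
#' Histogram of CENP-A foci per DNA mass, split by individualization call.
#'
#' @param records Tibble from [count_cenpa_foci()].
#' @return A ggplot.
#' @export
plot_foci_counts <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(
    x = .data$n_foci,
    fill = .data$individualized
  )) +
    ggplot2::geom_bar() +
    ggplot2::labs(
      x = "CENP-A foci per DNA mass", y = "masses",
      fill = "individualized\n(< 4 foci)"
    ) +
    ggplot2::theme_classic()
}

#' Plot grouped measurements by condition
#'
#' Per-nucleus values (jittered points) with replicate medians
#' superimposed, the layout used for condition-level intensity
#' comparisons.
#'
#' @param g Tibble with columns `condition`, `value` and optionally
#'   `replicate`.
#' @return A ggplot.
#' @export
plot_group_measurements <- function(g) {
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.35, size = 0.8) +
    ggplot2::theme_classic() +
    ggplot2::labs(x = NULL, y = "normalized intensity")
  if ("replicate" %in% names(g)) {
    med <- dplyr::summarise(
      dplyr::group_by(g, .data$condition, .data$replicate),
      value = stats::median(.data$value), .groups = "drop"
    )
    p <- p + ggplot2::geom_point(
      data = med, shape = 21, size = 2.5, fill = "black"
    )
  }
  p
}

label_bp <- function(x) {
  ifelse(x >= 1e6, paste0(x / 1e6, " Mb"),
    ifelse(x >= 1e3, paste0(x / 1e3, " kb"), paste0(x, " bp"))
  )
}
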