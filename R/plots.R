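#' Plot an adjustment chain
#'
#' Point estimates with confidence bars per correction stage, on a log10
#' scale; infinite upper bounds are drawn as open-ended arrows.
#'
#' @param object An `adjusted_estimate`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot adjusted_estimate
#' @export
autoplot.adjusted_estimate <- function(object, ...) {
  ch <- object$chain
  ch$stage <- factor(ch$stage, levels = ch$stage)
  ch$upper_capped <- ifelse(is.finite(ch$upper), ch$upper, NA_real_)
  ch$upper_open <- !is.na(ch$lower) & !is.finite(ch$upper)
  cap <- max(c(ch$point[is.finite(ch$point)], ch$upper_capped), na.rm = TRUE) * 3

  p <- ggplot2::ggplot(ch, ggplot2::aes(x = .data$stage, y = .data$point)) +
    ggplot2::geom_point(size = 2)
  if (any(!is.na(ch$lower))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper_capped), width = 0.15,
      na.rm = TRUE)
    if (any(ch$upper_open)) {
      p <- p + ggplot2::geom_segment(
        data = ch[ch$upper_open, ],
        ggplot2::aes(xend = .data$stage, y = .data$lower, yend = cap),
        arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "cm")),
        linetype = "dashed")
    }
  }
  p +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "correction stage",
                  y = if (object$path == "cohort") "effective size (Nb, then Ne)" else "generational Ne",
                  title = sprintf("%s-path bias-correction chain", object$path)) +
    ggplot2::theme_minimal()
}

#' Plot leave-one-out sensitivity of an LD estimate set
#'
#' Companion display for a set of estimates (e.g. across samples or
#' replicates): points with CI bars, `Inf` upper bounds open-ended.
#'
#' @param estimates A tibble with columns `label`, `estimate`, `ci_lower`,
#'   `ci_upper` (e.g. row-bound [tidy()] outputs with a label column).
#' @return A ggplot.
#' @export
plot_estimates <- function(estimates) {
  stopifnot(all(c("label", "estimate", "ci_lower", "ci_upper") %in% names(estimates)))
  est <- tidyr::pivot_longer(estimates, cols = "estimate", values_to = "point")
  est$upper_capped <- ifelse(is.finite(est$ci_upper), est$ci_upper, NA_real_)
  ggplot2::ggplot(est, ggplot2::aes(x = .data$label, y = .data$point)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower, ymax = .data$upper_capped),
                           width = 0.15, na.rm = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "effective size") +
    ggplot2::theme_minimal()
}
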