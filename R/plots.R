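#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Occlusal-view plot of a recognised arch
#'
#' Peaks, fitted jawline and labelled landmarks in the arch's horizontal
#' frame coordinates (transverse vs anteroposterior), occlusal view.
#'
#' @param object an `arch_recognition`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.arch_recognition <- function(object, ...) {
  pk <- object$peaks
  jl <- object$jawline
  tt <- seq(min(pk$t), max(pk$t), length.out = 200)
  curve <- tibble::tibble(t = tt, ap = jawline_ap(jl, tt))
  lm <- object$landmarks
  lm_fc <- frame_coordinates(as.matrix(lm[, c("x", "y", "z")]), object$frame)
  lm$t <- lm_fc[, "t"]
  lm$ap <- lm_fc[, "ap"]
  ggplot2::ggplot(pk, ggplot2::aes(x = .data$t, y = .data$ap)) +
    ggplot2::geom_path(data = curve, colour = "grey50", linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$spilled), alpha = 0.6) +
    ggplot2::geom_text(
      data = lm, ggplot2::aes(label = .data$tooth_type),
      size = 3, vjust = -0.8
    ) +
    ggplot2::geom_point(data = lm, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "transverse (mm)", y = "anteroposterior (mm)",
      shape = "spilled peak",
      title = sprintf("%s %s arch, occlusal view", object$jaw, object$dentition)
    ) +
    ggplot2::theme_minimal()
}

#' MHB scorecard plot
#'
#' Signed transverse displacement per scored tooth, coloured by ordinal
#' score, with the scoring breakpoints of the tooth's segment drawn as
#' reference lines.
#'
#' @param object an `mhb_scorecard`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mhb_scorecard <- function(object, ...) {
  sc <- object$scores
  sc$tooth_type <- factor(sc$tooth_type, levels = sc$tooth_type)
  ggplot2::ggplot(sc, ggplot2::aes(
    x = .data$tooth_type, y = .data$displacement,
    fill = factor(.data$score)
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30") +
    ggplot2::labs(
      x = NULL, y = "transverse displacement (mm, + buccal)",
      fill = "MHB score",
      title = sprintf("MHB scorecard (arch total %d)", as.integer(object$total))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Deviation report plot
#'
#' Mean landmark deviation per tooth class with the overall geometric mean
#' and its 95% confidence band.
#'
#' @param object a `deviation_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.deviation_report <- function(object, ...) {
  ggplot2::ggplot(
    object$by_class,
    ggplot2::aes(x = .data$class, y = .data$mean_mm)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::annotate("rect",
      xmin = -Inf, xmax = Inf,
      ymin = object$ci_lower, ymax = object$ci_upper, alpha = 0.2
    ) +
    ggplot2::geom_hline(yintercept = object$geometric_mean, linetype = 2) +
    ggplot2::labs(
      x = NULL, y = "mean deviation (mm)",
      title = sprintf(
        "Landmark deviation: geometric mean %.3f mm [%.3f, %.3f]",
        object$geometric_mean, object$ci_lower, object$ci_upper
      )
    ) +
    ggplot2::theme_minimal()
}
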