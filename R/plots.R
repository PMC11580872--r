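#' Plot a cue map
#'
#' Median ITD (or ILD) versus azimuth per band, with an interquartile-range
#' ribbon across subjects and, for ITD, the phase-ambiguity branches.
#'
#' @param object a `cue_map`.
#' @param cue `"itd"` or `"ild"`.
#' @param show_branches overlay the ambiguity branches (ITD only;
#'   default TRUE).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cue_map
#' @export
autoplot.cue_map <- function(object, cue = c("itd", "ild"),
                             show_branches = TRUE, ...) {
  cue <- match.arg(cue)
  s <- object$summary
  if (cue == "itd") {
    p <- ggplot2::ggplot(s, ggplot2::aes(.data$azimuth_deg, .data$itd_median))
    if (show_branches && nrow(object$branches) > 0) {
      p <- p + ggplot2::geom_line(
        data = object$branches,
        ggplot2::aes(y = .data$itd_us, group = .data$k),
        colour = "tan", linewidth = 0.4
      )
    }
    p <- p +
      ggplot2::geom_ribbon(
        ggplot2::aes(
          ymin = .data$itd_median - .data$itd_iqr / 2,
          ymax = .data$itd_median + .data$itd_iqr / 2
        ),
        alpha = 0.2
      ) +
      ggplot2::geom_line(linewidth = 0.8) +
      ggplot2::labs(x = "azimuth (deg)", y = "ITD (µs)")
  } else {
    p <- ggplot2::ggplot(s, ggplot2::aes(.data$azimuth_deg, .data$ild_median)) +
      ggplot2::geom_ribbon(
        ggplot2::aes(
          ymin = .data$ild_median - .data$ild_iqr / 2,
          ymax = .data$ild_median + .data$ild_iqr / 2
        ),
        alpha = 0.2
      ) +
      ggplot2::geom_line(linewidth = 0.8) +
      ggplot2::labs(x = "azimuth (deg)", y = "ILD (dB)")
  }
  p + ggplot2::facet_wrap(~band_hz, scales = "free_y",
                          labeller = ggplot2::label_both) +
    ggplot2::theme_minimal()
}

#' Plot pooled z-scored estimate curves
#'
#' Across-subject mean of the z-scored estimates (and their SDs) per ITD,
#' with percentile-bootstrap confidence ribbons.
#'
#' @param object a `normalized_summary` from [zscore_pool()], or a list of
#'   them (one per task) to overlay.
#' @param which `"mean"` or `"sd"` panel.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot normalized_summary
#' @export
autoplot.normalized_summary <- function(object, which = c("mean", "sd"),
                                        ...) {
  which <- match.arg(which)
  objs <- if (inherits(object, "normalized_summary")) list(object) else object
  d <- purrr::map_dfr(objs, function(o) {
    dplyr::mutate(o$pooled, task = o$task)
  })
  if (which == "mean") {
    ggplot2::ggplot(d, ggplot2::aes(.data$itd_us, .data$mean_z,
      colour = .data$task, fill = .data$task
    )) +
      ggplot2::geom_ribbon(
        ggplot2::aes(
          ymin = .data$mean_conf.low,
          ymax = .data$mean_conf.high
        ),
        alpha = 0.15, colour = NA
      ) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(
        x = "ITD (µs)",
        y = "mean estimate (z)"
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(.data$itd_us, .data$sd_z,
      colour = .data$task, fill = .data$task
    )) +
      ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$sd_conf.low, ymax = .data$sd_conf.high),
        alpha = 0.15, colour = NA
      ) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(
        x = "ITD (µs)",
        y = "SD of estimates (scaled)"
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot a fitted response sigmoid over its data
#'
#' @param object a `sigmoid_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot sigmoid_fit
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  grid <- tibble::tibble(
    itd_us = seq(min(object$data$itd_us), max(object$data$itd_us),
      length.out = 201
    )
  )
  grid$estimate <- object$fitted(grid$itd_us)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$itd_us, .data$estimate)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "darkgreen", linewidth = 0.9) +
    ggplot2::labs(x = "ITD (µs)", y = "azimuth estimate (deg)") +
    ggplot2::theme_minimal()
}

#' Plot a bias curve
#'
#' Top: perceived (sigmoid fit, with CI) and acoustic azimuth versus ITD.
#' Bottom (`which = "bias"`): their difference.
#'
#' @param object a `bias_curve` from [compute_bias_curve()].
#' @param which `"bias"` (default) or `"curves"`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot bias_curve
#' @export
autoplot.bias_curve <- function(object, which = c("bias", "curves"), ...) {
  which <- match.arg(which)
  if (which == "curves") {
    ggplot2::ggplot(object, ggplot2::aes(.data$itd_us)) +
      ggplot2::geom_ribbon(
        ggplot2::aes(
          ymin = .data$perceived_conf.low,
          ymax = .data$perceived_conf.high
        ),
        fill = "darkgreen", alpha = 0.15
      ) +
      ggplot2::geom_line(
        ggplot2::aes(y = .data$acoustic_deg, linetype = "acoustic"),
        colour = "black"
      ) +
      ggplot2::geom_line(
        ggplot2::aes(y = .data$perceived_deg, linetype = "perceived"),
        colour = "darkgreen"
      ) +
      ggplot2::labs(
        x = "ITD (µs)", y = "azimuth (deg)",
        linetype = NULL
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data$itd_us, .data$bias_deg)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 3) +
      ggplot2::geom_ribbon(
        ggplot2::aes(
          ymin = .data$bias_conf.low,
          ymax = .data$bias_conf.high
        ),
        fill = "darkgreen", alpha = 0.15
      ) +
      ggplot2::geom_line(colour = "darkgreen", linewidth = 0.9) +
      ggplot2::labs(x = "ITD (µs)", y = "azimuth bias (deg)") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
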