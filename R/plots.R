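#' Plot the reconstructed time course of phytomer development
#'
#' Fraction of final phytomer length against days after tip emergence,
#' visible and initial phases distinguished, with an optional fitted curve
#' overlaid.
#'
#' @param timecourse Time-course tibble (columns `age`, `f_L`, `phase`).
#' @param fit Optional `phyto_fit` whose curve to draw.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(timecourse, fit = NULL) {
  p <- ggplot2::ggplot(timecourse, ggplot2::aes(x = .data$age, y = .data$f_L,
                                                colour = .data$phase)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(x = "Days after tip emergence",
                  y = "Fraction of final phytomer length", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    crv <- fit$curve
    xr <- range(timecourse$age, na.rm = TRUE)
    xs <- seq(xr[1], xr[2], length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(age = xs, f_L = eval_sigmoid(crv, xs), phase = "fit"),
      colour = "black")
  }
  p
}

#' Plot final phytomer length against rank
#'
#' The rank profile of mature phytomer lengths (plateau then decline), per
#' treatment when available.
#'
#' @param dissection Dissection table.
#' @return A ggplot object.
#' @export
plot_rank_profile <- function(dissection) {
  d <- dplyr::filter(dissection, .data$maturity == "mature")
  mapping <- if ("treatment" %in% names(d)) {
    ggplot2::aes(x = .data$rank, y = .data$phytomer_length, colour = .data$treatment)
  } else {
    ggplot2::aes(x = .data$rank, y = .data$phytomer_length)
  }
  ggplot2::ggplot(d, mapping) +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::labs(x = "Phytomer rank", y = "Final phytomer length (mm)") +
    ggplot2::theme_minimal()
}

#' Plot within-phytomer coordination
#'
#' Component fractions of final phytomer length against the phytomer's own
#' fraction, faceted by component, optionally with reference curves.
#'
#' @param within Within-phytomer coordination table.
#' @param rules Optional [coordination_rules()] whose blade/sheath/internode
#'   curves to overlay.
#' @return A ggplot object.
#' @export
plot_coordination <- function(within, rules = NULL) {
  long <- within |>
    tidyr::pivot_longer(dplyr::all_of(c("blade_f", "sheath_f", "internode_f")),
                        names_to = "component", values_to = "fraction") |>
    dplyr::mutate(component = sub("_f$", "", .data$component))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$f_L, y = .data$fraction)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = "Fraction of final phytomer length",
                  y = "Component fraction of final phytomer length") +
    ggplot2::theme_minimal()
  if (!is.null(rules)) {
    xs <- seq(0.01, 1, length.out = 200)
    ref <- dplyr::bind_rows(
      tibble::tibble(component = "blade", f_L = xs,
                     fraction = eval_sigmoid(rules$blade, xs)),
      tibble::tibble(component = "sheath", f_L = xs,
                     fraction = eval_sigmoid(rules$sheath, xs)),
      tibble::tibble(component = "internode", f_L = xs,
                     fraction = eval_linear(rules$internode, xs))
    )
    p <- p + ggplot2::geom_line(data = ref, colour = "black")
  }
  p
}

#' Autoplot a curve fit
#'
#' @param object A `phyto_fit`.
#' @param ... Unused.
#' @return A ggplot of the points and fitted curve.
#' @exportS3Method ggplot2::autoplot
autoplot.phyto_fit <- function(object, ...) {
  d <- object$data
  xs <- seq(min(d$x), max(d$x), length.out = 200)
  ys <- if (inherits(object$curve, "sigmoid_curve")) eval_sigmoid(object$curve, xs)
        else eval_linear(object$curve, xs)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_line(data = tibble::tibble(x = xs, y = ys), colour = "black") +
    ggplot2::theme_minimal()
}
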