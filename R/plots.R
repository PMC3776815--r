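# ggplot2 visualisations for the main result types.

#' @describeIn bullying_fraction_curve Plot the bullying fraction against
#'   county obesity prevalence, faceted by inquiry class.
#' @param object A `bullying_curve`.
#' @param ... Unused.
#' @method autoplot bullying_curve
#' @export
autoplot.bullying_curve <- function(object, ...) {
  df <- object[!is.na(object$fraction), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$fraction)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_askers), alpha = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$term_class)) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(
      x = "County obesity prevalence (%)",
      y = "Fraction of askers with a later bullying post",
      size = "Askers"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn category_overexpression Dot plot of posting ratios by
#'   category and stratum; filled points mark significant over-expression.
#' @param object An `overexpression_result`.
#' @param ... Unused.
#' @method autoplot overexpression_result
#' @export
autoplot.overexpression_result <- function(object, ...) {
  df <- object[object$evaluable, ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$ratio, y = .data$category,
    colour = .data$overexpressed
  )) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$stratum)) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey30"), na.value = "grey70"
    ) +
    ggplot2::labs(
      x = "Posting ratio vs pooled askers", y = NULL,
      colour = "Over-expressed"
    ) +
    ggplot2::theme_minimal()
}

#' Median reported weight by age against the reference curve
#'
#' The checkable analogue of a reported-vs-reference weight figure: per
#' integer age and gender, the median extracted weight of askers overlaid
#' on the generator's reference median curve.
#'
#' @param records Asker records with `age`, `gender`, `weight_lb`.
#' @param model Anthropometric model supplying the reference curve.
#' @return A ggplot object.
#' @export
plot_weight_reference <- function(records, model = default_anthropometric_model()) {
  med <- records |>
    dplyr::group_by(.data$gender, .data$age) |>
    dplyr::summarise(median_weight = median(.data$weight_lb), .groups = "drop")
  ref <- reference_anthropometrics(med$age, med$gender, model)
  med$reference <- ref$weight_lb
  ggplot2::ggplot(med, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$reference), colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$median_weight)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gender)) +
    ggplot2::labs(
      x = "Age (years)", y = "Weight (lb)",
      title = "Median reported weight vs reference curve"
    ) +
    ggplot2::theme_minimal()
}
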