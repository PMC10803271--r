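# ggplot2 graphics for the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Kaplan-Meier plot for a survival stratification
#'
#' Step curves of the product-limit estimate per group with optional
#' confidence bands.
#'
#' @param object A `wga_survival`.
#' @param conf_int Draw confidence bands?
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wga_survival <- function(object, conf_int = TRUE, ...) {
  d <- km_curves(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Overall survival", colour = NULL,
                  subtitle = sprintf("HR %.2f (95%% CI %.2f-%.2f), log-rank p = %.3g",
                                     object$hazard_ratio, object$ci_low,
                                     object$ci_high, object$logrank_p)) +
    ggplot2::theme_minimal()
  if (conf_int) {
    p <- p + ggplot2::geom_step(ggplot2::aes(y = .data$lower), alpha = 0.35,
                                linetype = "dashed") +
      ggplot2::geom_step(ggplot2::aes(y = .data$upper), alpha = 0.35,
                         linetype = "dashed")
  }
  p
}

#' Signature exposure bar plot
#'
#' @param exposure A `signature_exposure`.
#' @param min_fraction Hide signatures below this fraction.
#' @return A ggplot.
#' @export
plot_signature_exposures <- function(exposure, min_fraction = 0.02) {
  d <- tidy(exposure) |> dplyr::filter(.data$exposure >= min_fraction)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$signature, -.data$exposure),
                                  y = .data$exposure)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Exposure fraction") +
    ggplot2::theme_minimal()
}

#' Actionability prevalence heatmap
#'
#' Gene-by-tumor-type prevalence tiles, indicated (directory) cells framed.
#'
#' @param object A `wga_actionability`.
#' @param variant_class Restrict to one variant class (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wga_actionability <- function(object, variant_class = NULL, ...) {
  d <- object$matrix
  if (!is.null(variant_class)) {
    d <- d[d$variant_class %in% variant_class, , drop = FALSE]
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tumor_type, y = .data$gene,
                                  fill = .data$prevalence,
                                  colour = .data$indicated)) +
    ggplot2::geom_tile(linewidth = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "magenta", `FALSE` = "steelblue")) +
    ggplot2::facet_wrap(~variant_class) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Prevalence", colour = "Indicated") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Co-occurrence bar plot
#'
#' CNA-event fraction among cases with vs without small variants, per gene.
#'
#' @param object A `wga_cooccurrence`.
#' @param max_q Show genes with q-value at or below this (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wga_cooccurrence <- function(object, max_q = Inf, ...) {
  d <- tidy(object) |>
    dplyr::filter(!.data$undefined, is.na(.data$q_value) | .data$q_value <= max_q) |>
    tidyr::pivot_longer(c("cna_frac_with", "cna_frac_without"),
                        names_to = "stratum", values_to = "fraction") |>
    dplyr::mutate(stratum = ifelse(.data$stratum == "cna_frac_with",
                                   "with small variant", "without small variant"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$fraction,
                                  fill = .data$stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Fraction of cases with CNA event", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
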