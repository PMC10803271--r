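# broom-style tidiers for fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stage-corrected survival stratification
#'
#' @param x A `wga_survival` object.
#' @param ... Unused.
#' @return One row per model term with hazard ratio and 95% CI.
#' @export
tidy.wga_survival <- function(x, ...) {
  co <- summary(x$cox)
  tibble::tibble(
    term = rownames(co$coefficients),
    estimate = co$coefficients[, "coef"],
    hazard_ratio = co$coefficients[, "exp(coef)"],
    std_error = co$coefficients[, "se(coef)"],
    p_value = co$coefficients[, "Pr(>|z|)"],
    conf_low = co$conf.int[, "lower .95"],
    conf_high = co$conf.int[, "upper .95"]
  )
}

#' @rdname tidy.wga_survival
#' @export
glance.wga_survival <- function(x, ...) {
  tibble::tibble(
    n = sum(x$groups$n),
    n_events = sum(x$groups$n_events),
    hazard_ratio = x$hazard_ratio,
    conf_low = x$ci_low,
    conf_high = x$ci_high,
    logrank_p = x$logrank_p,
    stage_corrected = x$stage_corrected,
    n_excluded_unknown_stage = x$n_excluded_unknown_stage
  )
}

#' Tidy a signature exposure fit
#'
#' @param x A `signature_exposure`.
#' @param ... Unused.
#' @return One row per signature with exposure fraction and fitted activity.
#' @export
tidy.signature_exposure <- function(x, ...) {
  tibble::tibble(
    signature = names(x$exposures),
    exposure = unname(x$exposures),
    activity = unname(x$activities)
  ) |>
    dplyr::arrange(dplyr::desc(.data$exposure))
}

#' @rdname tidy.signature_exposure
#' @export
glance.signature_exposure <- function(x, ...) {
  tibble::tibble(
    n_mutations = x$n_mutations,
    n_active_signatures = sum(x$exposures > 0),
    residual = x$residual
  )
}

#' Tidy a co-occurrence result
#'
#' @param x A `wga_cooccurrence`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.wga_cooccurrence <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "wga_cooccurrence")
  tibble::as_tibble(out)
}

#' Tidy an actionability summary
#'
#' @param x A `wga_actionability`.
#' @param ... Unused.
#' @return The prevalence matrix in long form.
#' @export
tidy.wga_actionability <- function(x, ...) {
  x$matrix
}

#' @rdname tidy.wga_actionability
#' @export
glance.wga_actionability <- function(x, ...) {
  tibble::tibble(
    n_tumor_types = nrow(x$any_indicated),
    n_cells = nrow(x$matrix),
    median_any_indicated = stats::median(x$any_indicated$prevalence)
  )
}
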