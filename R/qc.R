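# Sequencing-quality gate.

#' Apply the sequencing quality gate
#'
#' A tumor-normal pair passes when the normal sample yields more than 85 Gb
#' and the tumor more than 210 Gb of high-quality bases (base quality > 30,
#' duplicates removed), more than 95% of the normal's autosomal genome is
#' covered at 15x or more, cross-patient contamination is below 3% (normal)
#' and 2.5% (tumor), and the pair is concordant (same patient). All
#' comparisons are strict, as stated.
#'
#' @param metrics A data frame with one row per pair and columns
#'   `normal_yield_gb`, `tumor_yield_gb`, `normal_autosome_cov15_frac`,
#'   `normal_contamination`, `tumor_contamination`, `pair_concordant`.
#'   Additional columns (e.g. `case_id`) are carried through.
#' @param config A [wga_config()].
#' @return The input tibble with `qc_pass` (logical) and `qc_fail_reasons`
#'   (list column of character vectors; empty when passing). Every violated
#'   threshold is listed.
#' @examples
#' m <- tibble::tibble(
#'   normal_yield_gb = 84, tumor_yield_gb = 250,
#'   normal_autosome_cov15_frac = 0.97, normal_contamination = 0.01,
#'   tumor_contamination = 0.01, pair_concordant = TRUE
#' )
#' qc_gate(m)$qc_fail_reasons
#' @export
qc_gate <- function(metrics, config = wga_config()) {
  metrics <- tibble::as_tibble(metrics)
  needed <- c("normal_yield_gb", "tumor_yield_gb", "normal_autosome_cov15_frac",
              "normal_contamination", "tumor_contamination", "pair_concordant")
  missing <- setdiff(needed, names(metrics))
  if (length(missing)) {
    abort(paste0("qc metrics missing column(s): ", paste(missing, collapse = ", ")))
  }
  fracs <- c("normal_autosome_cov15_frac", "normal_contamination", "tumor_contamination")
  for (f in fracs) {
    v <- metrics[[f]]
    if (any(is.na(v)) || any(v < 0 | v > 1)) {
      abort(paste0("`", f, "` must be a fraction in [0, 1]"))
    }
  }
  if (any(metrics$normal_yield_gb < 0) || any(metrics$tumor_yield_gb < 0)) {
    abort("yields must be nonnegative")
  }

  checks <- list(
    normal_yield = metrics$normal_yield_gb > config$qc_normal_yield_gb,
    tumor_yield = metrics$tumor_yield_gb > config$qc_tumor_yield_gb,
    autosome_cov15 = metrics$normal_autosome_cov15_frac > config$qc_cov15_frac,
    normal_contamination = metrics$normal_contamination < config$qc_normal_contamination,
    tumor_contamination = metrics$tumor_contamination < config$qc_tumor_contamination,
    pair_concordance = as.logical(metrics$pair_concordant)
  )
  ok <- do.call(cbind, checks)
  metrics$qc_pass <- apply(ok, 1, all)
  metrics$qc_fail_reasons <- apply(ok, 1, function(row) names(checks)[!row], simplify = FALSE)
  metrics
}
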