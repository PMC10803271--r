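# Cohort-level analytics: actionability prevalence, CNA/small-variant
# co-occurrence testing, and stage-corrected survival stratification.

#' Summarize actionability prevalence
#'
#' Per tumor type, gene and variant class: the fraction of cases with at
#' least one finding, split into the directory-indicated partition (the gene
#' and class are in the test directory for that type) and the non-indicated
#' partition. The denominator is the number of cases of the type passing the
#' gates relevant to the class (the purity gate for CNA findings; all cases
#' otherwise). A combined any-indicated-finding summary per type is included.
#'
#' @param findings Per-case findings tibble (`case_id, gene, variant_class`),
#'   e.g. from [interpret_cohort()].
#' @param cases Case tibble (`case_id, tumor_type, purity`).
#' @param directory Test-directory table (`gene, tumor_type, variant_class`).
#' @param config A [wga_config()].
#' @return A list of class `wga_actionability`: `matrix` (tumor_type, gene,
#'   variant_class, n_cases, n_with_finding, prevalence, indicated) and
#'   `any_indicated` (tumor_type, n_cases, n_with_finding, prevalence).
#' @export
summarize_actionability <- function(findings, cases, directory,
                                    config = wga_config()) {
  findings <- tibble::as_tibble(findings) |>
    dplyr::inner_join(dplyr::select(cases, "case_id", "tumor_type", "purity"),
                      by = "case_id")
  denom <- cases |>
    dplyr::group_by(.data$tumor_type) |>
    dplyr::summarise(
      n_all = dplyr::n(),
      n_cna_eligible = sum(.data$purity > config$purity_min),
      .groups = "drop"
    )
  cells <- findings |>
    dplyr::distinct(.data$case_id, .data$tumor_type, .data$gene, .data$variant_class) |>
    dplyr::count(.data$tumor_type, .data$gene, .data$variant_class,
                 name = "n_with_finding") |>
    dplyr::left_join(denom, by = "tumor_type") |>
    dplyr::mutate(
      n_cases = ifelse(.data$variant_class == "cna", .data$n_cna_eligible, .data$n_all),
      prevalence = ifelse(.data$n_cases > 0, .data$n_with_finding / .data$n_cases, NA_real_)
    ) |>
    dplyr::left_join(
      dplyr::mutate(directory, indicated = TRUE),
      by = c("tumor_type", "gene", "variant_class")
    ) |>
    dplyr::mutate(indicated = !is.na(.data$indicated)) |>
    dplyr::select("tumor_type", "gene", "variant_class", "n_cases",
                  "n_with_finding", "prevalence", "indicated") |>
    dplyr::arrange(.data$tumor_type, .data$gene, .data$variant_class)

  any_ind <- findings |>
    dplyr::semi_join(directory, by = c("tumor_type", "gene", "variant_class")) |>
    dplyr::distinct(.data$case_id, .data$tumor_type) |>
    dplyr::count(.data$tumor_type, name = "n_with_finding") |>
    dplyr::right_join(dplyr::select(denom, "tumor_type", n_cases = "n_all"),
                      by = "tumor_type") |>
    dplyr::mutate(
      n_with_finding = tidyr::replace_na(.data$n_with_finding, 0L),
      prevalence = .data$n_with_finding / .data$n_cases
    ) |>
    dplyr::arrange(.data$tumor_type)

  structure(list(matrix = cells, any_indicated = any_ind),
            class = "wga_actionability")
}

#' @exportS3Method base::print
print.wga_actionability <- function(x, ...) {
  cat("<wga_actionability> ", nrow(x$matrix), " cells over ",
      nrow(x$any_indicated), " tumor types\n", sep = "")
  print(x$any_indicated)
  invisible(x)
}

#' Gene mutation status for survival stratification
#'
#' A case is mutated in a gene when it carries a protein-altering small
#' variant in that gene, or -- for tumor suppressor genes -- a homozygous
#' deletion (total CN 0) overlapping the gene.
#'
#' @param variants Annotated variant tibble for the case.
#' @param segments CNA segment tibble for the case.
#' @param gene One gene-model row.
#' @return Logical scalar.
#' @export
gene_mutation_status <- function(variants, segments, gene) {
  small <- nrow(variants) > 0 && any(
    variants$gene %in% gene$gene &
      variants$consequence %in% protein_altering_consequences(), na.rm = TRUE)
  if (small) return(TRUE)
  if (gene$role %in% c("tsg", "both")) {
    seg <- segments_overlapping_gene(segments, gene)
    return(nrow(seg) > 0 && any(seg$total_cn == 0))
  }
  FALSE
}

#' Test CNA / small-variant co-occurrence
#'
#' For each gene, cases are divided into those with and without small
#' variants in the gene, and the frequency of CNA events (gain for
#' oncogenes, loss for tumor suppressors, per
#' [cna_event_for_cooccurrence()]) is compared between the two groups with a
#' two-sided Fisher's exact test; p-values are corrected across genes
#' (Benjamini-Hochberg by default).
#'
#' @param status Tibble with one row per case x gene: `case_id, gene,
#'   has_small_variant` (logical), `has_cna_event` (logical; NA rows --
#'   e.g. purity-ineligible cases -- are dropped).
#' @param config A [wga_config()].
#' @return Tibble of class `wga_cooccurrence`: per gene, group sizes, CNA
#'   fractions, `p_value`, `q_value`, and `undefined` for genes with an
#'   empty stratum.
#' @export
cooccurrence_test <- function(status, config = wga_config()) {
  res <- status |>
    dplyr::filter(!is.na(.data$has_cna_event)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_with_sv = sum(.data$has_small_variant),
      n_without_sv = sum(!.data$has_small_variant),
      cna_with = sum(.data$has_cna_event & .data$has_small_variant),
      cna_without = sum(.data$has_cna_event & !.data$has_small_variant),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      cna_frac_with = ifelse(.data$n_with_sv > 0, .data$cna_with / .data$n_with_sv, NA_real_),
      cna_frac_without = ifelse(.data$n_without_sv > 0,
                                .data$cna_without / .data$n_without_sv, NA_real_),
      undefined = .data$n_with_sv == 0 | .data$n_without_sv == 0
    )
  res$p_value <- purrr::pmap_dbl(
    list(res$cna_with, res$n_with_sv, res$cna_without, res$n_without_sv, res$undefined),
    function(a, n1, c, n2, und) {
      if (und) return(NA_real_)
      stats::fisher.test(matrix(c(a, n1 - a, c, n2 - c), nrow = 2, byrow = TRUE))$p.value
    }
  )
  method <- if (identical(config$cooccurrence_adjust, "BH")) "BH" else "bonferroni"
  res$q_value <- stats::p.adjust(res$p_value, method = method)
  res <- res |>
    dplyr::select("gene", "n_with_sv", "n_without_sv", "cna_frac_with",
                  "cna_frac_without", "p_value", "q_value", "undefined") |>
    dplyr::arrange(.data$p_value)
  class(res) <- c("wga_cooccurrence", class(res))
  res
}

#' Assemble survival data from the clinical bundle
#'
#' Survival origin is the registry diagnosis date when available (sampling
#' date otherwise, configurable); the endpoint is the mortality-table death
#' date, or right-censoring at the last date the individual was seen (latest
#' episode or treatment date).
#'
#' @param cases Case tibble.
#' @param clinical Clinical bundle (registry/episodes/treatments/deaths).
#' @param config A [wga_config()].
#' @return Tibble `case_id, time` (days), `event` (1 death, 0 censored).
#' @export
build_survival_data <- function(cases, clinical, config = wga_config()) {
  reg_first <- clinical$registry |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(diagnosis_date = min(.data$diagnosis_date), .groups = "drop")
  last_ep <- dplyr::bind_rows(
    dplyr::select(clinical$episodes, "participant_id", date = "appointment_date"),
    dplyr::select(clinical$treatments, "participant_id", date = "treatment_date")
  ) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(last_seen = max(.data$date), .groups = "drop")

  cases |>
    dplyr::left_join(reg_first, by = c(case_id = "participant_id")) |>
    dplyr::left_join(last_ep, by = c(case_id = "participant_id")) |>
    dplyr::left_join(
      dplyr::select(clinical$deaths, "participant_id", "death_date"),
      by = c(case_id = "participant_id")
    ) |>
    dplyr::mutate(
      origin = if (identical(config$survival_origin, "diagnosis")) {
        dplyr::coalesce(.data$diagnosis_date, .data$sample_date)
      } else .data$sample_date,
      event = as.integer(!is.na(.data$death_date)),
      end_date = dplyr::coalesce(.data$death_date, .data$last_seen),
      time = as.numeric(.data$end_date - .data$origin)
    ) |>
    dplyr::filter(!is.na(.data$time) & .data$time > 0) |>
    dplyr::select("case_id", "time", "event")
}

#' Stage-corrected survival stratification
#'
#' Kaplan-Meier estimates per group, a stage-stratified log-rank test, and a
#' Cox proportional-hazards model with the group indicator and categorical
#' stage as covariates (the stage correction). Cases with unknown stage are
#' excluded from the stage-corrected model and test.
#'
#' @param data Tibble with `time` (days), `event` (0/1), `group` (two or
#'   more levels; the first level is the reference) and `stage` (integer
#'   1-4, NA allowed).
#' @param stage_correct Correct for stage (default) or fit crude models.
#' @return Object of class `wga_survival`: `groups` (per-group n, events),
#'   `hazard_ratio`, `ci_low`, `ci_high`, `logrank_p`, `cox` (the coxph
#'   fit), `km` (the survfit object), `n_excluded_unknown_stage`.
#' @examples
#' d <- simulate_survival_cohort(400, hr = 0.5, seed = 7)
#' s <- survival_analysis(d)
#' round(s$hazard_ratio, 2)
#' @export
survival_analysis <- function(data, stage_correct = TRUE) {
  d <- tibble::as_tibble(data)
  if (!all(c("time", "event", "group") %in% names(d))) {
    abort("survival data needs columns time, event, group")
  }
  if (sum(d$event) == 0) abort("no events: all observations are censored")
  d$group <- factor(d$group)
  if (nlevels(d$group) < 2) abort("need at least two groups")

  n_excluded <- 0L
  dm <- d
  if (stage_correct) {
    if (!"stage" %in% names(d)) abort("stage correction requires a stage column")
    dm <- d[!is.na(d$stage), , drop = FALSE]
    n_excluded <- nrow(d) - nrow(dm)
    dm$stage <- factor(dm$stage)
  }
  groups <- dm |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), n_events = sum(.data$event), .groups = "drop")

  km <- survival::survfit(survival::Surv(time, event) ~ group, data = dm)
  if (stage_correct && nlevels(dm$stage) < 2) stage_correct <- FALSE  # nothing to correct
  if (stage_correct) {
    cox <- survival::coxph(survival::Surv(time, event) ~ group + stage, data = dm)
    lr <- survival::survdiff(survival::Surv(time, event) ~ group +
                               survival::strata(stage), data = dm)
  } else {
    cox <- survival::coxph(survival::Surv(time, event) ~ group, data = dm)
    lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = dm)
  }
  logrank_p <- stats::pchisq(lr$chisq, df = length(lr$n) - 1, lower.tail = FALSE)

  co <- summary(cox)
  idx <- grep("^group", rownames(co$coefficients))
  zero_event_group <- any(groups$n_events == 0)
  hr <- if (zero_event_group) NA_real_ else unname(co$coefficients[idx[1], "exp(coef)"])
  ci <- if (zero_event_group) c(NA_real_, NA_real_) else
    unname(co$conf.int[idx[1], c("lower .95", "upper .95")])

  structure(
    list(
      groups = groups, hazard_ratio = hr, ci_low = ci[1], ci_high = ci[2],
      logrank_p = logrank_p, cox = cox, km = km,
      stage_corrected = stage_correct, n_excluded_unknown_stage = n_excluded
    ),
    class = "wga_survival"
  )
}

#' @exportS3Method base::print
print.wga_survival <- function(x, ...) {
  cat("<wga_survival>", if (x$stage_corrected) "stage-corrected" else "crude", "\n")
  print(x$groups)
  cat(sprintf("  HR %.3f (95%% CI %.3f-%.3f), stratified log-rank p = %.3g\n",
              x$hazard_ratio, x$ci_low, x$ci_high, x$logrank_p))
  if (x$n_excluded_unknown_stage > 0) {
    cat("  excluded (unknown stage):", x$n_excluded_unknown_stage, "\n")
  }
  invisible(x)
}

#' Kaplan-Meier curve data
#'
#' Product-limit estimates per group in a plotting-friendly tibble.
#'
#' @param x A `wga_survival` object (or a `survfit`).
#' @return Tibble `group, time, n_risk, n_event, surv, lower, upper`.
#' @export
km_curves <- function(x) {
  fit <- if (inherits(x, "wga_survival")) x$km else x
  s <- summary(fit)
  grp <- if (!is.null(s$strata)) sub("^group=", "", as.character(s$strata)) else "all"
  tibble::tibble(
    group = grp, time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    surv = s$surv, lower = s$lower, upper = s$upper
  )
}

#' Lowest-vs-highest TMB quartile groups
#'
#' Within the supplied cases (typically one tumor type), assigns `low` to
#' the lowest TMB quartile and `high` to the highest and drops the middle
#' two quartiles, the contrast used for TMB prognosis.
#'
#' @param tmb Tibble `case_id, tmb`.
#' @return Tibble `case_id, tmb, group` restricted to the two outer
#'   quartiles, with the quartile medians as attributes `median_low` /
#'   `median_high`.
#' @export
tmb_quartile_groups <- function(tmb) {
  q <- stats::quantile(tmb$tmb, c(0.25, 0.75), na.rm = TRUE, type = 7)
  out <- tmb |>
    dplyr::mutate(group = dplyr::case_when(
      .data$tmb <= q[[1]] ~ "low",
      .data$tmb >= q[[2]] ~ "high",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::mutate(group = factor(.data$group, levels = c("low", "high")))
  attr(out, "median_low") <- stats::median(out$tmb[out$group == "low"])
  attr(out, "median_high") <- stats::median(out$tmb[out$group == "high"])
  out
}
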