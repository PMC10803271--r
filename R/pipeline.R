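# Per-case interpretation and cohort orchestration: simulate -> run ->
# analyze, with file round-trips through the standard formats.

#' Interpret one tumor case
#'
#' Runs the full per-case interpretation: consequence annotation and the
#' five-rule filter cascade on somatic small variants; copy-number gain/loss
#' actionability and SV fusion frame assessment; germline predisposition and
#' pharmacogenomic reporting; and the pangenomic markers (96-context
#' catalog, signature refit, etiology/MMR call, TMB).
#'
#' @param case One-row case tibble (`case_id, tumor_type, purity, ploidy`).
#' @param call_set List with `small_variants`, `germline_variants`,
#'   `cna_segments`, `svs`.
#' @param bundle A [reference_bundle()].
#' @return A list of class `wga_case_report`: `variants` (annotated +
#'   flagged), `findings` (case_id, gene, variant_class, detail), `markers`
#'   (one-row tibble), `fusions`, `exposure` (signature_exposure or NULL),
#'   `filter_tally`.
#' @export
interpret_case <- function(case, call_set, bundle) {
  cfg <- bundle$config
  gm <- bundle$gene_models

  v <- call_set$small_variants |>
    annotate_consequence(gm, bundle$reference) |>
    apply_somatic_filters(bundle)

  hc_snvs <- v |> dplyr::filter(.data$high_confidence, .data$vtype == "SNV")
  catalog <- build_catalog(hc_snvs, bundle$reference)
  exposure <- NULL
  etiology <- NULL
  if (sum(catalog) > 0) {
    exposure <- fit_exposures(catalog, bundle$signature_matrix)
    etiology <- classify_etiologies(exposure, cfg)
  }
  tmb <- compute_tmb(v, bundle$coding_mb, cfg)

  findings <- list()
  add <- function(gene, variant_class, detail) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(
      case_id = case$case_id, gene = gene, variant_class = variant_class,
      detail = detail
    )
  }
  # reportable small variants (flagged variants are labeled, not removed)
  rep_small <- v |>
    dplyr::filter(!is.na(.data$consequence),
                  .data$consequence %in% curated_consequences(),
                  !is.na(.data$gene))
  for (g in unique(rep_small$gene)) {
    add(g, "small_variant",
        paste(sort(unique(rep_small$consequence[rep_small$gene == g])), collapse = ","))
  }
  # CNA findings
  cna_findings <- list()
  for (i in seq_len(nrow(gm))) {
    g <- gm[i, ]
    gain <- classify_gain(g, call_set$cna_segments, case$purity, case$ploidy, cfg)
    loss <- classify_loss(g, call_set$cna_segments, v, call_set$svs,
                          case$purity, case$ploidy, cfg)
    for (f in list(gain, loss)) {
      if (!is.null(f)) {
        cna_findings[[length(cna_findings) + 1L]] <- f
        if (isTRUE(f$eligible)) {
          add(g$gene, "cna", paste0(f$kind,
                                    ifelse(is.na(f$scenario), "", paste0("_scenario", f$scenario))))
        }
      }
    }
  }
  # fusions
  fusions <- list()
  for (i in seq_len(nrow(call_set$svs))) {
    fa <- assess_fusion(call_set$svs[i, ], gm)
    fa$sv_id <- call_set$svs$sv_id[i]
    fusions[[length(fusions) + 1L]] <- fa
    if (isTRUE(fa$reportable)) {
      add(fa$downstream_gene, "sv", paste0(fa$status, ":", fa$upstream_gene,
                                           "-", fa$downstream_gene))
    }
  }
  # germline + PGx
  germ <- call_set$germline_variants |>
    annotate_consequence(gm, bundle$reference)
  gfind <- classify_germline(germ, bundle$clinvar, gm, bundle$directory,
                             case$tumor_type, cfg)
  for (i in seq_len(nrow(gfind))) {
    add(gfind$gene[i], "germline", gfind$basis[i])
  }
  pgx <- flag_pgx(germ, bundle$pgx_alleles)
  for (i in seq_len(nrow(pgx))) {
    add(pgx$gene[i], "pgx", pgx$allele[i])
  }

  markers <- tibble::tibble(
    case_id = case$case_id,
    tmb = tmb,
    n_high_confidence_snvs = sum(catalog),
    mmr_deficient = if (!is.null(etiology)) etiology$mmr_deficient else NA,
    refit_residual = if (!is.null(exposure)) exposure$residual else NA_real_
  )
  structure(
    list(
      case_id = case$case_id,
      variants = v,
      findings = if (length(findings)) dplyr::bind_rows(findings) else
        tibble::tibble(case_id = character(), gene = character(),
                       variant_class = character(), detail = character()),
      cna = if (length(cna_findings)) dplyr::bind_rows(cna_findings) else NULL,
      fusions = if (length(fusions)) dplyr::bind_rows(fusions) else NULL,
      germline = gfind, pgx = pgx,
      markers = markers, catalog = catalog, exposure = exposure,
      etiology = etiology,
      filter_tally = dplyr::bind_cols(tibble::tibble(case_id = case$case_id),
                                      filter_tally(v))
    ),
    class = "wga_case_report"
  )
}

#' @exportS3Method base::print
print.wga_case_report <- function(x, ...) {
  cat("<wga_case_report> ", x$case_id, ": ", nrow(x$findings), " findings, TMB ",
      signif(x$markers$tmb, 3), "/Mb\n", sep = "")
  invisible(x)
}

#' Interpret a whole cohort
#'
#' Maps [interpret_case()] over a cohort and collects per-case findings,
#' markers and filter tallies.
#'
#' @param cases Case tibble.
#' @param call_sets Named list of call sets (one per `case_id`).
#' @param bundle A [reference_bundle()].
#' @return A list of class `wga_cohort_report`: `findings`, `markers`,
#'   `filter_tallies`, `reports` (per-case list).
#' @export
interpret_cohort <- function(cases, call_sets, bundle) {
  reports <- purrr::map(seq_len(nrow(cases)), function(i) {
    interpret_case(cases[i, ], call_sets[[cases$case_id[i]]], bundle)
  })
  names(reports) <- cases$case_id
  structure(
    list(
      findings = dplyr::bind_rows(purrr::map(reports, "findings")),
      markers = dplyr::bind_rows(purrr::map(reports, "markers")),
      filter_tallies = dplyr::bind_rows(purrr::map(reports, "filter_tally")),
      reports = reports
    ),
    class = "wga_cohort_report"
  )
}

#' @exportS3Method base::print
print.wga_cohort_report <- function(x, ...) {
  cat("<wga_cohort_report> ", length(x$reports), " cases, ",
      nrow(x$findings), " findings\n", sep = "")
  invisible(x)
}

#' Per-case, per-gene status for co-occurrence testing
#'
#' @param report A `wga_cohort_report`.
#' @param cases Case tibble.
#' @param call_sets Call-set list (for segments).
#' @param bundle A [reference_bundle()].
#' @param genes Genes to tabulate (default: every directory gene).
#' @return Tibble `case_id, gene, has_small_variant, has_cna_event`.
#' @export
cooccurrence_status <- function(report, cases, call_sets, bundle,
                                genes = unique(bundle$directory$gene)) {
  gm <- bundle$gene_models
  rows <- list()
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    v <- report$reports[[cs$case_id]]$variants
    segs <- call_sets[[cs$case_id]]$cna_segments
    for (gn in genes) {
      g <- gm[gm$gene == gn, ]
      ev <- cna_event_for_cooccurrence(g, segs, cs$purity, cs$ploidy, bundle$config)
      expected <- if (g$role %in% c("oncogene", "both")) "gain_event" else "loss_event"
      rows[[length(rows) + 1L]] <- tibble::tibble(
        case_id = cs$case_id, gene = gn,
        has_small_variant = any(v$gene %in% gn & !is.na(v$consequence)),
        has_cna_event = if (is.na(ev) && cs$purity <= bundle$config$purity_min)
          NA else identical(ev, expected)
      )
    }
  }
  dplyr::bind_rows(rows)
}

# --- file round-trip -------------------------------------------------------

#' Write / read one case's call sets
#'
#' A case directory holds `small_variants.vcf`, `germline.vcf`, `cna.tsv`
#' and `sv.vcf`, plus the case metadata as `case.tsv`.
#'
#' @param case One-row case tibble.
#' @param call_set Call-set list.
#' @param dir Case directory.
#' @param reference Optional reference for normalization on read.
#' @return `read_case_dir()` returns `list(case, call_set)`.
#' @export
write_case_dir <- function(case, call_set, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_small_variant_vcf(call_set$small_variants, file.path(dir, "small_variants.vcf"))
  write_small_variant_vcf(call_set$germline_variants, file.path(dir, "germline.vcf"),
                          sample = "NORMAL")
  write_cna_tsv(call_set$cna_segments, file.path(dir, "cna.tsv"))
  write_sv_vcf(call_set$svs, file.path(dir, "sv.vcf"))
  readr::write_tsv(case, file.path(dir, "case.tsv"))
  invisible(dir)
}

#' @rdname write_case_dir
#' @export
read_case_dir <- function(dir, reference = NULL) {
  case <- readr::read_tsv(file.path(dir, "case.tsv"), show_col_types = FALSE)
  list(
    case = case,
    call_set = list(
      small_variants = read_small_variant_vcf(file.path(dir, "small_variants.vcf"),
                                              reference),
      germline_variants = read_small_variant_vcf(file.path(dir, "germline.vcf"),
                                                 reference),
      cna_segments = read_cna_tsv(file.path(dir, "cna.tsv")),
      svs = read_sv_vcf(file.path(dir, "sv.vcf"))
    )
  )
}

#' Write a simulated cohort to disk
#'
#' Emits everything the pipeline consumes: per-case directories, the
#' clinical tables, the resource TSVs and the per-case truth records as
#' JSON.
#'
#' @param sim A `wga_simulation`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(nrow(sim$cases))) {
    id <- sim$cases$case_id[i]
    write_case_dir(sim$cases[i, ], sim$call_sets[[id]], file.path(dir, "cases", id))
  }
  write_clinical_bundle(sim$clinical, file.path(dir, "clinical"))
  res_dir <- file.path(dir, "resources")
  if (!dir.exists(res_dir)) dir.create(res_dir, recursive = TRUE)
  write_reference_fasta(sim$genome$reference, file.path(res_dir, "reference.fa"))
  write_gene_models_tsv(sim$bundle$gene_models, file.path(res_dir, "gene_models.tsv"))
  write_bed(sim$bundle$repeats, file.path(res_dir, "repeats.bed"))
  readr::write_tsv(sim$bundle$pop_af, file.path(res_dir, "pop_af.tsv"))
  readr::write_tsv(sim$bundle$recurrence, file.path(res_dir, "recurrence.tsv"))
  write_pon_tsv(sim$bundle$pon, file.path(res_dir, "pon.tsv"))
  readr::write_tsv(sim$bundle$quality_fail, file.path(res_dir, "quality_fail.tsv"))
  write_signature_matrix_tsv(sim$bundle$signature_matrix,
                             file.path(res_dir, "signatures.tsv"))
  readr::write_tsv(sim$bundle$clinvar, file.path(res_dir, "clinvar.tsv"))
  readr::write_tsv(sim$bundle$directory, file.path(res_dir, "directory.tsv"))
  readr::write_tsv(sim$bundle$pgx_alleles, file.path(res_dir, "pgx_alleles.tsv"))
  yaml::write_yaml(
    list(resources = list(
      gene_models = "gene_models.tsv", repeats = "repeats.bed",
      pop_af = "pop_af.tsv", recurrence = "recurrence.tsv", pon = "pon.tsv",
      quality_fail = "quality_fail.tsv", signature_matrix = "signatures.tsv",
      clinvar = "clinvar.tsv", directory = "directory.tsv",
      pgx_alleles = "pgx_alleles.tsv", reference = "reference.fa"
    )),
    file.path(res_dir, "config.yaml")
  )
  truth_dir <- file.path(dir, "truth")
  if (!dir.exists(truth_dir)) dir.create(truth_dir)
  jsonlite::write_json(sim$truth$events, file.path(truth_dir, "events.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  readr::write_tsv(
    dplyr::select(sim$truth$case_truth, -"exposures"),
    file.path(truth_dir, "case_truth.tsv")
  )
  invisible(dir)
}
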