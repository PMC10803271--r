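# Pipeline configuration: every threshold used anywhere in the engine lives
# here, with the published defaults. All are overridable, either directly or
# through a YAML/JSON config file.

#' Pipeline configuration
#'
#' Returns the full set of tunable thresholds with their defaults. The
#' defaults are the values used by the interpretation pipeline the package
#' models: sequencing-QC gates (85/210 Gb yield, 95% autosome coverage at
#' 15x, 3%/2.5% contamination), the five somatic filter thresholds
#' (population allele frequency > 1%, cohort recurrence > 5%, simple-repeat
#' overlap, noisy-indel window fraction >= 10% over +/-50 bp, panel-of-normals
#' Fisher Phred < 50), the copy-number actionability gates (purity > 30%,
#' gain at CN >= 2 x ploidy), the 20% etiology display/MMR thresholds, and
#' the clinical-linkage date windows (< 7 days flexible match, < 365 days
#' stage validity).
#'
#' @param ... Named overrides for any default, e.g. `phred_threshold = 30`.
#'   Unknown names are an error.
#' @return A named list of class `wga_config`.
#' @examples
#' cfg <- wga_config(phred_threshold = 30)
#' cfg$phred_threshold
#' @export
wga_config <- function(...) {
  cfg <- list(
    # sequencing QC (strict inequalities, as printed)
    qc_normal_yield_gb = 85,
    qc_tumor_yield_gb = 210,
    qc_cov15_frac = 0.95,
    qc_normal_contamination = 0.03,
    qc_tumor_contamination = 0.025,
    # somatic filter cascade
    pop_af_threshold = 0.01,      # flag if strictly above
    recurrence_threshold = 0.05,  # flag if strictly above
    noisy_window_threshold = 0.10, # flag if >= (inclusive, "at least 10%")
    noisy_window_halfwidth = 50L,
    noisy_default_depth = 30L,
    phred_threshold = 50,          # flag if strictly below
    fisher_alternative = "two.sided",
    pon_default_ref_depth = 30L,   # per panel individual, for sites absent from the PoN
    pon_carrier_min_fraction = 0.35, # alt fraction at/above which an individual "carries" the allele
    # CNA / SV interpretation
    purity_min = 0.30,             # strict: purity must exceed this
    gain_multiplier = 2,           # gain iff CN >= gain_multiplier * ploidy
    cn_neutral_tol = 0.5,          # |CN - ploidy| tolerance for copy-neutral LOH
    # markers
    etiology_other_threshold = 0.20, # group fraction <= this -> "other" (strict "more than 20%" retained)
    mmr_threshold = 0.20,            # MMR deficient iff MMR group fraction strictly above
    tmb_exclude = "splice_region_variant",
    # germline / PGx
    clinvar_min_stars = 2L,
    germline_tumor_type_restricted = TRUE,
    # clinical linkage
    flexible_match_max_days = 7L,   # strict: |delta| < 7 days
    stage_max_days = 365L,          # strict: |delta| < 365 days
    figo_tumor_types = c("ovarian_hgs", "endometrial"),
    dukes_tumor_types = c("colon", "rectum"),
    flexible_registry_type = "colorectal",
    flexible_submitted_types = c("hepato_pancreatobiliary", "endometrial", "lung_adeno"),
    # survival
    survival_origin = "diagnosis", # or "sample"
    cooccurrence_adjust = "BH"     # or "bonferroni"
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      abort(paste0("unknown configuration field(s): ", paste(bad, collapse = ", ")))
    }
    cfg[names(overrides)] <- overrides
  }
  structure(cfg, class = "wga_config")
}

#' Read a configuration file
#'
#' Reads a YAML (or JSON) file of threshold overrides and merges it over the
#' defaults of [wga_config()].
#'
#' @param path Path to a YAML/JSON file whose top-level keys are
#'   configuration field names.
#' @return A `wga_config` list.
#' @export
read_wga_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  do.call(wga_config, raw)
}

#' @exportS3Method base::print
print.wga_config <- function(x, ...) {
  cat("<wga_config> ", length(x), " fields\n", sep = "")
  flat <- vapply(x, function(v) paste(format(v), collapse = ","), character(1))
  cat(paste0("  ", format(names(x)), " = ", flat, collapse = "\n"), "\n")
  invisible(x)
}

#' Validate a signature matrix
#'
#' A signature matrix is a numeric matrix with 96 rows (one per
#' trinucleotide substitution context, in [sbs96_contexts()] order) and one
#' column per signature; every column is a probability vector over contexts.
#'
#' @param m Matrix to validate.
#' @param tol Column-sum tolerance.
#' @return `m`, invisibly, or an error.
#' @export
validate_signature_matrix <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != 96) {
    abort("signature matrix must have 96 rows (one per trinucleotide context)")
  }
  if (is.null(colnames(m))) abort("signature matrix must have signature column names")
  if (any(m < 0)) abort("signature matrix entries must be nonnegative")
  sums <- colSums(m)
  off <- which(abs(sums - 1) > tol)
  if (length(off)) {
    abort(paste0(
      "signature column(s) not summing to 1: ",
      paste0(colnames(m)[off], " (", signif(sums[off], 6), ")", collapse = ", ")
    ))
  }
  invisible(m)
}

#' Assemble a reference bundle
#'
#' The reference bundle carries every cohort-level resource the per-case
#' interpretation stages need: canonical gene models, simple-repeat
#' intervals, population allele-frequency and cohort-recurrence tables, the
#' panel of normals, the per-base quality-fail track, the signature matrix,
#' the ClinVar-style classification table, the test-directory table, the
#' pharmacogenomic allele table, and the coding footprint in megabases.
#'
#' @param gene_models Gene-model tibble (see [toy_genome()]).
#' @param repeats Simple-repeat intervals: tibble `chrom,start,end` (1-based
#'   closed).
#' @param pop_af Population allele frequencies: `chrom,pos,ref,alt,af`.
#' @param recurrence Cohort recurrence: `chrom,pos,ref,alt,recurrence`.
#' @param pon Panel of normals, from [simulate_pon()] or [read_pon_tsv()].
#' @param quality_fail Per-position `chrom,pos,fail_frac,depth` track.
#' @param signature_matrix 96 x K matrix, validated.
#' @param clinvar ClinVar-style table: `chrom,pos,ref,alt,classification,review_stars`.
#' @param directory Test-directory table: `gene,tumor_type,variant_class`.
#' @param pgx_alleles PGx allele table: `chrom,pos,ref,alt,gene,allele,recommendation`.
#' @param coding_mb Coding footprint in megabases; when `NULL`, computed from
#'   the CDS union of `gene_models`.
#' @param reference Named character vector (or `Biostrings::DNAStringSet`) of
#'   contig sequences, used for trinucleotide contexts and normalization.
#' @param config A `wga_config`.
#' @return A list of class `reference_bundle`.
#' @export
reference_bundle <- function(gene_models, repeats, pop_af, recurrence, pon,
                             quality_fail, signature_matrix, clinvar,
                             directory, pgx_alleles, coding_mb = NULL,
                             reference = NULL, config = wga_config()) {
  validate_signature_matrix(signature_matrix)
  if (is.null(coding_mb)) coding_mb <- coding_footprint_mb(gene_models)
  if (coding_mb <= 0) abort("coding footprint must be positive")
  structure(
    list(
      gene_models = gene_models, repeats = repeats, pop_af = pop_af,
      recurrence = recurrence, pon = pon, quality_fail = quality_fail,
      signature_matrix = signature_matrix, clinvar = clinvar,
      directory = directory, pgx_alleles = pgx_alleles,
      coding_mb = coding_mb, reference = reference, config = config
    ),
    class = "reference_bundle"
  )
}

#' @exportS3Method base::print
print.reference_bundle <- function(x, ...) {
  cat("<reference_bundle>\n")
  cat("  genes:", nrow(x$gene_models),
      " repeats:", nrow(x$repeats),
      " PoN sites:", nrow(x$pon$sites),
      " signatures:", ncol(x$signature_matrix), "\n")
  cat("  coding footprint:", signif(x$coding_mb, 4), "Mb\n")
  invisible(x)
}

#' Coding footprint from gene models
#'
#' Megabases covered by the union of CDS intervals across canonical
#' transcripts (exonic positions within `[cds_start, cds_end]`).
#'
#' @param gene_models Gene-model tibble.
#' @return Megabases (numeric scalar).
#' @export
coding_footprint_mb <- function(gene_models) {
  cds <- gene_models |>
    dplyr::mutate(exons = purrr::map(.data$exons, identity)) |>
    tidyr::unnest("exons") |>
    dplyr::mutate(
      start = pmax(.data$start, .data$cds_start),
      end = pmin(.data$end, .data$cds_end)
    ) |>
    dplyr::filter(.data$start <= .data$end)
  if (!nrow(cds)) return(0)
  total <- cds |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(d, key) {
      d <- dplyr::arrange(d, .data$start, .data$end)
      # merge overlapping intervals
      merged_len <- 0
      cur_s <- d$start[1]; cur_e <- d$end[1]
      if (nrow(d) > 1) {
        for (i in 2:nrow(d)) {
          if (d$start[i] <= cur_e + 1) {
            cur_e <- max(cur_e, d$end[i])
          } else {
            merged_len <- merged_len + (cur_e - cur_s + 1)
            cur_s <- d$start[i]; cur_e <- d$end[i]
          }
        }
      }
      merged_len + (cur_e - cur_s + 1)
    }) |>
    unlist() |>
    sum()
  total / 1e6
}

#' Load a reference bundle from a config file
#'
#' The YAML config lists resource paths (relative to the file) under
#' `resources:` and threshold overrides under `thresholds:`. See the package
#' vignette for the documented headers of each TSV resource.
#'
#' @param config_path Path to YAML config.
#' @return A `reference_bundle`.
#' @export
load_reference_bundle <- function(config_path) {
  stopifnot(file.exists(config_path))
  raw <- yaml::read_yaml(config_path)
  res <- raw$resources
  needed <- c("gene_models", "repeats", "pop_af", "recurrence", "pon",
              "quality_fail", "signature_matrix", "clinvar", "directory",
              "pgx_alleles", "reference")
  missing <- setdiff(needed, names(res))
  if (length(missing)) {
    abort(paste0("config missing resource path(s): ", paste(missing, collapse = ", ")))
  }
  dir <- dirname(config_path)
  p <- function(f) file.path(dir, res[[f]])
  cfg <- do.call(wga_config, raw$thresholds %||% list())
  sig <- read_signature_matrix_tsv(p("signature_matrix"))
  # allele columns must never be type-guessed (an all-"T" column is not logical)
  site_cols <- readr::cols(chrom = readr::col_character(),
                           ref = readr::col_character(),
                           alt = readr::col_character())
  read_site_tsv <- function(f) {
    readr::read_tsv(p(f), show_col_types = FALSE, col_types = site_cols)
  }
  reference_bundle(
    gene_models = read_gene_models_tsv(p("gene_models")),
    repeats = read_bed(p("repeats")),
    pop_af = read_site_tsv("pop_af"),
    recurrence = read_site_tsv("recurrence"),
    pon = read_pon_tsv(p("pon")),
    quality_fail = readr::read_tsv(p("quality_fail"), show_col_types = FALSE),
    signature_matrix = sig,
    clinvar = read_site_tsv("clinvar"),
    directory = readr::read_tsv(p("directory"), show_col_types = FALSE),
    pgx_alleles = read_site_tsv("pgx_alleles"),
    coding_mb = raw$coding_mb,
    reference = read_reference_fasta(p("reference")),
    config = cfg
  )
}
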