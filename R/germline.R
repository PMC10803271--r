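# Germline cancer-predisposition reporting and pharmacogenomic flagging.

#' Classify germline variants for predisposition reporting
#'
#' A germline variant is reportable on one of two bases, for genes in the
#' test directory's germline-indicated set for the case's tumor type (or
#' panel-wide when `germline_tumor_type_restricted` is off):
#' \describe{
#'   \item{clinvar}{listed as pathogenic or likely pathogenic with a review
#'     rating of at least two stars}
#'   \item{predicted_truncating}{a predicted protein-truncating consequence
#'     (stop gained/lost, start lost, frameshift, splice acceptor/donor) in a
#'     gene whose mechanism of pathogenicity is loss of function}
#' }
#'
#' @param variants Annotated germline variant tibble (`chrom,pos,ref,alt`,
#'   `gene`, `consequence`).
#' @param clinvar ClinVar-style table (`chrom,pos,ref,alt,classification,
#'   review_stars`).
#' @param gene_models Gene-model tibble (for `lof_mechanism`).
#' @param directory Test-directory table (`gene,tumor_type,variant_class`).
#' @param tumor_type The case's tumor type.
#' @param config A [wga_config()].
#' @return Tibble of reportable findings: `gene, chrom, pos, ref, alt,
#'   basis, classification, review_stars`.
#' @export
classify_germline <- function(variants, clinvar, gene_models, directory,
                              tumor_type, config = wga_config()) {
  v <- tibble::as_tibble(variants)
  empty <- tibble::tibble(
    gene = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), basis = character(),
    classification = character(), review_stars = integer()
  )
  if (!nrow(v)) return(empty)

  indicated <- directory |> dplyr::filter(.data$variant_class == "germline")
  if (isTRUE(config$germline_tumor_type_restricted)) {
    indicated <- indicated |> dplyr::filter(.data$tumor_type == !!tumor_type)
  }
  v <- v |> dplyr::filter(.data$gene %in% indicated$gene)
  if (!nrow(v)) return(empty)

  v <- v |>
    dplyr::left_join(
      dplyr::select(clinvar, "chrom", "pos", "ref", "alt",
                    "classification", "review_stars"),
      by = c("chrom", "pos", "ref", "alt")
    ) |>
    dplyr::left_join(
      dplyr::select(gene_models, "gene", "lof_mechanism"),
      by = "gene"
    )
  clinvar_basis <- !is.na(v$classification) &
    v$classification %in% c("pathogenic", "likely_pathogenic") &
    v$review_stars >= config$clinvar_min_stars
  truncating_basis <- !is.na(v$consequence) &
    v$consequence %in% truncating_consequences() &
    v$lof_mechanism
  v$basis <- dplyr::case_when(
    clinvar_basis ~ "clinvar",
    truncating_basis ~ "predicted_truncating",
    TRUE ~ NA_character_
  )
  v |>
    dplyr::filter(!is.na(.data$basis)) |>
    dplyr::select("gene", "chrom", "pos", "ref", "alt", "basis",
                  "classification", "review_stars") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Flag pharmacogenomic alleles
#'
#' Matches germline variants against the pharmacogenomic allele table (e.g.
#' DPYD alleles linked to fluoropyrimidine toxicity) and returns one flag
#' per matched allele with the recommendation text passed through, ordered
#' by genomic position.
#'
#' @param variants Germline variant tibble (`chrom,pos,ref,alt`).
#' @param pgx_alleles Allele table (`chrom,pos,ref,alt,gene,allele,
#'   recommendation`).
#' @return Tibble of flags (possibly empty).
#' @export
flag_pgx <- function(variants, pgx_alleles) {
  tibble::as_tibble(variants) |>
    dplyr::select("chrom", "pos", "ref", "alt") |>
    dplyr::inner_join(pgx_alleles, by = c("chrom", "pos", "ref", "alt")) |>
    dplyr::select("gene", "allele", "chrom", "pos", "ref", "alt", "recommendation") |>
    dplyr::arrange(.data$chrom, .data$pos)
}
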