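# Copy-number and structural-variant interpretation: gain/loss actionability
# rules and fusion reading-frame assessment.

segments_overlapping_gene <- function(segments, g) {
  ex <- g$exons[[1]]
  span_start <- min(ex$start); span_end <- max(ex$end)
  segments[segments$chrom == g$chrom & segments$start <= span_end &
             segments$end >= span_start, , drop = FALSE]
}

#' Classify an oncogene copy-number gain
#'
#' A gain is reported when the segment's total copy number is at least
#' `gain_multiplier` (default 2) times the case's overall ploidy. Cases with
#' tumor purity at or below 30% are ineligible for copy-number actionability
#' and return `eligible = FALSE` with the reason.
#'
#' @param gene One gene-model row; must have oncogene in its role.
#' @param segments Segment tibble `chrom,start,end,total_cn,minor_cn`.
#' @param purity,ploidy Case purity and ploidy.
#' @param config A [wga_config()].
#' @return One-row tibble (gene, kind, scenario, eligible, reason) or `NULL`.
#' @export
classify_gain <- function(gene, segments, purity, ploidy, config = wga_config()) {
  if (ploidy <= 0) abort("ploidy must be positive")
  if (!gene$role %in% c("oncogene", "both")) return(NULL)
  if (purity <= config$purity_min) {
    return(tibble::tibble(gene = gene$gene, kind = "gain", scenario = NA_integer_,
                          eligible = FALSE, reason = "purity_at_or_below_30pct"))
  }
  seg <- segments_overlapping_gene(segments, gene)
  if (!nrow(seg)) return(NULL)
  if (max(seg$total_cn) >= config$gain_multiplier * ploidy) {
    return(tibble::tibble(gene = gene$gene, kind = "gain", scenario = NA_integer_,
                          eligible = TRUE, reason = "cn_at_least_twice_ploidy"))
  }
  NULL
}

#' Classify a tumor-suppressor copy-number loss
#'
#' Three loss scenarios, with precedence 1 > 2 > 3:
#' \enumerate{
#'   \item homozygous deletion (total CN = 0), reported regardless of small
#'     variants;
#'   \item LOH (total CN = 1), or copy-neutral LOH (minor CN = 0 with total
#'     CN within `cn_neutral_tol` of ploidy), in combination with a
#'     nonsynonymous somatic small variant in the gene;
#'   \item an SV breakpoint disrupting the coding region (strictly inside
#'     `[cds_start, cds_end]`), in combination with a nonsynonymous somatic
#'     small variant.
#' }
#' The purity gate applies as for gains.
#'
#' @param gene One gene-model row; must have tumor suppressor in its role.
#' @param segments Segment tibble.
#' @param small_variants Annotated variant tibble for the case (needs
#'   `gene`, `consequence`, and ideally `high_confidence`).
#' @param svs SV tibble (see [read_sv_vcf()]); may be empty.
#' @param purity,ploidy Case purity and ploidy.
#' @param config A [wga_config()].
#' @return One-row tibble or `NULL`.
#' @export
classify_loss <- function(gene, segments, small_variants, svs, purity, ploidy,
                          config = wga_config()) {
  if (ploidy <= 0) abort("ploidy must be positive")
  if (!gene$role %in% c("tsg", "both")) return(NULL)
  if (purity <= config$purity_min) {
    return(tibble::tibble(gene = gene$gene, kind = "loss", scenario = NA_integer_,
                          eligible = FALSE, reason = "purity_at_or_below_30pct"))
  }
  seg <- segments_overlapping_gene(segments, gene)
  has_nonsyn <- nrow(small_variants) > 0 &&
    any(small_variants$gene %in% gene$gene &
          small_variants$consequence %in% protein_altering_consequences(),
        na.rm = TRUE)

  if (nrow(seg) && any(seg$total_cn == 0)) {
    return(tibble::tibble(gene = gene$gene, kind = "loss", scenario = 1L,
                          eligible = TRUE, reason = "homozygous_deletion"))
  }
  loh <- nrow(seg) > 0 && any(
    seg$total_cn == 1 |
      (!is.na(seg$minor_cn) & seg$minor_cn == 0 &
         abs(seg$total_cn - ploidy) <= config$cn_neutral_tol)
  )
  if (loh && has_nonsyn) {
    return(tibble::tibble(gene = gene$gene, kind = "loss", scenario = 2L,
                          eligible = TRUE, reason = "loh_plus_small_variant"))
  }
  if (nrow(svs)) {
    disrupts <- (svs$chrom_a == gene$chrom & svs$pos_a > gene$cds_start & svs$pos_a < gene$cds_end) |
      (svs$chrom_b == gene$chrom & svs$pos_b > gene$cds_start & svs$pos_b < gene$cds_end)
    if (any(disrupts) && has_nonsyn) {
      return(tibble::tibble(gene = gene$gene, kind = "loss", scenario = 3L,
                            eligible = TRUE, reason = "sv_disruption_plus_small_variant"))
    }
  }
  NULL
}

#' Copy-number event for co-occurrence testing
#'
#' The relaxed one-copy rule used for co-occurrence analysis (distinct from
#' the actionability rules): against the rounded ploidy, a gain event is a
#' gain of at least one copy for oncogenes and a loss event is a loss of at
#' least one copy for tumor suppressor genes.
#'
#' @inheritParams classify_gain
#' @return `"gain_event"`, `"loss_event"` or `NA_character_`.
#' @export
cna_event_for_cooccurrence <- function(gene, segments, purity, ploidy,
                                       config = wga_config()) {
  if (purity <= config$purity_min) return(NA_character_)
  seg <- segments_overlapping_gene(segments, gene)
  if (!nrow(seg)) return(NA_character_)
  p <- round(ploidy)
  if (gene$role %in% c("oncogene", "both") && max(seg$total_cn) >= p + 1) {
    return("gain_event")
  }
  if (gene$role %in% c("tsg", "both") && min(seg$total_cn) <= p - 1) {
    return("loss_event")
  }
  NA_character_
}

# --- fusion reading-frame assessment ---------------------------------------

# Coding phase contributed by a transcript up to the junction.
#
# L = number of CDS bases transcript-5' of the junction (for the upstream
# partner the retained breakpoint base counts; for the downstream partner the
# breakpoint base belongs to the retained 3' remainder and does not). The
# fused CDS keeps the downstream reading frame iff L_up = L_dn (mod 3).
# Returns list(kind, phase):
#   "cds"   phase defined (L mod 3; exonic junctions only when they fall on
#           a codon boundary, where the phase is 0)
#   "split" exonic junction splitting a codon (phase undefined -> ambiguous)
#   "utr5"/"utr3"/"intergenic" untranslated placements
# retained: "five" for the upstream partner, "three" for the downstream one.
breakpoint_phase <- function(g, pos, retained) {
  ex <- g$exons[[1]]
  span_start <- min(ex$start); span_end <- max(ex$end)
  if (pos < span_start || pos > span_end) return(list(kind = "intergenic", phase = NA_integer_))
  five_of_cds <- if (g$strand == "+") pos < g$cds_start else pos > g$cds_end
  three_of_cds <- if (g$strand == "+") pos > g$cds_end else pos < g$cds_start
  if (five_of_cds) return(list(kind = "utr5", phase = NA_integer_))
  if (three_of_cds) return(list(kind = "utr3", phase = NA_integer_))

  cdsvec <- cds_positions(g)  # translation order
  n_before <- sum(if (g$strand == "+") cdsvec < pos else cdsvec > pos)
  at <- any(cdsvec == pos)
  if (at) {
    # exonic CDS junction
    L <- n_before + as.integer(retained == "five")
    if (retained == "five" && L >= length(cdsvec)) {
      # the complete CDS including its stop codon is retained: no fusion ORF
      return(list(kind = "utr3", phase = NA_integer_))
    }
    if (L %% 3 != 0) return(list(kind = "split", phase = NA_integer_))
    return(list(kind = "cds", phase = 0L))
  }
  # intronic within the CDS span
  list(kind = "cds", phase = as.integer(n_before %% 3))
}

# can gene g act as the given fusion partner with this breakend orientation?
# upstream partner needs its 5' side retained; downstream its 3' side.
orientation_compatible <- function(strand, orient, partner) {
  if (partner == "upstream") {
    (strand == "+" && orient == "L") || (strand == "-" && orient == "R")
  } else {
    (strand == "+" && orient == "R") || (strand == "-" && orient == "L")
  }
}

#' Assess a structural variant for a productive fusion
#'
#' Determines whether a breakend junction can produce an in-frame fusion
#' transcript: the upstream partner must contribute its 5' end and the
#' downstream partner its 3' end in a 5'-to-3' read-through consistent with
#' both strands and breakend orientations (otherwise `untranscribed`); when
#' both breakpoint coding phases are defined, the fusion is `inframe` when
#' the cumulative CDS lengths on either side of the junction agree modulo 3,
#' `out_of_frame` otherwise. A downstream breakpoint in the 5' UTR (the whole
#' CDS is retained) or an exonic breakpoint splitting a codon gives
#' `ambiguous`. Only `inframe` and `ambiguous` events are reportable;
#' `out_of_frame` and `untranscribed` events are discarded.
#'
#' @param sv One SV row (`chrom_a,pos_a,orient_a,chrom_b,pos_b,orient_b`).
#' @param gene_models Gene-model tibble.
#' @return One-row tibble with `status`, `upstream_gene`, `downstream_gene`,
#'   `reportable`.
#' @export
assess_fusion <- function(sv, gene_models) {
  find_gene <- function(chrom, pos) {
    for (i in seq_len(nrow(gene_models))) {
      g <- gene_models[i, ]
      ex <- g$exons[[1]]
      if (g$chrom == chrom && pos >= min(ex$start) && pos <= max(ex$end)) return(g)
    }
    NULL
  }
  ga <- find_gene(sv$chrom_a, sv$pos_a)
  gb <- find_gene(sv$chrom_b, sv$pos_b)
  not_reportable <- function(status) {
    tibble::tibble(status = status, upstream_gene = NA_character_,
                   downstream_gene = NA_character_, reportable = FALSE)
  }
  if (is.null(ga) || is.null(gb)) return(not_reportable("untranscribed"))

  assignments <- list(
    list(up = ga, up_or = sv$orient_a, up_pos = sv$pos_a,
         dn = gb, dn_or = sv$orient_b, dn_pos = sv$pos_b),
    list(up = gb, up_or = sv$orient_b, up_pos = sv$pos_b,
         dn = ga, dn_or = sv$orient_a, dn_pos = sv$pos_a)
  )
  results <- list()
  for (asn in assignments) {
    if (!orientation_compatible(asn$up$strand, asn$up_or, "upstream")) next
    if (!orientation_compatible(asn$dn$strand, asn$dn_or, "downstream")) next
    up <- breakpoint_phase(asn$up, asn$up_pos, "five")
    dn <- breakpoint_phase(asn$dn, asn$dn_pos, "three")
    # a junction retaining the complete upstream CDS (incl. its stop codon)
    # or discarding the whole downstream CDS produces no fusion ORF
    if (up$kind == "utr3" || dn$kind == "utr3") next
    status <-
      if (dn$kind == "utr5" || up$kind == "utr5") "ambiguous"  # whole downstream CDS retained / promoter swap
      else if (up$kind == "split" || dn$kind == "split") "ambiguous"
      else if (up$phase == dn$phase) "inframe"
      else "out_of_frame"
    results[[length(results) + 1L]] <- tibble::tibble(
      status = status, upstream_gene = asn$up$gene, downstream_gene = asn$dn$gene,
      reportable = status %in% c("inframe", "ambiguous")
    )
  }
  if (!length(results)) return(not_reportable("untranscribed"))
  res <- dplyr::bind_rows(results)
  # prefer the reportable interpretation, then inframe over ambiguous
  res |>
    dplyr::arrange(dplyr::desc(.data$reportable),
                   match(.data$status, c("inframe", "ambiguous", "out_of_frame"))) |>
    dplyr::slice(1)
}
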