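# Somatic interpretation: consequence annotation on canonical transcripts
# and the five-rule somatic filter cascade.
#
# The cascade labels rather than deletes: every rule sets its own flag, the
# flags are additive and order-independent, and the high-confidence subset
# (input to TMB and mutation catalogs) is the set with no flags. Reportable
# actionable variants keep their labels so clinical review sees them.

# --- consequence annotation -------------------------------------------------

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

#' Annotate variant consequences on canonical transcripts
#'
#' Assigns to each variant at most one consequence from the curated set
#' ([curated_consequences()]) on the canonical transcript of the single
#' overlapping gene: coding SNVs are translated (start/stop aware), coding
#' indels are classified by length modulo 3, the first/last 2 intronic bases
#' of each intron are splice donor/acceptor sites (strand aware), and the
#' conventional splice region is 3-8 intronic or 1-3 exonic bases from an
#' exon-intron junction. Variants outside every transcript, deep intronic
#' variants and synonymous SNVs get `NA` (not reportable).
#'
#' @param variants Tibble with `chrom,pos,ref,alt` (normalized).
#' @param gene_models Gene-model tibble.
#' @param reference Named character vector of contig sequences.
#' @return `variants` with added `gene`, `transcript_id`, `consequence`.
#' @export
annotate_consequence <- function(variants, gene_models, reference) {
  v <- tibble::as_tibble(variants)
  n <- nrow(v)
  gene <- rep(NA_character_, n)
  tx <- rep(NA_character_, n)
  cons <- rep(NA_character_, n)
  if (!n) {
    return(dplyr::mutate(v, gene = character(), transcript_id = character(),
                         consequence = character()))
  }
  spans <- gene_models |>
    dplyr::mutate(
      span_start = purrr::map_int(.data$exons, ~ min(.x$start)),
      span_end = purrr::map_int(.data$exons, ~ max(.x$end))
    )
  code <- genetic_code()
  for (i in seq_len(n)) {
    vstart <- v$pos[i]
    vend <- v$pos[i] + nchar(v$ref[i]) - 1L
    hit <- which(spans$chrom == v$chrom[i] & spans$span_start <= vend & spans$span_end >= vstart)
    if (!length(hit)) next
    g <- gene_models[hit[1], ]
    gene[i] <- g$gene
    tx[i] <- g$transcript_id
    cons[i] <- consequence_one(v$chrom[i], v$pos[i], v$ref[i], v$alt[i], g, reference, code)
  }
  v$gene <- gene
  v$transcript_id <- tx
  v$consequence <- cons
  v
}

consequence_one <- function(chrom, pos, ref, alt, g, reference, code) {
  ex <- g$exons[[1]]
  n_ex <- nrow(ex)
  is_snv <- nchar(ref) == 1 && nchar(alt) == 1
  vstart <- pos
  vend <- pos + nchar(ref) - 1L

  exonic_positions <- function(p) {
    any(p >= ex$start & p <= ex$end)
  }
  # splice classification for a genomic position
  splice_class <- function(p) {
    if (n_ex < 2) return(NA_character_)
    for (j in seq_len(n_ex - 1L)) {
      intron_l <- ex$end[j] + 1L
      intron_r <- ex$start[j + 1L] - 1L
      if (p >= intron_l && p <= intron_r) {
        dl <- p - intron_l + 1L   # 1 = first intron base (left side)
        dr <- intron_r - p + 1L   # 1 = last intron base (right side)
        left_site <- if (g$strand == "+") "splice_donor_variant" else "splice_acceptor_variant"
        right_site <- if (g$strand == "+") "splice_acceptor_variant" else "splice_donor_variant"
        if (dl <= 2) return(left_site)
        if (dr <= 2) return(right_site)
        if (dl <= 8 || dr <= 8) return("splice_region_variant")
        return(NA_character_)
      }
    }
    NA_character_
  }
  exonic_splice_region <- function(p) {
    for (j in seq_len(n_ex)) {
      if (p >= ex$start[j] && p <= ex$end[j]) {
        near_left <- j > 1 && (p - ex$start[j]) <= 2L
        near_right <- j < n_ex && (ex$end[j] - p) <= 2L
        return(near_left || near_right)
      }
    }
    FALSE
  }

  if (!is_snv) {
    # indel: coding if any affected base is exonic CDS
    affected <- seq(vstart, vend)
    in_cds <- any(vapply(affected, function(p) {
      p >= g$cds_start && p <= g$cds_end && exonic_positions(p)
    }, logical(1)))
    if (in_cds) {
      delta <- nchar(alt) - nchar(ref)
      if (delta %% 3 != 0) return("frameshift_variant")
      return(if (delta > 0) "inframe_insertion" else "inframe_deletion")
    }
    for (p in affected) {
      sc <- splice_class(p)
      if (!is.na(sc)) return(sc)
    }
    if (any(vapply(affected, exonic_splice_region, logical(1)))) {
      return("splice_region_variant")
    }
    return(NA_character_)
  }

  # SNV
  if (exonic_positions(pos)) {
    if (pos >= g$cds_start && pos <= g$cds_end) {
      cdsvec <- cds_positions(g)
      idx <- match(pos, cdsvec)
      if (!is.na(idx)) {
        codon_i <- ceiling(idx / 3)
        offset <- (idx - 1L) %% 3L + 1L
        cpos <- cdsvec[(codon_i - 1L) * 3L + 1:3]
        bases <- vapply(cpos, function(p) substr(reference[[chrom]], p, p), character(1))
        if (g$strand == "-") bases <- complement_base(bases)
        ref_codon <- paste(bases, collapse = "")
        alt_base <- if (g$strand == "-") complement_base(alt) else alt
        alt_bases <- bases
        alt_bases[offset] <- alt_base
        alt_codon <- paste(alt_bases, collapse = "")
        aa_ref <- code[[ref_codon]]
        aa_alt <- code[[alt_codon]]
        if (codon_i == 1 && alt_codon != "ATG") return("start_lost")
        if (aa_ref != "*" && aa_alt == "*") return("stop_gained")
        if (aa_ref == "*" && aa_alt != "*") return("stop_lost")
        if (aa_ref != aa_alt) return("missense_variant")
        if (exonic_splice_region(pos)) return("splice_region_variant")
        return(NA_character_)
      }
    }
    # UTR
    if (exonic_splice_region(pos)) return("splice_region_variant")
    return(NA_character_)
  }
  splice_class(pos)
}

# --- panel-of-normals Fisher test -------------------------------------------

fisher_phred_p <- function(a, b, c, d, alternative = "two.sided") {
  if (a + b + c + d == 0) return(1)
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                     alternative = alternative)$p.value
}

#' Aggregate panel allele depths at a site
#'
#' Sums ref and alt depths across panel individuals that do not carry the
#' relevant alternate allele as a germline variant (alt allele fraction below
#' `pon_carrier_min_fraction`). For a site absent from the panel the panel is
#' treated as alt-free at `pon_default_ref_depth` per individual.
#'
#' @param pon A `panel_of_normals`.
#' @param chrom,pos,alt Site key.
#' @param config A [wga_config()].
#' @return List with `ref`, `alt` aggregated counts and `n_included`.
#' @export
pon_site_counts <- function(pon, chrom, pos, alt, config = wga_config()) {
  hit <- which(pon$sites$chrom == chrom & pon$sites$pos == pos & pon$sites$alt == alt)
  if (!length(hit)) {
    n <- max(pon$n_individuals, 1L)
    return(list(ref = n * config$pon_default_ref_depth, alt = 0L, n_included = n))
  }
  rd <- pon$sites$ref_depths[[hit[1]]]
  ad <- pon$sites$alt_depths[[hit[1]]]
  tot <- rd + ad
  frac <- ifelse(tot > 0, ad / tot, 0)
  thr <- config$pon_carrier_min_fraction
  keep <- if (thr <= 0) ad == 0 else frac < thr
  list(ref = sum(rd[keep]), alt = sum(ad[keep]), n_included = sum(keep))
}

#' Panel-of-normals Fisher exact test on the Phred scale
#'
#' Tests whether the tumor ref/alt allele-depth ratio at a site differs from
#' the aggregated ratio in the panel of normals (two-sided Fisher's exact
#' test by default) and reports the p-value as a Phred score,
#' `-10 log10(p)`. Systematic mapping/calling artifacts give tumor ratios
#' close to the panel's noise ratio, hence high p and a Phred score below
#' the filter threshold (50 by default).
#'
#' @param tumor_ref,tumor_alt Tumor allele depths at the site.
#' @param pon A `panel_of_normals`.
#' @param chrom,pos,alt Site key.
#' @param config A [wga_config()].
#' @return A list with `p_value`, `phred` and `table` (2x2 counts: tumor
#'   ref/alt over panel ref/alt). An all-zero table gives phred 0.
#' @examples
#' pon <- simulate_pon(n_individuals = 20, sites = tibble::tibble(
#'   chrom = "chr1", pos = 100L, ref = "C", alt = "T"
#' ), artifact_fraction = 0, seed = 1)
#' pon_fisher_phred(30, 30, pon, "chr1", 100L, "T")$phred
#' @export
pon_fisher_phred <- function(tumor_ref, tumor_alt, pon, chrom, pos, alt,
                             config = wga_config()) {
  if (tumor_ref < 0 || tumor_alt < 0) abort("tumor depths must be nonnegative")
  pc <- pon_site_counts(pon, chrom, pos, alt, config)
  p <- fisher_phred_p(tumor_ref, tumor_alt, pc$ref, pc$alt,
                      alternative = config$fisher_alternative)
  tab <- matrix(c(tumor_ref, tumor_alt, pc$ref, pc$alt), nrow = 2, byrow = TRUE,
                dimnames = list(c("tumor", "panel"), c("ref", "alt")))
  list(p_value = p, phred = phred_from_p(p), table = tab)
}

# --- noisy indel windows ----------------------------------------------------

#' Fraction of failed base calls around an indel
#'
#' Computes the fraction of base calls failed by the caller's quality
#' filters in the window extending `noisy_window_halfwidth` (default 50)
#' bases to either side of the indel position (101 positions including the
#' indel itself; truncated at the contig start). The track is a per-position
#' `(fail_frac, depth)` approximation of the caller's read-level counts;
#' positions absent from the track contribute `noisy_default_depth`
#' fail-free calls.
#'
#' @param chrom,pos Indel site.
#' @param quality_fail Track tibble `chrom,pos,fail_frac,depth`.
#' @param config A [wga_config()].
#' @return Fraction in `[0, 1]`.
#' @export
noisy_window_fraction <- function(chrom, pos, quality_fail, config = wga_config()) {
  hw <- config$noisy_window_halfwidth
  lo <- max(1L, pos - hw)
  hi <- pos + hw
  win <- quality_fail[quality_fail$chrom == chrom &
                        quality_fail$pos >= lo & quality_fail$pos <= hi, , drop = FALSE]
  n_missing <- (hi - lo + 1L) - nrow(win)
  failed <- sum(win$fail_frac * win$depth)
  total <- sum(win$depth) + n_missing * config$noisy_default_depth
  if (total <= 0) return(0)
  failed / total
}

# --- the filter cascade -----------------------------------------------------

#' Apply the five-rule somatic filter cascade
#'
#' Sets one flag per rule (the rules commute; flags are additive):
#' \describe{
#'   \item{pop_af}{population germline allele frequency above 1%}
#'   \item{recurrent}{cohort somatic recurrence above 5%}
#'   \item{simple_repeat}{overlap with a simple-repeat interval}
#'   \item{noisy_indel}{indel with at least 10% of base calls failed in the
#'     +/-50 bp window}
#'   \item{pon_artifact}{SNV whose panel-of-normals Fisher Phred score is
#'     below 50}
#' }
#' Flagged variants are retained and labeled, not removed; the
#' high-confidence subset (`high_confidence == TRUE`, no flags) is the input
#' to TMB and mutation catalogs.
#'
#' @param variants Tibble with `chrom,pos,ref,alt,vtype` and tumor depths.
#' @param bundle A [reference_bundle()].
#' @return `variants` with `population_af`, `cohort_recurrence`, `pon_phred`,
#'   the five logical `flag_*` columns, a `filter_flags` list column, and
#'   `high_confidence`.
#' @export
apply_somatic_filters <- function(variants, bundle) {
  cfg <- bundle$config
  v <- tibble::as_tibble(variants)
  if (!"vtype" %in% names(v)) {
    v$vtype <- ifelse(nchar(v$ref) == 1 & nchar(v$alt) == 1, "SNV", "indel")
  }
  v <- v |>
    dplyr::left_join(
      dplyr::select(bundle$pop_af, "chrom", "pos", "ref", "alt", population_af = "af"),
      by = c("chrom", "pos", "ref", "alt")
    ) |>
    dplyr::left_join(
      dplyr::select(bundle$recurrence, "chrom", "pos", "ref", "alt", cohort_recurrence = "recurrence"),
      by = c("chrom", "pos", "ref", "alt")
    ) |>
    dplyr::mutate(
      population_af = tidyr::replace_na(.data$population_af, 0),
      cohort_recurrence = tidyr::replace_na(.data$cohort_recurrence, 0)
    )

  # repeat overlap (variant footprint vs 1-based closed repeat intervals)
  rep_tab <- bundle$repeats
  v$flag_simple_repeat <- vapply(seq_len(nrow(v)), function(i) {
    vs <- v$pos[i]; ve <- v$pos[i] + nchar(v$ref[i]) - 1L
    any(rep_tab$chrom == v$chrom[i] & rep_tab$start <= ve & rep_tab$end >= vs)
  }, logical(1))

  v$flag_pop_af <- v$population_af > cfg$pop_af_threshold
  v$flag_recurrent <- v$cohort_recurrence > cfg$recurrence_threshold

  v$noisy_fraction <- NA_real_
  idx_indel <- which(v$vtype == "indel")
  for (i in idx_indel) {
    v$noisy_fraction[i] <- noisy_window_fraction(v$chrom[i], v$pos[i],
                                                 bundle$quality_fail, cfg)
  }
  v$flag_noisy_indel <- !is.na(v$noisy_fraction) &
    v$noisy_fraction >= cfg$noisy_window_threshold

  # PoN Fisher for SNVs, memoized on the aggregated 2x2 table
  v$pon_phred <- NA_real_
  idx_snv <- which(v$vtype == "SNV")
  if (length(idx_snv)) {
    tabs <- t(vapply(idx_snv, function(i) {
      pc <- pon_site_counts(bundle$pon, v$chrom[i], v$pos[i], v$alt[i], cfg)
      c(v$tumor_ref_depth[i] %||% 0L, v$tumor_alt_depth[i] %||% 0L, pc$ref, pc$alt)
    }, numeric(4)))
    key <- apply(tabs, 1, paste, collapse = ",")
    uniq <- !duplicated(key)
    pu <- vapply(which(uniq), function(r) {
      fisher_phred_p(tabs[r, 1], tabs[r, 2], tabs[r, 3], tabs[r, 4],
                     alternative = cfg$fisher_alternative)
    }, numeric(1))
    p <- pu[match(key, key[uniq])]
    v$pon_phred[idx_snv] <- phred_from_p(p)
  }
  v$flag_pon_artifact <- !is.na(v$pon_phred) & v$pon_phred < cfg$phred_threshold

  flag_cols <- c("flag_pop_af", "flag_recurrent", "flag_simple_repeat",
                 "flag_noisy_indel", "flag_pon_artifact")
  flag_names <- c("pop_af", "recurrent", "simple_repeat", "noisy_indel", "pon_artifact")
  fm <- as.matrix(v[flag_cols])
  v$filter_flags <- apply(fm, 1, function(row) flag_names[row], simplify = FALSE)
  v$high_confidence <- rowSums(fm) == 0
  v
}

#' Per-case filter tally
#'
#' @param variants Output of [apply_somatic_filters()].
#' @return One-row tibble with counts per flag, total and high-confidence.
#' @export
filter_tally <- function(variants) {
  tibble::tibble(
    n_variants = nrow(variants),
    n_pop_af = sum(variants$flag_pop_af),
    n_recurrent = sum(variants$flag_recurrent),
    n_simple_repeat = sum(variants$flag_simple_repeat),
    n_noisy_indel = sum(variants$flag_noisy_indel),
    n_pon_artifact = sum(variants$flag_pon_artifact),
    n_high_confidence = sum(variants$high_confidence)
  )
}
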