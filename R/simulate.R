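# Synthetic cohort generator.
#
# Generates every input the pipeline consumes -- call sets, resource tables,
# panel of normals, clinical tables -- with a per-case ground-truth record, so
# that every downstream stage is testable without any external data. The
# generator is deterministic under a fixed seed. Actionable events are
# planted, not emergent; mutation placement respects trinucleotide context
# but not selection.

#' Simulation configuration
#'
#' Defaults define the study conditions the generator emulates: a solid-tumor
#' cohort over ten tumor types with type-specific signature mixtures and
#' log-normal mutation counts, planted actionable events of every class,
#' panel-of-normals noise sites, purity/ploidy draws, registry/episode tables
#' with a configurable type-mismatch rate and stage availability, and
#' proportional-hazards survival with stage as a confounder.
#'
#' @param ... Named overrides of any default. Unknown names error.
#' @return A named list of class `sim_config`.
#' @export
simulation_config <- function(...) {
  tumor_mix <- c(
    breast = 0.20, colon = 0.15, rectum = 0.05, ovarian_hgs = 0.10,
    endometrial = 0.10, melanoma = 0.10, lung_adeno = 0.10,
    glioblastoma = 0.05, sarcoma = 0.10, pancreatic = 0.05
  )
  base_mixtures <- list(
    breast = c(SBS1 = 0.35, SBS2 = 0.20, SBS13 = 0.15, SBS5 = 0.20, SBS3 = 0.10),
    colon = c(SBS1 = 0.50, SBS5 = 0.30, SBS18 = 0.20),
    rectum = c(SBS1 = 0.50, SBS5 = 0.30, SBS18 = 0.20),
    ovarian_hgs = c(SBS1 = 0.30, SBS3 = 0.40, SBS5 = 0.30),
    endometrial = c(SBS1 = 0.45, SBS5 = 0.35, SBS2 = 0.20),
    melanoma = c(SBS7a = 0.40, SBS7b = 0.30, SBS1 = 0.15, SBS5 = 0.15),
    lung_adeno = c(SBS4 = 0.45, SBS92 = 0.15, SBS1 = 0.20, SBS5 = 0.20),
    glioblastoma = c(SBS1 = 0.60, SBS5 = 0.40),
    sarcoma = c(SBS1 = 0.45, SBS5 = 0.40, SBS8 = 0.15),
    pancreatic = c(SBS1 = 0.45, SBS5 = 0.35, SBS18 = 0.20)
  )
  mmr_mixture <- c(SBS6 = 0.25, SBS15 = 0.15, SBS20 = 0.10, SBS44 = 0.15,
                   SBS1 = 0.20, SBS5 = 0.15)
  cfg <- list(
    n_cases = 300L,
    genome_seed = 1L,
    tumor_type_mix = tumor_mix,
    base_mixtures = base_mixtures,
    mmr_mixture = mmr_mixture,
    mmr_prob = c(colon = 0.15, endometrial = 0.25, rectum = 0.10),
    mmr_prob_default = 0.02,
    hrd_prob = c(ovarian_hgs = 0.40, breast = 0.10),
    hrd_prob_default = 0.03,
    hrd_disagreement_rate = 0.008,  # CHORD-vs-HRDetect style discordance
    # mutation counts (log-normal), multiplied under MMR deficiency
    mutation_meanlog = c(melanoma = log(700), lung_adeno = log(450)),
    mutation_meanlog_default = log(180),
    mutation_sdlog = 0.45,
    mmr_burden_multiplier = 5,
    # depths
    tumor_depth = 60L,
    # planted event frequencies (per case)
    p_small_variant = 0.50,
    p_off_directory_small_variant = 0.15,
    p_cna_gain = 0.20,
    p_cna_loss = 0.25,
    p_fusion = 0.10,
    p_germline = 0.12,
    p_pgx = 0.08,
    # planted filter violations (per case)
    p_pop_af_site = 0.25,
    p_recurrent_site = 0.25,
    p_repeat_indel = 0.25,
    p_noisy_indel = 0.25,
    p_artifact_sites = 0.40,
    # panel of normals
    pon_individuals = 60L,
    pon_sites = 40L,
    pon_artifact_fraction = 0.4,
    pon_noise_vaf = 0.12,
    # purity / ploidy
    p_low_purity = 0.10,
    purity_shape = c(8, 4),         # beta for eligible cases (~0.67 mean)
    ploidy_levels = c(2, 2, 2, 3, 4),
    # clinical tables
    registry_coverage = 1.0,
    registry_mismatch_rate = 0.05,
    stage_availability = 0.85,
    p_metastatic = 0.10,
    p_pcr_amplified = 0.05,
    diagnosis_offset_max_days = 300L,
    followup_days = 1825L,
    stage_probs = c(0.25, 0.30, 0.25, 0.20),
    # survival (days; exponential, stage-dependent baseline)
    baseline_hazard = 1 / 1200,
    stage_hazard_multiplier = 1.6,
    marker_hr = list(hrd = 0.5),
    gene_hr = list(TP53 = 1.5),
    treatment_probs = list(platinum = c(ovarian_hgs = 0.7, breast = 0.4),
                           immunotherapy = c(melanoma = 0.5, lung_adeno = 0.4)),
    treatment_prob_default = 0.10,
    seed = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) abort(paste0("unknown simulation field(s): ", paste(bad, collapse = ", ")))
    cfg[names(overrides)] <- overrides
  }
  structure(cfg, class = "sim_config")
}

# per-position pyrimidine-strand trinucleotide context for the whole genome
context_index <- function(reference) {
  purrr::imap(reference, function(seq, chrom) {
    n <- nchar(seq)
    bases <- strsplit(seq, "")[[1]]
    up <- bases[1:(n - 2)]
    mid <- bases[2:(n - 1)]
    down <- bases[3:n]
    pyr <- mid %in% c("C", "T")
    ctx <- ifelse(pyr, paste0(up, mid, down),
                  revcomp_vec(up, mid, down))
    tibble::tibble(chrom = chrom, pos = 2:(n - 1), base = mid, context = ctx)
  }) |>
    dplyr::bind_rows()
}

revcomp_vec <- function(up, mid, down) {
  paste0(chartr("ACGT", "TGCA", down), chartr("ACGT", "TGCA", mid),
         chartr("ACGT", "TGCA", up))
}

#' Draw a mutation catalog from a signature mixture
#'
#' Draws `n_mutations` substitutions multinomially from the 96-context
#' probability vector implied by the exposure mixture, then places each
#' mutation on the toy genome at a position with the matching trinucleotide
#' context (reverse-complemented placements get complemented alleles).
#'
#' @param exposures Named nonnegative vector over signature-matrix columns,
#'   summing to 1.
#' @param n_mutations Number of substitutions (>= 0).
#' @param signature_matrix 96 x K signature matrix.
#' @param reference Named character vector of contig sequences.
#' @param seed Integer seed.
#' @param ctx Optional precomputed [context_index()] of `reference`.
#' @return List: `catalog` (named length-96 counts summing to
#'   `n_mutations`), `variants` (tibble `chrom,pos,ref,alt,context96`).
#' @export
simulate_catalog <- function(exposures, n_mutations, signature_matrix,
                             reference, seed = 1L, ctx = NULL) {
  if (n_mutations < 0) abort("n_mutations must be nonnegative")
  if (any(exposures < 0)) abort("exposures must be nonnegative")
  if (abs(sum(exposures) - 1) > 1e-8) abort("exposures must sum to 1")
  expo <- setNames(numeric(ncol(signature_matrix)), colnames(signature_matrix))
  expo[names(exposures)] <- exposures
  probs <- as.numeric(signature_matrix %*% expo)
  contexts <- sbs96_contexts()
  if (is.null(ctx)) ctx <- context_index(reference)
  with_seed(seed, {
    counts <- if (n_mutations > 0) {
      as.integer(rmultinom(1, n_mutations, probs))
    } else integer(96)
    names(counts) <- contexts
    rows <- list()
    for (k in which(counts > 0)) {
      lab <- contexts[k]
      flank <- paste0(substr(lab, 1, 1), substr(lab, 3, 3), substr(lab, 7, 7))
      altp <- substr(lab, 5, 5)  # pyrimidine-strand alternate
      cand <- ctx[ctx$context == flank, , drop = FALSE]
      if (!nrow(cand)) abort(paste0("toy genome lacks context ", flank))
      take <- cand[sample.int(nrow(cand), counts[k], replace = counts[k] > nrow(cand)), ]
      alt <- ifelse(take$base %in% c("C", "T"), altp, complement_base(altp))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = take$chrom, pos = take$pos, ref = take$base, alt = alt,
        context96 = lab
      )
    }
    variants <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), context96 = character())
    list(catalog = counts, variants = variants)
  })
}

#' Simulate a panel of normals
#'
#' Clean sites are alt-free across every panel individual; artifact sites
#' carry low-level alternate-allele noise (binomial at `noise_vaf`) across
#' most individuals, emulating systematic mapping/calling artifacts.
#'
#' @param n_individuals Panel size (>= 1).
#' @param sites Tibble `chrom,pos,ref,alt` of panel sites.
#' @param artifact_fraction Fraction of sites planted as artifacts.
#' @param seed Integer seed.
#' @param depth_mean Mean per-individual depth.
#' @param noise_vaf Alternate-allele fraction at artifact sites.
#' @return A `panel_of_normals`; `$artifact_sites` lists the planted sites.
#' @export
simulate_pon <- function(n_individuals, sites, artifact_fraction, seed = 1L,
                         depth_mean = 30, noise_vaf = 0.12) {
  if (n_individuals < 1) abort("n_individuals must be >= 1")
  sites <- tibble::as_tibble(sites)
  with_seed(seed, {
    n_art <- round(artifact_fraction * nrow(sites))
    art_idx <- if (n_art > 0) sample.int(nrow(sites), n_art) else integer()
    ref_depths <- vector("list", nrow(sites))
    alt_depths <- vector("list", nrow(sites))
    for (i in seq_len(nrow(sites))) {
      depth <- stats::rpois(n_individuals, depth_mean)
      if (i %in% art_idx) {
        alt <- stats::rbinom(n_individuals, depth, noise_vaf)
      } else {
        alt <- integer(n_individuals)
      }
      ref_depths[[i]] <- as.integer(depth - alt)
      alt_depths[[i]] <- as.integer(alt)
    }
    out <- sites
    out$ref_depths <- ref_depths
    out$alt_depths <- alt_depths
    new_pon(
      dplyr::select(out, "chrom", "pos", "alt", "ref_depths", "alt_depths"),
      artifact_sites = sites[sort(art_idx), c("chrom", "pos", "ref", "alt")],
      n_individuals = n_individuals
    )
  })
}

# find a coding SNV/indel of the requested consequence inside a gene;
# consumes RNG state (call under with_seed)
plant_coding_variant <- function(g, reference, kind = "missense_variant") {
  code <- genetic_code()
  cdsvec <- cds_positions(g)
  n_codon <- length(cdsvec) / 3
  if (kind %in% c("splice_donor_variant", "splice_acceptor_variant",
                  "splice_region_variant")) {
    ex <- g$exons[[1]]
    cand <- unlist(purrr::map(seq_len(nrow(ex) - 1L), function(j) {
      seq(ex$end[j] + 1L, ex$start[j + 1L] - 1L)
    }))
    for (p in sample(cand)) {
      ref <- ref_seq(reference, g$chrom, p, p)
      for (alt in sample(setdiff(c("A", "C", "G", "T"), ref))) {
        if (identical(consequence_one(g$chrom, p, ref, alt, g, reference, code), kind)) {
          return(tibble::tibble(chrom = g$chrom, pos = p, ref = ref, alt = alt))
        }
      }
    }
    abort(paste0("could not plant a ", kind, " in gene ", g$gene))
  }
  if (kind %in% c("frameshift_variant", "inframe_deletion")) {
    width <- if (kind == "frameshift_variant") 2L else 4L  # anchor + deleted
    for (ci in sample(seq(4, n_codon - 3))) {
      p <- cdsvec[(ci - 1) * 3 + 1]
      ps <- sort(cdsvec)
      run <- seq(p, p + width - 1L)
      if (!all(run %in% ps)) next  # must not cross an exon boundary
      # avoid ambiguity under left-alignment by requiring a non-repeat anchor
      ref <- ref_seq(reference, g$chrom, p, p + width - 1L)
      alt <- substr(ref, 1, 1)
      cons <- consequence_one(g$chrom, p, ref, alt, g, reference, code)
      if (identical(cons, kind)) {
        return(tibble::tibble(chrom = g$chrom, pos = p, ref = ref, alt = alt))
      }
    }
  } else {
    for (ci in sample(seq(4, n_codon - 3))) {
      for (off in sample(1:3)) {
        p <- cdsvec[(ci - 1) * 3 + off]
        ref <- ref_seq(reference, g$chrom, p, p)
        for (alt in sample(setdiff(c("A", "C", "G", "T"), ref))) {
          cons <- consequence_one(g$chrom, p, ref, alt, g, reference, code)
          if (identical(cons, kind)) {
            return(tibble::tibble(chrom = g$chrom, pos = p, ref = ref, alt = alt))
          }
        }
      }
    }
  }
  abort(paste0("could not plant a ", kind, " in gene ", g$gene))
}

# intergenic positions (outside every gene span, away from contig ends)
intergenic_positions <- function(genome, margin = 60L) {
  gm <- genome$gene_models
  out <- list()
  for (chrom in names(genome$reference)) {
    n <- nchar(genome$reference[[chrom]])
    mask <- rep(TRUE, n)
    mask[seq_len(margin)] <- FALSE
    mask[(n - margin):n] <- FALSE
    for (i in which(gm$chrom == chrom)) {
      ex <- gm$exons[[i]]
      lo <- max(1L, min(ex$start) - 10L); hi <- min(n, max(ex$end) + 10L)
      mask[lo:hi] <- FALSE
    }
    out[[chrom]] <- tibble::tibble(chrom = chrom, pos = which(mask))
  }
  dplyr::bind_rows(out)
}

#' Simulate a full cohort with ground truth
#'
#' Builds the toy genome and every cohort resource (simple repeats,
#' population-AF and recurrence tables, panel of normals, quality-fail
#' track, ClinVar-style and PGx tables, signature matrix), then simulates
#' `n_cases` tumor cases with background mutations drawn from type-specific
#' signature mixtures plus planted actionable events and filter violations,
#' and finally the linked clinical tables.
#'
#' @param config A [simulation_config()].
#' @return A list of class `wga_simulation`: `genome`, `bundle`
#'   (a [reference_bundle()]), `cases` (tibble), `call_sets` (per-case list
#'   of `small_variants`, `germline_variants`, `cna_segments`, `svs`),
#'   `truth` (list: `events` tibble of planted events, `case_truth` tibble
#'   of case-level truth), `clinical` (registry/episodes/treatments/deaths).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  genome <- toy_genome(config$genome_seed)
  seed <- config$seed
  ctx <- context_index(genome$reference)
  sig <- synthetic_signature_matrix()
  gm <- genome$gene_models

  resources <- with_seed(child_seed(seed, 1), {
    inter <- intergenic_positions(genome)
    pick <- function(n) inter[sample.int(nrow(inter), n), ]

    # simple repeats: intergenic intervals plus one intronic interval
    rep_anchor <- pick(6)
    repeats <- tibble::tibble(
      chrom = rep_anchor$chrom,
      start = rep_anchor$pos,
      end = rep_anchor$pos + 24L
    )
    tp53 <- gm[gm$gene == "TP53", ]
    ex <- tp53$exons[[1]]
    intron_mid <- (ex$end[1] + ex$start[2]) %/% 2
    repeats <- dplyr::bind_rows(repeats, tibble::tibble(
      chrom = tp53$chrom, start = intron_mid + 10L, end = intron_mid + 20L
    ))

    base_at <- function(d) {
      purrr::map2_chr(d$chrom, d$pos, ~ substr(genome$reference[[.x]], .y, .y))
    }
    rand_alt <- function(ref) {
      vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
             character(1), USE.NAMES = FALSE)
    }
    pa <- pick(12); pa$ref <- base_at(pa); pa$alt <- rand_alt(pa$ref)
    pop_af <- dplyr::mutate(pa, af = rep(c(0.02, 0.05, 0.002), each = 4))
    rc <- pick(12); rc$ref <- base_at(rc); rc$alt <- rand_alt(rc$ref)
    recurrence <- dplyr::mutate(rc, recurrence = rep(c(0.06, 0.10, 0.01), each = 4))

    pon_sites <- pick(config$pon_sites)
    pon_sites$ref <- base_at(pon_sites)
    pon_sites$alt <- rand_alt(pon_sites$ref)

    # noisy regions: quality-fail track elevated around two anchors
    noisy_anchor <- pick(2)
    quality_fail <- purrr::pmap(noisy_anchor, function(chrom, pos, ...) {
      tibble::tibble(chrom = chrom, pos = seq(pos - 60L, pos + 60L),
                     fail_frac = 0.2, depth = 30L)
    }) |> dplyr::bind_rows()

    # ClinVar-style table: planted pathogenic entries for the germline genes,
    # plus under-starred and benign entries
    germ_genes <- c("BRCA1", "PMS2")
    clinvar_rows <- purrr::map(germ_genes, function(gn) {
      g <- gm[gm$gene == gn, ]
      v <- plant_coding_variant(g, genome$reference, "missense_variant")
      v$gene <- gn
      v
    }) |> dplyr::bind_rows()
    clinvar <- dplyr::bind_rows(
      dplyr::mutate(clinvar_rows, classification = "pathogenic", review_stars = 2L),
      {
        g <- gm[gm$gene == "BRCA1", ]
        v <- plant_coding_variant(g, genome$reference, "missense_variant")
        while (v$pos %in% clinvar_rows$pos) {
          v <- plant_coding_variant(g, genome$reference, "missense_variant")
        }
        dplyr::mutate(v, gene = "BRCA1", classification = "pathogenic", review_stars = 1L)
      }
    )
    # PGx alleles in DPYD
    dpyd <- gm[gm$gene == "DPYD", ]
    pgx_rows <- dplyr::bind_rows(
      plant_coding_variant(dpyd, genome$reference, "missense_variant"),
      plant_coding_variant(dpyd, genome$reference, "splice_donor_variant")
    ) |> dplyr::distinct(.data$pos, .keep_all = TRUE)
    pgx_alleles <- pgx_rows |>
      dplyr::mutate(
        gene = "DPYD",
        allele = paste0("DPYD*", dplyr::row_number() + 1L),
        recommendation = "fluoropyrimidine dose omission or adjustment"
      )
    list(repeats = repeats, pop_af = dplyr::select(pop_af, -dplyr::any_of("base")),
         recurrence = recurrence, pon_sites = pon_sites,
         quality_fail = quality_fail, clinvar = clinvar,
         pgx_alleles = pgx_alleles, noisy_anchor = noisy_anchor)
  })

  pon <- simulate_pon(config$pon_individuals, resources$pon_sites,
                      config$pon_artifact_fraction, seed = child_seed(seed, 2),
                      noise_vaf = config$pon_noise_vaf)

  bundle <- reference_bundle(
    gene_models = gm, repeats = resources$repeats, pop_af = resources$pop_af,
    recurrence = resources$recurrence, pon = pon,
    quality_fail = resources$quality_fail, signature_matrix = sig,
    clinvar = resources$clinvar, directory = genome$directory,
    pgx_alleles = resources$pgx_alleles, reference = genome$reference
  )

  cases <- vector("list", config$n_cases)
  call_sets <- vector("list", config$n_cases)
  events <- vector("list", config$n_cases)
  case_truth <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    sim <- simulate_case(genome, bundle, resources, config, i,
                         seed = child_seed(seed, 100 + i), ctx = ctx)
    cases[[i]] <- sim$case
    call_sets[[i]] <- sim$call_set
    events[[i]] <- sim$events
    case_truth[[i]] <- sim$case_truth
  }
  cases <- dplyr::bind_rows(cases)
  names(call_sets) <- cases$case_id
  truth <- list(
    events = dplyr::bind_rows(events),
    case_truth = dplyr::bind_rows(case_truth)
  )
  clinical <- simulate_clinical_tables(cases, truth$case_truth, genome, config,
                                       seed = child_seed(seed, 3))
  structure(
    list(genome = genome, bundle = bundle, cases = cases,
         call_sets = call_sets, truth = truth, clinical = clinical,
         config = config),
    class = "wga_simulation"
  )
}

#' @exportS3Method base::print
print.wga_simulation <- function(x, ...) {
  cat("<wga_simulation> ", nrow(x$cases), " cases, ",
      nrow(x$truth$events), " planted events\n", sep = "")
  invisible(x)
}

# one case: metadata, call sets, planted events, truth
simulate_case <- function(genome, bundle, resources, config, case_index, seed, ctx) {
  gm <- genome$gene_models
  with_seed(seed, {
    case_id <- sprintf("CASE_%04d", case_index)
    tumor_type <- sample(names(config$tumor_type_mix), 1,
                         prob = config$tumor_type_mix)
    low_purity <- runif(1) < config$p_low_purity
    purity <- if (low_purity) runif(1, 0.10, 0.30) else
      rbeta(1, config$purity_shape[1], config$purity_shape[2])
    purity <- round(purity, 3)
    ploidy <- sample(config$ploidy_levels, 1)
    submitted_metastatic <- runif(1) < config$p_metastatic
    stage <- sample(1:4, 1, prob = config$stage_probs)
    if (submitted_metastatic) stage <- 4L
    sample_date <- as.Date("2016-01-01") + sample.int(1000, 1)
    sample_route <- if (runif(1) < 0.945) "surgical_resection" else "biopsy"

    # markers
    mmr_p <- config$mmr_prob[tumor_type]
    if (is.na(mmr_p)) mmr_p <- config$mmr_prob_default
    mmr <- runif(1) < mmr_p
    hrd_p <- config$hrd_prob[tumor_type]
    if (is.na(hrd_p)) hrd_p <- config$hrd_prob_default
    hrd <- runif(1) < hrd_p

    expo <- if (mmr) config$mmr_mixture else config$base_mixtures[[tumor_type]]
    if (hrd && !mmr) {
      expo <- c(expo * 0.6, SBS3 = if ("SBS3" %in% names(expo)) NA else 0.4)
      expo <- expo[!is.na(expo)]
      expo <- tapply(expo, names(expo), sum)
      expo <- expo / sum(expo)
      expo <- setNames(as.numeric(expo), names(expo))
    }
    meanlog <- config$mutation_meanlog[tumor_type]
    if (is.na(meanlog)) meanlog <- config$mutation_meanlog_default
    n_mut <- round(rlnorm(1, meanlog, config$mutation_sdlog))
    if (mmr) n_mut <- n_mut * config$mmr_burden_multiplier

    cat_sim <- simulate_catalog(expo, n_mut, bundle$signature_matrix,
                                genome$reference, seed = child_seed(seed, 7),
                                ctx = ctx)
    somatic <- cat_sim$variants |>
      dplyr::distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
      dplyr::select("chrom", "pos", "ref", "alt")

    depth <- config$tumor_depth
    vaf <- max(purity / 2, 0.05)
    somatic$tumor_alt_depth <- pmin(depth, stats::rbinom(nrow(somatic), depth, vaf) + 1L)
    somatic$tumor_ref_depth <- depth - somatic$tumor_alt_depth

    events <- list()
    add_event <- function(kind, gene = NA_character_, chrom = NA_character_,
                          pos = NA_integer_, ref = NA_character_,
                          alt = NA_character_, scenario = NA_integer_,
                          expected_flag = NA_character_, clean = TRUE) {
      events[[length(events) + 1L]] <<- tibble::tibble(
        case_id = case_id, kind = kind, gene = gene, chrom = chrom, pos = pos,
        ref = ref, alt = alt, scenario = scenario,
        expected_flag = expected_flag, clean = clean
      )
    }
    plant_somatic <- function(v, vaf_planted = max(purity / 2, 0.30)) {
      # deterministic depths keep planted events clear of the PoN filter
      alt_d <- as.integer(round(depth * vaf_planted))
      row <- tibble::tibble(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                            tumor_alt_depth = alt_d,
                            tumor_ref_depth = depth - alt_d)
      somatic <<- somatic |>
        dplyr::filter(!(.data$chrom == v$chrom & .data$pos == v$pos &
                          .data$alt == v$alt)) |>
        dplyr::bind_rows(row)
    }

    dir_small <- genome$directory |>
      dplyr::filter(.data$variant_class == "small_variant")
    # actionable small variant in an indicated gene
    if (runif(1) < config$p_small_variant) {
      genes_here <- dir_small$gene[dir_small$tumor_type == tumor_type]
      if (length(genes_here)) {
        gn <- sample(genes_here, 1)
        v <- plant_coding_variant(gm[gm$gene == gn, ], genome$reference,
                                  "missense_variant")
        plant_somatic(v)
        add_event("small_variant", gene = gn, chrom = v$chrom, pos = v$pos,
                  ref = v$ref, alt = v$alt)
      }
    }
    # small variant in a gene not indicated for this type
    if (runif(1) < config$p_off_directory_small_variant) {
      genes_off <- setdiff(unique(dir_small$gene),
                           dir_small$gene[dir_small$tumor_type == tumor_type])
      if (length(genes_off)) {
        gn <- sample(genes_off, 1)
        v <- plant_coding_variant(gm[gm$gene == gn, ], genome$reference,
                                  "missense_variant")
        plant_somatic(v)
        add_event("small_variant_off_directory", gene = gn, chrom = v$chrom,
                  pos = v$pos, ref = v$ref, alt = v$alt)
      }
    }

    # CNA: background diploid segments at the case ploidy, then planted events
    cna <- purrr::imap(genome$reference, function(seq, chrom) {
      tibble::tibble(chrom = chrom, start = 1L, end = nchar(seq),
                     total_cn = ploidy, minor_cn = 1)
    }) |> dplyr::bind_rows()
    cna_eligible <- purity > bundle$config$purity_min
    seg_over_gene <- function(g, total_cn, minor_cn) {
      ex <- g$exons[[1]]
      tibble::tibble(chrom = g$chrom, start = min(ex$start) - 5L,
                     end = max(ex$end) + 5L, total_cn = total_cn,
                     minor_cn = minor_cn)
    }
    onco <- gm$gene[gm$role %in% c("oncogene", "both")]
    tsg <- gm$gene[gm$role %in% c("tsg", "both")]
    if (runif(1) < config$p_cna_gain) {
      gn <- sample(onco, 1)
      g <- gm[gm$gene == gn, ]
      cna <- dplyr::bind_rows(cna, seg_over_gene(g, 2 * ploidy + 1, 1))
      add_event("cna_gain", gene = gn, clean = cna_eligible)
    }
    if (runif(1) < config$p_cna_loss) {
      gn <- sample(tsg, 1)
      g <- gm[gm$gene == gn, ]
      scenario <- sample(1:3, 1)
      if (scenario == 1) {
        cna <- dplyr::bind_rows(cna, seg_over_gene(g, 0, 0))
      } else if (scenario == 2) {
        cna <- dplyr::bind_rows(cna, seg_over_gene(g, 1, 0))
        v <- plant_coding_variant(g, genome$reference, "missense_variant")
        plant_somatic(v)
      } else {
        v <- plant_coding_variant(g, genome$reference, "missense_variant")
        plant_somatic(v)
      }
      add_event("cna_loss", gene = gn, scenario = scenario, clean = cna_eligible)
    }

    # SVs
    svs <- tibble::tibble(
      sv_id = character(), svtype = character(),
      chrom_a = character(), pos_a = integer(), orient_a = character(),
      chrom_b = character(), pos_b = integer(), orient_b = character()
    )
    loss3 <- any(purrr::map_lgl(events, ~ .x$kind == "cna_loss" && identical(.x$scenario, 3L)))
    if (loss3) {
      ev <- dplyr::bind_rows(events)
      gn <- ev$gene[ev$kind == "cna_loss"][1]
      g <- gm[gm$gene == gn, ]
      bp <- as.integer((g$cds_start + g$cds_end) %/% 2)
      svs <- dplyr::bind_rows(svs, tibble::tibble(
        sv_id = paste0(case_id, "_SV_DISRUPT"), svtype = "BND",
        chrom_a = g$chrom, pos_a = bp, orient_a = "L",
        chrom_b = "chr1", pos_b = 200L, orient_b = "R"
      ))
    }
    if (runif(1) < config$p_fusion) {
      up <- gm[gm$gene == "EML4", ]; dn <- gm[gm$gene == "ALK", ]
      exu <- up$exons[[1]]; exd <- dn$exons[[1]]
      pos_up <- as.integer((exu$end[1] + exu$start[2]) %/% 2)  # intron 1
      pos_dn <- as.integer((exd$end[1] + exd$start[2]) %/% 2)
      svs <- dplyr::bind_rows(svs, tibble::tibble(
        sv_id = paste0(case_id, "_SV_FUSION"), svtype = "BND",
        chrom_a = up$chrom, pos_a = pos_up, orient_a = "L",
        chrom_b = dn$chrom, pos_b = pos_dn, orient_b = "R"
      ))
      add_event("fusion", gene = "ALK", chrom = dn$chrom, pos = pos_dn)
    }

    # germline call set: planted pathogenic / truncating + benign background
    germline <- tibble::tibble(chrom = character(), pos = integer(),
                               ref = character(), alt = character())
    germ_dir <- genome$directory |>
      dplyr::filter(.data$variant_class == "germline", .data$tumor_type == !!tumor_type)
    if (nrow(germ_dir) && runif(1) < config$p_germline) {
      gn <- sample(unique(germ_dir$gene), 1)
      if (runif(1) < 0.5) {
        cv <- bundle$clinvar |>
          dplyr::filter(.data$gene == gn, .data$classification == "pathogenic",
                        .data$review_stars >= 2)
        v <- cv[1, c("chrom", "pos", "ref", "alt")]
        basis <- "clinvar"
      } else {
        v <- plant_coding_variant(gm[gm$gene == gn, ], genome$reference,
                                  "frameshift_variant")
        basis <- "predicted_truncating"
      }
      germline <- dplyr::bind_rows(germline, v)
      add_event("germline", gene = gn, chrom = v$chrom, pos = v$pos,
                ref = v$ref, alt = v$alt, expected_flag = basis)
    }
    pgx_hit <- runif(1) < config$p_pgx
    if (pgx_hit) {
      al <- bundle$pgx_alleles[sample.int(nrow(bundle$pgx_alleles), 1), ]
      germline <- dplyr::bind_rows(
        germline, dplyr::select(al, "chrom", "pos", "ref", "alt")
      )
      add_event("pgx", gene = al$gene, chrom = al$chrom, pos = al$pos,
                ref = al$ref, alt = al$alt)
    }
    # benign germline background: a common SNP from the population-AF table
    snp <- resources$pop_af[sample.int(nrow(resources$pop_af), 1), ]
    germline <- dplyr::bind_rows(
      germline, dplyr::select(snp, "chrom", "pos", "ref", "alt")
    ) |> dplyr::distinct(.data$chrom, .data$pos, .keep_all = TRUE)

    # planted filter violations (somatic, expected to be flagged)
    if (runif(1) < config$p_pop_af_site) {
      s <- resources$pop_af |> dplyr::filter(.data$af > 0.01)
      s <- s[sample.int(nrow(s), 1), ]
      plant_somatic(s)
      add_event("filter_violation", chrom = s$chrom, pos = s$pos, ref = s$ref,
                alt = s$alt, expected_flag = "pop_af", clean = FALSE)
    }
    if (runif(1) < config$p_recurrent_site) {
      s <- resources$recurrence |> dplyr::filter(.data$recurrence > 0.05)
      s <- s[sample.int(nrow(s), 1), ]
      plant_somatic(s)
      add_event("filter_violation", chrom = s$chrom, pos = s$pos, ref = s$ref,
                alt = s$alt, expected_flag = "recurrent", clean = FALSE)
    }
    if (runif(1) < config$p_repeat_indel) {
      r <- resources$repeats[sample.int(nrow(resources$repeats), 1), ]
      p <- r$start + 2L
      ref <- ref_seq(genome$reference, r$chrom, p, p + 1L)
      v <- tibble::tibble(chrom = r$chrom, pos = p, ref = ref,
                          alt = substr(ref, 1, 1))
      plant_somatic(v)
      add_event("filter_violation", chrom = v$chrom, pos = v$pos, ref = v$ref,
                alt = v$alt, expected_flag = "simple_repeat", clean = FALSE)
    }
    if (runif(1) < config$p_noisy_indel) {
      a <- resources$noisy_anchor[sample.int(nrow(resources$noisy_anchor), 1), ]
      ref <- ref_seq(genome$reference, a$chrom, a$pos, a$pos + 1L)
      v <- tibble::tibble(chrom = a$chrom, pos = a$pos, ref = ref,
                          alt = substr(ref, 1, 1))
      plant_somatic(v)
      add_event("filter_violation", chrom = v$chrom, pos = v$pos, ref = v$ref,
                alt = v$alt, expected_flag = "noisy_indel", clean = FALSE)
    }
    if (runif(1) < config$p_artifact_sites && nrow(bundle$pon$artifact_sites)) {
      s <- bundle$pon$artifact_sites[sample.int(nrow(bundle$pon$artifact_sites), 1), ]
      alt_d <- as.integer(round(depth * config$pon_noise_vaf))
      somatic <- somatic |>
        dplyr::filter(!(.data$chrom == s$chrom & .data$pos == s$pos)) |>
        dplyr::bind_rows(tibble::tibble(
          chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
          tumor_alt_depth = alt_d, tumor_ref_depth = depth - alt_d
        ))
      add_event("filter_violation", chrom = s$chrom, pos = s$pos, ref = s$ref,
                alt = s$alt, expected_flag = "pon_artifact", clean = FALSE)
    }

    somatic <- somatic |>
      dplyr::arrange(.data$chrom, .data$pos) |>
      dplyr::mutate(vtype = ifelse(nchar(.data$ref) == 1 & nchar(.data$alt) == 1,
                                   "SNV", "indel"))

    # HRD classifier calls (the classifiers themselves are upstream inputs)
    hrd_a <- if (hrd) "positive" else "negative"
    hrd_b <- if (runif(1) < config$hrd_disagreement_rate) {
      if (hrd_a == "positive") "negative" else "positive"
    } else hrd_a

    case <- tibble::tibble(
      case_id = case_id, tumor_type = tumor_type, sample_route = sample_route,
      treatment_status = if (runif(1) < 0.936) "naive" else "post_treatment",
      sample_preservation = if (runif(1) < 0.959) "fresh_frozen" else "FFPE",
      purity = purity, ploidy = ploidy, sample_date = sample_date,
      submitted_metastatic = submitted_metastatic,
      pcr_amplified = runif(1) < config$p_pcr_amplified
    )
    case_truth <- tibble::tibble(
      case_id = case_id, tumor_type = tumor_type, stage = stage,
      mmr_deficient = mmr, hrd_status = hrd_a, hrd_status_b = hrd_b,
      n_background_mutations = n_mut, cna_eligible = cna_eligible,
      exposures = list(expo),
      icd10 = genome$icd10_map$icd10[genome$icd10_map$tumor_type == tumor_type]
    )
    list(
      case = case,
      call_set = list(small_variants = somatic, germline_variants = germline,
                      cna_segments = cna, svs = svs),
      events = if (length(events)) dplyr::bind_rows(events) else NULL,
      case_truth = case_truth
    )
  })
}

#' Simulate linked clinical tables
#'
#' Registry rows carry the mapped ICD-10 site of the true tumor type except
#' for a configured fraction of mismatching rows (exercising the
#' hospital-episode fallback); stage fields are present per the configured
#' availability and use the staging vocabulary of the tumor type (FIGO,
#' Dukes, stage_best). Survival times are exponential with a
#' stage-dependent baseline and configured marker/gene hazard ratios; cases
#' without a death are right-censored at their last episode date.
#'
#' @param cases Case tibble from [simulate_cohort()].
#' @param case_truth Case-level truth tibble.
#' @param genome [toy_genome()] output (for the ICD-10/opcode maps).
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return Named list: `registry`, `episodes`, `treatments`, `deaths`.
#' @export
simulate_clinical_tables <- function(cases, case_truth, genome, config, seed = 1L) {
  icd <- genome$icd10_map
  ops <- genome$opcode_map
  with_seed(seed, {
    registry <- list(); episodes <- list(); treatments <- list(); deaths <- list()
    for (i in seq_len(nrow(cases))) {
      cs <- cases[i, ]; tr <- case_truth[case_truth$case_id == cs$case_id, ]
      diagnosis_date <- cs$sample_date - sample.int(config$diagnosis_offset_max_days, 1)

      # survival
      hr <- 1
      if (tr$hrd_status == "positive") hr <- hr * config$marker_hr$hrd
      lambda <- config$baseline_hazard *
        config$stage_hazard_multiplier^(tr$stage - 1) * hr
      t_death <- rexp(1, lambda)
      censor_t <- config$followup_days
      event <- t_death <= censor_t
      t_obs <- min(t_death, censor_t)
      last_seen <- diagnosis_date + ceiling(t_obs)

      # registry
      if (runif(1) < config$registry_coverage) {
        mismatch <- runif(1) < config$registry_mismatch_rate
        site <- if (mismatch) {
          sample(setdiff(icd$icd10, tr$icd10), 1)
        } else tr$icd10
        has_stage <- runif(1) < config$stage_availability
        sub <- sample(c("", "a", "b"), 1)
        registry[[length(registry) + 1L]] <- tibble::tibble(
          participant_id = cs$case_id, diagnosis_date = diagnosis_date,
          icd10_site = site, morphology_code = paste0("M", 8000 + tr$stage),
          behavior = "malignant",
          stage_best = if (has_stage) paste0(tr$stage, sub) else NA_character_,
          figo_stage = if (has_stage && cs$tumor_type %in% c("ovarian_hgs", "endometrial"))
            c("I", "II", "III", "IV")[tr$stage] else NA_character_,
          dukes_stage = if (has_stage && cs$tumor_type %in% c("colon", "rectum"))
            LETTERS[tr$stage] else NA_character_
        )
      }
      # episodes: one at the sampling date (with the type's operation code),
      # plus follow-ups through to the censoring date
      n_ep <- 2L + sample.int(4L, 1)
      span <- max(as.integer(ceiling(t_obs)), 2L)
      ep_dates <- sort(c(cs$sample_date,
                         diagnosis_date + sort(sample.int(span, min(n_ep - 1L, span))),
                         last_seen))
      opcode <- ops$opcode[ops$tumor_type == cs$tumor_type]
      episodes[[length(episodes) + 1L]] <- tibble::tibble(
        participant_id = cs$case_id, appointment_date = ep_dates,
        primary_diagnosis_icd10 = tr$icd10,
        operation_codes = ifelse(ep_dates == cs$sample_date, opcode, "")
      )
      # treatments
      for (tt in c("platinum", "immunotherapy")) {
        p <- config$treatment_probs[[tt]][cs$tumor_type]
        if (is.na(p)) p <- config$treatment_prob_default
        if (runif(1) < p) {
          treatments[[length(treatments) + 1L]] <- tibble::tibble(
            participant_id = cs$case_id,
            treatment_date = diagnosis_date + sample.int(60, 1),
            treatment_type = tt
          )
        }
      }
      if (event) {
        deaths[[length(deaths) + 1L]] <- tibble::tibble(
          participant_id = cs$case_id,
          death_date = diagnosis_date + ceiling(t_obs)
        )
      }
    }
    empty_deaths <- tibble::tibble(participant_id = character(),
                                   death_date = as.Date(character()))
    list(
      registry = dplyr::bind_rows(registry),
      episodes = dplyr::bind_rows(episodes),
      treatments = dplyr::bind_rows(treatments),
      deaths = if (length(deaths)) dplyr::bind_rows(deaths) else empty_deaths
    )
  })
}

#' Simulate a survival cohort with a known hazard ratio
#'
#' Two-arm proportional-hazards generator with stage as a confounder: stage
#' is drawn per subject, the marker group is drawn with stage-dependent
#' probability (so the crude group contrast is confounded), and event times
#' are exponential with a stage-dependent baseline times `hr` for the marker
#' group. Administrative censoring yields roughly the requested censoring
#' fraction.
#'
#' @param n Total subjects.
#' @param hr True hazard ratio of the marker-positive group.
#' @param seed Integer seed.
#' @param censoring Approximate censoring fraction.
#' @param stage_confounded Draw group probability increasing with stage?
#' @return Tibble `time, event, group, stage`.
#' @export
simulate_survival_cohort <- function(n, hr, seed = 1L, censoring = 0.3,
                                     stage_confounded = TRUE) {
  with_seed(seed, {
    stage <- sample(1:4, n, replace = TRUE, prob = c(0.25, 0.3, 0.25, 0.2))
    p_group <- if (stage_confounded) 0.2 + 0.15 * (stage - 1) else rep(0.5, n)
    group <- rbinom(n, 1, p_group)
    lambda <- (1 / 1200) * 1.6^(stage - 1) * hr^group
    t_death <- rexp(n, lambda)
    c_time <- runif(n, 0, stats::quantile(t_death, 1 - censoring / 2) * 2)
    tibble::tibble(
      time = pmin(t_death, c_time),
      event = as.integer(t_death <= c_time),
      group = group, stage = stage
    )
  })
}
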