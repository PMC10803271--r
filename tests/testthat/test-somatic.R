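test_that("consequence annotation covers the curated set on toy transcripts", {
  g <- fixture_genome()
  gm <- g$gene_models
  code <- oncowga:::genetic_code()

  # every plantable consequence type annotates back to itself, on both strands
  kinds <- c("missense_variant", "stop_gained", "frameshift_variant",
             "inframe_deletion", "splice_donor_variant",
             "splice_acceptor_variant", "splice_region_variant")
  for (gene in c("TP53", "KRAS")) {  # plus and minus strand
    gr <- gm[gm$gene == gene, ]
    for (kind in kinds) {
      v <- oncowga:::with_seed(9, oncowga:::plant_coding_variant(gr, g$reference, kind))
      ann <- annotate_consequence(v, gm, g$reference)
      expect_identical(ann$consequence, kind)
      expect_identical(ann$gene, gene)
    }
  }

  # indel length mod 3: 3-bp insertion in frame, 2-bp insertion frameshift
  gr <- gm[gm$gene == "TP53", ]
  p <- oncowga:::cds_positions(gr)[16]
  rb <- substr(g$reference[[gr$chrom]], p, p)
  ins3 <- tibble::tibble(chrom = gr$chrom, pos = p, ref = rb,
                         alt = paste0(rb, "AGT"))
  ins2 <- tibble::tibble(chrom = gr$chrom, pos = p, ref = rb,
                         alt = paste0(rb, "AG"))
  expect_identical(annotate_consequence(ins3, gm, g$reference)$consequence,
                   "inframe_insertion")
  expect_identical(annotate_consequence(ins2, gm, g$reference)$consequence,
                   "frameshift_variant")

  # deep intronic (50 bp from the exon) and intergenic positions: no consequence
  ex <- gr$exons[[1]]
  deep <- tibble::tibble(chrom = gr$chrom, pos = ex$end[1] + 30L, ref = "N", alt = "A")
  deep$ref <- substr(g$reference[[gr$chrom]], deep$pos, deep$pos)
  deep$alt <- setdiff(c("A", "C"), deep$ref)[1]
  expect_true(is.na(annotate_consequence(deep, gm, g$reference)$consequence))
  inter <- tibble::tibble(chrom = "chr1", pos = 5L, ref = "N", alt = "A")
  inter$ref <- substr(g$reference[["chr1"]], 5, 5)
  inter$alt <- setdiff(c("A", "C"), inter$ref)[1]
  ann <- annotate_consequence(inter, gm, g$reference)
  expect_true(is.na(ann$consequence))
  expect_true(is.na(ann$gene))

  # a start-codon disruption is start_lost; synonymous third-position change is NA
  gr2 <- gm[gm$gene == "BRAF", ]
  p1 <- oncowga:::cds_positions(gr2)[1]
  start <- tibble::tibble(chrom = gr2$chrom, pos = p1,
                          ref = substr(g$reference[[gr2$chrom]], p1, p1), alt = "C")
  expect_identical(annotate_consequence(start, gm, g$reference)$consequence,
                   "start_lost")
})

test_that("panel-of-normals Fisher phred matches the hypergeometric oracle", {
  sim <- fixture_sim()
  pon <- sim$bundle$pon

  # a het-like somatic site vs a clean deep panel: strong separation
  clean_site <- dplyr::anti_join(
    pon$sites[1:5, c("chrom", "pos", "alt")],
    dplyr::bind_rows(pon$artifact_sites)[, c("chrom", "pos")],
    by = c("chrom", "pos")
  )[1, ]
  r <- pon_fisher_phred(50, 50, pon, clean_site$chrom, clean_site$pos, clean_site$alt)
  expect_gt(r$phred, 50)
  expect_lt(r$p_value, 1e-5)

  # identical ratios: no association, phred ~ 0
  empty_pon <- oncowga:::new_pon(
    tibble::tibble(chrom = "chrX", pos = 1L, alt = "T",
                   ref_depths = list(c(9900L)), alt_depths = list(c(100L))),
    n_individuals = 1L
  )
  r2 <- pon_fisher_phred(99, 1, empty_pon, "chrX", 1L, "T",
                         wga_config(pon_carrier_min_fraction = 0.5))
  expect_gt(r2$p_value, 0.5)
  expect_lt(r2$phred, 3)

  # implementation equals the enumeration oracle on a grid of tables
  set.seed(31)
  for (i in 1:60) {
    tab <- rmultinom(1, sample(10:150, 1), runif(4, 0.05, 1))
    p_imp <- oncowga:::fisher_phred_p(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p_imp, fisher_p_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
  }
  # degenerate all-zero table: defined result, phred 0
  expect_equal(oncowga:::fisher_phred_p(0, 0, 0, 0), 1)
})

test_that("panel aggregation excludes germline carriers and handles absent sites", {
  pon <- oncowga:::new_pon(
    tibble::tibble(
      chrom = "chr1", pos = 10L, alt = "T",
      ref_depths = list(c(30L, 28L, 10L)),
      alt_depths = list(c(0L, 4L, 12L))   # fractions 0, 0.125, 0.545
    ),
    n_individuals = 3L
  )
  cc <- pon_site_counts(pon, "chr1", 10L, "T")  # carrier threshold 0.35
  expect_equal(cc$n_included, 2L)
  expect_equal(cc$ref, 58L)
  expect_equal(cc$alt, 4L)
  # literal "alt depth 0" reading is recoverable via the threshold
  cc0 <- pon_site_counts(pon, "chr1", 10L, "T",
                         wga_config(pon_carrier_min_fraction = 0))
  expect_equal(cc0$n_included, 1L)
  expect_equal(cc0$alt, 0L)
  # absent site: alt-free panel at the default depth
  ca <- pon_site_counts(pon, "chr9", 1L, "A")
  expect_equal(ca$alt, 0L)
  expect_equal(ca$ref, 3L * wga_config()$pon_default_ref_depth)
})

test_that("artifact sites are flagged while true somatic sites are not", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L),
                          ref = c("A", "C"), alt = c("T", "G"))
  pon <- simulate_pon(80, sites, artifact_fraction = 0.5, seed = 3)
  art <- pon$artifact_sites[1, ]
  clean <- dplyr::anti_join(sites, pon$artifact_sites, by = "pos")[1, ]

  # artifact: tumor ratio drawn at the panel noise ratio -> below threshold
  r_art <- pon_fisher_phred(53, 7, pon, art$chrom, art$pos, art$alt)
  expect_lt(r_art$phred, 50)
  # clean het-like somatic: far above threshold
  r_cln <- pon_fisher_phred(30, 30, pon, clean$chrom, clean$pos, clean$alt)
  expect_gte(r_cln$phred, 50)

  # artifact_fraction 0 -> every site alt-free
  pon0 <- simulate_pon(20, sites, artifact_fraction = 0, seed = 4)
  expect_true(all(vapply(pon0$sites$alt_depths, function(x) all(x == 0), logical(1))))

  # removing the artifact contamination from the panel (alt noise zeroed at
  # constant panel depth) never decreases phred at a true somatic site that
  # coincides with an artifact position
  stripped_sites <- pon$sites
  i <- which(stripped_sites$pos == art$pos)
  tot <- stripped_sites$ref_depths[[i]] + stripped_sites$alt_depths[[i]]
  stripped_sites$ref_depths[[i]] <- tot
  stripped_sites$alt_depths[[i]] <- 0L * tot
  stripped <- oncowga:::new_pon(stripped_sites, n_individuals = pon$n_individuals)
  r_full <- pon_fisher_phred(30, 30, pon, art$chrom, art$pos, art$alt)
  r_strip <- pon_fisher_phred(30, 30, stripped, art$chrom, art$pos, art$alt)
  expect_gte(r_strip$phred, r_full$phred)
})

test_that("noisy-window fraction counts failed base calls over 101 positions", {
  uniform <- tidyr::crossing(chrom = "chr1", pos = 1:300) |>
    dplyr::mutate(fail_frac = 0.2, depth = 30L)
  expect_equal(noisy_window_fraction("chr1", 150L, uniform), 0.2)

  zero <- dplyr::mutate(uniform, fail_frac = 0)
  expect_equal(noisy_window_fraction("chr1", 150L, zero), 0)

  # 10 fully-failed positions of 101 with equal depth: 10/101 < 0.10
  ten <- dplyr::mutate(uniform,
                       fail_frac = ifelse(pos >= 120 & pos <= 129, 1, 0))
  frac <- noisy_window_fraction("chr1", 150L, ten)
  expect_equal(frac, 10 / 101)
  expect_lt(frac, 0.10)

  # window truncates at the contig start
  expect_equal(noisy_window_fraction("chr1", 10L, uniform), 0.2)
})

test_that("filter flags are additive, order-independent and label rather than delete", {
  sim <- fixture_sim()
  bundle <- sim$bundle
  id <- sim$cases$case_id[1]
  v <- sim$call_sets[[id]]$small_variants |>
    annotate_consequence(bundle$gene_models, bundle$reference)
  f1 <- apply_somatic_filters(v, bundle)
  # permuting input order changes nothing
  perm <- sample(nrow(v))
  f2 <- apply_somatic_filters(v[perm, ], bundle) |> dplyr::arrange(chrom, pos, alt)
  f1s <- dplyr::arrange(f1, chrom, pos, alt)
  expect_equal(f2$filter_flags, f1s$filter_flags)
  expect_equal(f2$high_confidence, f1s$high_confidence)
  # nothing dropped
  expect_equal(nrow(f1), nrow(v))
  # high confidence iff no flags
  expect_equal(f1$high_confidence, lengths(f1$filter_flags) == 0)
})

test_that("each filter rule flags its planted violation", {
  bundle <- fixture_sim()$bundle
  g <- fixture_genome()
  pop_site <- bundle$pop_af[bundle$pop_af$af > 0.01, ][1, ]
  rec_site <- bundle$recurrence[bundle$recurrence$recurrence > 0.05, ][1, ]
  low_site <- bundle$pop_af[bundle$pop_af$af <= 0.01, ][1, ]
  rpt <- bundle$repeats[1, ]
  rpt_ref <- substr(g$reference[[rpt$chrom]], rpt$start, rpt$start + 1L)
  v <- tibble::tibble(
    chrom = c(pop_site$chrom, rec_site$chrom, low_site$chrom, rpt$chrom),
    pos = c(pop_site$pos, rec_site$pos, low_site$pos, rpt$start),
    ref = c(pop_site$ref, rec_site$ref, low_site$ref, rpt_ref),
    alt = c(pop_site$alt, rec_site$alt, low_site$alt, substr(rpt_ref, 1, 1)),
    tumor_ref_depth = 30L, tumor_alt_depth = 30L
  )
  f <- apply_somatic_filters(v, bundle)
  expect_true("pop_af" %in% f$filter_flags[[1]])
  expect_true("recurrent" %in% f$filter_flags[[2]])
  expect_false("pop_af" %in% f$filter_flags[[3]])   # 1% rule is strict
  expect_true("simple_repeat" %in% f$filter_flags[[4]])
  expect_false(f$high_confidence[[1]])
})
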