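onco_gene <- function() fixture_genome()$gene_models |> dplyr::filter(gene == "EGFR")
tsg_gene <- function() fixture_genome()$gene_models |> dplyr::filter(gene == "TP53")

seg_over <- function(g, total_cn, minor_cn = NA_real_) {
  ex <- g$exons[[1]]
  tibble::tibble(chrom = g$chrom, start = min(ex$start) - 5L,
                 end = max(ex$end) + 5L, total_cn = total_cn, minor_cn = minor_cn)
}

missense_in <- function(g) {
  tibble::tibble(gene = g$gene, consequence = "missense_variant")
}
no_variants <- tibble::tibble(gene = character(), consequence = character())
no_svs <- tibble::tibble(sv_id = character(), svtype = character(),
                         chrom_a = character(), pos_a = integer(),
                         orient_a = character(), chrom_b = character(),
                         pos_b = integer(), orient_b = character())

test_that("oncogene gains require CN at least twice the ploidy and purity above 30%", {
  g <- onco_gene()
  hit <- classify_gain(g, seg_over(g, 4), purity = 0.6, ploidy = 2)
  expect_identical(hit$kind, "gain")
  expect_true(hit$eligible)
  # 6 < 2 x 3.1: no finding (real-valued comparison, no rounding)
  expect_null(classify_gain(g, seg_over(g, 6), purity = 0.6, ploidy = 3.1))
  expect_identical(classify_gain(g, seg_over(g, 6.2), purity = 0.6, ploidy = 3.1)$kind,
                   "gain")
  # purity gate: at or below 0.30 returns ineligible, never a finding
  low <- classify_gain(g, seg_over(g, 10), purity = 0.25, ploidy = 2)
  expect_false(low$eligible)
  low2 <- classify_gain(g, seg_over(g, 10), purity = 0.30, ploidy = 2)
  expect_false(low2$eligible)
  # tumor suppressors are not assessed for gain
  expect_null(classify_gain(tsg_gene(), seg_over(tsg_gene(), 10), 0.6, 2))
  expect_error(classify_gain(g, seg_over(g, 4), 0.6, ploidy = 0), "ploidy")
})

test_that("loss scenarios follow the published rules with precedence 1 > 2 > 3", {
  g <- tsg_gene()
  # scenario 1: homozygous deletion, regardless of small variants
  s1 <- classify_loss(g, seg_over(g, 0, 0), no_variants, no_svs, 0.6, 2)
  expect_identical(s1$scenario, 1L)
  # CN = 1 without a small variant: nothing
  expect_null(classify_loss(g, seg_over(g, 1, 0), no_variants, no_svs, 0.6, 2))
  # CN = 1 with a nonsynonymous small variant: scenario 2
  s2 <- classify_loss(g, seg_over(g, 1, 0), missense_in(g), no_svs, 0.6, 2)
  expect_identical(s2$scenario, 2L)
  # copy-neutral LOH: total at ploidy, minor CN 0, plus small variant
  s2b <- classify_loss(g, seg_over(g, 2, 0), missense_in(g), no_svs, 0.6, 2)
  expect_identical(s2b$scenario, 2L)
  # minor CN 1 at ploidy is not LOH
  expect_null(classify_loss(g, seg_over(g, 2, 1), missense_in(g), no_svs, 0.6, 2))
  # splice_region alone is not "nonsynonymous"
  sr <- tibble::tibble(gene = g$gene, consequence = "splice_region_variant")
  expect_null(classify_loss(g, seg_over(g, 1, 0), sr, no_svs, 0.6, 2))
  # scenario 3: SV breakpoint inside the CDS plus small variant
  sv <- tibble::tibble(sv_id = "S", svtype = "BND", chrom_a = g$chrom,
                       pos_a = as.integer((g$cds_start + g$cds_end) %/% 2),
                       orient_a = "L", chrom_b = "chr1", pos_b = 5L, orient_b = "R")
  s3 <- classify_loss(g, seg_over(g, 2, 1), missense_in(g), sv, 0.6, 2)
  expect_identical(s3$scenario, 3L)
  # precedence: CN 0 wins over an SV + small variant combination
  s1b <- classify_loss(g, seg_over(g, 0, 0), missense_in(g), sv, 0.6, 2)
  expect_identical(s1b$scenario, 1L)
  # purity gate
  expect_false(classify_loss(g, seg_over(g, 0, 0), no_variants, no_svs, 0.2, 2)$eligible)
})

test_that("co-occurrence CNA events use the one-copy rule against rounded ploidy", {
  og <- onco_gene(); tg <- tsg_gene()
  expect_identical(cna_event_for_cooccurrence(og, seg_over(og, 3), 0.6, 2), "gain_event")
  expect_true(is.na(cna_event_for_cooccurrence(og, seg_over(og, 2), 0.6, 2)))
  expect_identical(cna_event_for_cooccurrence(tg, seg_over(tg, 3), 0.6, 4), "loss_event")
  expect_identical(cna_event_for_cooccurrence(tg, seg_over(tg, 1), 0.6, 2), "loss_event")
  expect_true(is.na(cna_event_for_cooccurrence(og, seg_over(og, 3), 0.2, 2)))
})

test_that("fusion frame assessment matches the mod-3 arithmetic on toy transcripts", {
  pair <- make_fusion_pair()
  gmA <- pair$gene_models[1, ]; gmB <- pair$gene_models[2, ]
  exA <- gmA$exons[[1]]; exB <- gmB$exons[[1]]
  sv <- function(pos_a, pos_b, orient_a = "L", orient_b = "R") {
    tibble::tibble(sv_id = "F", svtype = "BND", chrom_a = "ctgA", pos_a = pos_a,
                   orient_a = orient_a, chrom_b = "ctgB", pos_b = pos_b,
                   orient_b = orient_b)
  }
  # introns after exon 1: cumulative CDS 12 and 12 -> phases match -> inframe
  i1A <- as.integer((exA$end[1] + exA$start[2]) %/% 2)
  i1B <- as.integer((exB$end[1] + exB$start[2]) %/% 2)
  fa <- assess_fusion(sv(i1A, i1B), pair$gene_models)
  expect_identical(fa$status, "inframe")
  expect_true(fa$reportable)
  expect_identical(fa$upstream_gene, "GctgA")
  # intron 1 of A (12 bases) vs intron 2 of B (12 + 15 bases): phases 0 vs 0
  i2B <- as.integer((exB$end[2] + exB$start[3]) %/% 2)
  expect_identical(assess_fusion(sv(i1A, i2B), pair$gene_models)$status, "inframe")
  # shifting the downstream breakpoint into the exon by one base breaks frame
  # (cumulative discarded CDS no longer 0 mod 3 -> exonic split -> ambiguous)
  amb <- assess_fusion(sv(i1A, exB$start[2] + 1L), pair$gene_models)
  expect_identical(amb$status, "ambiguous")
  expect_true(amb$reportable)
  # downstream breakpoint in B's 5' UTR: whole CDS retained -> ambiguous, reported
  utr <- assess_fusion(sv(i1A, exB$start[1] + 2L), pair$gene_models)
  expect_identical(utr$status, "ambiguous")
  expect_true(utr$reportable)
  # incompatible orientations: untranscribed, discarded
  unt <- assess_fusion(sv(i1A, i1B, orient_a = "R", orient_b = "R"), pair$gene_models)
  expect_identical(unt$status, "untranscribed")
  expect_false(unt$reportable)
  # breakpoints outside both transcripts
  off <- assess_fusion(sv(5L, 5L), pair$gene_models)
  expect_identical(off$status, "untranscribed")
})

test_that("reportable fusions are exactly the inframe and ambiguous events", {
  pair <- make_fusion_pair()
  exA <- pair$gene_models$exons[[1]]; exB <- pair$gene_models$exons[[2]]
  set.seed(11)
  pos_a <- sample(seq(min(exA$start) - 5L, max(exA$end) + 5L), 60)
  pos_b <- sample(seq(min(exB$start) - 5L, max(exB$end) + 5L), 60)
  for (k in seq_along(pos_a)) {
    fa <- assess_fusion(
      tibble::tibble(sv_id = "F", svtype = "BND", chrom_a = "ctgA",
                     pos_a = pos_a[k], orient_a = "L", chrom_b = "ctgB",
                     pos_b = pos_b[k], orient_b = "R"),
      pair$gene_models
    )
    expect_identical(fa$reportable, fa$status %in% c("inframe", "ambiguous"))
  }
})

test_that("fusion calls agree with the sequence-level ORF oracle", {
  pair <- make_fusion_pair()
  gmA <- pair$gene_models[1, ]; gmB <- pair$gene_models[2, ]
  exA <- gmA$exons[[1]]; exB <- gmB$exons[[1]]
  # all breakpoint placements across both transcripts (plus margins)
  span_a <- seq(gmA$cds_start, max(exA$end))
  span_b <- seq(min(exB$start), gmB$cds_end)
  set.seed(3)
  grid <- tidyr::crossing(pos_a = span_a, pos_b = span_b) |>
    dplyr::slice_sample(n = 1500)
  n_frame_checked <- 0
  for (k in seq_len(nrow(grid))) {
    sv <- tibble::tibble(sv_id = "F", svtype = "BND", chrom_a = "ctgA",
                         pos_a = grid$pos_a[k], orient_a = "L",
                         chrom_b = "ctgB", pos_b = grid$pos_b[k], orient_b = "R")
    fa <- assess_fusion(sv, pair$gene_models)
    if (!fa$status %in% c("inframe", "out_of_frame")) next
    oracle <- fusion_orf_oracle(pair, grid$pos_a[k], grid$pos_b[k])
    if (oracle == "no_orf") next
    n_frame_checked <- n_frame_checked + 1
    if (fa$status == "inframe") {
      expect_identical(oracle, "inframe")
    } else {
      expect_false(identical(oracle, "inframe"))
    }
  }
  expect_gt(n_frame_checked, 200)
})
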