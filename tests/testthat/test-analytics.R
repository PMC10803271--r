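test_that("actionability prevalence counts cases against gated denominators", {
  cases <- tibble::tibble(
    case_id = sprintf("C%03d", 1:100),
    tumor_type = "melanoma",
    purity = c(rep(0.6, 90), rep(0.2, 10))
  )
  directory <- tibble::tibble(
    gene = c("BRAF", "CDKN2A"), tumor_type = "melanoma",
    variant_class = c("small_variant", "cna")
  )
  # plant findings in the first 60 cases; a duplicate row must not double count
  findings <- dplyr::bind_rows(
    tibble::tibble(case_id = cases$case_id[1:60], gene = "BRAF",
                   variant_class = "small_variant"),
    tibble::tibble(case_id = cases$case_id[1], gene = "BRAF",
                   variant_class = "small_variant"),
    tibble::tibble(case_id = cases$case_id[1:18], gene = "CDKN2A",
                   variant_class = "cna"),
    tibble::tibble(case_id = cases$case_id[1:5], gene = "KRAS",
                   variant_class = "small_variant")
  )
  act <- summarize_actionability(findings, cases, directory)
  m <- act$matrix
  braf <- m[m$gene == "BRAF" & m$variant_class == "small_variant", ]
  expect_equal(braf$prevalence, 0.60)
  expect_true(braf$indicated)
  expect_equal(braf$n_cases, 100L)
  # CNA denominators exclude purity-ineligible cases
  cdk <- m[m$gene == "CDKN2A" & m$variant_class == "cna", ]
  expect_equal(cdk$n_cases, 90L)
  expect_equal(cdk$prevalence, 18 / 90)
  # a gene outside the directory for this type lands in the non-indicated partition
  kras <- m[m$gene == "KRAS", ]
  expect_false(kras$indicated)
  # combined any-indicated column: findings in indicated cells only
  expect_equal(act$any_indicated$prevalence, 0.60)
  # fractions are invariant to case order and recomputable from findings alone
  act2 <- summarize_actionability(findings[sample(nrow(findings)), ],
                                  cases[sample(nrow(cases)), ], directory)
  expect_equal(dplyr::arrange(act2$matrix, gene, variant_class),
               dplyr::arrange(m, gene, variant_class))
})

test_that("zero-findings genes and absent directory types are handled", {
  cases <- tibble::tibble(case_id = c("A", "B"), tumor_type = "sarcoma", purity = 0.5)
  directory <- tibble::tibble(gene = "RB1", tumor_type = "melanoma",
                              variant_class = "cna")
  findings <- tibble::tibble(case_id = "A", gene = "RB1", variant_class = "cna")
  act <- summarize_actionability(findings, cases, directory)
  # tumor type absent from the directory: everything non-indicated
  expect_false(any(act$matrix$indicated))
  expect_equal(act$any_indicated$n_with_finding, 0L)
})

test_that("co-occurrence testing matches the Fisher oracle and corrects with BH", {
  status <- function(a, b, c, d) {
    # a: sv+cna, b: sv only, c: cna only, d: neither
    tibble::tibble(
      case_id = sprintf("C%04d", seq_len(a + b + c + d)),
      gene = "G1",
      has_small_variant = rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c, d)),
      has_cna_event = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d))
    )
  }
  r <- cooccurrence_test(status(40, 10, 10, 140))
  expect_equal(r$p_value, fisher_p_oracle(40, 10, 10, 140), tolerance = 1e-10)
  expect_equal(r$cna_frac_with, 0.8)
  expect_equal(r$cna_frac_without, 10 / 150)
  expect_equal(r$n_with_sv, 50L)
  # q-values: BH over the tested genes, never below their p
  multi <- dplyr::bind_rows(
    dplyr::mutate(status(40, 10, 10, 140), gene = "G1"),
    dplyr::mutate(status(20, 30, 25, 125), gene = "G2"),
    dplyr::mutate(status(12, 38, 25, 125), gene = "G3")
  )
  rm <- cooccurrence_test(multi)
  expect_true(all(rm$q_value >= rm$p_value - 1e-12))
  expect_equal(rm$q_value, p.adjust(rm$p_value, "BH"))
  # Bonferroni alternative
  rb <- cooccurrence_test(multi, wga_config(cooccurrence_adjust = "bonferroni"))
  expect_equal(rb$q_value, p.adjust(rb$p_value, "bonferroni"))
  # empty stratum: undefined result flagged, not an error
  one_sided <- dplyr::mutate(status(10, 0, 5, 0), has_small_variant = TRUE)
  ru <- cooccurrence_test(one_sided)
  expect_true(ru$undefined)
  expect_true(is.na(ru$p_value))
})

test_that("gene mutation status uses protein-altering variants plus TSG homozygous deletions", {
  gm <- fixture_genome()$gene_models
  tp53 <- gm[gm$gene == "TP53", ]
  egfr <- gm[gm$gene == "EGFR", ]
  seg0 <- function(g) tibble::tibble(
    chrom = g$chrom, start = g$cds_start - 50L, end = g$cds_end + 50L,
    total_cn = 0, minor_cn = 0
  )
  vmiss <- tibble::tibble(gene = "TP53", consequence = "missense_variant")
  vsplice <- tibble::tibble(gene = "TP53", consequence = "splice_region_variant")
  none <- tibble::tibble(gene = character(), consequence = character())
  empty_seg <- tibble::tibble(chrom = character(), start = integer(),
                              end = integer(), total_cn = numeric(),
                              minor_cn = numeric())
  expect_true(gene_mutation_status(vmiss, empty_seg, tp53))
  expect_false(gene_mutation_status(vsplice, empty_seg, tp53))
  expect_true(gene_mutation_status(none, seg0(tp53), tp53))
  # homozygous deletion counts for tumor suppressors only
  expect_false(gene_mutation_status(none, seg0(egfr), egfr))
})

test_that("the KM estimator reproduces the hand-computed product limit", {
  # classic 5-subject fixture: deaths at 6 and 15, censoring at 10, 20, 25
  d <- tibble::tibble(
    time = c(6, 10, 15, 20, 25),
    event = c(1, 0, 1, 0, 0),
    group = "all"
  )
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  s <- summary(fit, times = c(6, 15))
  expect_equal(s$surv, c(4 / 5, 4 / 5 * 2 / 3), tolerance = 1e-12)
  # km_curves exposes the same numbers
  d2 <- dplyr::bind_rows(dplyr::mutate(d, group = "a", stage = 1L),
                         dplyr::mutate(d, group = "b", stage = 1L))
  sa <- survival_analysis(d2, stage_correct = FALSE)
  kc <- km_curves(sa)
  expect_equal(kc$surv[kc$group == "a" & kc$time == 6], 0.8)
  expect_equal(kc$surv[kc$group == "a" & kc$time == 15], 0.8 * 2 / 3)
})

test_that("survival analysis handles degenerate inputs as specified", {
  all_censored <- tibble::tibble(time = 1:10, event = 0L,
                                 group = rep(c("a", "b"), 5), stage = 1L)
  expect_error(survival_analysis(all_censored), "no events")
  one_group <- tibble::tibble(time = 1:10, event = 1L, group = "a", stage = 1L)
  expect_error(survival_analysis(one_group), "two groups")
  # a zero-event group yields an undefined HR, reported as NA
  zg <- tibble::tibble(
    time = c(rexp(30, 1 / 100), rep(50, 10)),
    event = rep(c(1L, 0L), c(30, 10)),
    group = rep(c("a", "b"), c(30, 10)),
    stage = 1L
  )
  sz <- suppressWarnings(survival_analysis(zg))
  expect_true(is.na(sz$hazard_ratio))
  # unknown-stage cases are excluded from stage-corrected fits
  d <- simulate_survival_cohort(300, hr = 1, seed = 5)
  d$stage[1:40] <- NA
  sfit <- survival_analysis(d)
  expect_equal(sfit$n_excluded_unknown_stage, 40L)
  expect_equal(sum(sfit$groups$n), 260L)
})

test_that("TMB quartile grouping keeps the outer quartiles only", {
  tmb <- tibble::tibble(case_id = sprintf("C%02d", 1:40), tmb = 1:40)
  q <- tmb_quartile_groups(tmb)
  expect_true(all(q$group %in% c("low", "high")))
  expect_true(all(q$tmb[q$group == "low"] <= quantile(tmb$tmb, 0.25)))
  expect_true(all(q$tmb[q$group == "high"] >= quantile(tmb$tmb, 0.75)))
  expect_lt(attr(q, "median_low"), attr(q, "median_high"))
  expect_equal(levels(q$group), c("low", "high"))
})

test_that("tidiers and plots expose the fitted quantities", {
  d <- simulate_survival_cohort(500, hr = 0.5, seed = 21)
  s <- survival_analysis(d)
  td <- tidy(s)
  expect_true(all(c("term", "hazard_ratio", "conf_low", "conf_high") %in% names(td)))
  expect_equal(glance(s)$n, 500L)
  expect_s3_class(autoplot(s), "ggplot")

  m <- synthetic_signature_matrix()
  fit <- fit_exposures(1000 * m[, "SBS1"], m)
  expect_equal(tidy(fit)$signature[1], "SBS1")
  expect_equal(glance(fit)$n_mutations, 1000)
  expect_s3_class(plot_signature_exposures(fit), "ggplot")
})
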