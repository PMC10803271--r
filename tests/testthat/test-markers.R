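test_that("TMB is nonsynonymous high-confidence variants per coding megabase", {
  v76 <- tibble::tibble(consequence = rep("missense_variant", 76))
  expect_equal(compute_tmb(v76, 20), 3.8)
  expect_equal(compute_tmb(v76[0, ], 20), 0)
  # flagged variants drop out of the numerator
  v10 <- tibble::tibble(
    consequence = rep("missense_variant", 10),
    high_confidence = rep(c(TRUE, FALSE), c(6, 4))
  )
  expect_equal(compute_tmb(v10, 1), 6)
  # splice_region is excluded from "nonsynonymous"; NA consequences ignored
  vmix <- tibble::tibble(consequence = c("missense_variant", "stop_gained",
                                         "splice_region_variant", NA))
  expect_equal(compute_tmb(vmix, 2), 1)
  expect_error(compute_tmb(v76, 0), "positive")
})

test_that("mutation catalogs follow the pyrimidine-strand convention", {
  reference <- c(chr = "AACGTT")
  # C>T at the ACG context counts in A[C>T]G
  cat1 <- build_catalog(tibble::tibble(chrom = "chr", pos = 3L, ref = "C", alt = "T"),
                        reference)
  expect_equal(sum(cat1), 1L)
  expect_equal(unname(cat1["A[C>T]G"]), 1L)
  # G>A at position 4 (context CGT) reverse-complements to A[C>T]G as well
  cat2 <- build_catalog(tibble::tibble(chrom = "chr", pos = 4L, ref = "G", alt = "A"),
                        reference)
  expect_equal(unname(cat2["A[C>T]G"]), 1L)
  # complementing the genome and flipping alleles leaves the catalog unchanged
  rc_ref <- c(chr = oncowga:::revcomp("AACGTT"))
  cat3 <- build_catalog(tibble::tibble(chrom = "chr", pos = 3L, ref = "C", alt = "T"),
                        rc_ref)
  expect_equal(cat3, cat1)
  # indels are excluded; reference mismatches error with the site named
  expect_equal(sum(build_catalog(
    tibble::tibble(chrom = "chr", pos = 3L, ref = "CG", alt = "C"), reference
  )), 0L)
  expect_error(build_catalog(
    tibble::tibble(chrom = "chr", pos = 3L, ref = "T", alt = "A"), reference
  ), "mismatch at chr:3")
})

test_that("generator catalogs round-trip through the catalog builder", {
  g <- fixture_genome()
  m <- synthetic_signature_matrix()
  sim <- simulate_catalog(c(SBS1 = 1), 500, m, g$reference, seed = 5)
  expect_equal(sum(sim$catalog), 500L)
  rebuilt <- build_catalog(sim$variants, g$reference)
  expect_equal(rebuilt, sim$catalog)
})

test_that("NNLS refitting recovers exact and mixed exposures", {
  m <- synthetic_signature_matrix()
  # exact single-signature catalog
  fit <- fit_exposures(1000 * m[, "SBS1"], m)
  expect_equal(unname(fit$exposures["SBS1"]), 1, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-8)
  # 70/30 mixture drawn at n = 20000
  g <- fixture_genome()
  sim <- simulate_catalog(c(SBS7a = 0.7, SBS1 = 0.3), 20000, m, g$reference, seed = 8)
  fit2 <- fit_exposures(sim$catalog, m)
  expect_lt(abs(fit2$exposures[["SBS7a"]] - 0.7), 0.05)
  expect_lt(abs(fit2$exposures[["SBS1"]] - 0.3), 0.05)
  # residual never increases as signatures are added to the matrix
  sub <- m[, c("SBS7a", "SBS4"), drop = FALSE]
  r_small <- fit_exposures(sim$catalog, sub)$residual
  r_mid <- fit_exposures(sim$catalog, m[, c("SBS7a", "SBS4", "SBS1")])$residual
  r_full <- fit_exposures(sim$catalog, m)$residual
  expect_lte(r_mid, r_small + 1e-12)
  expect_lte(r_full, r_mid + 1e-12)
  # noise added to the catalog shows up in the residual, barely in exposures
  set.seed(44)
  noisy <- sim$catalog + rpois(96, 5)
  fitn <- fit_exposures(noisy, m)
  expect_gt(fitn$residual, 0)
  expect_lt(max(abs(fitn$exposures - fit2$exposures)), 0.05)
  expect_error(fit_exposures(numeric(96), m), "empty")
})

test_that("etiology grouping applies the 20% rules and the SBS14 exclusion", {
  mk <- function(x) {
    e <- setNames(numeric(0), character(0))
    e[names(x)] <- x
    e
  }
  # MMR group above 20%: deficient
  c1 <- classify_etiologies(mk(c(SBS6 = 0.15, SBS15 = 0.10, SBS1 = 0.75)))
  expect_true(c1$mmr_deficient)
  expect_true(c1$groups$retained[c1$groups$etiology == "mmr"])
  # MMR at 15% goes to other; POLE at 30% retained; not MMR deficient
  c2 <- classify_etiologies(mk(c(SBS6 = 0.15, SBS10a = 0.30, SBS1 = 0.55)))
  expect_false(c2$mmr_deficient)
  expect_false(c2$groups$retained[c2$groups$etiology == "mmr"])
  expect_true(c2$groups$retained[c2$groups$etiology == "pole"])
  expect_equal(c2$other_fraction, 0.15)
  # SBS14 alone is POLE, never MMR
  c3 <- classify_etiologies(mk(c(SBS14 = 0.5, SBS5 = 0.5)))
  expect_false(c3$mmr_deficient)
  expect_equal(c3$groups$fraction[c3$groups$etiology == "pole"], 0.5)
  # exactly 20% is not "more than 20%"
  c4 <- classify_etiologies(mk(c(SBS6 = 0.20, SBS1 = 0.80)))
  expect_false(c4$mmr_deficient)
})

test_that("HRD classifier concordance counts matched statuses over known pairs", {
  # the two classifiers' published agreement: 10,764 of 10,854
  a <- rep("negative", 10854)
  a[1:2000] <- "positive"
  b <- a
  b[1:45] <- "negative"           # 45 disagreements each way
  b[2001:2045] <- "positive"
  r <- hrd_concordance(a, b)
  expect_equal(r$n_compared, 10854)
  expect_equal(r$n_concordant, 10764)
  expect_equal(round(100 * r$concordance, 1), 99.2)
  # identical lists
  expect_equal(hrd_concordance(a, a)$concordance, 1)
  # unknowns are excluded pairwise
  b2 <- b; b2[1:100] <- "unknown"
  expect_equal(hrd_concordance(a, b2)$n_compared, 10754)
  expect_error(hrd_concordance(rep("unknown", 3), rep("unknown", 3)), "no cases")
  # planted 5% disagreement at n = 1000
  set.seed(12)
  a3 <- sample(c("positive", "negative"), 1000, replace = TRUE)
  flip <- rbinom(1000, 1, 0.05) == 1
  b3 <- ifelse(flip, ifelse(a3 == "positive", "negative", "positive"), a3)
  expect_equal(hrd_concordance(a3, b3)$concordance, 1 - mean(flip))
})
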