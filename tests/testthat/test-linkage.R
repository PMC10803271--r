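linkage_fixture <- function() {
  g <- fixture_genome()
  case <- tibble::tibble(
    case_id = "C1", tumor_type = "breast",
    sample_date = as.Date("2017-06-15"), submitted_metastatic = FALSE
  )
  registry <- tibble::tibble(
    participant_id = "C1", diagnosis_date = as.Date("2017-05-01"),
    icd10_site = "C50", morphology_code = "M8500", behavior = "malignant",
    stage_best = "2", figo_stage = NA_character_, dukes_stage = NA_character_
  )
  episodes <- tibble::tibble(
    participant_id = "C1",
    appointment_date = as.Date(c("2017-06-12", "2017-06-25")),
    primary_diagnosis_icd10 = c("C50", "C34"),
    operation_codes = c("B27", "")
  )
  list(g = g, case = case, registry = registry, episodes = episodes)
}

test_that("the corroboration cascade runs registry, episode and fallback approaches in order", {
  fx <- linkage_fixture()
  # registry maps to the submitted type
  r <- corroborate_diagnosis(fx$case, fx$registry, fx$episodes,
                             fx$g$icd10_map, fx$g$opcode_map)
  expect_identical(r$status, "registry_confirmed")

  # registry disagrees: fall to the nearest type-matching episode
  reg_bad <- dplyr::mutate(fx$registry, icd10_site = "C34")
  ep <- tibble::tibble(
    participant_id = "C1",
    appointment_date = fx$case$sample_date + c(-3, 10),
    primary_diagnosis_icd10 = c("C50", "C50"),
    operation_codes = ""
  )
  r2 <- corroborate_diagnosis(fx$case, reg_bad, ep, fx$g$icd10_map, fx$g$opcode_map)
  expect_identical(r2$status, "hes_confirmed")
  expect_match(r2$evidence, as.character(fx$case$sample_date - 3))

  # benign registry rows are ignored
  reg_benign <- dplyr::mutate(fx$registry, behavior = "benign")
  r3 <- corroborate_diagnosis(fx$case, reg_benign, ep, fx$g$icd10_map, fx$g$opcode_map)
  expect_identical(r3$status, "hes_confirmed")

  # approach 1: operation code on the exact sampling date
  ep_op <- tibble::tibble(
    participant_id = "C1", appointment_date = fx$case$sample_date,
    primary_diagnosis_icd10 = "C34", operation_codes = "B27"
  )
  r4 <- corroborate_diagnosis(fx$case, reg_bad, ep_op, fx$g$icd10_map, fx$g$opcode_map)
  expect_identical(r4$status, "operation_code_confirmed")
  # a day off the sampling date: no approach-1 match
  ep_op2 <- dplyr::mutate(ep_op, appointment_date = fx$case$sample_date + 1)
  r5 <- corroborate_diagnosis(fx$case, reg_bad, ep_op2, fx$g$icd10_map, fx$g$opcode_map)
  expect_identical(r5$status, "unmatched")

  # approach 3: submitted codes
  case_sub <- dplyr::mutate(fx$case, submitted_icd10 = "C50")
  r6 <- corroborate_diagnosis(case_sub, reg_bad, ep_op2, fx$g$icd10_map, fx$g$opcode_map)
  expect_identical(r6$status, "gmc_code_confirmed")
})

test_that("the flexible match honors the restricted pairs and the strict 7-day window", {
  fx <- linkage_fixture()
  case <- dplyr::mutate(fx$case, tumor_type = "lung_adeno", submitted_metastatic = TRUE)
  reg_crc <- dplyr::mutate(fx$registry, icd10_site = "C18")  # colorectal registry
  ep_at <- function(delta) tibble::tibble(
    participant_id = "C1", appointment_date = case$sample_date + delta,
    primary_diagnosis_icd10 = "C25",  # maps to neither type
    operation_codes = ""
  )
  r7 <- corroborate_diagnosis(case, reg_crc, ep_at(7), fx$g$icd10_map, fx$g$opcode_map)
  expect_identical(r7$status, "unmatched")
  r8 <- corroborate_diagnosis(case, reg_crc, ep_at(6), fx$g$icd10_map, fx$g$opcode_map)
  expect_identical(r8$status, "flexible_match_confirmed")
  # non-colorectal registry type does not qualify
  reg_br <- dplyr::mutate(fx$registry, icd10_site = "C50")
  r9 <- corroborate_diagnosis(case, reg_br, ep_at(6), fx$g$icd10_map, fx$g$opcode_map)
  expect_identical(r9$status, "unmatched")
})

test_that("row order never changes linkage outcomes", {
  sim <- fixture_sim()
  base <- corroborate_diagnosis(sim$cases, sim$clinical$registry,
                                sim$clinical$episodes, sim$genome$icd10_map,
                                sim$genome$opcode_map)
  set.seed(2)
  perm <- corroborate_diagnosis(
    sim$cases,
    sim$clinical$registry[sample(nrow(sim$clinical$registry)), ],
    sim$clinical$episodes[sample(nrow(sim$clinical$episodes)), ],
    sim$genome$icd10_map, sim$genome$opcode_map
  )
  expect_equal(perm, base)
})

test_that("stage resolution follows metastatic default, staging system and the 365-day rule", {
  fx <- linkage_fixture()
  # submitted metastatic: stage 4 even when the registry says otherwise
  meta <- dplyr::mutate(fx$case, submitted_metastatic = TRUE)
  expect_equal(resolve_stage(meta, fx$registry)$stage, 4L)
  # stage_best with a sub-letter simplifies to its digit
  reg_3a <- dplyr::mutate(fx$registry, stage_best = "3a")
  expect_equal(resolve_stage(fx$case, reg_3a)$stage, 3L)
  # diagnosis 400 days away: unknown
  reg_old <- dplyr::mutate(fx$registry,
                           diagnosis_date = fx$case$sample_date - 400)
  expect_true(is.na(resolve_stage(fx$case, reg_old)$stage))
  # exactly 365 days is outside the strict window
  reg_365 <- dplyr::mutate(fx$registry,
                           diagnosis_date = fx$case$sample_date - 365)
  expect_true(is.na(resolve_stage(fx$case, reg_365)$stage))
  # FIGO and Dukes vocabularies by tumor type
  ov <- dplyr::mutate(fx$case, tumor_type = "ovarian_hgs")
  reg_figo <- dplyr::mutate(fx$registry, figo_stage = "IIIc", stage_best = "1")
  expect_equal(resolve_stage(ov, reg_figo)$stage, 3L)
  col <- dplyr::mutate(fx$case, tumor_type = "colon")
  reg_dukes <- dplyr::mutate(fx$registry, dukes_stage = "B", stage_best = "4")
  expect_equal(resolve_stage(col, reg_dukes)$stage, 2L)
  # unparseable stage code warns and yields unknown
  reg_bad <- dplyr::mutate(fx$registry, stage_best = "X")
  expect_warning(st <- resolve_stage(fx$case, reg_bad), "unmapped stage")
  expect_true(is.na(st$stage))
  # no registry row at all
  expect_true(is.na(resolve_stage(fx$case, fx$registry[0, ])$stage))
})

test_that("zero mismatch rate gives registry confirmation and the configured stage availability", {
  sim0 <- simulate_cohort(simulation_config(
    n_cases = 60L, seed = 202L, registry_mismatch_rate = 0
  ))
  link <- corroborate_diagnosis(sim0$cases, sim0$clinical$registry,
                                sim0$clinical$episodes, sim0$genome$icd10_map,
                                sim0$genome$opcode_map)
  expect_true(all(link$status == "registry_confirmed"))
  st <- resolve_stage(sim0$cases, sim0$clinical$registry)
  avail <- mean(!is.na(st$stage))
  p_meta <- mean(sim0$cases$submitted_metastatic)
  expected <- p_meta + (1 - p_meta) * sim0$config$stage_availability
  expect_lt(abs(avail - expected), 0.12)
  # resolved stages agree with the generator's truth
  cmp <- dplyr::inner_join(st, sim0$truth$case_truth, by = "case_id")
  expect_true(all(cmp$stage.x == cmp$stage.y | is.na(cmp$stage.x)))
})
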