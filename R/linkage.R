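# Clinical-data linkage: corroborate the submitted tumor type against
# registry and hospital-episode data, and resolve cancer stage.

map_icd10 <- function(codes, icd10_map) {
  icd10_map$tumor_type[match(substr(codes, 1, 3), icd10_map$icd10)]
}

#' Corroborate submitted tumor types
#'
#' Ordered cascade, per case:
#' \enumerate{
#'   \item registry rows (benign/in-situ tumors excluded) whose ICD-10 site
#'     maps to the submitted type confirm it (`registry_confirmed`);
#'   \item otherwise the nearest-in-time cancer-primary hospital episode
#'     whose ICD-10 maps to the submitted type (`hes_confirmed`; ties broken
#'     toward the earlier date);
#'   \item otherwise, for primary tumors, a curated operation code for the
#'     submitted type on an episode whose date exactly matches the sampling
#'     date (`operation_code_confirmed`);
#'   \item otherwise, for the configured restricted registry/submission type
#'     pairs, any episode within strictly fewer than 7 days
#'     (`flexible_match_confirmed`);
#'   \item otherwise the codes submitted at sample collection
#'     (`gmc_code_confirmed`, requires a `submitted_icd10` column);
#'   \item otherwise `unmatched`.
#' }
#'
#' @param cases Case tibble (`case_id, tumor_type, sample_date,
#'   submitted_metastatic`, optionally `submitted_icd10`).
#' @param registry,episodes Clinical tables (see [write_clinical_bundle()]).
#' @param icd10_map Tibble `icd10, tumor_type`.
#' @param opcode_map Tibble `opcode, tumor_type`.
#' @param config A [wga_config()].
#' @return Tibble `case_id, status, matched_tumor_type, evidence`.
#' @export
corroborate_diagnosis <- function(cases, registry, episodes, icd10_map,
                                  opcode_map, config = wga_config()) {
  if (any(is.na(cases$sample_date))) abort("every case needs a sample_date")
  registry <- registry |>
    dplyr::filter(!.data$behavior %in% c("benign", "in_situ"))

  out <- purrr::map(seq_len(nrow(cases)), function(i) {
    cs <- cases[i, ]
    res <- function(status, type = NA_character_, evidence = NA_character_) {
      tibble::tibble(case_id = cs$case_id, status = status,
                     matched_tumor_type = type, evidence = evidence)
    }
    reg <- registry[registry$participant_id == cs$case_id, , drop = FALSE]
    reg_types <- map_icd10(reg$icd10_site, icd10_map)
    if (nrow(reg) && any(reg_types %in% cs$tumor_type)) {
      return(res("registry_confirmed", cs$tumor_type,
                 paste0("icd10=", reg$icd10_site[match(cs$tumor_type, reg_types)])))
    }
    ep <- episodes[episodes$participant_id == cs$case_id, , drop = FALSE]
    if (nrow(ep)) {
      ep$type <- map_icd10(ep$primary_diagnosis_icd10, icd10_map)
      cancer <- ep[!is.na(ep$type), , drop = FALSE]
      matching <- cancer[cancer$type %in% cs$tumor_type, , drop = FALSE]
      if (nrow(matching)) {
        dd <- abs(as.numeric(matching$appointment_date - cs$sample_date))
        pickd <- matching[order(dd, matching$appointment_date), ][1, ]
        return(res("hes_confirmed", cs$tumor_type,
                   paste0("episode_date=", pickd$appointment_date)))
      }
      # approach 1: operation code on the exact sampling date, primary tumors
      if (!isTRUE(cs$submitted_metastatic)) {
        opcodes <- opcode_map$opcode[opcode_map$tumor_type == cs$tumor_type]
        op_hit <- ep$appointment_date == cs$sample_date &
          purrr::map_lgl(strsplit(ep$operation_codes %||% "", ",", fixed = TRUE),
                         function(x) any(x %in% opcodes))
        if (any(op_hit, na.rm = TRUE)) {
          return(res("operation_code_confirmed", cs$tumor_type,
                     paste0("opcode=", paste(opcodes, collapse = ","))))
        }
      }
      # approach 2: restricted registry/submission pairs, |delta| < 7 days
      reg_is_flexible <- any(reg_types %in% flexible_registry_types(config))
      if (reg_is_flexible && cs$tumor_type %in% config$flexible_submitted_types) {
        dd <- abs(as.numeric(ep$appointment_date - cs$sample_date))
        if (any(dd < config$flexible_match_max_days)) {
          return(res("flexible_match_confirmed", cs$tumor_type,
                     paste0("delta_days=", min(dd))))
        }
      }
    }
    # approach 3: codes submitted at sample collection
    if ("submitted_icd10" %in% names(cases) && !is.na(cs$submitted_icd10)) {
      sub_type <- map_icd10(cs$submitted_icd10, icd10_map)
      if (!is.na(sub_type) && sub_type == cs$tumor_type) {
        return(res("gmc_code_confirmed", cs$tumor_type,
                   paste0("submitted_icd10=", cs$submitted_icd10)))
      }
    }
    res("unmatched")
  })
  dplyr::bind_rows(out)
}

flexible_registry_types <- function(config) {
  if (config$flexible_registry_type == "colorectal") c("colon", "rectum")
  else config$flexible_registry_type
}

parse_stage_best <- function(x) {
  d <- suppressWarnings(as.integer(substr(x, 1, 1)))
  ifelse(d %in% 1:4, d, NA_integer_)
}

parse_figo <- function(x) {
  core <- stringr::str_match(toupper(x), "^(IV|III|II|I)")[, 2]
  match(core, c("I", "II", "III", "IV"))
}

parse_dukes <- function(x) {
  match(toupper(substr(x, 1, 1)), c("A", "B", "C", "D"))
}

#' Resolve cancer stage
#'
#' Tumors submitted as metastatic are stage 4 unconditionally. Otherwise the
#' registry row nearest in diagnosis date supplies the stage, using the
#' staging vocabulary of the tumor type -- FIGO for ovarian/endometrial
#' indications (I-IV, sub-letters ignored), Dukes for colon and rectum
#' adenocarcinomas (A-D mapped to 1-4), `stage_best` simplified to 1-4 for
#' everything else -- and only when the diagnosis date lies strictly within
#' 365 days of the sampling date. Anything else is `NA` (unknown);
#' unparseable stage codes give `NA` with a warning.
#'
#' @inheritParams corroborate_diagnosis
#' @return Tibble `case_id, stage` (integer 1-4 or NA).
#' @export
resolve_stage <- function(cases, registry, config = wga_config()) {
  # nearest registry row per case (ties: earlier diagnosis date)
  nearest <- dplyr::inner_join(
    dplyr::select(cases, "case_id", "sample_date"),
    registry, by = c(case_id = "participant_id"),
    relationship = "many-to-many"
  ) |>
    dplyr::mutate(dd = abs(as.numeric(.data$diagnosis_date - .data$sample_date))) |>
    dplyr::arrange(.data$case_id, .data$dd, .data$diagnosis_date) |>
    dplyr::distinct(.data$case_id, .keep_all = TRUE)
  d <- dplyr::select(cases, "case_id", "tumor_type", "submitted_metastatic") |>
    dplyr::left_join(nearest, by = "case_id")
  in_window <- !is.na(d$dd) & d$dd < config$stage_max_days
  use_figo <- in_window & d$tumor_type %in% config$figo_tumor_types & !is.na(d$figo_stage)
  use_dukes <- in_window & d$tumor_type %in% config$dukes_tumor_types & !is.na(d$dukes_stage)
  use_best <- in_window & !use_figo & !use_dukes & !is.na(d$stage_best)
  stage <- rep(NA_integer_, nrow(d))
  stage[use_figo] <- parse_figo(d$figo_stage[use_figo])
  stage[use_dukes] <- parse_dukes(d$dukes_stage[use_dukes])
  stage[use_best] <- parse_stage_best(d$stage_best[use_best])
  unmapped <- use_best & is.na(stage)
  if (any(unmapped)) {
    warn(paste0("unmapped stage code(s) for ",
                paste(utils::head(d$case_id[unmapped], 5), collapse = ", "),
                if (sum(unmapped) > 5) " ..." else ""))
  }
  stage[d$submitted_metastatic] <- 4L  # metastatic submissions: stage 4 by default
  tibble::tibble(case_id = d$case_id, stage = stage)
}
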