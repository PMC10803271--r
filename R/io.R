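# Readers and writers for the standard formats the pipeline touches.
#
# Internal conventions: coordinates are 1-based closed everywhere; BED input
# (0-based half-open) is converted on read. Small variants are decomposed
# (one ALT per record), left-aligned and trimmed on read when a reference is
# supplied. VCF parsing goes through vcfR; the writers emit minimal plain
# VCF 4.2 so that synthetic fixtures stay text.

vcf_header <- function(extra = character()) {
  c(
    "##fileformat=VCFv4.2",
    "##source=oncowga",
    extra
  )
}

#' Write small-variant calls as VCF
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt` and (optionally)
#'   `tumor_ref_depth`, `tumor_alt_depth`.
#' @param path Output path (plain text `.vcf`).
#' @param sample Sample column name.
#' @return `path`, invisibly.
#' @export
write_small_variant_vcf <- function(variants, path, sample = "TUMOR") {
  v <- tibble::as_tibble(variants)
  rd <- v[["tumor_ref_depth"]] %||% rep(30L, nrow(v))
  ad <- v[["tumor_alt_depth"]] %||% rep(15L, nrow(v))
  header <- vcf_header(c(
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", sample), collapse = "\t"))
  ))
  body <- if (nrow(v)) {
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "AD",
          paste0(rd, ",", ad), sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read small-variant calls from VCF
#'
#' Multi-allelic records are decomposed into one row per alternate allele
#' (allele depths are taken from the matching AD slot); when `reference` is
#' supplied, indels are left-aligned and trimmed to the parsimonious
#' representation.
#'
#' @param path VCF path.
#' @param reference Optional named character vector of contig sequences.
#' @return Tibble `chrom,pos,ref,alt,vtype,tumor_ref_depth,tumor_alt_depth`.
#' @export
read_small_variant_vcf <- function(path, reference = NULL) {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  empty <- tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    vtype = character(), tumor_ref_depth = integer(), tumor_alt_depth = integer()
  )
  if (!nrow(fix)) return(empty)
  pos <- suppressWarnings(as.integer(fix$POS))
  bad <- which(is.na(pos) | is.na(fix$REF) | is.na(fix$ALT) |
                 !grepl("^[ACGTN]+$", fix$REF))
  if (length(bad)) {
    abort(paste0("malformed VCF record in ", path, " at body line ", bad[1]))
  }
  ad <- if (ncol(v@gt) >= 2) vcfR::extract.gt(v, element = "AD")[, 1] else rep(NA_character_, nrow(fix))

  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    depths <- if (!is.na(ad[i])) as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]]) else NULL
    tibble::tibble(
      chrom = fix$CHROM[i], pos = pos[i], ref = fix$REF[i], alt = alts,
      tumor_ref_depth = if (!is.null(depths)) rep(depths[1], length(alts)) else NA_integer_,
      tumor_alt_depth = if (!is.null(depths)) depths[seq_along(alts) + 1L] else NA_integer_
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(reference)) out <- normalize_variants(out, reference)
  out |>
    dplyr::mutate(vtype = ifelse(nchar(.data$ref) == 1 & nchar(.data$alt) == 1, "SNV", "indel")) |>
    dplyr::relocate("vtype", .after = "alt")
}

#' Normalize variant representation
#'
#' Parsimony-normalizes each record: shared trailing then leading bases are
#' trimmed, and indels are shifted to their leftmost equivalent position
#' (extending with reference bases while the trailing base matches), the
#' standard left-align-and-trim convention.
#'
#' @param variants Tibble with `chrom,pos,ref,alt`.
#' @param reference Named character vector of contig sequences.
#' @return The normalized tibble, other columns carried through.
#' @export
normalize_variants <- function(variants, reference) {
  v <- tibble::as_tibble(variants)
  if (!nrow(v)) return(v)
  norm1 <- function(chrom, pos, ref, alt) {
    r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
    repeat {
      if (length(r) >= 1 && length(a) >= 1 && r[length(r)] == a[length(a)] &&
          (length(r) > 1 || length(a) > 1)) {
        r <- r[-length(r)]; a <- a[-length(a)]
        if (!length(r) || !length(a)) {
          if (pos <= 1) abort("cannot left-extend past contig start")
          pos <- pos - 1L
          b <- substr(reference[[chrom]], pos, pos)
          r <- c(b, r); a <- c(b, a)
        }
      } else break
    }
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]; a <- a[-1]; pos <- pos + 1L
    }
    list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
  }
  res <- purrr::pmap(list(v$chrom, v$pos, v$ref, v$alt), norm1)
  v$pos <- purrr::map_int(res, "pos")
  v$ref <- purrr::map_chr(res, "ref")
  v$alt <- purrr::map_chr(res, "alt")
  v
}

# CNA segments ------------------------------------------------------------

#' Read / write copy-number segments
#'
#' TSV with header `chrom, start, end, total_cn, minor_cn` (1-based closed
#' coordinates; `minor_cn` may be NA when the caller did not phase alleles).
#'
#' @param path TSV path.
#' @param segments Segment tibble.
#' @return `read_cna_tsv()` returns the segment tibble.
#' @export
read_cna_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         start = readr::col_integer(),
                         end = readr::col_integer(),
                         total_cn = readr::col_double(),
                         minor_cn = readr::col_double()
                       ))
  bad <- which(!is.na(d$minor_cn) & d$minor_cn > d$total_cn)
  if (length(bad)) {
    abort(paste0("malformed CNA record in ", path, " at line ", bad[1] + 1L,
                 ": minor_cn exceeds total_cn"))
  }
  d
}

#' @rdname read_cna_tsv
#' @export
write_cna_tsv <- function(segments, path) {
  readr::write_tsv(tibble::as_tibble(segments), path)
  invisible(path)
}

# structural variants ------------------------------------------------------

# orientation encoding: "L" means the derivative allele retains positions
# <= pos on that contig (junction at the breakpoint's right flank), "R"
# retains positions >= pos.
bnd_alt <- function(ref, chrom_mate, pos_mate, orient_self, orient_mate) {
  mate <- paste0(chrom_mate, ":", pos_mate)
  if (orient_self == "L" && orient_mate == "R") paste0(ref, "[", mate, "[")
  else if (orient_self == "L" && orient_mate == "L") paste0(ref, "]", mate, "]")
  else if (orient_self == "R" && orient_mate == "L") paste0("]", mate, "]", ref)
  else paste0("[", mate, "[", ref)
}

#' Write structural variants as a breakend VCF
#'
#' Breakend (BND) events are written as mated record pairs; DEL/DUP/INV are
#' written as symbolic-ALT records with an `END` INFO field.
#'
#' @param svs Tibble with `sv_id, svtype, chrom_a, pos_a, orient_a, chrom_b,
#'   pos_b, orient_b` (orientations `"L"`/`"R"`: side of the breakpoint
#'   retained in the derivative allele).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, path) {
  s <- tibble::as_tibble(svs)
  header <- vcf_header(c(
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend id\">",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
                      collapse = "\t"))
  ))
  body <- character()
  for (i in seq_len(nrow(s))) {
    r <- s[i, ]
    if (r$svtype == "BND") {
      id_a <- paste0(r$sv_id, "_1"); id_b <- paste0(r$sv_id, "_2")
      body <- c(
        body,
        paste(r$chrom_a, r$pos_a, id_a, "N",
              bnd_alt("N", r$chrom_b, r$pos_b, r$orient_a, r$orient_b),
              ".", "PASS", paste0("SVTYPE=BND;MATEID=", id_b), sep = "\t"),
        paste(r$chrom_b, r$pos_b, id_b, "N",
              bnd_alt("N", r$chrom_a, r$pos_a, r$orient_b, r$orient_a),
              ".", "PASS", paste0("SVTYPE=BND;MATEID=", id_a), sep = "\t")
      )
    } else {
      body <- c(body, paste(
        r$chrom_a, r$pos_a, r$sv_id, "N", paste0("<", r$svtype, ">"), ".", "PASS",
        paste0("SVTYPE=", r$svtype, ";END=", r$pos_b), sep = "\t"
      ))
    }
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read structural variants from a breakend VCF
#'
#' BND mates are paired via `MATEID`; symbolic DEL/DUP/INV records become a
#' breakpoint pair with the conventional junction orientations (deletion
#' joins left-of-start to right-of-end; duplication the reverse; one of the
#' two inversion junctions is represented).
#'
#' @param path VCF path.
#' @return Tibble `sv_id, svtype, chrom_a, pos_a, orient_a, chrom_b, pos_b,
#'   orient_b`.
#' @export
read_sv_vcf <- function(path) {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  empty <- tibble::tibble(
    sv_id = character(), svtype = character(),
    chrom_a = character(), pos_a = integer(), orient_a = character(),
    chrom_b = character(), pos_b = integer(), orient_b = character()
  )
  if (!nrow(fix)) return(empty)
  info_get <- function(info, key) {
    m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    m
  }
  fix$svtype <- info_get(fix$INFO, "SVTYPE")
  parse_bnd <- function(alt) {
    m <- stringr::str_match(alt, "^([ACGTN]*)([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])([ACGTN]*)$")
    if (is.na(m[1, 1])) abort(paste0("malformed breakend ALT: ", alt))
    before <- nzchar(m[1, 2])   # bases precede the bracket: left side retained
    bracket <- m[1, 3]
    list(
      chrom = m[1, 4], pos = as.integer(m[1, 5]),
      orient_self = if (before) "L" else "R",
      orient_mate = if (bracket == "[") "R" else "L"
    )
  }
  done <- character()
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    r <- fix[i, ]
    if (identical(r$svtype, "BND")) {
      if (r$ID %in% done) next
      mate <- info_get(r$INFO, "MATEID")
      done <- c(done, r$ID, mate)
      b <- parse_bnd(r$ALT)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sv_id = sub("_[12]$", "", r$ID), svtype = "BND",
        chrom_a = r$CHROM, pos_a = as.integer(r$POS), orient_a = b$orient_self,
        chrom_b = b$chrom, pos_b = b$pos, orient_b = b$orient_mate
      )
    } else {
      endp <- as.integer(info_get(r$INFO, "END"))
      orient <- switch(r$svtype,
        DEL = c("L", "R"), DUP = c("R", "L"), INV = c("L", "L"),
        abort(paste0("unsupported SVTYPE in ", path, ": ", r$svtype))
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sv_id = r$ID, svtype = r$svtype,
        chrom_a = r$CHROM, pos_a = as.integer(r$POS), orient_a = orient[1],
        chrom_b = r$CHROM, pos_b = endp, orient_b = orient[2]
      )
    }
  }
  dplyr::bind_rows(rows)
}

# BED ----------------------------------------------------------------------

#' Read BED intervals
#'
#' Converts the BED 0-based half-open convention to the internal 1-based
#' closed convention on read.
#'
#' @param path BED path (no header; first three columns used).
#' @return Tibble `chrom, start, end`.
#' @export
read_bed <- function(path) {
  d <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  tibble::tibble(
    chrom = as.character(d[[1]]),
    start = as.integer(d[[2]]) + 1L,
    end = as.integer(d[[3]])
  )
}

#' @rdname read_bed
#' @param intervals Tibble `chrom,start,end` in 1-based closed coordinates.
#' @export
write_bed <- function(intervals, path) {
  d <- tibble::as_tibble(intervals)
  readr::write_tsv(
    tibble::tibble(chrom = d$chrom, start = d$start - 1L, end = d$end),
    path, col_names = FALSE
  )
  invisible(path)
}

# panel of normals ----------------------------------------------------------

#' Read / write a panel of normals
#'
#' Long TSV with header `chrom, pos, alt, individual, ref_depth, alt_depth`;
#' in memory the panel is a nested tibble (`$sites`) with one row per
#' `(chrom, pos, alt)` site and integer-vector list columns `ref_depths`,
#' `alt_depths` over panel individuals.
#'
#' @param path TSV path.
#' @param pon Panel object.
#' @return `read_pon_tsv()` returns a list of class `panel_of_normals`.
#' @export
read_pon_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(chrom = readr::col_character(),
                                               alt = readr::col_character()))
  sites <- d |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt, .data$individual) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$alt) |>
    dplyr::summarise(
      ref_depths = list(as.integer(.data$ref_depth)),
      alt_depths = list(as.integer(.data$alt_depth)),
      .groups = "drop"
    )
  new_pon(sites)
}

#' @rdname read_pon_tsv
#' @export
write_pon_tsv <- function(pon, path) {
  d <- pon$sites |>
    dplyr::mutate(individual = purrr::map(.data$ref_depths, seq_along)) |>
    tidyr::unnest(c("individual", "ref_depths", "alt_depths")) |>
    dplyr::rename(ref_depth = "ref_depths", alt_depth = "alt_depths")
  readr::write_tsv(d, path)
  invisible(path)
}

new_pon <- function(sites, artifact_sites = NULL, n_individuals = NULL) {
  if (anyDuplicated(paste(sites$chrom, sites$pos, sites$alt))) {
    abort("panel of normals has duplicate site keys")
  }
  if (is.null(n_individuals)) {
    n_individuals <- if (nrow(sites)) length(sites$ref_depths[[1]]) else 0L
  }
  structure(list(sites = sites, artifact_sites = artifact_sites,
                 n_individuals = as.integer(n_individuals)),
            class = "panel_of_normals")
}

#' @exportS3Method base::print
print.panel_of_normals <- function(x, ...) {
  n_ind <- if (nrow(x$sites)) length(x$sites$ref_depths[[1]]) else 0L
  cat("<panel_of_normals> ", nrow(x$sites), " sites x ", n_ind, " individuals\n", sep = "")
  invisible(x)
}

# gene models ---------------------------------------------------------------

#' Read / write gene models
#'
#' TSV with one row per canonical transcript; exons are serialized as
#' `start-end` pairs joined by commas.
#'
#' @param path TSV path.
#' @param gene_models Gene-model tibble.
#' @return `read_gene_models_tsv()` returns the gene-model tibble.
#' @export
write_gene_models_tsv <- function(gene_models, path) {
  d <- gene_models |>
    dplyr::mutate(exons = purrr::map_chr(.data$exons, function(e) {
      paste(paste0(e$start, "-", e$end), collapse = ",")
    }))
  readr::write_tsv(d, path)
  invisible(path)
}

#' @rdname write_gene_models_tsv
#' @export
read_gene_models_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  d$exons <- purrr::map(d$exons, function(s) {
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
    tibble::tibble(
      start = as.integer(vapply(parts, `[`, character(1), 1)),
      end = as.integer(vapply(parts, `[`, character(1), 2))
    )
  })
  validate_gene_models(tibble::as_tibble(d))
}

validate_gene_models <- function(gene_models) {
  for (i in seq_len(nrow(gene_models))) {
    e <- gene_models$exons[[i]]
    if (is.unsorted(e$start) || any(e$end[-nrow(e)] >= e$start[-1])) {
      abort(paste0("gene ", gene_models$gene[i], ": exons must be ordered and non-overlapping"))
    }
    if (gene_models$cds_start[i] < min(e$start) || gene_models$cds_end[i] > max(e$end)) {
      abort(paste0("gene ", gene_models$gene[i], ": CDS outside exon span"))
    }
  }
  gene_models
}

# clinical tables -----------------------------------------------------------

#' Read / write the clinical bundle
#'
#' The clinical bundle holds four TSV tables: `registry` (tumor-registry
#' rows: participant_id, diagnosis_date, icd10_site, morphology_code,
#' behavior, stage_best, figo_stage, dukes_stage), `episodes` (hospital
#' episodes: participant_id, appointment_date, primary_diagnosis_icd10,
#' operation_codes), `treatments` (participant_id, treatment_date,
#' treatment_type) and `deaths` (participant_id, death_date).
#'
#' @param bundle Named list of the four tibbles.
#' @param dir Directory holding `registry.tsv`, `episodes.tsv`,
#'   `treatments.tsv`, `deaths.tsv`.
#' @return `read_clinical_bundle()` returns the named list.
#' @export
write_clinical_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("registry", "episodes", "treatments", "deaths")) {
    readr::write_tsv(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_clinical_bundle
#' @export
read_clinical_bundle <- function(dir) {
  types <- list(
    registry = readr::cols(stage_best = readr::col_character(),
                           figo_stage = readr::col_character(),
                           dukes_stage = readr::col_character(),
                           diagnosis_date = readr::col_date()),
    episodes = readr::cols(operation_codes = readr::col_character(),
                           appointment_date = readr::col_date()),
    treatments = readr::cols(treatment_date = readr::col_date()),
    deaths = readr::cols(death_date = readr::col_date())
  )
  out <- lapply(names(types), function(nm) {
    d <- readr::read_tsv(file.path(dir, paste0(nm, ".tsv")),
                         show_col_types = FALSE, col_types = types[[nm]])
    if (nm == "episodes" && "operation_codes" %in% names(d)) {
      d$operation_codes <- tidyr::replace_na(d$operation_codes, "")
    }
    d
  })
  names(out) <- names(types)
  out
}
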