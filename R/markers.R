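# Pangenomic markers: TMB, 96-context catalogs, signature refitting,
# etiology grouping, MMR classification and HRD-classifier concordance.

#' Tumor mutational burden
#'
#' The number of nonsynonymous high-confidence somatic small variants per
#' megabase of coding sequence. "Nonsynonymous" is the curated
#' protein-altering consequence set (everything reportable except
#' `splice_region_variant`); variants carrying any filter flag are excluded
#' when a `high_confidence` column is present.
#'
#' @param variants Annotated (and ideally filtered) variant tibble.
#' @param coding_mb Coding footprint in megabases (> 0).
#' @param config A [wga_config()].
#' @return TMB in variants per megabase.
#' @examples
#' v <- tibble::tibble(consequence = rep("missense_variant", 76))
#' compute_tmb(v, coding_mb = 20)  # 3.8
#' @export
compute_tmb <- function(variants, coding_mb, config = wga_config()) {
  if (is.na(coding_mb) || coding_mb <= 0) abort("coding_mb must be positive")
  v <- tibble::as_tibble(variants)
  if ("high_confidence" %in% names(v)) v <- v[v$high_confidence, , drop = FALSE]
  qualifying <- setdiff(curated_consequences(), config$tmb_exclude)
  n <- sum(v$consequence %in% qualifying, na.rm = TRUE)
  n / coding_mb
}

#' Build a 96-context mutation catalog
#'
#' Counts SNVs by pyrimidine-strand trinucleotide context: substitutions
#' from a purine reference base are reverse-complemented so every mutation
#' is expressed as C>N or T>N with its 5'/3' flanks. Indels are excluded.
#'
#' @param snvs Variant tibble (`chrom,pos,ref,alt`); non-SNV rows dropped.
#' @param reference Named character vector of contig sequences.
#' @return Named integer vector of length 96 in [sbs96_contexts()] order;
#'   the sum equals the number of contributing SNVs.
#' @export
build_catalog <- function(snvs, reference) {
  v <- tibble::as_tibble(snvs)
  v <- v[nchar(v$ref) == 1 & nchar(v$alt) == 1, , drop = FALSE]
  contexts <- sbs96_contexts()
  counts <- setNames(integer(96), contexts)
  if (!nrow(v)) return(counts)
  labs <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    chrom <- v$chrom[i]; pos <- v$pos[i]
    if (pos < 2 || pos >= nchar(reference[[chrom]])) {
      abort(paste0("site without full trinucleotide context: ", chrom, ":", pos))
    }
    tri <- substr(reference[[chrom]], pos - 1L, pos + 1L)
    refb <- substr(tri, 2, 2)
    if (refb != v$ref[i]) {
      abort(paste0("reference mismatch at ", chrom, ":", pos,
                   " (expected ", refb, ", got ", v$ref[i], ")"))
    }
    altb <- v$alt[i]
    if (refb %in% c("A", "G")) {
      tri <- revcomp(tri)
      refb <- substr(tri, 2, 2)
      altb <- complement_base(altb)
    }
    labs[i] <- paste0(substr(tri, 1, 1), "[", refb, ">", altb, "]", substr(tri, 3, 3))
  }
  tab <- table(factor(labs, levels = contexts))
  counts[] <- as.integer(tab)
  counts
}

#' Refit signature exposures by nonnegative least squares
#'
#' Decomposes a 96-context catalog against a signature matrix by NNLS and
#' normalizes the fitted activities to fractions of the assigned mass. The
#' reconstruction residual (L2 norm of catalog minus reconstruction, divided
#' by the catalog total) is reported alongside.
#'
#' @param catalog Length-96 count vector (sum > 0).
#' @param signature_matrix 96 x K matrix, columns summing to 1.
#' @return A list of class `signature_exposure`: `exposures` (named
#'   fractions summing to 1 over assigned mass), `activities` (fitted
#'   counts), `residual`, `n_mutations`.
#' @export
fit_exposures <- function(catalog, signature_matrix) {
  validate_signature_matrix(signature_matrix)
  if (length(catalog) != 96) abort("catalog must have 96 context counts")
  if (sum(catalog) <= 0) abort("catalog is empty: no SNVs to decompose")
  fit <- pracma::lsqnonneg(signature_matrix, as.numeric(catalog))
  act <- setNames(fit$x, colnames(signature_matrix))
  total <- sum(act)
  expo <- if (total > 0) act / total else act
  recon <- as.numeric(signature_matrix %*% act)
  structure(
    list(
      exposures = expo,
      activities = act,
      residual = sqrt(sum((catalog - recon)^2)) / sum(catalog),
      n_mutations = sum(catalog)
    ),
    class = "signature_exposure"
  )
}

#' @exportS3Method base::print
print.signature_exposure <- function(x, ...) {
  top <- sort(x$exposures[x$exposures > 0.01], decreasing = TRUE)
  cat("<signature_exposure> ", x$n_mutations, " mutations, residual ",
      signif(x$residual, 3), "\n", sep = "")
  cat(paste0("  ", names(top), ": ", sprintf("%.3f", top), collapse = "\n"), "\n")
  invisible(x)
}

#' Group signature exposures by etiology and call MMR status
#'
#' Sums fitted exposure fractions within each etiology group of
#' [signature_etiology_map()] (signatures outside the map count as other).
#' A named group whose total is not above `etiology_other_threshold` (20%)
#' is reassigned to `other`. The tumor is MMR deficient when the MMR group
#' total exceeds `mmr_threshold` (20%); SBS14 sits in the POLE group only
#' and never contributes to the MMR call.
#'
#' @param exposure A `signature_exposure` (or named fraction vector).
#' @param config A [wga_config()].
#' @return Tibble with one row per etiology (`etiology`, `fraction`,
#'   `retained`) plus attributes; see also `mmr_deficient` in the returned
#'   object: a list of class `etiology_call` with `groups`, `mmr_deficient`,
#'   `other_fraction`.
#' @export
classify_etiologies <- function(exposure, config = wga_config()) {
  expo <- if (inherits(exposure, "signature_exposure")) exposure$exposures else exposure
  map <- signature_etiology_map()
  et <- map$etiology[match(names(expo), map$signature)]
  et[is.na(et)] <- "other"
  raw <- tapply(expo, et, sum)
  groups <- tibble::tibble(
    etiology = names(raw),
    fraction = as.numeric(raw)
  )
  named <- groups |> dplyr::filter(.data$etiology != "other")
  named$retained <- named$fraction > config$etiology_other_threshold
  other_frac <- sum(groups$fraction[groups$etiology == "other"]) +
    sum(named$fraction[!named$retained])
  mmr_frac <- sum(named$fraction[named$etiology == "mmr"])
  structure(
    list(
      groups = named,
      other_fraction = other_frac,
      mmr_deficient = mmr_frac > config$mmr_threshold
    ),
    class = "etiology_call"
  )
}

#' @exportS3Method base::print
print.etiology_call <- function(x, ...) {
  kept <- x$groups[x$groups$retained, ]
  cat("<etiology_call> MMR deficient:", x$mmr_deficient, "\n")
  if (nrow(kept)) {
    cat(paste0("  ", kept$etiology, ": ", sprintf("%.3f", kept$fraction),
               collapse = "\n"), "\n")
  }
  cat("  other:", sprintf("%.3f", x$other_fraction), "\n")
  invisible(x)
}

#' Concordance between two HRD classifiers
#'
#' Fraction of cases on which two homologous-recombination-deficiency
#' classifiers return the same status; cases where either call is unknown
#' are excluded pairwise.
#'
#' @param calls_a,calls_b Character vectors (`"positive"`, `"negative"`,
#'   `"unknown"`) over the same cases, or tibbles with `case_id` and
#'   `status` (joined on `case_id`).
#' @return List: `concordance` (fraction), `n_compared`, `n_concordant`.
#' @examples
#' a <- rep(c("positive", "negative"), c(10, 90))
#' b <- a; b[1:2] <- "negative"
#' hrd_concordance(a, b)$concordance
#' @export
hrd_concordance <- function(calls_a, calls_b) {
  if (is.data.frame(calls_a)) {
    j <- dplyr::inner_join(
      dplyr::select(calls_a, "case_id", a = "status"),
      dplyr::select(calls_b, "case_id", b = "status"),
      by = "case_id"
    )
    a <- j$a; b <- j$b
  } else {
    stopifnot(length(calls_a) == length(calls_b))
    a <- calls_a; b <- calls_b
  }
  keep <- !is.na(a) & !is.na(b) & a != "unknown" & b != "unknown"
  if (!any(keep)) abort("no cases with known status in both call sets")
  n_conc <- sum(a[keep] == b[keep])
  list(
    concordance = n_conc / sum(keep),
    n_compared = sum(keep),
    n_concordant = n_conc
  )
}
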