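# Packaged single-base-substitution signature matrix.
#
# SYNTHETIC STAND-IN: the column names follow the COSMIC v3 SBS naming used
# by the etiology map, but the profiles themselves are generated
# deterministically in code (sparse, well-separated probability vectors over
# the 96 contexts). Real COSMIC profiles, where available, are a drop-in TSV
# with the same shape (read_signature_matrix_tsv()).

#' Synthetic signature matrix
#'
#' Deterministically generates a 96 x K signature matrix carrying the
#' signatures referenced by [signature_etiology_map()] plus a few decoys
#' (SBS5, SBS8, SBS17b, SBS18). Each profile concentrates most of its mass
#' on a signature-specific subset of contexts, giving well-conditioned
#' nonnegative refits; columns sum to 1.
#'
#' The profiles are synthetic: they are suitable for simulation, refitting
#' and testing, not for interpreting real tumors. Substitute real COSMIC
#' profiles via [read_signature_matrix_tsv()] for real data.
#'
#' @param signatures Character vector of signature names.
#' @param peak_mass Fraction of each profile's mass on its peak contexts.
#' @param n_peaks Number of peak contexts per signature.
#' @return A 96 x K matrix with context rownames and signature colnames.
#' @examples
#' m <- synthetic_signature_matrix()
#' colSums(m)[1:3]
#' @export
synthetic_signature_matrix <- function(signatures = c(
                                         signature_etiology_map()$signature,
                                         "SBS5", "SBS8", "SBS17b", "SBS18"
                                       ),
                                       peak_mass = 0.85, n_peaks = 6L) {
  contexts <- sbs96_contexts()
  k <- length(signatures)
  # fixed internal stream so that the packaged matrix is a constant
  rs <- with_seed(961203L, {
    m <- matrix(0, 96, k, dimnames = list(contexts, signatures))
    # assign peak contexts round-robin with jitter so signatures overlap little
    perm <- sample.int(96)
    for (j in seq_len(k)) {
      idx <- perm[((j - 1L) * n_peaks + seq_len(n_peaks) - 1L) %% 96 + 1L]
      w_peak <- stats::rgamma(n_peaks, shape = 2)
      w_base <- stats::rgamma(96, shape = 0.3)
      prof <- (1 - peak_mass) * w_base / sum(w_base)
      prof[idx] <- prof[idx] + peak_mass * w_peak / sum(w_peak)
      m[, j] <- prof / sum(prof)
    }
    m
  })
  validate_signature_matrix(rs)
  rs
}

#' Read / write a signature matrix TSV
#'
#' The TSV has a `context` column (96 rows, [sbs96_contexts()] values) and
#' one numeric column per signature. Columns are validated to sum to 1.
#'
#' @param path TSV path.
#' @param m Matrix to write.
#' @return `read_signature_matrix_tsv()` returns a validated 96 x K matrix.
#' @export
read_signature_matrix_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot("context" %in% names(d))
  m <- as.matrix(d[setdiff(names(d), "context")])
  rownames(m) <- d$context
  m <- m[match(sbs96_contexts(), rownames(m)), , drop = FALSE]
  validate_signature_matrix(m)
  m
}

#' @rdname read_signature_matrix_tsv
#' @export
write_signature_matrix_tsv <- function(m, path) {
  d <- dplyr::bind_cols(tibble::tibble(context = rownames(m)), tibble::as_tibble(m))
  readr::write_tsv(d, path)
  invisible(path)
}
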