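# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Fisher oracle enumerates the hypergeometric
# support directly, and the fusion oracle translates the fused spliced
# sequence base by base.

# two-sided Fisher exact p for a 2x2 table (a b / c d) by enumeration of the
# conditional hypergeometric support
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  if (m + n == 0) return(1)
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

phred_oracle <- function(a, b, c, d) {
  p <- fisher_p_oracle(a, b, c, d)
  if (p <= 0) Inf else max(0, -10 * log10(p))
}

# build a custom two-gene toy pair (both plus strand, separate contigs) with
# 3 exons each and fully controlled coding sequence; returns list(reference,
# gene_models, cds) where cds are the spliced coding strings
make_fusion_pair <- function(seed = 42) {
  set.seed(seed)
  stop_codons <- c("TAA", "TAG", "TGA")
  all_codons <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                                c("A","C","G","T"), paste0))
  safe <- setdiff(all_codons, c(stop_codons, "ATG"))
  build <- function(chrom, n_codons_per_exon = c(4, 5, 4)) {
    utr5 <- 6L; utr3 <- 6L; intron <- 12L
    cds_len <- sum(n_codons_per_exon) * 3L
    coding <- paste0("ATG",
                     paste(sample(safe, cds_len / 3 - 2, replace = TRUE), collapse = ""),
                     "TAA")
    ex_len <- c(utr5 + n_codons_per_exon[1] * 3L,
                n_codons_per_exon[2] * 3L,
                n_codons_per_exon[3] * 3L + utr3)
    start <- 20L
    ex_start <- start + cumsum(c(0L, head(ex_len, -1) + intron))
    ex_end <- ex_start + ex_len - 1L
    cds_start <- ex_start[1] + utr5
    cds_end <- ex_end[3] - utr3
    total_len <- ex_end[3] + 20L
    seq <- paste(sample(c("A","C","G","T"), total_len, replace = TRUE), collapse = "")
    # write coding bases into CDS positions
    gm <- tibble::tibble(
      gene = paste0("G", chrom), transcript_id = paste0("TX", chrom),
      chrom = chrom, strand = "+",
      exons = list(tibble::tibble(start = ex_start, end = ex_end)),
      cds_start = cds_start, cds_end = cds_end, role = "oncogene",
      lof_mechanism = FALSE
    )
    pos <- oncowga:::cds_positions(gm)
    ref <- strsplit(seq, "")[[1]]
    ref[sort(pos)] <- strsplit(coding, "")[[1]]
    list(gm = gm, seq = paste(ref, collapse = ""), coding = coding)
  }
  a <- build("ctgA"); b <- build("ctgB")
  list(
    reference = c(ctgA = a$seq, ctgB = b$seq),
    gene_models = dplyr::bind_rows(a$gm, b$gm),
    cds = list(ctgA = a$coding, ctgB = b$coding)
  )
}

translate_str <- function(s) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(s) %/% 3
  if (n == 0) return("")
  codons <- substring(s, seq(1, by = 3, length.out = n), seq(3, by = 3, length.out = n))
  paste(as.character(code[codons]), collapse = "")
}

# sequence-level fusion oracle for a plus/plus junction retaining the left
# side of gene A (upstream) and the right side of gene B (downstream):
# splice both retained pieces, translate from A's native start codon, and
# call the fusion in frame iff the ribosome's first stop is B's native
# terminal stop codon, in B's native frame.
fusion_orf_oracle <- function(pair, pos_a, pos_b) {
  gma <- pair$gene_models[1, ]; gmb <- pair$gene_models[2, ]
  exa <- oncowga:::exon_positions(gma)    # transcript order (plus strand)
  exb <- oncowga:::exon_positions(gmb)
  up <- exa[exa <= pos_a]                 # retained exonic bases of A
  dn <- exb[exb >= pos_b]                 # retained exonic bases of B
  base_at <- function(ref, chrom, p) substr(ref[[chrom]], p, p)
  mrna <- paste0(
    paste(vapply(up, function(p) base_at(pair$reference, "ctgA", p), character(1)),
          collapse = ""),
    paste(vapply(dn, function(p) base_at(pair$reference, "ctgB", p), character(1)),
          collapse = "")
  )
  # position of A's start codon within the fused mRNA
  utr5_a <- sum(exa < gma$cds_start)
  if (length(up) < utr5_a + 3) return("no_orf")        # start codon lost
  orf <- substr(mrna, utr5_a + 1, nchar(mrna))
  # B's terminal stop codon position within the fused mRNA
  cdsb <- oncowga:::cds_positions(gmb)
  stop_b <- tail(cdsb, 3)                               # genomic pos of stop codon
  if (!all(stop_b %in% dn)) return("no_orf")
  stop_off <- length(up) + match(stop_b[1], dn) - utr5_a  # 1-based in orf
  aa <- translate_str(substr(orf, 1, nchar(orf) - nchar(orf) %% 3))
  first_stop <- regexpr("*", aa, fixed = TRUE)[1]
  if (first_stop < 0) return("readthrough")
  stop_codon_start <- (first_stop - 1) * 3 + 1
  if (stop_codon_start == stop_off) "inframe" else "not_inframe"
}
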