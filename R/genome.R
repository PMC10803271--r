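# Toy reference genome and canonical gene models.
#
# A desk-scale reference (two contigs, ~13 kb) carrying 14 canonical
# transcripts with realistic structure: 3 exons, 5'/3' UTRs, introns, an ATG
# start and a stop codon, and internally stop-free coding sequence so that
# consequence annotation and fusion reading-frame assessment are exactly
# computable. Gene roles and the test-directory table mirror the field's
# conventions (oncogene vs tumor suppressor; per-tumor-type indications).

#' Build the toy genome and its annotation resources
#'
#' Deterministically generates a small two-contig reference plus canonical
#' gene models, the test-directory table, and the ICD-10 / operation-code
#' maps used by clinical linkage. The same seed always yields byte-identical
#' output.
#'
#' @param seed Integer seed controlling the random portions of the sequence.
#' @return A list with elements `reference` (named character vector of contig
#'   sequences), `gene_models` (tibble: gene, transcript_id, chrom, strand,
#'   exons (list of start/end tibbles), cds_start, cds_end, role,
#'   lof_mechanism), `directory` (gene, tumor_type, variant_class),
#'   `tumor_types`, `icd10_map` (icd10, tumor_type), and `opcode_map`
#'   (opcode, tumor_type).
#' @examples
#' g <- toy_genome()
#' nchar(g$reference)
#' @export
toy_genome <- function(seed = 1L) {
  with_seed(seed, build_toy_genome())
}

build_toy_genome <- function() {
  specs <- tibble::tribble(
    ~gene, ~chrom, ~strand, ~role, ~lof_mechanism, ~mid_cds,
    "TP53",   "chr1", "+", "tsg",      TRUE,  120L,
    "KRAS",   "chr1", "-", "oncogene", FALSE,  99L,
    "BRAF",   "chr1", "+", "oncogene", FALSE, 120L,
    "PTEN",   "chr1", "-", "tsg",      TRUE,   99L,
    "CDKN2A", "chr1", "+", "tsg",      TRUE,   99L,
    "BRCA1",  "chr1", "-", "tsg",      TRUE,  150L,
    "EML4",   "chr1", "+", "oncogene", FALSE, 120L,
    "EGFR",   "chr2", "+", "oncogene", FALSE, 150L,
    "PIK3CA", "chr2", "+", "oncogene", FALSE, 120L,
    "RB1",    "chr2", "-", "tsg",      TRUE,   99L,
    "APC",    "chr2", "+", "tsg",      TRUE,  120L,
    "PMS2",   "chr2", "-", "tsg",      TRUE,   99L,
    "ALK",    "chr2", "+", "oncogene", FALSE, 150L,
    "DPYD",   "chr2", "-", "both",     FALSE, 120L
  )
  utr5 <- 30L; utr3 <- 30L; intron <- 60L
  pad <- 400L

  contigs <- list()
  rows <- vector("list", nrow(specs))
  cursor <- list(chr1 = pad, chr2 = pad)
  seqs <- list(chr1 = character(), chr2 = character())

  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    c1 <- 60L; c2 <- sp$mid_cds; c3 <- 90L
    cds_len <- c1 + c2 + c3
    stopifnot(cds_len %% 3 == 0)
    # exon lengths in genomic (left-to-right) order
    if (sp$strand == "+") {
      ex_len <- c(utr5 + c1, c2, c3 + utr3)
    } else {
      ex_len <- c(utr3 + c3, c2, c1 + utr5)
    }
    start <- cursor[[sp$chrom]] + 1L
    ex_start <- start + cumsum(c(0L, head(ex_len, -1) + intron))
    ex_end <- ex_start + ex_len - 1L
    gene_end <- ex_end[3]
    cursor[[sp$chrom]] <- gene_end + pad

    if (sp$strand == "+") {
      cds_start <- ex_start[1] + utr5
      cds_end <- ex_end[3] - utr3
    } else {
      cds_start <- ex_start[1] + utr3
      cds_end <- ex_end[3] - utr5
    }
    rows[[i]] <- tibble::tibble(
      gene = sp$gene,
      transcript_id = paste0("TX_", sp$gene),
      chrom = sp$chrom, strand = sp$strand,
      exons = list(tibble::tibble(start = ex_start, end = ex_end)),
      cds_start = cds_start, cds_end = cds_end,
      role = sp$role, lof_mechanism = sp$lof_mechanism
    )
  }
  gene_models <- dplyr::bind_rows(rows)

  # raw random sequence per contig, then embed coding sequence per gene
  lens <- vapply(cursor, function(x) x + pad, numeric(1))
  reference <- vapply(names(lens), function(chr) {
    paste(sample(c("A", "C", "G", "T"), lens[[chr]], replace = TRUE), collapse = "")
  }, character(1))

  stop_codons <- c("TAA", "TAG", "TGA")
  all_codons <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
                                c("A", "C", "G", "T"), paste0))
  safe_codons <- setdiff(all_codons, c(stop_codons, "ATG"))

  for (i in seq_len(nrow(gene_models))) {
    g <- gene_models[i, ]
    n_codon <- cds_genomic_length(g) / 3
    coding <- paste0(
      "ATG",
      paste(sample(safe_codons, n_codon - 2L, replace = TRUE), collapse = ""),
      "TAA"
    )
    genomic <- if (g$strand == "+") coding else revcomp(coding)
    # write the coding bases into the CDS positions, transcript order
    pos <- cds_positions(g)                      # translation order
    gpos <- sort(pos)                            # genomic order
    bases <- strsplit(genomic, "")[[1]]
    ref <- strsplit(reference[[g$chrom]], "")[[1]]
    ref[gpos] <- bases
    reference[[g$chrom]] <- paste(ref, collapse = "")
  }

  tumor_types <- c("breast", "colon", "rectum", "ovarian_hgs", "endometrial",
                   "melanoma", "lung_adeno", "glioblastoma", "sarcoma",
                   "pancreatic")
  directory <- tibble::tribble(
    ~gene, ~tumor_type, ~variant_class,
    "BRAF", "melanoma", "small_variant",
    "KRAS", "colon", "small_variant",
    "KRAS", "rectum", "small_variant",
    "KRAS", "lung_adeno", "small_variant",
    "KRAS", "pancreatic", "small_variant",
    "APC", "colon", "small_variant",
    "APC", "rectum", "small_variant",
    "PIK3CA", "breast", "small_variant",
    "PIK3CA", "colon", "small_variant",
    "TP53", "ovarian_hgs", "small_variant",
    "TP53", "glioblastoma", "small_variant",
    "TP53", "sarcoma", "small_variant",
    "PTEN", "endometrial", "small_variant",
    "EGFR", "lung_adeno", "small_variant",
    "EGFR", "glioblastoma", "cna",
    "CDKN2A", "glioblastoma", "cna",
    "CDKN2A", "melanoma", "cna",
    "RB1", "sarcoma", "cna",
    "PTEN", "glioblastoma", "cna",
    "ALK", "lung_adeno", "sv",
    "BRCA1", "ovarian_hgs", "germline",
    "BRCA1", "breast", "germline",
    "PMS2", "endometrial", "germline",
    "PMS2", "colon", "germline"
  )
  icd10_map <- tibble::tribble(
    ~icd10, ~tumor_type,
    "C50", "breast", "C18", "colon", "C20", "rectum",
    "C56", "ovarian_hgs", "C54", "endometrial", "C43", "melanoma",
    "C34", "lung_adeno", "C71", "glioblastoma", "C49", "sarcoma",
    "C25", "pancreatic"
  )
  opcode_map <- tibble::tibble(
    opcode = c("B27", "H04", "H33", "Q22", "Q07", "S06", "E54", "A38", "X10", "J56"),
    tumor_type = tumor_types
  )
  list(
    reference = reference, gene_models = gene_models, directory = directory,
    tumor_types = tumor_types, icd10_map = icd10_map, opcode_map = opcode_map
  )
}

# reverse complement of a character string
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

cds_genomic_length <- function(gene_row) {
  ex <- gene_row$exons[[1]]
  s <- pmax(ex$start, gene_row$cds_start)
  e <- pmin(ex$end, gene_row$cds_end)
  sum(pmax(0L, e - s + 1L))
}

# genomic positions of CDS bases in translation (5'->3' transcript) order;
# memoized per transcript since callers hit the same genes repeatedly
.cds_cache <- new.env(parent = emptyenv())

cds_positions <- function(gene_row) {
  key <- paste0(gene_row$transcript_id, "|", gene_row$chrom, "|",
                gene_row$cds_start, "|", gene_row$cds_end)
  hit <- .cds_cache[[key]]
  if (!is.null(hit)) return(hit)
  ex <- gene_row$exons[[1]]
  s <- pmax(ex$start, gene_row$cds_start)
  e <- pmin(ex$end, gene_row$cds_end)
  keep <- s <= e
  pos <- unlist(purrr::map2(s[keep], e[keep], seq))
  pos <- if (gene_row$strand == "-") rev(pos) else pos
  .cds_cache[[key]] <- pos
  pos
}

# exonic positions (incl. UTR) in transcript order
exon_positions <- function(gene_row) {
  ex <- gene_row$exons[[1]]
  pos <- unlist(purrr::map2(ex$start, ex$end, seq))
  if (gene_row$strand == "-") rev(pos) else pos
}

ref_seq <- function(reference, chrom, start, end) {
  substr(reference[[chrom]], start, end)
}

#' Write / read the toy reference as FASTA
#'
#' Thin wrappers over `Biostrings` for the reference contigs.
#' @param reference Named character vector of contig sequences.
#' @param path FASTA path.
#' @return `read_reference_fasta()` returns a named character vector.
#' @export
write_reference_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}
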