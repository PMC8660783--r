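# Hand-rolled transcript helpers for the consequence-caller oracle. These
# re-derive coordinate mappings and rebuild + translate the full mutant CDS
# independently of the package implementation.

make_test_tx <- function(strand = "+", exon_lengths = c(30L, 33L, 30L),
                         seed = 7) {
  stopifnot(sum(exon_lengths) %% 3 == 0)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  set.seed(seed)
  n_codon <- sum(exon_lengths) / 3L
  cds <- paste(c("ATG", sample(sense, n_codon - 2L, replace = TRUE), "TAA"),
               collapse = "")
  starts <- cumsum(c(500L, utils::head(exon_lengths, -1) + 100L))
  tibble::tibble(
    gene = "TESTG", accession = "TX_TEST", chrom = "chrT", strand = strand,
    exons = list(tibble::tibble(start = starts,
                                end = starts + exon_lengths)),
    cds_sequence = cds
  )
}

# 1-based CDS coordinate -> 0-based genomic position (own derivation).
helper_cds_to_genomic <- function(tx, k) {
  ex <- tx$exons[[1]]
  widths <- ex$end - ex$start
  n <- nrow(ex)
  order_idx <- if (tx$strand == "+") seq_len(n) else rev(seq_len(n))
  acc <- 0L
  for (i in order_idx) {
    if (k <= acc + widths[i]) {
      off <- k - acc - 1L
      return(if (tx$strand == "+") ex$start[i] + off else ex$end[i] - 1L - off)
    }
    acc <- acc + widths[i]
  }
  stop("cds coordinate out of range")
}

# 0-based genomic position -> 1-based CDS coordinate, or NA.
helper_genomic_to_cds <- function(tx, g0) {
  L <- sum(tx$exons[[1]]$end - tx$exons[[1]]$start)
  for (k in seq_len(L)) {
    if (helper_cds_to_genomic(tx, k) == g0) return(k)
  }
  NA_integer_
}

helper_comp <- function(b) chartr("ACGT", "TGCA", b)

# Genomic-strand base at a coding position.
helper_base <- function(tx, g0) {
  k <- helper_genomic_to_cds(tx, g0)
  b <- substr(tx$cds_sequence, k, k)
  if (tx$strand == "-") helper_comp(b) else b
}

# Transcription-order index of the exon containing a genomic position.
helper_exon_index <- function(tx, g0) {
  ex <- tx$exons[[1]]
  i <- which(g0 >= ex$start & g0 < ex$end)
  if (tx$strand == "+") i else nrow(ex) - i + 1L
}

helper_translate <- function(s) {
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     no.init.codon = TRUE))
}

# Oracle for an SNV at CDS coordinate k with coding-strand alternate base:
# rebuild the whole mutant CDS, translate both proteins, compare.
oracle_snv_consequence <- function(cds, k, alt_coding) {
  mutant <- cds
  substr(mutant, k, k) <- alt_coding
  p0 <- helper_translate(cds)
  p1 <- helper_translate(mutant)
  ci <- (k - 1) %/% 3 + 1
  if (substr(p1, ci, ci) == "*" && substr(p0, ci, ci) != "*") {
    "stop_gained"
  } else if (p1 == p0) {
    "synonymous"
  } else {
    "missense"
  }
}

# Oracle for a pure deletion of coding bases: rebuild the mutant CDS and
# classify by reading-frame disruption.
oracle_del_consequence <- function(cds, k_first, len) {
  mutant <- paste0(substr(cds, 1, k_first - 1), substr(cds, k_first + len,
                                                       nchar(cds)))
  if ((nchar(cds) - nchar(mutant)) %% 3 != 0) "frameshift" else "inframe_indel"
}
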