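PTV_CONSEQUENCES <- c("stop_gained", "frameshift", "canonical_splice")

CLASSIFICATION_REASONS <- c("clinvar_plp", "conflicting_ptv", "novel_ptv",
                            "last_exon_ptv_excluded", "clinvar_benign",
                            "not_rare", "non_truncating_unclassified")

#' Is a variant rare in the reference population?
#'
#' A variant is rare iff it is absent from the reference frequency table
#' (unobserved implies below threshold) or its minor allele frequency is at
#' most `maf_max` (inclusive).
#'
#' @param key Character vector of variant keys.
#' @param freq_table Tibble with columns `key`, `maf`
#'   (see [read_frequency_table()]).
#' @param maf_max Rarity threshold (default 0.01).
#' @return Logical vector.
#' @export
is_rare <- function(key, freq_table, maf_max = 0.01) {
  maf <- freq_table$maf[match(key, freq_table$key)]
  is.na(maf) | maf <= maf_max
}

comp_base <- function(b) {
  chartr("ACGTacgt", "TGCAtgca", b)
}

revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(comp_base(x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# CDS coordinate (1-based) and transcription-order exon index of a 0-based
# genomic position inside a coding exon; NULL if not exonic.
cds_coordinate <- function(g0, tx) {
  ex <- tx$exons[[1]]
  n <- nrow(ex)
  widths <- ex$end - ex$start
  i <- which(g0 >= ex$start & g0 < ex$end)
  if (length(i) != 1) return(NULL)
  if (tx$strand == "+") {
    offset <- if (i > 1) sum(widths[seq_len(i - 1)]) else 0L
    offset <- offset + (g0 - ex$start[i])
    list(cds_pos = offset + 1L, exon_index = i)
  } else {
    offset <- if (i < n) sum(widths[seq(i + 1, n)]) else 0L
    offset <- offset + (ex$end[i] - 1L - g0)
    list(cds_pos = offset + 1L, exon_index = n - i + 1L)
  }
}

# Splice-window lookup: does the 0-based half-open span [a, b) hit a +/-2
# intronic window? Returns the transcription-order index of the downstream
# exon, or NULL.
splice_hit <- function(a, b, tx, window = 2L) {
  ex <- tx$exons[[1]]
  n <- nrow(ex)
  if (n < 2) return(NULL)
  for (j in seq_len(n - 1)) {
    win_starts <- c(ex$end[j], ex$start[j + 1] - window)
    win_ends <- c(ex$end[j] + window, ex$start[j + 1])
    hit <- any(a < win_ends & b > win_starts)
    if (hit) {
      idx <- if (tx$strand == "+") j + 1L else n - j + 1L
      return(idx)
    }
  }
  NULL
}

#' Call the coding consequence of a variant on a transcript model
#'
#' SNVs inside the coding sequence are classified by translating the
#' affected codon: `stop_gained` if the new codon is a stop, `synonymous` if
#' the amino acid is unchanged, otherwise `missense`. Indels inside the CDS
#' are `frameshift` when the allele length difference is not a multiple of
#' three, else `inframe_indel`. Intronic positions within 2 bases of a
#' coding-exon boundary are `canonical_splice` (assigned to the downstream
#' exon in transcription order). Everything else is `other`. Minus-strand
#' transcripts are handled by complementing the alleles.
#'
#' @param chrom,pos,ref,alt A single normalised variant (1-based `pos`).
#' @param tx A one-row transcript tibble (see [read_transcripts()]).
#' @return A one-row tibble: `consequence`, `cds_position`, `exon_index`.
#' @export
call_consequence <- function(chrom, pos, ref, alt, tx) {
  none <- tibble(consequence = "other", cds_position = NA_integer_,
                 exon_index = NA_integer_)
  if (!identical(chrom, tx$chrom)) return(none)
  g0 <- as.integer(pos) - 1L
  snv <- nchar(ref) == 1L && nchar(alt) == 1L

  if (snv) {
    co <- cds_coordinate(g0, tx)
    if (!is.null(co)) {
      cds <- tx$cds_sequence
      ref_c <- if (tx$strand == "+") ref else comp_base(ref)
      alt_c <- if (tx$strand == "+") alt else comp_base(alt)
      if (substr(cds, co$cds_pos, co$cds_pos) != toupper(ref_c)) {
        warn(paste0("Reference allele mismatch at ", chrom, ":", pos,
                    " for gene ", tx$gene, "; consequence called anyway"))
      }
      ci <- (co$cds_pos - 1L) %/% 3L
      within <- (co$cds_pos - 1L) %% 3L + 1L
      codon_old <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
      codon_new <- codon_old
      substr(codon_new, within, within) <- toupper(alt_c)
      aa_old <- translate_codon(codon_old)
      aa_new <- translate_codon(codon_new)
      cons <- if (!is.na(aa_new) && aa_new == "*") "stop_gained"
        else if (identical(aa_old, aa_new)) "synonymous"
        else "missense"
      return(tibble(consequence = cons, cds_position = co$cds_pos,
                    exon_index = co$exon_index))
    }
    idx <- splice_hit(g0, g0 + 1L, tx)
    if (!is.null(idx)) {
      return(tibble(consequence = "canonical_splice",
                    cds_position = NA_integer_, exon_index = idx))
    }
    return(none)
  }

  if (nchar(ref) == nchar(alt)) {
    # equal-length multi-nucleotide substitution: not classified further
    return(none)
  }

  # indel: locate the first base that actually changes (skip shared prefix)
  k <- 0L
  while (k < min(nchar(ref), nchar(alt)) &&
         substr(ref, k + 1L, k + 1L) == substr(alt, k + 1L, k + 1L)) {
    k <- k + 1L
  }
  aff_start <- g0 + k
  aff_end <- max(aff_start + 1L, g0 + nchar(ref))
  ex <- tx$exons[[1]]
  exonic <- any(aff_start < ex$end & aff_end > ex$start)
  if (exonic) {
    cons <- if (abs(nchar(ref) - nchar(alt)) %% 3L != 0L) "frameshift"
      else "inframe_indel"
    # first affected coding base in transcription order (lowest CDS coord)
    cos <- purrr::compact(map(seq(aff_start, aff_end - 1L),
                              function(g) cds_coordinate(g, tx)))
    co <- if (length(cos)) cos[[which.min(map_int(cos, "cds_pos"))]] else
      list(cds_pos = NA_integer_, exon_index = NA_integer_)
    return(tibble(consequence = cons, cds_position = co$cds_pos,
                  exon_index = co$exon_index))
  }
  idx <- splice_hit(aff_start, aff_end, tx)
  if (!is.null(idx)) {
    return(tibble(consequence = "canonical_splice",
                  cds_position = NA_integer_, exon_index = idx))
  }
  none
}

#' Is a consequence located in the transcript's last coding exon?
#'
#' Truncating variants in the last coding exon are expected to escape
#' nonsense-mediated decay, so novel truncating variants there are not
#' counted as pathogenic.
#'
#' @param consequence A one-row tibble from [call_consequence()] (needs
#'   `exon_index`), or an integer exon index.
#' @param tx A one-row transcript tibble.
#' @return Logical.
#' @export
in_last_coding_exon <- function(consequence, tx) {
  idx <- if (is.data.frame(consequence)) consequence$exon_index else consequence
  if (is.na(idx)) return(FALSE)
  idx == nrow(tx$exons[[1]])
}

#' Classify one variant as pathogenic or not
#'
#' Rule cascade (first match wins):
#' 1. not rare -> `not_rare`;
#' 2. ClinVar Pathogenic/LikelyPathogenic -> pathogenic (`clinvar_plp`),
#'    regardless of exon position;
#' 3. ClinVar Benign/LikelyBenign -> not pathogenic (`clinvar_benign`), even
#'    for truncating variants;
#' 4. protein-truncating + ClinVar Conflicting with submissions tending
#'    towards pathogenicity -> pathogenic (`conflicting_ptv`);
#' 5. protein-truncating + absent from ClinVar + not in the last coding
#'    exon -> pathogenic (`novel_ptv`);
#' 6. protein-truncating + absent + last coding exon -> not pathogenic
#'    (`last_exon_ptv_excluded`);
#' 7. otherwise not pathogenic (`non_truncating_unclassified`).
#'
#' "Tending towards pathogenicity" means at least `conflicting_min_plp`
#' pathogenic/likely-pathogenic submissions and strictly more of them than
#' benign/likely-benign submissions.
#'
#' @param key Variant key.
#' @param gene Gene symbol.
#' @param consequence Consequence string (see [call_consequence()]).
#' @param last_exon Logical: in the last coding exon?
#' @param significance ClinVar-style significance (Pathogenic,
#'   LikelyPathogenic, Conflicting, Benign, LikelyBenign, VUS, Absent).
#' @param n_plp,n_blb Submission counts for Conflicting records.
#' @param rare Logical from [is_rare()].
#' @param conflicting_min_plp Minimum P/LP submissions for rule 4.
#' @return A one-row tibble: `key`, `gene`, `verdict`, `reason`, `is_ptv`.
#' @export
classify_variant <- function(key, gene, consequence, last_exon, significance,
                             n_plp = 0L, n_blb = 0L, rare = TRUE,
                             conflicting_min_plp = 1L) {
  is_ptv <- consequence %in% PTV_CONSEQUENCES
  reason <- if (!rare) {
    "not_rare"
  } else if (significance %in% c("Pathogenic", "LikelyPathogenic")) {
    "clinvar_plp"
  } else if (significance %in% c("Benign", "LikelyBenign")) {
    "clinvar_benign"
  } else if (is_ptv && significance == "Conflicting" &&
             n_plp >= conflicting_min_plp && n_plp > n_blb) {
    "conflicting_ptv"
  } else if (is_ptv && significance == "Absent" && !last_exon) {
    "novel_ptv"
  } else if (is_ptv && significance == "Absent" && last_exon) {
    "last_exon_ptv_excluded"
  } else {
    "non_truncating_unclassified"
  }
  verdict <- if (reason %in% c("clinvar_plp", "conflicting_ptv", "novel_ptv")) {
    "pathogenic"
  } else {
    "not_pathogenic"
  }
  tibble(key = key, gene = gene, verdict = verdict, reason = reason,
         is_ptv = is_ptv)
}

#' Classify all variants in a harmonised call table
#'
#' Joins each distinct variant key against the transcript models (for
#' consequence calling), the classification table (ClinVar-style
#' assertions; unmatched keys are `Absent`) and the reference frequency
#' table (rarity), then runs the decision cascade of [classify_variant()].
#'
#' @param calls Tibble of calls with `key`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene` (or a `harmonised_calls` object).
#' @param transcripts Transcript tibble (see [read_transcripts()]).
#' @param classification Classification tibble
#'   (see [read_classification_table()]).
#' @param frequency Frequency tibble (see [read_frequency_table()]).
#' @param maf_max Rarity threshold (default 0.01).
#' @param conflicting_min_plp See [classify_variant()].
#' @return A tibble with one row per distinct variant: `key`, `gene`,
#'   `consequence`, `cds_position`, `exon_index`, `last_exon`, `rare`,
#'   `significance`, `is_ptv`, `verdict`, `reason`.
#' @export
classify_variants <- function(calls, transcripts, classification = NULL,
                              frequency = NULL, maf_max = 0.01,
                              conflicting_min_plp = 1L) {
  if (inherits(calls, "harmonised_calls")) calls <- calls$calls
  if (nrow(calls) == 0) {
    return(tibble(key = character(0), gene = character(0),
                  consequence = character(0), cds_position = integer(0),
                  exon_index = integer(0), last_exon = logical(0),
                  rare = logical(0), significance = character(0),
                  is_ptv = logical(0), verdict = character(0),
                  reason = character(0)))
  }
  if (is.null(classification)) {
    classification <- tibble(key = character(0), significance = character(0),
                             n_plp_submissions = integer(0),
                             n_blb_submissions = integer(0))
  }
  if (is.null(frequency)) {
    frequency <- tibble(key = character(0), maf = numeric(0))
  }
  uniq <- calls %>%
    distinct(.data$key, .data$chrom, .data$pos, .data$ref, .data$alt,
             .data$gene)
  uniq <- uniq %>%
    left_join(classification, by = "key") %>%
    mutate(
      significance = ifelse(is.na(.data$significance), "Absent",
                            .data$significance),
      n_plp_submissions = ifelse(is.na(.data$n_plp_submissions), 0L,
                                 .data$n_plp_submissions),
      n_blb_submissions = ifelse(is.na(.data$n_blb_submissions), 0L,
                                 .data$n_blb_submissions),
      rare = is_rare(.data$key, frequency, maf_max)
    )
  rows <- map(seq_len(nrow(uniq)), function(i) {
    r <- uniq[i, ]
    tx <- transcripts[transcripts$gene == r$gene, ]
    cons <- if (nrow(tx) == 1) {
      call_consequence(r$chrom, r$pos, r$ref, r$alt, tx)
    } else {
      tibble(consequence = "other", cds_position = NA_integer_,
             exon_index = NA_integer_)
    }
    last_ex <- if (nrow(tx) == 1) in_last_coding_exon(cons, tx) else FALSE
    cl <- classify_variant(r$key, r$gene, cons$consequence, last_ex,
                           r$significance, r$n_plp_submissions,
                           r$n_blb_submissions, r$rare,
                           conflicting_min_plp = conflicting_min_plp)
    tibble(key = r$key, gene = r$gene, consequence = cons$consequence,
           cds_position = cons$cds_position, exon_index = cons$exon_index,
           last_exon = last_ex, rare = r$rare, significance = r$significance,
           is_ptv = cl$is_ptv, verdict = cl$verdict, reason = cl$reason)
  })
  bind_rows(rows)
}
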