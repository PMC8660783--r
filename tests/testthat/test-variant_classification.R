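test_that("rarity uses the inclusive MAF threshold and treats unobserved as rare", {
  freq <- tibble::tibble(key = c("k1", "k2", "k3"),
                         maf = c(0.01, 0.05, 0.0001))
  expect_equal(is_rare(c("k1", "k2", "k3", "k_absent"), freq),
               c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(is_rare("k1", freq, maf_max = 0.005), FALSE)
})

test_that("SNV consequences match the full-CDS-rebuild-and-translate oracle", {
  for (strand in c("+", "-")) {
    tx <- make_test_tx(strand, seed = if (strand == "+") 7 else 8)
    cds <- tx$cds_sequence
    L <- nchar(cds)

    # forced example: mutate a codon into TAA
    k <- regexpr("TAC", substr(cds, 4, L - 3), fixed = TRUE)[1] + 3
    if (k > 3 && (k - 1) %% 3 == 0) {
      g0 <- helper_cds_to_genomic(tx, k + 2)
      alt_coding <- "A"
      alt <- if (strand == "+") alt_coding else helper_comp(alt_coding)
      got <- call_consequence(tx$chrom, g0 + 1, helper_base(tx, g0), alt, tx)
      expect_equal(got$consequence, "stop_gained")
    }

    set.seed(17)
    for (i in 1:300) {
      k <- sample(seq(1, L - 3), 1)     # skip the terminal stop codon
      g0 <- helper_cds_to_genomic(tx, k)
      ref_gen <- helper_base(tx, g0)
      alt_gen <- sample(setdiff(c("A", "C", "G", "T"), ref_gen), 1)
      alt_coding <- if (strand == "+") alt_gen else helper_comp(alt_gen)
      got <- call_consequence(tx$chrom, g0 + 1, ref_gen, alt_gen, tx)
      expect_equal(got$consequence, oracle_snv_consequence(cds, k, alt_coding),
                   info = paste(strand, k, ref_gen, alt_gen))
      expect_equal(got$cds_position, k)
      expect_equal(got$exon_index, helper_exon_index(tx, g0))
    }
  }
})

test_that("indel consequences follow the reading-frame rule with correct anchoring", {
  for (strand in c("+", "-")) {
    tx <- make_test_tx(strand, seed = 9)
    ex <- tx$exons[[1]]
    set.seed(23)
    for (i in 1:100) {
      e <- sample(1:3, 1)
      len <- sample(1:4, 1)
      p <- sample(seq(ex$start[e] + 1L, ex$end[e] - len - 1L), 1)
      anchor <- p - 1L
      ref <- paste(vapply(seq(anchor, p + len - 1L),
                          function(g) helper_base(tx, g), ""), collapse = "")
      alt <- helper_base(tx, anchor)
      got <- call_consequence(tx$chrom, anchor + 1L, ref, alt, tx)
      ks <- vapply(seq(p, p + len - 1L),
                   function(g) helper_genomic_to_cds(tx, g), 1L)
      expect_equal(got$consequence,
                   oracle_del_consequence(tx$cds_sequence, min(ks), len))
      expect_equal(got$cds_position, min(ks))
      expect_equal(got$exon_index, helper_exon_index(tx, p))
    }
    # contiguous 3bp deletion is in-frame, 2bp shifts the frame
    p <- ex$start[2] + 5L
    ref4 <- paste(vapply(seq(p - 1, p + 2), function(g) helper_base(tx, g),
                         ""), collapse = "")
    expect_equal(call_consequence(tx$chrom, p, substr(ref4, 1, 3),
                                  substr(ref4, 1, 1), tx)$consequence,
                 "frameshift")
    expect_equal(call_consequence(tx$chrom, p, ref4, substr(ref4, 1, 1),
                                  tx)$consequence, "inframe_indel")
  }
})

test_that("splice-window variants are canonical_splice assigned to the downstream exon", {
  for (strand in c("+", "-")) {
    tx <- make_test_tx(strand, seed = 10)
    ex <- tx$exons[[1]]
    n <- nrow(ex)
    for (j in 1:(n - 1)) {
      downstream <- if (strand == "+") j + 1L else n - j + 1L
      for (off in 0:1) {
        # donor-side intron bases (genomic): first two after exon j
        got <- call_consequence(tx$chrom, ex$end[j] + off + 1L, "A", "C", tx)
        expect_equal(got$consequence, "canonical_splice")
        expect_equal(got$exon_index, downstream)
        # acceptor-side: last two before exon j+1
        got <- call_consequence(tx$chrom, ex$start[j + 1] - off, "A", "C", tx)
        expect_equal(got$consequence, "canonical_splice")
        expect_equal(got$exon_index, downstream)
      }
      # three bases into the intron: outside the canonical window
      expect_equal(call_consequence(tx$chrom, ex$end[j] + 3L, "A", "C",
                                    tx)$consequence, "other")
    }
    # far outside the transcript
    expect_equal(call_consequence(tx$chrom, 5L, "A", "C", tx)$consequence,
                 "other")
    expect_equal(call_consequence("chrZ", ex$start[1] + 2L, "A", "C",
                                  tx)$consequence, "other")
  }
})

test_that("last-coding-exon detection follows transcription order, including final-intron splice", {
  for (strand in c("+", "-")) {
    tx <- make_test_tx(strand, seed = 12)
    ex <- tx$exons[[1]]
    n <- nrow(ex)
    last_genomic <- if (strand == "+") n else 1L
    first_genomic <- if (strand == "+") 1L else n
    g_last <- ex$start[last_genomic] + 4L
    g_first <- ex$start[first_genomic] + 4L
    cons_last <- call_consequence(tx$chrom, g_last + 1L,
                                  helper_base(tx, g_last), "N", tx)
    cons_first <- call_consequence(tx$chrom, g_first + 1L,
                                   helper_base(tx, g_first), "N", tx)
    expect_true(in_last_coding_exon(cons_last, tx))
    expect_false(in_last_coding_exon(cons_first, tx))
    # splice variant at the boundary of the final intron in transcription
    # order is assigned downstream, i.e. to the last exon
    final_intron_donor <- if (strand == "+") ex$end[n - 1] + 1L else
      ex$start[2] - 2L
    spl <- call_consequence(tx$chrom, final_intron_donor + 1L, "A", "C", tx)
    expect_equal(spl$consequence, "canonical_splice")
    expect_true(in_last_coding_exon(spl, tx))
  }
})

test_that("the decision cascade is total, deterministic, and matches the truth table", {
  consequences <- c("stop_gained", "frameshift", "canonical_splice",
                    "missense", "synonymous", "inframe_indel", "other")
  sigs <- c("Pathogenic", "LikelyPathogenic", "Conflicting", "Benign",
            "LikelyBenign", "VUS", "Absent")
  counts <- list(c(0L, 0L), c(1L, 0L), c(1L, 1L), c(3L, 1L), c(2L, 2L),
                 c(0L, 3L))
  n_checked <- 0
  for (cons in consequences) for (sig in sigs) for (last in c(TRUE, FALSE))
    for (rare in c(TRUE, FALSE)) for (cnt in counts) {
      got <- classify_variant("k", "G", cons, last, sig, cnt[1], cnt[2], rare)
      exp <- expected_classification(cons, sig, last, rare, cnt[1], cnt[2])
      expect_equal(got$verdict, exp$verdict,
                   info = paste(cons, sig, last, rare, cnt[1], cnt[2]))
      expect_equal(got$reason, exp$reason,
                   info = paste(cons, sig, last, rare, cnt[1], cnt[2]))
      expect_equal(got$is_ptv,
                   cons %in% c("stop_gained", "frameshift",
                               "canonical_splice"))
      # the internal invariant: verdict <-> reason coupling
      expect_equal(got$verdict == "pathogenic",
                   got$reason %in% c("clinvar_plp", "conflicting_ptv",
                                     "novel_ptv"))
      n_checked <- n_checked + 1
    }
  expect_gte(n_checked, 7 * 7 * 2 * 2)
})

test_that("the named classification examples behave as specified", {
  # recurrent frameshift with Conflicting ClinVar record tending pathogenic
  got <- classify_variant("chek2_1100delC", "CHEK2", "frameshift", FALSE,
                          "Conflicting", n_plp = 3, n_blb = 1, rare = TRUE)
  expect_equal(got$verdict, "pathogenic")
  expect_equal(got$reason, "conflicting_ptv")
  # novel frameshift in the last coding exon
  got <- classify_variant("k", "G", "frameshift", TRUE, "Absent", 0, 0, TRUE)
  expect_equal(got$reason, "last_exon_ptv_excluded")
  # asserted likely-pathogenic missense
  got <- classify_variant("k", "G", "missense", FALSE, "LikelyPathogenic",
                          1, 0, TRUE)
  expect_equal(got$reason, "clinvar_plp")
  # P/LP assertion overrides the last-exon exclusion
  got <- classify_variant("k", "G", "stop_gained", TRUE, "Pathogenic", 2, 0,
                          TRUE)
  expect_equal(got$verdict, "pathogenic")
})

test_that("classification is monotone when evidence is upgraded Absent -> Pathogenic", {
  consequences <- c("stop_gained", "frameshift", "canonical_splice",
                    "missense", "synonymous", "inframe_indel", "other")
  for (cons in consequences) for (last in c(TRUE, FALSE)) {
    before <- classify_variant("k", "G", cons, last, "Absent", 0, 0, TRUE)
    after <- classify_variant("k", "G", cons, last, "Pathogenic", 1, 0, TRUE)
    if (before$verdict == "pathogenic") {
      expect_equal(after$verdict, "pathogenic")
    }
  }
})

test_that("classify_variants joins transcripts, ClinVar and frequency tables", {
  tx <- toy_transcripts(genes = c("ATM", "BARD1"))
  t1 <- tx[1, ]
  ex <- t1$exons[[1]]
  g_del <- ex$start[1] + 5L
  calls <- tibble::tibble(
    subject_id = c("s1", "s2", "s3"),
    chrom = t1$chrom,
    pos = c(g_del, g_del + 20L, g_del + 30L),
    ref = c(paste0(panelor:::genomic_base(t1, g_del - 1L),
                   panelor:::genomic_base(t1, g_del)),
            panelor:::genomic_base(t1, g_del + 19L),
            panelor:::genomic_base(t1, g_del + 29L)),
    alt = c(panelor:::genomic_base(t1, g_del - 1L), "N", "N"),
    gene = "ATM", depth = 99, vaf = 0.5, platform = "HiPlex", qc_pass = TRUE)
  calls$key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  classification <- tibble::tibble(
    key = calls$key[2], significance = "Pathogenic",
    n_plp_submissions = 2L, n_blb_submissions = 0L)
  frequency <- tibble::tibble(key = calls$key[3], maf = 0.05)
  got <- classify_variants(calls, tx, classification, frequency)
  expect_equal(nrow(got), 3)
  expect_equal(got$reason[match(calls$key, got$key)],
               c("novel_ptv", "clinvar_plp", "not_rare"))
  expect_equal(got$significance[match(calls$key, got$key)],
               c("Absent", "Pathogenic", "Absent"))
  # empty input -> empty, correctly typed output
  expect_equal(nrow(classify_variants(calls[0, ], tx)), 0)
})
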