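write_test_vcf <- function(path, records, sample = "S1",
                           format = "GT:DP:AF") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"gene\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"af\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  writeLines(c(header, records), path)
}

test_that("allele normalisation is idempotent, anchored and matches the hand-trim oracle", {
  # the worked example: CAG>CA trims one prefix base and shifts the anchor
  nm <- normalise_alleles(100, "CAG", "CA")
  expect_equal(nm$ref, "AG")
  expect_equal(nm$alt, "A")
  expect_equal(nm$pos, oracle_trim(100, "CAG", "CA")$pos)

  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    core_ref <- paste(sample(bases, sample(1:4, 1), replace = TRUE),
                      collapse = "")
    core_alt <- paste(sample(bases, sample(1:4, 1), replace = TRUE),
                      collapse = "")
    if (core_ref == core_alt) next
    pad_l <- paste(sample(bases, sample(0:3, 1), replace = TRUE),
                   collapse = "")
    pad_r <- paste(sample(bases, sample(0:3, 1), replace = TRUE),
                   collapse = "")
    pos <- sample(1:1000, 1)
    ref <- paste0(pad_l, core_ref, pad_r)
    alt <- paste0(pad_l, core_alt, pad_r)
    got <- normalise_alleles(pos, ref, alt)
    exp <- oracle_trim(pos, ref, alt)
    expect_equal(got$pos, exp$pos)
    expect_equal(got$ref, exp$ref)
    expect_equal(got$alt, exp$alt)
    # idempotence
    again <- normalise_alleles(got$pos, got$ref, got$alt)
    expect_equal(again, got)
    # representation independence: differently padded forms map to one key
    pad2 <- paste(sample(bases, 2, replace = TRUE), collapse = "")
    k1 <- variant_key("chr1", pos, ref, alt)
    k2 <- variant_key("chr1", pos, paste0(ref, pad2), paste0(alt, pad2))
    expect_equal(k1, k2)
  }
  expect_error(normalise_alleles(5, "A", "A"), "must differ")
})

test_that("read_vcf parses calls, splits multi-allelics and rejects missing fields", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, character(0))
  expect_equal(nrow(read_vcf(f, "HiPlex")), 0)

  write_test_vcf(f, c(
    "chr1\t100\t.\tG\tA,T\t.\tPASS\tGENE=ATM\tGT:DP:AF\t0/1:80:0.45,0.12",
    "chr1\t200\t.\tCAG\tCA\t.\tPASS\tGENE=ATM\tGT:DP:AF\t0/1:95:0.5"
  ))
  calls <- read_vcf(f, "HiPlex")
  expect_equal(nrow(calls), 3)
  multi <- calls[calls$pos == 100, ]
  expect_equal(multi$alt, c("A", "T"))
  expect_equal(multi$vaf, c(0.45, 0.12))
  expect_equal(unique(multi$ref), "G")
  # indel record is key-normalised (anchor shifts by the trimmed prefix)
  indel <- calls[calls$ref == "AG", ]
  expect_equal(indel$pos, 201L)
  expect_equal(indel$alt, "A")
  expect_equal(indel$key, "chr1:201:AG:A")
  expect_equal(unique(calls$subject_id), "S1")
  expect_true(all(is.na(calls$qc_pass)))

  # depth field missing -> hard error naming the record
  write_test_vcf(f, "chr2\t5\t.\tA\tC\t.\tPASS\t.\tGT:AF\t0/1:0.4",
                 format = "GT:AF")
  expect_error(read_vcf(f, "HiPlex"), "chr2:5.*depth")
})

test_that("read_panel_bed merges intervals and rejects malformed rows", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr17\t1\t10", "chr17\t5\t20"), f)
  p <- read_panel_bed(f, "toy")
  expect_equal(nrow(p), 1)
  expect_equal(p$start, 1L)
  expect_equal(p$end, 20L)
  expect_equal(attr(p, "panel_name"), "toy")

  file.create(f2 <- withr::local_tempfile(fileext = ".bed"))
  expect_equal(nrow(read_panel_bed(f2, "empty")), 0)

  writeLines(c("chr1\t10\t5"), f)
  expect_error(read_panel_bed(f, "bad"), "end <= start")

  # merge equals per-base union oracle on random small interval sets
  set.seed(21)
  for (i in 1:30) {
    raw <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 8, replace = TRUE),
      start = sample(0:800, 8))
    raw$end <- raw$start + sample(1:120, 8)
    writeLines(sprintf("%s\t%d\t%d", raw$chrom, raw$start, raw$end), f)
    p <- read_panel_bed(f, "rand")
    expect_setequal(oracle_base_set(p), unique(oracle_base_set(raw)))
    # disjoint after merge
    by_chrom <- split(p, p$chrom)
    for (d in by_chrom) {
      if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)]))
    }
  }

  # 3 disjoint intervals stay disjoint and total span is the length sum
  writeLines(c("chr3\t0\t10", "chr3\t20\t30", "chr3\t40\t55"), f)
  p <- read_panel_bed(f, "disjoint")
  expect_equal(nrow(p), 3)
  expect_equal(sum(p$end - p$start), 10 + 10 + 15)
})

test_that("phenotype tables round-trip exactly and reject unknown codes", {
  subj <- tibble::tibble(
    subject_id = "A1", study = "ABCFS", sex = "F", case_status = "case",
    er_status = "positive", age = 43.2, height = 1.66, bmi = 24.1,
    parity = 2, education = 12, alcohol = 3, prior_breast_cancer = FALSE,
    family_history = TRUE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(subj, f)
  got <- read_phenotypes(f)
  expect_equal(as.data.frame(got), as.data.frame(subj))

  # missing parity preserved as NA, not imputed
  subj2 <- subj
  subj2$subject_id <- "A2"
  subj2$study <- "ASPREE"
  subj2$case_status <- "control"
  subj2$er_status <- "unknown"
  subj2$parity <- NA_real_
  write_phenotypes(rbind(subj, subj2), f)
  got <- read_phenotypes(f)
  expect_true(is.na(got$parity[2]))

  # 50 random subjects round-trip to identity
  set.seed(5)
  n <- 50
  rand <- tibble::tibble(
    subject_id = sprintf("R%03d", 1:n),
    study = sample(c("ABCFS", "ASPREE"), n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.9, 0.1)),
    case_status = sample(c("case", "control"), n, replace = TRUE),
    age = round(runif(n, 25, 90), 1),
    height = replace(round(runif(n, 1.45, 1.85), 2),
                     sample(n, 4), NA),
    bmi = round(runif(n, 18, 40), 1),
    parity = as.numeric(replace(rpois(n, 2), sample(n, 3), NA)),
    education = as.numeric(rpois(n, 11)),
    alcohol = as.numeric(rpois(n, 3)),
    prior_breast_cancer = sample(c(TRUE, FALSE), n, replace = TRUE),
    family_history = replace(sample(c(TRUE, FALSE), n, replace = TRUE),
                             sample(n, 2), NA))
  rand$case_status[rand$study == "ASPREE"] <- "control"
  rand$er_status <- ifelse(rand$case_status == "case",
                           sample(c("positive", "negative", "unknown"), n,
                                  replace = TRUE), "unknown")
  rand <- rand[, names(subj)]
  write_phenotypes(rand, f)
  got <- read_phenotypes(f)
  expect_equal(as.data.frame(got), as.data.frame(rand))

  # unknown codes are rejected with the offending rows listed
  writeLines(c("subject_id,study,sex,case_status",
               "X1,ABCFS,F,case", "X2,NOTASTUDY,F,control"), f)
  expect_error(read_phenotypes(f), "study.*2")
})

test_that("classification and frequency tables validate their contents", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("key\tsignificance\tn_plp_submissions\tn_blb_submissions",
               "chr1:1:A:T\tPathogenic\t3\t0",
               "chr1:2:A:T\tAbsent\t0\t0"), f)
  d <- read_classification_table(f)
  expect_equal(nrow(d), 2)

  writeLines(c("key\tsignificance\tn_plp_submissions\tn_blb_submissions",
               "chr1:1:A:T\tWeird\t0\t0"), f)
  expect_error(read_classification_table(f), "unknown significance")

  writeLines(c("key\tsignificance\tn_plp_submissions\tn_blb_submissions",
               "chr1:1:A:T\tAbsent\t2\t0"), f)
  expect_error(read_classification_table(f), "Absent")

  writeLines(c("key\tmaf", "chr1:1:A:T\t0.002"), f)
  expect_equal(read_frequency_table(f)$maf, 0.002)
  writeLines(c("key\tmaf", "chr1:1:A:T\t0.7"), f)
  expect_error(read_frequency_table(f), "maf")
})

test_that("transcript TSVs round-trip and are validated", {
  tx <- toy_transcripts(genes = c("BRCA1", "CHEK2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_transcripts(tx, f)
  got <- read_transcripts(f)
  expect_equal(got$gene, tx$gene)
  expect_equal(got$cds_sequence, tx$cds_sequence)
  expect_equal(got$exons, tx$exons)

  bad <- tx
  bad$cds_sequence[1] <- substr(bad$cds_sequence[1], 1, 100)
  write_transcripts(bad, f)
  expect_error(read_transcripts(f), "does not match")
})

test_that("GFF3 transcript import splices and reverse-complements the CDS", {
  skip_if_not_installed("rtracklayer")
  tx <- make_test_tx("-")
  ex <- tx$exons[[1]]
  # genome: random background with the transcript's exon bases patched in
  set.seed(3)
  genome <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
                  collapse = "")
  for (g0 in unlist(Map(seq, ex$start, ex$end - 1))) {
    substr(genome, g0 + 1, g0 + 1) <- helper_base(tx, g0)
  }
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrT", genome), fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    sprintf("chrT\ttest\tmRNA\t%d\t%d\t.\t-\t.\tID=TX_TEST",
            min(ex$start) + 1, max(ex$end)),
    sprintf("chrT\ttest\tCDS\t%d\t%d\t.\t-\t0\tID=cds%d;Parent=TX_TEST;gene=TESTG",
            ex$start + 1, ex$end, seq_len(nrow(ex)))
  ), gff)
  got <- read_transcripts_gff3(gff, fa)
  expect_equal(got$gene, "TESTG")
  expect_equal(got$strand, "-")
  expect_equal(got$cds_sequence, tx$cds_sequence)
  expect_equal(got$exons[[1]]$start, ex$start)
})

test_that("association tables render dashes for non-estimable cells and read back", {
  res <- tibble::tibble(
    gene = c("BRCA1", "CDH1"), n_case_carriers = c(46L, 1L),
    case_pct = c(3.1, 0.1), n_control_carriers = c(6L, 0L),
    control_pct = c(0.1, 0), or = c(40.04, NA), ci_low = c(17.0, NA),
    ci_high = c(94.3, NA), p = c(1e-10, NA))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_association_table(res, f)
  raw <- readLines(f)
  expect_true(grepl("–", raw[3]))
  got <- read_association_table(f)
  expect_equal(got$or, res$or, tolerance = 1e-12)
  expect_true(is.na(got$p[2]))
})
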