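#' Read per-subject variant calls from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into one row per subject x
#' alternate allele. Multi-allelic records are split, alleles are normalised
#' to variant-key form, and per-call depth and variant allele fraction are
#' taken from the genotype FORMAT fields.
#'
#' @param path Path to a VCF file.
#' @param platform Sequencing platform of origin, one of `"HiPlex"`,
#'   `"HaloPlexHS"`, `"AmpliSeq"`.
#' @param subject_id Subject identifier; defaults to the VCF sample name.
#' @param depth_field FORMAT field holding read depth (default `"DP"`).
#' @param vaf_fields Candidate FORMAT fields for the variant allele fraction,
#'   tried in order (default `c("AF", "VAF")`).
#' @return A tibble of variant calls: `subject_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `key`, `gene`, `depth`, `vaf`, `platform`, `qc_pass` (`NA` until
#'   QC is applied).
#' @export
read_vcf <- function(path, platform, subject_id = NULL,
                     depth_field = "DP", vaf_fields = c("AF", "VAF")) {
  platform <- match.arg(platform, PLATFORMS)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
    error = function(e) abort(paste0("Malformed VCF '", path, "': ",
                                     conditionMessage(e)))
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(empty_calls(platform))
  }
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) {
    abort(paste0("VCF '", path, "' has no genotype (FORMAT) columns; ",
                 "per-call depth and allele fraction are required"))
  }
  if (is.null(subject_id)) subject_id <- colnames(gt)[2]

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    fmt <- str_split(gt[i, 1], stringr::fixed(":"))[[1]]
    val <- str_split(gt[i, 2], stringr::fixed(":"))[[1]]
    rec <- paste0(fix$CHROM[i], ":", fix$POS[i])
    di <- match(depth_field, fmt)
    if (is.na(di) || di > length(val) || val[di] %in% c(".", "")) {
      abort(paste0("VCF record ", rec, " in '", path,
                   "' is missing the depth field '", depth_field, "'"))
    }
    vi <- match(vaf_fields, fmt)
    vi <- vi[!is.na(vi)][1]
    if (is.na(vi) || vi > length(val) || val[vi] %in% c(".", "")) {
      abort(paste0("VCF record ", rec, " in '", path,
                   "' is missing an allele-fraction field (tried ",
                   paste(vaf_fields, collapse = ", "), ")"))
    }
    alts <- str_split(fix$ALT[i], stringr::fixed(","))[[1]]
    vafs <- as.numeric(str_split(val[vi], stringr::fixed(","))[[1]])
    if (length(vafs) == 1L) vafs <- rep(vafs, length(alts))
    if (length(vafs) != length(alts)) {
      abort(paste0("VCF record ", rec, ": allele-fraction field has ",
                   length(vafs), " values for ", length(alts), " ALT alleles"))
    }
    gene <- NA_character_
    if (!is.null(fix$INFO) && !is.na(fix$INFO[i])) {
      m <- regmatches(fix$INFO[i], regexpr("(?:^|;)GENE=[^;]+", fix$INFO[i]))
      if (length(m) == 1) gene <- sub(".*GENE=", "", m)
    }
    rows[[i]] <- tibble(
      chrom = fix$CHROM[i],
      pos = as.integer(fix$POS[i]),
      ref = fix$REF[i],
      alt = alts,
      gene = gene,
      depth = as.numeric(val[di]),
      vaf = vafs
    )
  }
  calls <- bind_rows(rows)
  nm <- normalise_alleles(calls$pos, calls$ref, calls$alt)
  calls %>%
    mutate(
      pos = nm$pos, ref = nm$ref, alt = nm$alt,
      key = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":"),
      subject_id = subject_id,
      platform = platform,
      qc_pass = NA
    ) %>%
    select("subject_id", "chrom", "pos", "ref", "alt", "key", "gene",
           "depth", "vaf", "platform", "qc_pass")
}

empty_calls <- function(platform = character(0)) {
  tibble(
    subject_id = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), key = character(0),
    gene = character(0), depth = numeric(0), vaf = numeric(0),
    platform = if (length(platform)) platform[0] else character(0),
    qc_pass = logical(0)
  )
}

#' Read a panel target-region BED file
#'
#' BED3+ input, 0-based half-open coordinates. Overlapping and adjacent
#' intervals are merged.
#'
#' @param path Path to a BED file.
#' @param name Panel name attached to the result.
#' @return A `panel_design`: tibble of merged `chrom`, `start`, `end`
#'   intervals (0-based half-open) with a `panel_name` attribute.
#' @export
read_panel_bed <- function(path, name = basename(path)) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  if (file.size(path) == 0) {
    return(new_panel_design(tibble(chrom = character(0), start = integer(0),
                                   end = integer(0)), name))
  }
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "track",
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 3) abort(paste0("BED file '", path, "' has fewer than 3 columns"))
  bed <- tibble(
    chrom = raw[[1]],
    start = suppressWarnings(as.integer(raw[[2]])),
    end = suppressWarnings(as.integer(raw[[3]]))
  )
  if (anyNA(bed$start) || anyNA(bed$end)) {
    abort(paste0("BED file '", path, "' has non-integer coordinates at rows: ",
                 paste(which(is.na(bed$start) | is.na(bed$end)), collapse = ", ")))
  }
  bad <- which(bed$end <= bed$start | bed$start < 0)
  if (length(bad)) {
    abort(paste0("BED file '", path, "' has invalid intervals (end <= start ",
                 "or negative start) at rows: ", paste(bad, collapse = ", ")))
  }
  new_panel_design(merge_regions(bed), name)
}

new_panel_design <- function(regions, name) {
  regions <- as_tibble(regions) %>% arrange(.data$chrom, .data$start)
  attr(regions, "panel_name") <- name
  class(regions) <- c("panel_design", class(regions))
  regions
}

# Merge overlapping/adjacent 0-based half-open intervals via IRanges::reduce.
merge_regions <- function(regions) {
  if (nrow(regions) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0)))
  }
  regions %>%
    group_by(.data$chrom) %>%
    group_modify(function(d, g) {
      ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
      tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$start)
}

#' Read a phenotype table
#'
#' Delimited text (comma for `.csv`, otherwise tab) with one row per subject.
#' Required columns: `subject_id`, `study` (ABCFS/ASPREE), `sex` (F/M),
#' `case_status` (case/control). Optional: `er_status`, `age`, `height`,
#' `bmi`, `parity`, `education`, `alcohol`, `prior_breast_cancer`,
#' `family_history`. Unknown columns are ignored; missing covariate values
#' are preserved as `NA` and never imputed.
#'
#' @param path Path to a CSV/TSV phenotype file.
#' @return A tibble of subjects.
#' @export
read_phenotypes <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           na = c("", "NA"),
                           col_types = readr::cols(.default = readr::col_character()))
  required <- c("subject_id", "study", "sex", "case_status")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Phenotype file '", path, "' is missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  check_codes <- function(x, allowed, what) {
    bad <- which(!is.na(x) & !x %in% allowed)
    if (length(bad)) {
      abort(paste0("Phenotype file '", path, "': unknown ", what,
                   " codes at rows ", paste(head(bad, 10), collapse = ", "),
                   " (values: ",
                   paste(unique(x[bad]), collapse = ", "), ")"))
    }
  }
  check_codes(raw$study, c("ABCFS", "ASPREE"), "study")
  check_codes(raw$sex, c("F", "M"), "sex")
  check_codes(raw$case_status, c("case", "control"), "case_status")
  if (any(is.na(raw$study) | is.na(raw$sex) | is.na(raw$case_status))) {
    abort(paste0("Phenotype file '", path,
                 "': study, sex and case_status may not be missing"))
  }
  opt_num <- function(nm) {
    if (nm %in% names(raw)) as.numeric(raw[[nm]]) else rep(NA_real_, nrow(raw))
  }
  opt_lgl <- function(nm) {
    if (!nm %in% names(raw)) return(rep(NA, nrow(raw)))
    x <- raw[[nm]]
    if (is.logical(x)) return(x)
    x <- toupper(as.character(x))
    out <- rep(NA, length(x))
    out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
    out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
    out
  }
  er <- if ("er_status" %in% names(raw)) as.character(raw$er_status) else
    rep(NA_character_, nrow(raw))
  check_codes(er, c("positive", "negative", "unknown"), "er_status")
  er[is.na(er)] <- "unknown"
  er[raw$case_status == "control"] <- "unknown"

  subjects <- tibble(
    subject_id = as.character(raw$subject_id),
    study = raw$study,
    sex = raw$sex,
    case_status = raw$case_status,
    er_status = er,
    age = opt_num("age"),
    height = opt_num("height"),
    bmi = opt_num("bmi"),
    parity = opt_num("parity"),
    education = opt_num("education"),
    alcohol = opt_num("alcohol"),
    prior_breast_cancer = opt_lgl("prior_breast_cancer"),
    family_history = opt_lgl("family_history")
  )
  bad_age <- which(!is.na(subjects$age) & subjects$age <= 0)
  if (length(bad_age)) {
    abort(paste0("Phenotype file '", path, "': non-positive ages at rows ",
                 paste(bad_age, collapse = ", ")))
  }
  subjects
}

#' Write a phenotype table
#'
#' Inverse of [read_phenotypes()]; write-then-read round-trips are exact.
#'
#' @param subjects Tibble of subjects as returned by [read_phenotypes()].
#' @param path Output path (`.csv` for comma-delimited, else tab).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(subjects, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(subjects, path, delim = delim, na = "")
  invisible(path)
}

#' Read a ClinVar-style classification table
#'
#' Tab-delimited with columns `key`, `significance`, `n_plp_submissions`,
#' `n_blb_submissions`. Significance must be one of Pathogenic,
#' LikelyPathogenic, Conflicting, Benign, LikelyBenign, VUS, Absent.
#'
#' @param path Path to a TSV file.
#' @return A tibble of classification records.
#' @export
read_classification_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("key", "significance", "n_plp_submissions", "n_blb_submissions")
  if (!all(req %in% names(d))) {
    abort(paste0("Classification table '", path, "' must have columns: ",
                 paste(req, collapse = ", ")))
  }
  allowed <- c("Pathogenic", "LikelyPathogenic", "Conflicting", "Benign",
               "LikelyBenign", "VUS", "Absent")
  bad <- which(!d$significance %in% allowed)
  if (length(bad)) {
    abort(paste0("Classification table '", path,
                 "': unknown significance at rows ",
                 paste(bad, collapse = ", ")))
  }
  bad_absent <- which(d$significance == "Absent" &
                        (d$n_plp_submissions != 0 | d$n_blb_submissions != 0))
  if (length(bad_absent)) {
    abort(paste0("Classification table '", path, "': 'Absent' records must ",
                 "carry zero submission counts (rows ",
                 paste(bad_absent, collapse = ", "), ")"))
  }
  d %>%
    transmute(
      key = as.character(.data$key),
      significance = .data$significance,
      n_plp_submissions = as.integer(.data$n_plp_submissions),
      n_blb_submissions = as.integer(.data$n_blb_submissions)
    )
}

#' Read a reference allele-frequency table
#'
#' Tab-delimited with columns `key` and `maf` (minor allele frequency in the
#' reference population, e.g. non-Finnish European non-TCGA).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `key`, `maf`.
#' @export
read_frequency_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("key", "maf") %in% names(d))) {
    abort(paste0("Frequency table '", path, "' must have columns key, maf"))
  }
  bad <- which(is.na(d$maf) | d$maf < 0 | d$maf > 0.5)
  if (length(bad)) {
    abort(paste0("Frequency table '", path, "': maf outside [0, 0.5] at rows ",
                 paste(bad, collapse = ", ")))
  }
  transmute(d, key = as.character(.data$key), maf = as.numeric(.data$maf))
}

#' Read transcript models from a TSV file
#'
#' One row per gene: `gene`, `accession`, `chrom`, `strand` (+/-),
#' `exon_starts`, `exon_ends` (semicolon-separated 0-based half-open genomic
#' coordinates of the coding exons, ascending), and `cds_sequence` (the
#' spliced coding sequence, 5' to 3' on the coding strand).
#'
#' @param path Path to a transcript TSV.
#' @return A tibble with an `exons` list-column of `(start, end)` tibbles in
#'   ascending genomic order.
#' @export
read_transcripts <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  req <- c("gene", "accession", "chrom", "strand", "exon_starts", "exon_ends",
           "cds_sequence")
  if (!all(req %in% names(d))) {
    abort(paste0("Transcript table '", path, "' must have columns: ",
                 paste(req, collapse = ", ")))
  }
  parse_ints <- function(x) as.integer(str_split(x, stringr::fixed(";"))[[1]])
  tx <- d %>%
    mutate(
      exons = map2(.data$exon_starts, .data$exon_ends, function(s, e) {
        tibble(start = parse_ints(s), end = parse_ints(e)) %>%
          arrange(.data$start)
      }),
      cds_sequence = toupper(.data$cds_sequence)
    ) %>%
    select("gene", "accession", "chrom", "strand", "exons", "cds_sequence")
  validate_transcripts(tx, path)
  tx
}

validate_transcripts <- function(tx, src = "transcripts") {
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    g <- tx$gene[i]
    if (!tx$strand[i] %in% c("+", "-")) {
      abort(paste0(src, ": gene ", g, " has invalid strand '", tx$strand[i], "'"))
    }
    if (any(ex$end <= ex$start)) {
      abort(paste0(src, ": gene ", g, " has an exon with end <= start"))
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      abort(paste0(src, ": gene ", g, " has overlapping coding exons"))
    }
    len <- sum(ex$end - ex$start)
    if (len != nchar(tx$cds_sequence[i])) {
      abort(paste0(src, ": gene ", g, " CDS length ", nchar(tx$cds_sequence[i]),
                   " does not match summed exon length ", len))
    }
    if (len %% 3L != 0L) {
      abort(paste0(src, ": gene ", g, " CDS length not a multiple of 3"))
    }
  }
  invisible(tx)
}

#' Write transcript models to a TSV file
#'
#' @param transcripts Tibble as returned by [read_transcripts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  d <- transcripts %>%
    mutate(
      exon_starts = map_chr(.data$exons, ~ paste(.x$start, collapse = ";")),
      exon_ends = map_chr(.data$exons, ~ paste(.x$end, collapse = ";"))
    ) %>%
    select("gene", "accession", "chrom", "strand", "exon_starts", "exon_ends",
           "cds_sequence")
  readr::write_tsv(d, path)
  invisible(path)
}

#' Import transcript models from GFF3 + FASTA (convenience)
#'
#' Reads CDS features from a GFF3 file (grouped by their `Parent` attribute)
#' and splices the coding sequence out of the accompanying genome FASTA,
#' reverse-complementing minus-strand transcripts.
#'
#' @param gff_path Path to a GFF3 file with CDS features.
#' @param fasta_path Path to the genome FASTA.
#' @param gene_map Optional named character vector mapping transcript ids to
#'   gene symbols; defaults to the GFF `gene` attribute when present, else
#'   the transcript id.
#' @return A transcript tibble as from [read_transcripts()].
#' @export
read_transcripts_gff3 <- function(gff_path, fasta_path, gene_map = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_transcripts_gff3() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(gr) == 0) abort(paste0("No CDS features in '", gff_path, "'"))
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*", "", names(genome))
  parent <- vapply(gr$Parent, function(p) as.character(p)[1], character(1))
  parts <- split(seq_along(gr), parent)
  rows <- map(names(parts), function(txid) {
    idx <- parts[[txid]]
    sub <- gr[idx]
    o <- order(BiocGenerics::start(sub))
    sub <- sub[o]
    chrom <- as.character(GenomicRanges::seqnames(sub))[1]
    strand <- as.character(BiocGenerics::strand(sub))[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    starts <- BiocGenerics::start(sub) - 1L  # to 0-based half-open
    ends <- BiocGenerics::end(sub)
    seqs <- map_chr(seq_along(sub), function(j) {
      as.character(Biostrings::subseq(genome[[chrom]], starts[j] + 1L, ends[j]))
    })
    cds <- paste(seqs, collapse = "")
    if (strand == "-") {
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    }
    gene <- if (!is.null(gene_map) && txid %in% names(gene_map)) {
      gene_map[[txid]]
    } else if (!is.null(sub$gene) && !is.na(sub$gene[1])) {
      as.character(sub$gene[1])
    } else txid
    tibble(gene = gene, accession = txid, chrom = chrom, strand = strand,
           exons = list(tibble(start = starts, end = ends)),
           cds_sequence = cds)
  })
  tx <- bind_rows(rows)
  validate_transcripts(tx, gff_path)
  tx
}

#' Write an association result table
#'
#' Mirrors the printed layout of a per-gene association table: gene, carrier
#' counts and percentages in cases and controls, odds ratio with Wald CI and
#' likelihood-ratio p-value. Non-estimable cells are rendered as an en dash.
#'
#' @param results A tibble of per-gene results (e.g. from
#'   [run_panel_association()]) with columns `gene`, `n_case_carriers`,
#'   `case_pct`, `n_control_carriers`, `control_pct`, `or`, `ci_low`,
#'   `ci_high`, `p`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(results, path) {
  fmt <- function(x) ifelse(is.na(x), "–", format(x, digits = 15,
                                                       trim = TRUE,
                                                       scientific = FALSE))
  cols <- c("gene", "n_case_carriers", "case_pct", "n_control_carriers",
            "control_pct", "or", "ci_low", "ci_high", "p")
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols)) {
    abort(paste0("Association results are missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- results %>%
    transmute(
      gene = .data$gene,
      n_case_carriers = .data$n_case_carriers,
      case_pct = .data$case_pct,
      n_control_carriers = .data$n_control_carriers,
      control_pct = .data$control_pct,
      or = fmt(.data$or),
      ci_low = fmt(.data$ci_low),
      ci_high = fmt(.data$ci_high),
      p = fmt(.data$p)
    )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read an association result table written by [write_association_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble with numeric columns; en-dash cells become `NA`.
#' @export
read_association_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "–", NA, x)))
  tibble(
    gene = d$gene,
    n_case_carriers = as.integer(d$n_case_carriers),
    case_pct = num(d$case_pct),
    n_control_carriers = as.integer(d$n_control_carriers),
    control_pct = num(d$control_pct),
    or = num(d$or),
    ci_low = num(d$ci_low),
    ci_high = num(d$ci_high),
    p = num(d$p)
  )
}
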