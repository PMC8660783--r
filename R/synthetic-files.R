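#' Toy transcript models for the panel genes
#'
#' Each gene gets a compact three-coding-exon transcript (~300 bp CDS) on
#' its own contig, alternating strand, with a valid open reading frame (ATG
#' start, no internal stops, TAA stop). Deterministic for a given seed and
#' independent of the caller's RNG state.
#'
#' @param genes Gene symbols (default the full panel).
#' @param exon_lengths Coding-exon lengths in bp (sum divisible by 3).
#' @param seed Seed for the sequence draw (default fixed).
#' @return A transcript tibble as from [read_transcripts()].
#' @export
toy_transcripts <- function(genes = panel_genes(),
                            exon_lengths = c(99L, 102L, 99L),
                            seed = 20200701) {
  stopifnot(sum(exon_lengths) %% 3 == 0)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  with_preserved_seed(seed, {
    rows <- map(seq_along(genes), function(i) {
      n_codon <- sum(exon_lengths) / 3L
      body <- sample(sense, n_codon - 2L, replace = TRUE)
      cds <- paste(c("ATG", body, "TAA"), collapse = "")
      starts <- integer(length(exon_lengths))
      s <- 1000L
      for (j in seq_along(exon_lengths)) {
        starts[j] <- s
        s <- s + exon_lengths[j] + 150L
      }
      tibble(
        gene = genes[i],
        accession = unname(PANEL_TRANSCRIPTS[genes[i]]) %||%
          paste0("TX_", genes[i]),
        chrom = paste0("chr", i),
        strand = if (i %% 2 == 1) "+" else "-",
        exons = list(tibble(start = starts, end = starts + exon_lengths)),
        cds_sequence = cds
      )
    })
    tx <- bind_rows(rows)
    tx$accession[is.na(tx$accession)] <- paste0("TX_", tx$gene[is.na(tx$accession)])
    validate_transcripts(tx, "toy_transcripts")
    tx
  })
}

# Genomic-strand base at 0-based position g0 of a transcript's coding exon.
genomic_base <- function(tx, g0) {
  co <- cds_coordinate(g0, tx)
  if (is.null(co)) abort("position not in a coding exon")
  b <- substr(tx$cds_sequence, co$cds_pos, co$cds_pos)
  if (tx$strand == "-") comp_base(b) else b
}

# Deterministic per-gene variant factories (0-based positions; VCF records
# are emitted 1-based).
variant_slot <- function(tx, slot, type = c("frameshift", "missense")) {
  type <- match.arg(type)
  ex <- tx$exons[[1]]
  if (type == "frameshift") {
    # 1 bp deletion inside the first two coding exons in *transcription*
    # order (so never the last coding exon), anchored on the previous exon
    # base; low end of the interior is reserved for the unique-variant pool
    keep <- if (tx$strand == "+") c(1L, 2L) else c(2L, 3L)
    pool <- c(seq(ex$start[keep[1]] + 1L, ex$end[keep[1]] - 6L),
              seq(ex$start[keep[2]] + 1L, ex$end[keep[2]] - 6L))
    g0 <- pool[(slot - 1L) %% length(pool) + 1L]
    anchor <- g0 - 1L
    tibble(
      chrom = tx$chrom, pos = anchor + 1L,
      ref = paste0(genomic_base(tx, anchor), genomic_base(tx, g0)),
      alt = genomic_base(tx, anchor)
    )
  } else {
    pool <- seq(ex$start[1] + 3L, ex$end[1] - 6L)
    g0 <- pool[(slot - 1L) %% length(pool) + 1L]
    ref <- genomic_base(tx, g0)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[(slot - 1L) %% 3L + 1L]
    tibble(chrom = tx$chrom, pos = g0 + 1L, ref = ref, alt = alt)
  }
}

# Reserved single-purpose variants at the high end of exon interiors, clear
# of the unique-variant pools.
reserved_variant <- function(tx, which) {
  ex <- tx$exons[[1]]
  switch(
    which,
    last_exon_ptv = {
      last_ex <- if (tx$strand == "+") 3L else 1L
      g0 <- ex$start[last_ex] + 10L
      tibble(chrom = tx$chrom, pos = g0,
             ref = paste0(genomic_base(tx, g0 - 1L), genomic_base(tx, g0)),
             alt = genomic_base(tx, g0 - 1L))
    },
    benign_ptv = {
      g0 <- ex$end[2] - 3L
      tibble(chrom = tx$chrom, pos = g0,
             ref = paste0(genomic_base(tx, g0 - 1L), genomic_base(tx, g0)),
             alt = genomic_base(tx, g0 - 1L))
    },
    conflicting_ptv = {
      g0 <- ex$end[2] - 5L
      tibble(chrom = tx$chrom, pos = g0,
             ref = paste0(genomic_base(tx, g0 - 1L), genomic_base(tx, g0)),
             alt = genomic_base(tx, g0 - 1L))
    },
    common_maf = {
      g0 <- ex$end[1] - 3L
      ref <- genomic_base(tx, g0)
      tibble(chrom = tx$chrom, pos = g0 + 1L, ref = ref,
             alt = setdiff(c("A", "C", "G", "T"), ref)[1])
    },
    common_artefact = {
      g0 <- ex$end[1] - 4L
      ref <- genomic_base(tx, g0)
      tibble(chrom = tx$chrom, pos = g0 + 1L, ref = ref,
             alt = setdiff(c("A", "C", "G", "T"), ref)[1])
    },
    low_call_rate = {
      g0 <- ex$end[1] - 5L
      ref <- genomic_base(tx, g0)
      tibble(chrom = tx$chrom, pos = g0 + 1L, ref = ref,
             alt = setdiff(c("A", "C", "G", "T"), ref)[1])
    },
    vardict_only = {
      g0 <- ex$end[1] - 2L
      ref <- genomic_base(tx, g0)
      tibble(chrom = tx$chrom, pos = g0 + 1L, ref = ref,
             alt = setdiff(c("A", "C", "G", "T"), ref)[1])
    },
    region_trap = {
      g0 <- ex$start[1] - 45L  # inside the Hi-Plex-only padding
      tibble(chrom = tx$chrom, pos = g0 + 1L, ref = "A", alt = "G")
    },
    abort(paste0("unknown reserved variant: ", which))
  )
}

panel_beds <- function(transcripts) {
  pad_regions <- function(pad) {
    transcripts %>%
      mutate(reg = map2(.data$exons, .data$chrom, function(ex, ch) {
        tibble(chrom = ch, start = pmax(0L, ex$start - pad),
               end = ex$end + pad)
      })) %>%
      pull(.data$reg) %>%
      bind_rows()
  }
  g1 <- transcripts[1, ]
  ex1 <- g1$exons[[1]]
  list(
    HiPlex = bind_rows(
      pad_regions(12L),
      tibble(chrom = g1$chrom, start = ex1$start[1] - 60L,
             end = ex1$start[1] - 30L)),
    HaloPlexHS = pad_regions(10L),
    AmpliSeq = bind_rows(
      pad_regions(8L),
      tibble(chrom = g1$chrom, start = ex1$end[3] + 20L,
             end = ex1$end[3] + 50L))
  )
}

write_vcf_text <- function(records, subject_id, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=panelor_synthetic_generator",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Panel gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Variant allele fraction\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", subject_id, sep = "\t")
  )
  body <- character(0)
  if (nrow(records)) {
    records <- arrange(records, .data$chrom, .data$pos)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tGENE=%s\tGT:DP:AF\t0/1:%d:%s",
                    records$chrom, records$pos, records$ref, records$alt,
                    records$gene, as.integer(records$depth),
                    sprintf("%.4f", records$vaf))
  }
  writeLines(c(header, body), path)
}

#' Emit a complete synthetic study input bundle
#'
#' Writes everything the pipeline consumes: per-subject VCFs (primary
#' caller; plus a second-caller call set for the elderly cohort), the three
#' panel BED files (whose intersection is a strict subset of each), toy
#' transcript models for all panel genes, a ClinVar-style classification
#' table, a reference frequency table, per-locus QC pass rates, the
#' phenotype table, and - for test harnesses only - the ground-truth carrier
#' table and the planted-artefact manifest.
#'
#' Subjects without any variant call get no VCF file; the phenotype table
#' defines the cohort.
#'
#' @param pop A `synthetic_population` from [generate_population()].
#' @param outdir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, a list of paths plus the `artefacts` tibble (artefact,
#'   subject, key and the pipeline rule designated to remove it).
#' @export
emit_study_files <- function(pop, outdir, overwrite = FALSE) {
  stopifnot(inherits(pop, "synthetic_population"))
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !overwrite) {
    abort(paste0("Output directory ", outdir,
                 " exists and is not empty; use overwrite = TRUE"))
  }
  dir.create(file.path(outdir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "vcf_tvc"), recursive = TRUE,
             showWarnings = FALSE)
  set.seed(pop$seed + 1L)

  transcripts <- toy_transcripts()
  tx_of <- function(g) transcripts[transcripts$gene == g, ]
  subjects <- pop$subjects
  genes <- pop$truth$gene
  spikes <- pop$config$spikes
  spike_ids <- function(kind) {
    pop$spike_assignments$subject_id[pop$spike_assignments$spike == kind]
  }

  key_of <- function(v) variant_key(v$chrom, v$pos, v$ref, v$alt)
  calls <- list()
  class_rows <- list()
  freq_rows <- list()
  artefacts <- list()
  slot_counter <- setNames(rep(0L, length(unique(c(genes, "MUTYH")))),
                           unique(c(genes, "MUTYH")))

  add_call <- function(subject_id, gene, v, depth = NULL, vaf = NULL) {
    if (is.null(depth)) depth <- 60L + rpois(1, 80)
    if (is.null(vaf)) vaf <- round(runif(1, 0.4, 0.6), 4)
    calls[[length(calls) + 1]] <<- mutate(
      v, subject_id = subject_id, gene = gene, depth = depth, vaf = vaf)
  }
  add_artefact <- function(kind, subject_id, v, rule) {
    artefacts[[length(artefacts) + 1]] <<- tibble(
      artefact = kind, subject_id = subject_id, key = key_of(v),
      designated_rule = rule)
  }
  next_slot <- function(gene) {
    slot_counter[gene] <<- slot_counter[gene] + 1L
    slot_counter[[gene]]
  }

  # --- true carriers: one private pathogenic variant each ------------------
  carr_long <- pop$carriers %>%
    pivot_longer(-"subject_id", names_to = "gene", values_to = "carrier") %>%
    filter(.data$carrier)
  conflicting_done <- FALSE
  for (i in seq_len(nrow(carr_long))) {
    sid <- carr_long$subject_id[i]
    g <- carr_long$gene[i]
    tx <- tx_of(g)
    slot <- next_slot(g)
    study <- subjects$study[match(sid, subjects$subject_id)]
    if (!conflicting_done && spikes$conflicting_ptv > 0 && study == "ABCFS") {
      # one true carrier's allele is a Conflicting-majority-pathogenic PTV
      v <- reserved_variant(tx, "conflicting_ptv")
      class_rows[[length(class_rows) + 1]] <- tibble(
        key = key_of(v), significance = "Conflicting",
        n_plp_submissions = 3L, n_blb_submissions = 1L)
      add_call(sid, g, v)
      conflicting_done <- TRUE
    } else if (slot %% 5L == 0L) {
      # ClinVar-asserted pathogenic missense
      v <- variant_slot(tx, slot, "missense")
      class_rows[[length(class_rows) + 1]] <- tibble(
        key = key_of(v), significance = "Pathogenic",
        n_plp_submissions = 2L, n_blb_submissions = 0L)
      add_call(sid, g, v)
    } else {
      # private truncating variant, absent from ClinVar
      add_call(sid, g, variant_slot(tx, slot, "frameshift"))
    }
  }

  # --- planted artefacts ---------------------------------------------------
  abcfs_hiplex <- subjects$subject_id[subjects$study == "ABCFS" &
                                        subjects$platform == "HiPlex" &
                                        subjects$has_panel_data]
  aspree_ids <- subjects$subject_id[subjects$study == "ASPREE" &
                                      subjects$sex == "F" &
                                      !subjects$prior_breast_cancer]
  non_carrier <- function(ids) {
    gm <- pop$carriers[match(ids, pop$carriers$subject_id), genes,
                       drop = FALSE]
    ids[rowSums(as.matrix(gm)) == 0]
  }
  vardict_skip <- tibble(subject_id = character(0), key = character(0))

  if (spikes$depth_fail > 0 && length(abcfs_hiplex)) {
    sid <- abcfs_hiplex[1]
    g <- genes[1]
    v <- variant_slot(tx_of(g), 9000L, "frameshift")
    add_call(sid, g, v, depth = 49L, vaf = 0.25)
    add_artefact("depth_fail", sid, v, "platform_qc")
  }
  if (spikes$region_trap > 0 && length(abcfs_hiplex) > 1) {
    sid <- abcfs_hiplex[2]
    v <- reserved_variant(transcripts[1, ], "region_trap")
    add_call(sid, transcripts$gene[1], v)
    add_artefact("region_trap", sid, v, "region_restriction")
  }
  if (spikes$vardict_only > 0 && length(aspree_ids)) {
    sid <- non_carrier(aspree_ids)[1]
    g <- genes[min(3, length(genes))]
    v <- reserved_variant(tx_of(g), "vardict_only")
    add_call(sid, g, v)
    vardict_skip <- tibble(subject_id = sid, key = key_of(v))
    add_artefact("vardict_only", sid, v, "caller_intersection")
  }
  if (isTRUE(spikes$common_artefact)) {
    n_asp <- length(aspree_ids)
    m <- floor(pop$config$n_aspree_controls * 0.0005) + 1L
    ids <- utils::tail(non_carrier(aspree_ids), m)
    g <- genes[min(2, length(genes))]
    v <- reserved_variant(tx_of(g), "common_artefact")
    for (sid in ids) add_call(sid, g, v)
    for (sid in ids) add_artefact("common_artefact", sid, v,
                                  "cohort_frequency")
  }
  low_call_key <- NULL
  if (isTRUE(spikes$low_call_rate)) {
    m <- max(1L, floor(pop$config$n_aspree_controls * 0.0005))
    ids <- head(non_carrier(aspree_ids), m + 2L)[seq_len(m)]
    g <- genes[1]
    v <- reserved_variant(tx_of(g), "low_call_rate")
    low_call_key <- key_of(v)
    for (sid in ids) {
      add_call(sid, g, v)
      add_artefact("low_call_rate", sid, v, "locus_call_rate")
    }
  }
  if (spikes$last_exon_ptv > 0) {
    sid <- non_carrier(subjects$subject_id[subjects$case_status == "case"])[1]
    g <- genes[1]
    v <- reserved_variant(tx_of(g), "last_exon_ptv")
    add_call(sid, g, v)
    add_artefact("last_exon_ptv", sid, v, "classification:last_exon_ptv_excluded")
  }
  if (spikes$benign_ptv > 0) {
    sid <- non_carrier(subjects$subject_id[subjects$case_status == "case"])[2]
    g <- genes[1]
    v <- reserved_variant(tx_of(g), "benign_ptv")
    class_rows[[length(class_rows) + 1]] <- tibble(
      key = key_of(v), significance = "Benign",
      n_plp_submissions = 0L, n_blb_submissions = 2L)
    add_call(sid, g, v)
    add_artefact("benign_ptv", sid, v, "classification:clinvar_benign")
  }
  if (spikes$common_maf_variant > 0) {
    sid <- non_carrier(subjects$subject_id[subjects$case_status == "case"])[3]
    g <- genes[1]
    v <- reserved_variant(tx_of(g), "common_maf")
    freq_rows[[length(freq_rows) + 1]] <- tibble(key = key_of(v), maf = 0.02)
    add_call(sid, g, v)
    add_artefact("common_maf_variant", sid, v, "classification:not_rare")
  }
  for (sid in spike_ids("mutyh_mono")) {
    tx <- tx_of("MUTYH")
    if (nrow(tx) == 0) tx <- transcripts[transcripts$gene == "MUTYH", ]
    v <- variant_slot(tx, next_slot("MUTYH"), "frameshift")
    add_call(sid, "MUTYH", v)
    add_artefact("mutyh_mono", sid, v, "carriers:mutyh_monoallelic")
  }

  # --- write the bundle ----------------------------------------------------
  calls <- bind_rows(calls) %>%
    mutate(key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
  # recurrent allele support exists via gene_params$recurrent_share = 0
  # defaults; private variants make every true key unique

  for (sid in unique(calls$subject_id)) {
    recs <- filter(calls, .data$subject_id == sid)
    write_vcf_text(recs, sid, file.path(outdir, "vcf", paste0(sid, ".vcf")))
    if (subjects$study[match(sid, subjects$subject_id)] == "ASPREE") {
      sec <- anti_join(recs, vardict_skip, by = c("subject_id", "key"))
      write_vcf_text(sec, sid,
                     file.path(outdir, "vcf_tvc", paste0(sid, ".vcf")))
    }
  }

  beds <- panel_beds(transcripts)
  for (nm in names(beds)) {
    readr::write_tsv(beds[[nm]],
                     file.path(outdir, paste0(tolower(nm), ".bed")),
                     col_names = FALSE)
  }
  write_transcripts(transcripts, file.path(outdir, "transcripts.tsv"))

  class_tbl <- if (length(class_rows)) {
    distinct(bind_rows(class_rows), .data$key, .keep_all = TRUE)
  } else {
    tibble(key = character(0), significance = character(0),
           n_plp_submissions = integer(0), n_blb_submissions = integer(0))
  }
  readr::write_tsv(class_tbl, file.path(outdir, "classification.tsv"))

  freq_tbl <- bind_rows(
    if (length(freq_rows)) bind_rows(freq_rows),
    # a couple of observed-but-rare decoy entries
    tibble(key = head(unique(calls$key), 2), maf = 1e-4)
  ) %>% distinct(.data$key, .keep_all = TRUE)
  readr::write_tsv(freq_tbl, file.path(outdir, "frequency.tsv"))

  locus_stats <- calls %>%
    distinct(.data$key) %>%
    mutate(pass_fraction = if (is.null(low_call_key)) 0.99 else
      ifelse(.data$key == low_call_key, 0.94, 0.99))
  readr::write_tsv(locus_stats, file.path(outdir, "locus_stats.tsv"))

  write_phenotypes(
    select(subjects, "subject_id", "study", "sex", "case_status", "er_status",
           "age", "height", "bmi", "parity", "education", "alcohol",
           "prior_breast_cancer", "family_history"),
    file.path(outdir, "phenotypes.csv"))
  readr::write_tsv(select(subjects, "subject_id", "platform",
                          "has_panel_data"),
                   file.path(outdir, "platforms.tsv"))

  truth_long <- pop$carriers %>%
    pivot_longer(-"subject_id", names_to = "gene", values_to = "carrier") %>%
    filter(.data$carrier) %>%
    left_join(pop$truth[, c("gene", "beta")], by = "gene")
  readr::write_tsv(truth_long, file.path(outdir, "ground_truth.tsv"))

  artefacts <- if (length(artefacts)) bind_rows(artefacts) else
    tibble(artefact = character(0), subject_id = character(0),
           key = character(0), designated_rule = character(0))
  readr::write_tsv(artefacts, file.path(outdir, "artefacts.tsv"))

  invisible(list(
    outdir = outdir,
    vcf_dir = file.path(outdir, "vcf"),
    vcf_secondary_dir = file.path(outdir, "vcf_tvc"),
    panels = setNames(file.path(outdir, paste0(tolower(names(beds)), ".bed")),
                      names(beds)),
    transcripts = file.path(outdir, "transcripts.tsv"),
    classification = file.path(outdir, "classification.tsv"),
    frequency = file.path(outdir, "frequency.tsv"),
    locus_stats = file.path(outdir, "locus_stats.tsv"),
    phenotypes = file.path(outdir, "phenotypes.csv"),
    platforms = file.path(outdir, "platforms.tsv"),
    ground_truth = file.path(outdir, "ground_truth.tsv"),
    artefacts_file = file.path(outdir, "artefacts.tsv"),
    artefacts = artefacts
  ))
}
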