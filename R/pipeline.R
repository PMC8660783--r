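#' Pipeline run configuration
#'
#' Validated container for a full pipeline run. Either `simulate` is given
#' (a [synthetic_config()]; the input bundle is generated under
#' `outdir/input`) or `inputs` must point at an existing bundle.
#'
#' @param outdir Output directory for all stage outputs and the manifest.
#' @param seed Integer seed (required when simulating).
#' @param simulate Optional [synthetic_config()].
#' @param inputs Optional named list of paths: `vcf_dir`,
#'   `vcf_secondary_dir` (optional), `phenotypes`, `platforms`, `panels`
#'   (named character vector of BED paths), `transcripts`, `classification`,
#'   `frequency`, `locus_stats` (optional).
#' @param qc A [qc_policy()].
#' @param scope Studies the cohort-level filters apply to.
#' @param maf_max Rarity threshold for classification.
#' @param adjust Adjustment set for the association stage.
#' @param genes Genes to analyse (default: the simulated risk genes when
#'   simulating, else the full panel).
#' @param overwrite Allow reuse of a non-empty `outdir`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(outdir, seed = 1L, simulate = NULL, inputs = NULL,
                       qc = qc_policy(), scope = "ASPREE", maf_max = 0.01,
                       adjust = "full", genes = NULL, overwrite = FALSE) {
  if (is.null(simulate) && is.null(inputs)) {
    abort("run_config(): give either `simulate` or `inputs`")
  }
  if (!is.null(simulate) && !inherits(simulate, "synthetic_config")) {
    abort("`simulate` must be a synthetic_config()")
  }
  if (!is.null(inputs)) {
    allowed <- c("vcf_dir", "vcf_secondary_dir", "phenotypes", "platforms",
                 "panels", "transcripts", "classification", "frequency",
                 "locus_stats")
    unknown <- setdiff(names(inputs), allowed)
    if (length(unknown)) {
      abort(paste0("Unknown input keys: ", paste(unknown, collapse = ", ")))
    }
    required <- c("vcf_dir", "phenotypes", "platforms", "panels",
                  "transcripts", "classification", "frequency")
    missing_keys <- setdiff(required, names(inputs))
    if (length(missing_keys)) {
      abort(paste0("Missing input keys: ",
                   paste(missing_keys, collapse = ", ")))
    }
    paths <- c(unlist(inputs[setdiff(names(inputs), "panels")],
                      use.names = FALSE),
               unlist(inputs$panels, use.names = FALSE))
    gone <- paths[!file.exists(paths)]
    if (length(gone)) {
      abort(paste0("Input paths do not exist: ", paste(gone, collapse = ", ")))
    }
  }
  structure(
    list(outdir = outdir, seed = as.integer(seed), simulate = simulate,
         inputs = inputs, qc = qc, scope = scope, maf_max = maf_max,
         adjust = adjust, genes = genes, overwrite = overwrite),
    class = "run_config"
  )
}

read_call_bundle <- function(inputs) {
  platforms <- readr::read_tsv(inputs$platforms, show_col_types = FALSE)
  vcfs <- list.files(inputs$vcf_dir, pattern = "\\.vcf$", full.names = TRUE)
  calls <- map(vcfs, function(p) {
    sid <- sub("\\.vcf$", "", basename(p))
    plat <- platforms$platform[match(sid, platforms$subject_id)]
    if (is.na(plat)) {
      abort(paste0("No platform recorded for subject ", sid))
    }
    read_vcf(p, platform = plat, subject_id = sid)
  }) %>% bind_rows()
  if (nrow(calls) == 0) calls <- empty_calls()

  secondary <- NULL
  if (!is.null(inputs$vcf_secondary_dir) &&
      dir.exists(inputs$vcf_secondary_dir)) {
    svcfs <- list.files(inputs$vcf_secondary_dir, pattern = "\\.vcf$",
                        full.names = TRUE)
    if (length(svcfs)) {
      secondary <- map(svcfs, function(p) {
        sid <- sub("\\.vcf$", "", basename(p))
        read_vcf(p, platform = "AmpliSeq", subject_id = sid)
      }) %>%
        bind_rows() %>%
        select("subject_id", "key")
      attr(secondary, "subjects") <- sub("\\.vcf$", "", basename(svcfs))
    }
  }
  list(calls = calls, secondary = secondary, platforms = platforms)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order - (optional) simulate, QC
#' harmonisation, variant classification, carrier-matrix construction,
#' association - writing each stage's table under `outdir` together with a
#' JSON run manifest (package version, seed, config hash, per-stage
#' attrition and counts). Reruns with the same configuration and seed
#' produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage objects
#'   (`harmonised`, `classifications`, `carrier_matrix`, `summary`,
#'   `association`) and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !config$overwrite) {
    abort(paste0("Output directory ", outdir,
                 " exists and is not empty; use overwrite = TRUE"))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name) inform(paste0("[panelor] stage: ", name))

  inputs <- config$inputs
  genes <- config$genes
  if (!is.null(config$simulate)) {
    stage("simulate")
    pop <- generate_population(config$simulate, config$seed)
    bundle <- emit_study_files(pop, file.path(outdir, "input"),
                               overwrite = config$overwrite)
    inputs <- list(
      vcf_dir = bundle$vcf_dir, vcf_secondary_dir = bundle$vcf_secondary_dir,
      phenotypes = bundle$phenotypes, platforms = bundle$platforms,
      panels = bundle$panels, transcripts = bundle$transcripts,
      classification = bundle$classification, frequency = bundle$frequency,
      locus_stats = bundle$locus_stats
    )
    if (is.null(genes)) genes <- config$simulate$gene_params$gene
  }
  if (is.null(genes)) genes <- panel_genes()

  stage("qc")
  subjects <- read_phenotypes(inputs$phenotypes)
  bundle_calls <- read_call_bundle(inputs)
  panels <- map(names(inputs$panels),
                function(nm) read_panel_bed(inputs$panels[[nm]], nm))
  locus_pass <- if (!is.null(inputs$locus_stats)) {
    readr::read_tsv(inputs$locus_stats, show_col_types = FALSE)
  } else NULL
  harmonised <- harmonise_callsets(
    bundle_calls$calls, subjects, policy = config$qc, panels = panels,
    secondary = bundle_calls$secondary, locus_pass = locus_pass,
    scope = config$scope)
  readr::write_tsv(harmonised$attrition, file.path(outdir, "attrition.tsv"))
  readr::write_tsv(select(harmonised$calls, -"qc_pass"),
                   file.path(outdir, "harmonised_calls.tsv"))

  stage("classify")
  transcripts <- read_transcripts(inputs$transcripts)
  classification_tbl <- read_classification_table(inputs$classification)
  frequency_tbl <- read_frequency_table(inputs$frequency)
  classifications <- classify_variants(harmonised, transcripts,
                                       classification_tbl, frequency_tbl,
                                       maf_max = config$maf_max)
  readr::write_tsv(classifications,
                   file.path(outdir, "variant_classification.tsv"))

  stage("carriers")
  tested <- unique(c(bundle_calls$platforms$subject_id[
    bundle_calls$platforms$has_panel_data %||% TRUE],
    harmonised$calls$subject_id))
  if ("has_panel_data" %in% names(bundle_calls$platforms)) {
    tested <- bundle_calls$platforms$subject_id[
      bundle_calls$platforms$has_panel_data]
  }
  cm <- build_carrier_matrix(subjects, harmonised, classifications,
                             policy = carrier_policy(tested_subjects = tested),
                             genes = genes)
  ledger <- exclusion_ledger(cm) %>%
    mutate(subject_ids = map_chr(.data$subject_ids, paste, collapse = ";"))
  readr::write_tsv(ledger, file.path(outdir, "exclusion_ledger.tsv"))
  cm_out <- as_tibble(cm) %>% select(-".pathogenic")
  readr::write_tsv(cm_out, file.path(outdir, "carrier_matrix.tsv"))
  summ <- summarize_cohort(cm)
  readr::write_tsv(summ$carriers, file.path(outdir, "carrier_summary.tsv"))
  readr::write_tsv(summ$covariates, file.path(outdir, "covariate_summary.tsv"))

  stage("associate")
  assoc <- run_panel_association(cm, genes = genes, adjust = config$adjust)
  write_association_table(assoc, file.path(outdir, "association.tsv"))

  manifest <- list(
    package = "panelor",
    version = as.character(utils::packageVersion("panelor")),
    seed = config$seed,
    adjust = config$adjust,
    scope = config$scope,
    config_hash = config_hash(config),
    stages = list(
      qc = as.list(setNames(harmonised$attrition$n_out,
                            harmonised$attrition$step)),
      classify = list(n_variants = nrow(classifications),
                      n_pathogenic = sum(classifications$verdict ==
                                           "pathogenic")),
      carriers = list(n_analysis = nrow(cm),
                      n_multi_gene = sum(cm$.multi_gene)),
      associate = list(n_genes = nrow(assoc),
                       n_estimable = sum(assoc$estimable))
    )
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    harmonised = harmonised, classifications = classifications,
    carrier_matrix = cm, summary = summ, association = assoc,
    outdir = outdir, inputs = inputs
  ))
}

# Stable hash of the run configuration (seed excluded stages included), via
# the md5 of its canonical JSON serialisation.
config_hash <- function(config) {
  drop <- c("overwrite", "outdir")
  x <- config[setdiff(names(config), drop)]
  x$simulate <- if (!is.null(x$simulate)) unclass(x$simulate)
  x$qc <- unclass(x$qc)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}
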