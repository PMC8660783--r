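#' Quality-control policy for harmonising platform call sets
#'
#' Per-platform read-depth and variant-allele-fraction thresholds (all
#' inclusive, `>=`), the cohort-level frequency cut-off above which a variant
#' is treated as a sequencing artefact or too common to drive risk, and the
#' minimum per-locus QC pass rate.
#'
#' Defaults follow the study design this package emulates: 50X / 0.2 for
#' Hi-Plex and AmpliSeq, 30X / 0.15 for HaloPlexHS; variants present in more
#' than 0.05% of cohort participants removed; loci where fewer than 95% of
#' genotype calls pass QC removed.
#'
#' @param thresholds Tibble with columns `platform`, `min_depth`, `min_vaf`.
#' @param cohort_freq_max Maximum fraction of participants that may carry a
#'   variant (strictly-greater-than removal).
#' @param min_locus_call_rate Minimum fraction of QC-passing genotype calls
#'   at a locus (inclusive).
#' @return A `qc_policy` list.
#' @export
qc_policy <- function(thresholds = tibble(
                        platform = c("HiPlex", "HaloPlexHS", "AmpliSeq"),
                        min_depth = c(50, 30, 50),
                        min_vaf = c(0.2, 0.15, 0.2)),
                      cohort_freq_max = 0.0005,
                      min_locus_call_rate = 0.95) {
  stopifnot(all(c("platform", "min_depth", "min_vaf") %in% names(thresholds)))
  if (any(thresholds$min_depth <= 0) || any(thresholds$min_vaf <= 0)) {
    abort("QC thresholds must be positive")
  }
  if (cohort_freq_max <= 0 || cohort_freq_max > 1 ||
      min_locus_call_rate <= 0 || min_locus_call_rate > 1) {
    abort("cohort_freq_max and min_locus_call_rate must lie in (0, 1]")
  }
  structure(
    list(thresholds = thresholds, cohort_freq_max = cohort_freq_max,
         min_locus_call_rate = min_locus_call_rate),
    class = "qc_policy"
  )
}

#' Flag calls by per-platform depth and allele-fraction thresholds
#'
#' Sets `qc_pass = depth >= min_depth AND vaf >= min_vaf` for each call's
#' platform (thresholds inclusive). No calls are removed, only flagged.
#'
#' @param calls A tibble of variant calls with `platform`, `depth`, `vaf`.
#' @param policy A [qc_policy()].
#' @return `calls` with `qc_pass` set.
#' @export
apply_platform_qc <- function(calls, policy = qc_policy()) {
  if (nrow(calls) == 0) return(mutate(calls, qc_pass = logical(0)))
  missing_platform <- setdiff(unique(calls$platform),
                              policy$thresholds$platform)
  if (length(missing_platform)) {
    abort(paste0("No QC thresholds for platform(s): ",
                 paste(missing_platform, collapse = ", ")))
  }
  calls %>%
    left_join(policy$thresholds, by = "platform") %>%
    mutate(qc_pass = .data$depth >= .data$min_depth &
             .data$vaf >= .data$min_vaf) %>%
    select(-"min_depth", -"min_vaf")
}

#' Intersect the target regions of several panels
#'
#' Returns the genomic regions targeted by every panel, i.e. the regions
#' that are equally callable across platforms.
#'
#' @param panels A list of `panel_design` objects (see [read_panel_bed()]).
#' @return A `panel_design` holding the set intersection.
#' @export
intersect_panels <- function(panels) {
  if (inherits(panels, "panel_design")) panels <- list(panels)
  if (length(panels) == 0) abort("intersect_panels() needs at least one panel")
  to_irl <- function(p) {
    split(IRanges::IRanges(start = p$start + 1L, end = p$end), p$chrom)
  }
  acc <- to_irl(merge_regions(panels[[1]]))
  for (p in panels[-1]) {
    cur <- to_irl(merge_regions(p))
    chroms <- intersect(names(acc), names(cur))
    acc <- setNames(
      lapply(chroms, function(ch) IRanges::intersect(acc[[ch]], cur[[ch]])),
      chroms
    )
  }
  rows <- map(names(acc), function(ch) {
    ir <- acc[[ch]]
    if (length(ir) == 0) return(NULL)
    tibble(chrom = ch, start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(0), start = integer(0), end = integer(0))
  }
  new_panel_design(out, "intersection")
}

#' Restrict calls to a set of target regions
#'
#' A call is kept iff its 1-based position, converted to 0-based, lies inside
#' a half-open region interval.
#'
#' @param calls A tibble of variant calls with `chrom`, `pos`.
#' @param regions A `panel_design` or tibble of `chrom`, `start`, `end`.
#' @return The subset of `calls` inside the regions.
#' @export
restrict_to_regions <- function(calls, regions) {
  if (nrow(calls) == 0 || nrow(regions) == 0) return(calls[0, ])
  keep <- logical(nrow(calls))
  for (ch in unique(calls$chrom)) {
    ci <- which(calls$chrom == ch)
    reg <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(reg) == 0) next
    q <- IRanges::IRanges(start = calls$pos[ci], end = calls$pos[ci]) # 1-based
    s <- IRanges::IRanges(start = reg$start + 1L, end = reg$end)
    keep[ci] <- IRanges::overlapsAny(q, s)
  }
  calls[keep, , drop = FALSE]
}

#' Cohort-level frequency filter
#'
#' Variants carried by more than `cohort_freq_max` of all participants are
#' removed, on the assumption that such "common" variants are either
#' sequencing artefacts or too common to be associated with disease risk.
#' Removal is strict ("more than"): a variant at exactly the threshold
#' survives.
#'
#' @param calls A tibble of calls with `subject_id` and `key`.
#' @param n_participants Total number of participants in the cohort the
#'   filter is scoped to (not just those with calls).
#' @param cohort_freq_max Frequency threshold (default 0.0005, i.e. 0.05%).
#' @return Character vector of surviving keys.
#' @export
cohort_frequency_filter <- function(calls, n_participants,
                                    cohort_freq_max = 0.0005) {
  if (n_participants <= 0) abort("n_participants must be positive")
  counts <- calls %>%
    distinct(.data$subject_id, .data$key) %>%
    count(.data$key, name = "n_carriers")
  counts$key[counts$n_carriers / n_participants <= cohort_freq_max]
}

#' Per-locus call-rate filter
#'
#' A locus survives iff the fraction of genotype calls passing QC at that
#' genomic location is at least `min_locus_call_rate` (inclusive boundary).
#'
#' @param pass_fractions Tibble with columns `key` and `pass_fraction`
#'   (in `[0, 1]`), or a named numeric vector.
#' @param min_locus_call_rate Minimum pass fraction (default 0.95).
#' @return Character vector of surviving keys.
#' @export
locus_call_rate_filter <- function(pass_fractions,
                                   min_locus_call_rate = 0.95) {
  if (!is.data.frame(pass_fractions)) {
    pass_fractions <- tibble(key = names(pass_fractions),
                             pass_fraction = as.numeric(pass_fractions))
  }
  if (any(pass_fractions$pass_fraction < 0 | pass_fractions$pass_fraction > 1,
          na.rm = TRUE)) {
    abort("pass fractions must lie in [0, 1]")
  }
  pass_fractions$key[pass_fractions$pass_fraction >= min_locus_call_rate]
}

#' Harmonise per-study call sets into one analysis-ready call table
#'
#' Applies the fixed pipeline: per-platform QC -> restriction to the panel
#' intersection -> (scoped) second-caller intersection -> (scoped)
#' cohort-frequency filter -> (scoped) per-locus call-rate filter. The
#' cohort-scoped filters apply by default only to the elderly-control cohort
#' (`scope = "ASPREE"`), matching the design in which that cohort's calls
#' form a conservative high-confidence set.
#'
#' @param calls Tibble of variant calls (all subjects, all platforms).
#' @param subjects Phenotype tibble (used to scope filters by study).
#' @param policy A [qc_policy()].
#' @param panels A list of `panel_design`s (intersected internally), a single
#'   `panel_design`/region tibble, or `NULL` to skip region restriction.
#' @param secondary Optional tibble `subject_id`, `key` of calls from a
#'   second variant caller; scoped subjects keep only keys present in both
#'   call sets.
#' @param secondary_subjects Subjects covered by the secondary call set
#'   (default: those appearing in `secondary`).
#' @param locus_pass Optional tibble `key`, `pass_fraction` of per-locus QC
#'   pass rates; when `NULL`, pass rates are computed from the platform-QC
#'   flags of the scoped calls at each locus.
#' @param n_participants Number of participants in the scoped cohort;
#'   defaults to the number of scoped subjects in `subjects`.
#' @param scope Studies the cohort-level filters apply to (default
#'   `"ASPREE"`; use `c("ABCFS", "ASPREE")` to apply them everywhere, or
#'   `character(0)` to disable).
#' @return A `harmonised_calls` list: `calls` (surviving calls), `attrition`
#'   (per-step `step`, `n_in`, `n_out`), `removed` (per-call removal record
#'   with the step responsible).
#' @export
harmonise_callsets <- function(calls, subjects, policy = qc_policy(),
                               panels = NULL, secondary = NULL,
                               secondary_subjects = NULL, locus_pass = NULL,
                               n_participants = NULL, scope = "ASPREE") {
  study_of <- setNames(subjects$study, subjects$subject_id)
  scoped <- function(d) {
    if (nrow(d) == 0) return(logical(0))
    study_of[d$subject_id] %in% scope
  }
  attrition <- list()
  removed <- list()
  note <- function(step, before, after) {
    attrition[[length(attrition) + 1]] <<- tibble(
      step = step, n_in = nrow(before), n_out = nrow(after))
    gone <- anti_join(before, after, by = c("subject_id", "key"))
    if (nrow(gone)) {
      removed[[length(removed) + 1]] <<- tibble(
        step = step, subject_id = gone$subject_id, key = gone$key)
    }
  }

  # 1. platform QC (flag, then drop flagged)
  flagged <- apply_platform_qc(calls, policy)
  cur <- filter(flagged, .data$qc_pass)
  note("platform_qc", calls, cur)

  # 2. restriction to the panel intersection
  if (!is.null(panels)) {
    regions <- if (is.data.frame(panels)) panels else intersect_panels(panels)
    nxt <- restrict_to_regions(cur, regions)
    note("region_restriction", cur, nxt)
    cur <- nxt
  }

  # 3. second-caller intersection for scoped subjects
  if (!is.null(secondary)) {
    if (is.null(secondary_subjects)) {
      secondary_subjects <- unique(secondary$subject_id)
    }
    in_scope <- scoped(cur) & cur$subject_id %in% secondary_subjects
    keep <- !in_scope |
      paste(cur$subject_id, cur$key) %in%
        paste(secondary$subject_id, secondary$key)
    nxt <- cur[keep, , drop = FALSE]
    note("caller_intersection", cur, nxt)
    cur <- nxt
  }

  # 4. cohort-frequency filter (scoped cohort only)
  if (length(scope)) {
    if (is.null(n_participants)) {
      n_participants <- sum(subjects$study %in% scope)
    }
    sc <- cur[scoped(cur), , drop = FALSE]
    keys_ok <- cohort_frequency_filter(sc, n_participants,
                                       policy$cohort_freq_max)
    nxt <- cur[!scoped(cur) | cur$key %in% keys_ok, , drop = FALSE]
    note("cohort_frequency", cur, nxt)
    inform(sprintf(
      "cohort-frequency filter: threshold %.4g over %d participants implies a maximum of %d carriers per variant",
      policy$cohort_freq_max, n_participants,
      floor(policy$cohort_freq_max * n_participants)))
    cur <- nxt

    # 5. per-locus call-rate filter (scoped cohort only)
    if (is.null(locus_pass)) {
      locus_pass <- flagged[scoped(flagged), , drop = FALSE] %>%
        group_by(.data$key) %>%
        summarise(pass_fraction = mean(.data$qc_pass), .groups = "drop")
    }
    loci_ok <- locus_call_rate_filter(locus_pass, policy$min_locus_call_rate)
    known <- cur$key %in% locus_pass$key
    nxt <- cur[!scoped(cur) | !known | cur$key %in% loci_ok, , drop = FALSE]
    note("locus_call_rate", cur, nxt)
    cur <- nxt
  }

  structure(
    list(
      calls = cur,
      attrition = bind_rows(attrition),
      removed = if (length(removed)) bind_rows(removed) else
        tibble(step = character(0), subject_id = character(0),
               key = character(0)),
      scope = scope,
      n_participants = if (length(scope)) n_participants else NA_integer_
    ),
    class = "harmonised_calls"
  )
}

#' @export
print.harmonised_calls <- function(x, ...) {
  cat("Harmonised call set:", nrow(x$calls), "calls surviving\n")
  cat("Cohort-scoped filters applied to:",
      if (length(x$scope)) paste(x$scope, collapse = ", ") else "(none)", "\n")
  print(x$attrition)
  invisible(x)
}
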