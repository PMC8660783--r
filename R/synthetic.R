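#' Configuration for the synthetic case-control study generator
#'
#' Defines the study conditions the generator emulates: a population-based
#' breast cancer case-control study with age-matched controls plus a large
#' arm of healthy elderly women as super-controls. Disease is sampled from a
#' logistic model in carrier status and age, and each arm is ascertained
#' from the corresponding stratum (affected young women; unaffected
#' age-matched women; women unaffected by an elderly baseline age), so
#' carrier depletion among the elderly controls emerges mechanically from
#' the ascertainment, not from an explicit bias knob.
#'
#' @param n_cases,n_abcfs_controls,n_aspree_controls Arm sizes (defaults
#'   1500 / 850 / 6500).
#' @param gene_params Tibble with one row per simulated risk gene: `gene`,
#'   `carrier_freq` (population carrier frequency), `or` (true per-gene
#'   disease odds ratio), `er_neg_odds_mult` (multiplier on the odds that a
#'   carrier's tumour is ER-negative; 1 = subtype-independent),
#'   `recurrent_share` (probability that a carrier's variant is the gene's
#'   recurrent allele rather than a private one).
#' @param baseline_logodds Log-odds of being affected for a 50-year-old
#'   non-carrier (default -3.6).
#' @param age_effect Additive log-odds of disease per year of age (default
#'   0.055).
#' @param er_neg_share Baseline probability that a case is ER-negative.
#' @param er_unknown_share Probability that a case's ER status is unknown.
#' @param ages Per-arm age distributions (`median`, `iqr`, `min`, `max`),
#'   normal on the IQR scale and truncated.
#' @param covariates Per-arm `median` / `iqr` settings for height, BMI,
#'   parity, education and alcohol (drawn independently of disease).
#' @param missing Missingness rates: `parity_aspree` (default 0.043) and
#'   `other` (default 0.005) applied to the remaining optional covariates.
#' @param family_history Baseline odds of a family history and odds
#'   multipliers for BRCA1/2 and other-gene carriers.
#' @param spikes Planted artefacts and special subjects (counts/flags):
#'   extra male and prior-breast-cancer ASPREE enrolees, subjects without
#'   panel data, a cohort-common artefact variant, a depth-failing call, a
#'   call outside the panel intersection, a single-caller-only call, a
#'   low-call-rate locus, a last-coding-exon PTV, a ClinVar-Benign PTV, a
#'   common (MAF 0.02) variant, a Conflicting-majority-pathogenic PTV,
#'   mono-allelic MUTYH carriers and one multi-gene carrier.
#' @param max_batches Rejection-sampling safety limit.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_cases = 1500, n_abcfs_controls = 850, n_aspree_controls = 6500,
    gene_params = tibble(
      gene = c("BRCA1", "BRCA2", "ATM", "CHEK2"),
      carrier_freq = c(0.006, 0.005, 0.006, 0.007),
      or = c(5, 4, 3.5, 1),
      er_neg_odds_mult = 1,
      recurrent_share = 0
    ),
    baseline_logodds = -3.6,
    age_effect = 0.055,
    er_neg_share = 0.25,
    er_unknown_share = 0.05,
    ages = list(
      aspree = list(median = 74, iqr = 5.8, min = 70, max = 95),
      case = list(median = 40, iqr = 14, min = 22, max = 59),
      abcfs_control = list(median = 39.4, iqr = 14.8, min = 22, max = 59)
    ),
    covariates = list(
      aspree = list(height = c(1.59, 0.08), bmi = c(27.4, 6.6),
                    parity = c(3, 2), education = c(11, 3), alcohol = c(1, 8)),
      case = list(height = c(1.63, 0.11), bmi = c(23.5, 5.5),
                  parity = c(2, 2), education = c(11, 2), alcohol = c(2, 7)),
      abcfs_control = list(height = c(1.63, 0.11), bmi = c(23.5, 5.4),
                           parity = c(2, 2), education = c(11, 5),
                           alcohol = c(2, 7))
    ),
    missing = list(parity_aspree = 0.043, other = 0.005),
    family_history = list(base_odds = 0.18, brca_mult = 3, other_mult = 1.5),
    spikes = list(males = 3, prior_bc = 2, no_panel_data = 2,
                  common_artefact = TRUE, depth_fail = 1, region_trap = 1,
                  vardict_only = 1, low_call_rate = TRUE, last_exon_ptv = 1,
                  benign_ptv = 1, common_maf_variant = 1, conflicting_ptv = 1,
                  mutyh_mono = 2, multi_gene = 1),
    max_batches = 500) {
  if (n_cases < 1 || n_abcfs_controls < 1 || n_aspree_controls < 1) {
    abort("All three arms must be non-empty")
  }
  if (any(gene_params$carrier_freq <= 0 | gene_params$carrier_freq >= 1)) {
    abort("carrier frequencies must lie in (0, 1)")
  }
  if (any(gene_params$or <= 0)) abort("true odds ratios must be positive")
  if (!all(c("er_neg_odds_mult", "recurrent_share") %in% names(gene_params))) {
    gene_params$er_neg_odds_mult <- gene_params$er_neg_odds_mult %||% 1
    gene_params$recurrent_share <- gene_params$recurrent_share %||% 0
  }
  structure(
    list(n_cases = n_cases, n_abcfs_controls = n_abcfs_controls,
         n_aspree_controls = n_aspree_controls, gene_params = gene_params,
         baseline_logodds = baseline_logodds, age_effect = age_effect,
         er_neg_share = er_neg_share, er_unknown_share = er_unknown_share,
         ages = ages, covariates = covariates, missing = missing,
         family_history = family_history, spikes = spikes,
         max_batches = max_batches),
    class = "synthetic_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rnorm_trunc <- function(n, median, iqr, min, max) {
  sd <- iqr / (2 * qnorm(0.75))
  out <- rnorm(n, median, sd)
  bad <- which(out < min | out > max)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), median, sd)
    bad <- which(out < min | out > max)
  }
  out
}

#' Generate a synthetic study population with known ground truth
#'
#' Samples carriers per gene at the configured population frequencies,
#' disease from the logistic model in carrier status and age, and then
#' ascertains the three arms by rejection sampling: cases from affected
#' women with the early-onset age profile, matched controls from unaffected
#' women of the same age profile, elderly controls from women still
#' unaffected at their (70+) baseline age.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; fixes every downstream byte.
#' @return A `synthetic_population`: `$subjects` (phenotypes plus `arm`,
#'   `platform`, `has_panel_data`), `$carriers` (wide subject x gene logical
#'   tibble of true carrier states), `$truth` (gene, carrier_freq, or,
#'   beta), `$spike_assignments`, `$config`, `$seed`.
#' @export
generate_population <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  gp <- config$gene_params
  genes <- gp$gene
  betas <- log(gp$or)

  draw_arm <- function(n_target, age_spec, want_affected, id_prefix) {
    ages <- list()
    cars <- list()
    got <- 0L
    batch <- max(4000L, 4L * n_target)
    tries <- 0
    while (got < n_target) {
      tries <- tries + 1
      if (tries > config$max_batches) {
        abort(paste0("Could not ascertain ", n_target, " subjects for arm ",
                     id_prefix, "; the disease model makes this stratum too ",
                     "rare - enlarge the base population or weaken the model"))
      }
      age <- rnorm_trunc(batch, age_spec$median, age_spec$iqr, age_spec$min,
                         age_spec$max)
      carr <- matrix(rbinom(batch * length(genes), 1,
                            rep(gp$carrier_freq, each = batch)) == 1,
                     nrow = batch)
      lp <- config$baseline_logodds + config$age_effect * (age - 50) +
        as.vector(carr %*% betas)
      affected <- runif(batch) < plogis(lp)
      keep <- which(affected == want_affected)
      ages[[tries]] <- age[keep]
      cars[[tries]] <- carr[keep, , drop = FALSE]
      got <- got + length(keep)
      # size the next batch from the observed acceptance rate
      rate <- max(got / (tries * batch), 1 / batch)
      batch <- as.integer(min(5e6, max(4000, 1.4 * (n_target - got) / rate)))
    }
    age <- do.call(c, ages)
    carr <- do.call(rbind, cars)
    idx <- seq_len(n_target)
    list(age = age[idx], carriers = carr[idx, , drop = FALSE])
  }

  cases <- draw_arm(config$n_cases, config$ages$case, TRUE, "case")
  abcfs_ctrl <- draw_arm(config$n_abcfs_controls, config$ages$case, FALSE,
                         "abcfs_control")
  aspree_ctrl <- draw_arm(config$n_aspree_controls, config$ages$aspree, FALSE,
                          "aspree_control")

  build_arm <- function(drawn, arm, study, case_status, prefix, cov_key) {
    n <- length(drawn$age)
    cv <- config$covariates[[cov_key]]
    sdv <- function(x) x[2] / (2 * qnorm(0.75))
    tibble(
      subject_id = sprintf("%s%05d", prefix, seq_len(n)),
      study = study, arm = arm, sex = "F", case_status = case_status,
      age = round(drawn$age, 1),
      height = round(rnorm(n, cv$height[1], sdv(cv$height)), 2),
      bmi = round(rnorm(n, cv$bmi[1], sdv(cv$bmi)), 1),
      parity = rpois(n, cv$parity[1]),
      education = pmax(0, round(rnorm(n, cv$education[1], sdv(cv$education)))),
      alcohol = rpois(n, cv$alcohol[1] + 1) - 1 + rbinom(n, 1, 0.2) * 4,
      prior_breast_cancer = FALSE,
      has_panel_data = TRUE
    ) %>% mutate(alcohol = pmax(0, .data$alcohol))
  }

  subjects <- bind_rows(
    build_arm(cases, "ABCFS cases", "ABCFS", "case", "CA", "case"),
    build_arm(abcfs_ctrl, "ABCFS controls", "ABCFS", "control", "CB",
              "abcfs_control"),
    build_arm(aspree_ctrl, "ASPREE controls", "ASPREE", "control", "AS",
              "aspree")
  )
  carriers <- rbind(cases$carriers, abcfs_ctrl$carriers, aspree_ctrl$carriers)
  colnames(carriers) <- genes
  carriers <- as_tibble(carriers) %>%
    mutate(subject_id = subjects$subject_id, .before = 1)

  spikes <- config$spikes
  spike_rows <- list()
  add_spike <- function(kind, ids) {
    spike_rows[[length(spike_rows) + 1]] <<- tibble(spike = kind,
                                                    subject_id = ids)
  }

  # extra enrolees exercising the subject-level exclusion rules
  extra <- list()
  if (spikes$males > 0) {
    ids <- sprintf("ASM%04d", seq_len(spikes$males))
    extra$males <- tibble(
      subject_id = ids, study = "ASPREE", arm = "ASPREE controls", sex = "M",
      case_status = "control",
      age = round(rnorm_trunc(spikes$males, 75, 6, 70, 95), 1),
      height = 1.75, bmi = 26, parity = 0, education = 11, alcohol = 4,
      prior_breast_cancer = FALSE, has_panel_data = TRUE)
    add_spike("male", ids)
  }
  if (spikes$prior_bc > 0) {
    ids <- sprintf("ASP%04d", seq_len(spikes$prior_bc))
    extra$prior <- tibble(
      subject_id = ids, study = "ASPREE", arm = "ASPREE controls", sex = "F",
      case_status = "control",
      age = round(rnorm_trunc(spikes$prior_bc, 74, 5.8, 70, 95), 1),
      height = 1.6, bmi = 27, parity = 2, education = 11, alcohol = 1,
      prior_breast_cancer = TRUE, has_panel_data = TRUE)
    add_spike("prior_breast_cancer", ids)
  }
  if (spikes$no_panel_data > 0) {
    ids <- sprintf("CBN%04d", seq_len(spikes$no_panel_data))
    extra$nodata <- tibble(
      subject_id = ids, study = "ABCFS", arm = "ABCFS controls", sex = "F",
      case_status = "control",
      age = round(rnorm_trunc(spikes$no_panel_data, 40, 14, 22, 59), 1),
      height = 1.63, bmi = 23, parity = 2, education = 11, alcohol = 2,
      prior_breast_cancer = FALSE, has_panel_data = FALSE)
    add_spike("no_panel_data", ids)
  }
  if (length(extra)) {
    subjects <- bind_rows(subjects, bind_rows(extra))
    pad <- as_tibble(matrix(FALSE, nrow = nrow(subjects) - nrow(carriers),
                            ncol = length(genes),
                            dimnames = list(NULL, genes))) %>%
      mutate(subject_id = setdiff(subjects$subject_id, carriers$subject_id),
             .before = 1)
    carriers <- bind_rows(carriers, pad)
  }

  gm <- as.matrix(carriers[, genes, drop = FALSE])
  # one multi-gene carrier among the cases (flagged, excluded in main runs)
  if (spikes$multi_gene > 0 && length(genes) >= 2) {
    cand <- which(subjects$case_status == "case" & rowSums(gm) == 0)
    take <- head(cand, spikes$multi_gene)
    if (length(take)) {
      carriers[take, genes[1]] <- TRUE
      carriers[take, genes[2]] <- TRUE
      add_spike("multi_gene", subjects$subject_id[take])
      gm <- as.matrix(carriers[, genes, drop = FALSE])
    }
  }
  # mono-allelic MUTYH enrolees (true non-carriers; get one MUTYH variant
  # when study files are emitted)
  if (spikes$mutyh_mono > 0) {
    cand <- which(subjects$study == "ASPREE" & subjects$sex == "F" &
                    !subjects$prior_breast_cancer & rowSums(gm) == 0)
    add_spike("mutyh_mono",
              subjects$subject_id[head(cand, spikes$mutyh_mono)])
  }

  # tumour ER subtype for cases
  base_odds <- config$er_neg_share / (1 - config$er_neg_share)
  mult <- rep(1, nrow(subjects))
  for (j in seq_along(genes)) {
    mult <- mult * ifelse(gm[, j], gp$er_neg_odds_mult[j], 1)
  }
  p_neg <- (base_odds * mult) / (1 + base_odds * mult)
  is_case <- subjects$case_status == "case"
  er <- rep("unknown", nrow(subjects))
  neg <- is_case & runif(nrow(subjects)) < p_neg
  er[is_case] <- ifelse(neg[is_case], "negative", "positive")
  u_unknown <- runif(nrow(subjects))
  er[is_case & u_unknown < config$er_unknown_share] <- "unknown"
  subjects$er_status <- er

  # family history: more likely for carriers, most of all BRCA1/2 carriers
  fh <- config$family_history
  brca <- rowSums(gm[, intersect(c("BRCA1", "BRCA2"), genes), drop = FALSE]) > 0
  other <- rowSums(gm[, setdiff(genes, c("BRCA1", "BRCA2")), drop = FALSE]) > 0
  odds <- fh$base_odds * ifelse(brca, fh$brca_mult, 1) *
    ifelse(!brca & other, fh$other_mult, 1)
  subjects$family_history <- runif(nrow(subjects)) < odds / (1 + odds)

  # platform of origin
  n_ab <- sum(subjects$study == "ABCFS")
  subjects$platform <- ifelse(
    subjects$study == "ASPREE", "AmpliSeq",
    rep_len(c("HiPlex", "HaloPlexHS"), nrow(subjects)))
  subjects$platform[subjects$study == "ABCFS"] <-
    rep_len(c("HiPlex", "HaloPlexHS"), n_ab)

  # covariate missingness (never imputed downstream)
  miss <- function(x, rate) replace(x, runif(length(x)) < rate, NA)
  aspree <- subjects$study == "ASPREE"
  subjects$parity[aspree] <- miss(subjects$parity[aspree],
                                  config$missing$parity_aspree)
  subjects$parity[!aspree] <- miss(subjects$parity[!aspree],
                                   config$missing$other)
  for (v in c("height", "bmi", "education", "alcohol")) {
    subjects[[v]] <- miss(subjects[[v]], config$missing$other)
  }

  structure(
    list(
      subjects = select(subjects, "subject_id", "study", "arm", "sex",
                        "case_status", "er_status", "age", "height", "bmi",
                        "parity", "education", "alcohol",
                        "prior_breast_cancer", "family_history", "platform",
                        "has_panel_data"),
      carriers = carriers,
      truth = tibble(gene = genes, carrier_freq = gp$carrier_freq,
                     or = gp$or, beta = betas),
      spike_assignments = if (length(spike_rows)) bind_rows(spike_rows) else
        tibble(spike = character(0), subject_id = character(0)),
      config = config, seed = seed
    ),
    class = "synthetic_population"
  )
}

#' Analysis table from a synthetic population's true carrier states
#'
#' Builds a carrier-matrix-style analysis table directly from the
#' generator's ground truth (bypassing the sequencing emulation), applying
#' the subject-level exclusions (males, prior breast cancer, no panel data)
#' and flagging multi-gene carriers. Used to validate the statistical
#' machinery against known truth.
#'
#' @param pop A `synthetic_population`.
#' @return A tibble usable by [fit_gene_or()] and friends, with the `genes`
#'   attribute set and `.multi_gene` flagged.
#' @export
population_analysis_table <- function(pop) {
  genes <- pop$truth$gene
  d <- pop$subjects %>%
    inner_join(pop$carriers, by = "subject_id") %>%
    filter(.data$sex == "F",
           !(.data$study == "ASPREE" & .data$prior_breast_cancer),
           .data$has_panel_data)
  gm <- as.matrix(d[, setdiff(genes, "MUTYH"), drop = FALSE])
  d$.multi_gene <- rowSums(gm) >= 2
  carr_long <- d %>%
    select("subject_id", all_of(genes)) %>%
    pivot_longer(-"subject_id", names_to = "gene", values_to = "carrier") %>%
    filter(.data$carrier) %>%
    mutate(key = paste0("truth:", .data$subject_id, ":", .data$gene)) %>%
    select("subject_id", "gene", "key")
  by_subject <- split(carr_long[, c("gene", "key")], carr_long$subject_id)
  none <- tibble(gene = character(0), key = character(0))
  d$.pathogenic <- unname(map(by_subject[d$subject_id],
                              function(x) if (is.null(x)) none else x))
  attr(d, "genes") <- genes
  class(d) <- c("carrier_matrix", class(d))
  d
}
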