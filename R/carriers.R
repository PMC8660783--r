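#' Carrier-matrix construction policy
#'
#' @param tested_subjects Optional character vector of subjects with panel
#'   data; subjects outside it are excluded under the `no_panel_data` rule.
#'   `NULL` means everyone was tested.
#' @param mutyh_biallelic_min Number of distinct pathogenic MUTYH variants
#'   required for MUTYH carrier status (bi-allelic proxy; default 2).
#'   Mono-allelic MUTYH carriers are demoted to non-carriers but logged,
#'   because MUTYH-associated risk is recessive.
#' @return A `carrier_policy` list.
#' @export
carrier_policy <- function(tested_subjects = NULL, mutyh_biallelic_min = 2L) {
  structure(list(tested_subjects = tested_subjects,
                 mutyh_biallelic_min = as.integer(mutyh_biallelic_min)),
            class = "carrier_policy")
}

#' Build the subject-by-gene carrier matrix with its exclusion ledger
#'
#' Subject-level exclusions are applied in a fixed order: males; ASPREE
#' women with a prior breast cancer diagnosis; subjects with no panel data.
#' A subject is a carrier of a gene iff they carry at least one pathogenic
#' variant in it, except MUTYH, where carrier status requires at least two
#' distinct pathogenic variants. Subjects carrying pathogenic variants in
#' two or more genes (MUTYH excepted) are retained in the matrix but flagged
#' `.multi_gene`; main analyses exclude them, sensitivity analyses re-admit
#' them.
#'
#' @param subjects Phenotype tibble (see [read_phenotypes()]).
#' @param calls Tibble of harmonised calls (`subject_id`, `key`, `gene`), or
#'   a `harmonised_calls` object.
#' @param classifications Per-variant verdicts from [classify_variants()].
#' @param policy A [carrier_policy()].
#' @param genes Genes forming the matrix columns (default [panel_genes()]).
#' @return A `carrier_matrix` tibble: subject covariates, one logical column
#'   per gene, `.multi_gene`, and a `.pathogenic` list-column of per-subject
#'   pathogenic variants. The exclusion ledger is attached as an attribute
#'   (see [exclusion_ledger()]).
#' @export
build_carrier_matrix <- function(subjects, calls, classifications,
                                 policy = carrier_policy(),
                                 genes = panel_genes()) {
  if (anyDuplicated(subjects$subject_id)) {
    dup <- unique(subjects$subject_id[duplicated(subjects$subject_id)])
    abort(paste0("Duplicate subject ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (inherits(calls, "harmonised_calls")) calls <- calls$calls

  ledger <- list()
  log_rule <- function(rule, ids) {
    ledger[[length(ledger) + 1]] <<- tibble(
      rule = rule, n_removed = length(ids), subject_ids = list(ids))
  }
  cur <- subjects

  drop_by <- function(cur, rule, idx) {
    ids <- cur$subject_id[idx]
    log_rule(rule, ids)
    cur[!idx, , drop = FALSE]
  }
  cur <- drop_by(cur, "males", cur$sex == "M")
  cur <- drop_by(cur, "aspree_prior_breast_cancer",
                 cur$study == "ASPREE" &
                   !is.na(cur$prior_breast_cancer) & cur$prior_breast_cancer)
  if (!is.null(policy$tested_subjects)) {
    cur <- drop_by(cur, "no_panel_data",
                   !cur$subject_id %in% policy$tested_subjects)
  } else {
    log_rule("no_panel_data", character(0))
  }

  path_calls <- calls %>%
    inner_join(filter(classifications, .data$verdict == "pathogenic"),
               by = c("key", "gene")) %>%
    distinct(.data$subject_id, .data$gene, .data$key) %>%
    filter(.data$subject_id %in% cur$subject_id)

  per_gene <- path_calls %>%
    count(.data$subject_id, .data$gene, name = "n_variants") %>%
    mutate(carrier = ifelse(.data$gene == "MUTYH",
                            .data$n_variants >= policy$mutyh_biallelic_min,
                            .data$n_variants >= 1L))

  mutyh_mono <- per_gene %>%
    filter(.data$gene == "MUTYH", !.data$carrier) %>%
    pull(.data$subject_id)
  log_rule("mutyh_monoallelic_demoted", mutyh_mono)

  wide <- per_gene %>%
    filter(.data$carrier) %>%
    select("subject_id", "gene") %>%
    mutate(carrier = TRUE) %>%
    pivot_wider(names_from = "gene", values_from = "carrier",
                values_fill = FALSE)
  for (g in setdiff(genes, names(wide))) wide[[g]] <- logical(nrow(wide))

  out <- cur %>%
    left_join(wide[, c("subject_id", genes)], by = "subject_id")
  for (g in genes) out[[g]] <- !is.na(out[[g]]) & out[[g]]

  # multi-gene carriers: distinct carrier genes other than MUTYH
  count_genes <- setdiff(genes, "MUTYH")
  n_genes <- rowSums(as.matrix(out[, count_genes, drop = FALSE]))
  out$.multi_gene <- n_genes >= 2
  log_rule("multi_gene_flagged", out$subject_id[out$.multi_gene])

  path_by_subject <- split(path_calls[, c("gene", "key")],
                           path_calls$subject_id)
  out$.pathogenic <- unname(path_by_subject[out$subject_id])
  out$.pathogenic <- map(out$.pathogenic, function(d) {
    if (is.null(d)) tibble(gene = character(0), key = character(0)) else
      as_tibble(d)
  })

  attr(out, "genes") <- genes
  attr(out, "ledger") <- bind_rows(ledger)
  attr(out, "n_input_subjects") <- nrow(subjects)
  class(out) <- c("carrier_matrix", class(out))
  out
}

#' Retrieve the exclusion ledger of a carrier matrix
#'
#' @param x A `carrier_matrix` from [build_carrier_matrix()].
#' @return Tibble with `rule`, `n_removed`, `subject_ids` (list-column), in
#'   application order. The `mutyh_monoallelic_demoted` and
#'   `multi_gene_flagged` rules do not remove rows from the matrix: the
#'   former demotes carrier status, the latter marks subjects that the main
#'   analyses drop.
#' @export
exclusion_ledger <- function(x) {
  attr(x, "ledger")
}

carrier_genes <- function(data, genes = NULL) {
  if (!is.null(genes)) return(genes)
  g <- attr(data, "genes")
  if (is.null(g)) g <- intersect(panel_genes(), names(data))
  g
}

arm_label <- function(study, case_status) {
  case_when(
    study == "ASPREE" ~ "ASPREE controls",
    case_status == "case" ~ "ABCFS cases",
    TRUE ~ "ABCFS controls"
  )
}

#' Summarise carrier counts and covariates by study arm
#'
#' Produces the descriptive tabulations of a case-control carrier study:
#' per-arm subject counts, per-gene carrier counts with percentages
#' (denominator the arm size, rounded half-up to one decimal), any-gene and
#' non-BRCA1/2 carrier counts, and covariate medians with inter-quartile
#' ranges.
#'
#' @param matrix A `carrier_matrix` (or compatible tibble).
#' @param genes Gene columns to summarise (default: matrix attribute).
#' @param include_multigene Keep `.multi_gene` subjects (default `FALSE`,
#'   matching the main analyses).
#' @return A `cohort_summary` list: `$arms` (arm, n, `empty_arm` flag),
#'   `$carriers` (arm, gene incl. `any_gene` / `non_brca12`, `n_carriers`,
#'   `pct`), `$covariates` (arm, variable, median, iqr).
#' @export
summarize_cohort <- function(matrix, genes = NULL, include_multigene = FALSE) {
  genes <- carrier_genes(matrix, genes)
  d <- as_tibble(matrix)
  if (!include_multigene && ".multi_gene" %in% names(d)) {
    d <- filter(d, !.data$.multi_gene)
  }
  d$arm <- arm_label(d$study, d$case_status)
  arms <- c("ABCFS cases", "ABCFS controls", "ASPREE controls")
  arm_n <- d %>% count(.data$arm, name = "n")
  arm_n <- tibble(arm = arms) %>%
    left_join(arm_n, by = "arm") %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n), empty_arm = .data$n == 0)

  gm <- as.matrix(d[, genes, drop = FALSE])
  non_b <- setdiff(genes, c("BRCA1", "BRCA2"))
  d$any_gene <- rowSums(gm) > 0
  d$non_brca12 <- rowSums(gm[, non_b, drop = FALSE]) > 0

  carriers <- map(c(genes, "any_gene", "non_brca12"), function(g) {
    d %>%
      group_by(.data$arm) %>%
      summarise(n_carriers = sum(.data[[g]]), .groups = "drop") %>%
      mutate(gene = g)
  }) %>%
    bind_rows() %>%
    right_join(tidyr::expand_grid(arm = arms,
                                  gene = c(genes, "any_gene", "non_brca12")),
               by = c("arm", "gene")) %>%
    mutate(n_carriers = ifelse(is.na(.data$n_carriers), 0L, .data$n_carriers)) %>%
    left_join(arm_n[, c("arm", "n")], by = "arm") %>%
    mutate(pct = ifelse(.data$n > 0,
                        round_half_up(100 * .data$n_carriers / .data$n, 1),
                        0)) %>%
    select("arm", "gene", "n_carriers", "n", "pct") %>%
    arrange(.data$arm, .data$gene)

  covars <- c("age", "height", "bmi", "parity", "education", "alcohol")
  covars <- intersect(covars, names(d))
  covariates <- d %>%
    select("arm", all_of(covars)) %>%
    pivot_longer(-"arm", names_to = "variable", values_to = "value") %>%
    group_by(.data$arm, .data$variable) %>%
    summarise(
      median = median(.data$value, na.rm = TRUE),
      iqr = unname(diff(quantile(.data$value, c(0.25, 0.75), na.rm = TRUE))),
      .groups = "drop"
    )

  structure(list(arms = arm_n, carriers = carriers, covariates = covariates),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  print(x$arms)
  cat("\nCarriers (any_gene / non_brca12 rows aggregate):\n")
  print(filter(x$carriers, .data$gene %in% c("any_gene", "non_brca12")))
  invisible(x)
}

#' Compare BRCA1/2 carriers with carriers of other panel genes
#'
#' Among cases only, compares carriers of pathogenic variants in BRCA1 or
#' BRCA2 against carriers of pathogenic variants in other panel genes.
#' Continuous variables (age at diagnosis) use Welch's two-sample t-test
#' with group means and 95% CIs; binary variables (family history) use the
#' chi-square test without continuity correction, falling back to Fisher's
#' exact test when any expected cell count is below 5.
#'
#' @param matrix A `carrier_matrix`.
#' @param variable `"age"` or `"family_history"`.
#' @param multigene_policy `"exclude"` drops multi-gene carriers;
#'   `"assign_brca"` assigns them to the BRCA1/2 group when they carry a
#'   BRCA1/2 variant.
#' @param genes Gene columns (default: matrix attribute).
#' @return A one-row tibble: `variable`, `test`, group sizes, group
#'   summaries, `estimate` (mean difference, or odds ratio for binary),
#'   `ci_low`, `ci_high`, `p`.
#' @export
compare_carrier_groups <- function(matrix,
                                   variable = c("age", "family_history"),
                                   multigene_policy = c("exclude",
                                                        "assign_brca"),
                                   genes = NULL) {
  variable <- match.arg(variable)
  multigene_policy <- match.arg(multigene_policy)
  genes <- carrier_genes(matrix, genes)
  d <- as_tibble(matrix) %>% filter(.data$case_status == "case")
  gm <- as.matrix(d[, genes, drop = FALSE])
  d$any_carrier <- rowSums(gm) > 0
  d$brca <- (("BRCA1" %in% genes) & d$BRCA1) | (("BRCA2" %in% genes) & d$BRCA2)
  d <- filter(d, .data$any_carrier)
  if (multigene_policy == "exclude" && ".multi_gene" %in% names(d)) {
    d <- filter(d, !.data$.multi_gene)
  }
  d$group <- ifelse(d$brca, "BRCA1/2", "other")
  n1 <- sum(d$group == "BRCA1/2")
  n2 <- sum(d$group == "other")
  if (n1 == 0 || n2 == 0) {
    abort("One of the carrier groups is empty; comparison is not estimable")
  }
  if (variable == "age") {
    x <- d$age[d$group == "BRCA1/2"]
    y <- d$age[d$group == "other"]
    if (stats::sd(c(x, y), na.rm = TRUE) == 0) {
      # degenerate: both groups constant and equal
      return(tibble(
        variable = variable, test = "welch_t",
        group1 = "BRCA1/2", group2 = "other", n1 = n1, n2 = n2,
        mean1 = mean(x, na.rm = TRUE), mean1_ci_low = mean(x, na.rm = TRUE),
        mean1_ci_high = mean(x, na.rm = TRUE),
        mean2 = mean(y, na.rm = TRUE), mean2_ci_low = mean(y, na.rm = TRUE),
        mean2_ci_high = mean(y, na.rm = TRUE),
        estimate = 0, ci_low = 0, ci_high = 0,
        statistic = NA_real_, p = 1))
    }
    tt <- t.test(x, y)
    ci_mean <- function(v) {
      v <- v[!is.na(v)]
      se <- stats::sd(v) / sqrt(length(v))
      mean(v) + c(-1, 1) * stats::qt(0.975, length(v) - 1) * se
    }
    c1 <- ci_mean(x)
    c2 <- ci_mean(y)
    tibble(
      variable = variable, test = "welch_t",
      group1 = "BRCA1/2", group2 = "other", n1 = n1, n2 = n2,
      mean1 = mean(x, na.rm = TRUE), mean1_ci_low = c1[1], mean1_ci_high = c1[2],
      mean2 = mean(y, na.rm = TRUE), mean2_ci_low = c2[1], mean2_ci_high = c2[2],
      estimate = unname(tt$estimate[1] - tt$estimate[2]),
      ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
      statistic = unname(tt$statistic), p = tt$p.value
    )
  } else {
    d <- filter(d, !is.na(.data$family_history))
    tab <- table(factor(d$group, c("BRCA1/2", "other")),
                 factor(d$family_history, c(TRUE, FALSE)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; dd <- tab[2, 2]
    if (any(expected < 5)) {
      ft <- fisher.test(tab)
      tibble(
        variable = variable, test = "fisher",
        group1 = "BRCA1/2", group2 = "other",
        n1 = sum(tab[1, ]), n2 = sum(tab[2, ]),
        prop1 = a / sum(tab[1, ]), prop2 = cc / sum(tab[2, ]),
        estimate = unname(ft$estimate),
        ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
        statistic = NA_real_, p = ft$p.value
      )
    } else {
      ct <- chisq.test(tab, correct = FALSE)
      or <- (a * dd) / (b * cc)
      se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / dd)  # Woolf
      tibble(
        variable = variable, test = "chi_square",
        group1 = "BRCA1/2", group2 = "other",
        n1 = sum(tab[1, ]), n2 = sum(tab[2, ]),
        prop1 = a / sum(tab[1, ]), prop2 = cc / sum(tab[2, ]),
        estimate = or,
        ci_low = exp(log(or) - qnorm(0.975) * se),
        ci_high = exp(log(or) + qnorm(0.975) * se),
        statistic = unname(ct$statistic), p = ct$p.value
      )
    }
  }
}
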