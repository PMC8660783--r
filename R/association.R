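adjustment_covariates <- function(adjust = c("full", "age", "none")) {
  adjust <- match.arg(adjust)
  switch(adjust,
         none = character(0),
         age = "age",
         full = c("age", "height", "bmi", "parity", "education", "alcohol"))
}

# Fit a logistic model y ~ x1 [+ x2] + covariates and the nested model
# without the exposure term(s), on the same complete-case rows; detects
# quasi-separation via the usual glm warning.
fit_logistic_pair <- function(df, exposure_terms, covariates) {
  rhs_full <- paste(c(exposure_terms, covariates, "1"), collapse = " + ")
  rhs_red <- paste(c(covariates, "1"), collapse = " + ")
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(as.formula(paste("y ~", rhs_full)), data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (anyNA(coef(fit)[exposure_terms]) ||
      anyNA(coef(fit)[setdiff(names(coef(fit)), exposure_terms)])) {
    abort("Collinear covariates: logistic model has inestimable coefficients")
  }
  fit0 <- suppressWarnings(
    glm(as.formula(paste("y ~", rhs_red)), data = df, family = binomial()))
  list(fit = fit, fit0 = fit0, separated = separated)
}

wald_ci <- function(beta, se, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  c(exp(beta - z * se), exp(beta + z * se))
}

or_result_row <- function(gene, adjustment, or = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p = NA_real_,
                          n_case_carriers = 0L, n_control_carriers = 0L,
                          n_cases = 0L, n_controls = 0L, estimable = FALSE,
                          separation = FALSE) {
  tibble(
    gene = gene, adjustment = adjustment, or = or, ci_low = ci_low,
    ci_high = ci_high, p = p,
    n_case_carriers = as.integer(n_case_carriers),
    n_control_carriers = as.integer(n_control_carriers),
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    case_pct = if (n_cases > 0)
      round_half_up(100 * n_case_carriers / n_cases, 1) else NA_real_,
    control_pct = if (n_controls > 0)
      round_half_up(100 * n_control_carriers / n_controls, 1) else NA_real_,
    estimable = estimable, separation = separation
  )
}

#' Estimate the per-gene carrier odds ratio by logistic regression
#'
#' Fits an unconditional maximum-likelihood logistic regression of case
#' status on carrier status for one gene, adjusted for the chosen covariate
#' set, on the complete-case rows for that set. Carriers of other genes
#' remain in the unexposed reference group. The odds ratio is the
#' exponentiated carrier coefficient with a 95% Wald interval; the p-value
#' is a two-sided likelihood-ratio test of the carrier term against the
#' nested covariate-only model refitted on the same rows.
#'
#' The model is fitted only when there is at least one carrier among cases
#' and one among controls (otherwise the result is flagged non-estimable,
#' matching the convention of printing a dash for such genes).
#'
#' @param data A `carrier_matrix` (or compatible tibble with `case_status`,
#'   covariates, and a logical column per gene).
#' @param gene Gene symbol (must be a column of `data`).
#' @param adjust `"full"` (age, height, BMI, parity, education, alcohol),
#'   `"age"`, or `"none"`.
#' @param include_multigene Keep `.multi_gene` subjects (default `FALSE`).
#' @param conf_level Wald CI level (default 0.95).
#' @return A `gene_or_fit` object; use [glance()] for the one-row odds-ratio
#'   summary or [tidy()] for the full coefficient table.
#' @export
fit_gene_or <- function(data, gene, adjust = "full",
                        include_multigene = FALSE, conf_level = 0.95) {
  covs <- adjustment_covariates(adjust)
  d <- as_tibble(data)
  if (!gene %in% names(d)) abort(paste0("No carrier column for gene ", gene))
  if (!include_multigene && ".multi_gene" %in% names(d)) {
    d <- filter(d, !.data$.multi_gene)
  }
  df <- tibble(
    y = as.integer(d$case_status == "case"),
    x = as.integer(d[[gene]])
  )
  for (cv in covs) df[[cv]] <- d[[cv]]
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]

  n_case_carriers <- sum(df$x == 1 & df$y == 1)
  n_control_carriers <- sum(df$x == 1 & df$y == 0)
  n_cases <- sum(df$y == 1)
  n_controls <- sum(df$y == 0)
  base <- list(gene = gene, adjust = adjust, fit = NULL, fit0 = NULL)

  if (n_case_carriers < 1 || n_control_carriers < 1) {
    base$result <- or_result_row(gene, adjust,
                                 n_case_carriers = n_case_carriers,
                                 n_control_carriers = n_control_carriers,
                                 n_cases = n_cases, n_controls = n_controls,
                                 estimable = FALSE)
    return(structure(base, class = "gene_or_fit"))
  }

  fits <- fit_logistic_pair(df, "x", covs)
  beta <- coef(fits$fit)[["x"]]
  se <- sqrt(vcov(fits$fit)["x", "x"])
  if (fits$separated && (abs(beta) > 10 || se > 50)) {
    base$result <- or_result_row(gene, adjust,
                                 n_case_carriers = n_case_carriers,
                                 n_control_carriers = n_control_carriers,
                                 n_cases = n_cases, n_controls = n_controls,
                                 estimable = FALSE, separation = TRUE)
    base$fit <- fits$fit
    return(structure(base, class = "gene_or_fit"))
  }
  ci <- wald_ci(beta, se, conf_level)
  p <- pchisq(fits$fit0$deviance - fits$fit$deviance, df = 1,
              lower.tail = FALSE)
  base$fit <- fits$fit
  base$fit0 <- fits$fit0
  base$result <- or_result_row(gene, adjust, or = exp(beta), ci_low = ci[1],
                               ci_high = ci[2], p = p,
                               n_case_carriers = n_case_carriers,
                               n_control_carriers = n_control_carriers,
                               n_cases = n_cases, n_controls = n_controls,
                               estimable = TRUE)
  structure(base, class = "gene_or_fit")
}

#' @export
print.gene_or_fit <- function(x, ...) {
  r <- x$result
  cat("Gene:", r$gene, " adjustment:", r$adjustment, "\n")
  if (r$estimable) {
    cat(sprintf("OR %.3g (95%% CI %.3g-%.3g), p = %.3g\n",
                r$or, r$ci_low, r$ci_high, r$p))
  } else {
    cat("Not estimable (", if (r$separation) "separation" else
      "zero carriers in cases or controls", ")\n", sep = "")
  }
  cat(sprintf("carriers: %d/%d cases, %d/%d controls\n",
              r$n_case_carriers, r$n_cases, r$n_control_carriers,
              r$n_controls))
  invisible(x)
}

#' @rdname fit_gene_or
#' @param x A `gene_or_fit`.
#' @param ... Unused.
#' @method glance gene_or_fit
#' @export
glance.gene_or_fit <- function(x, ...) {
  x$result
}

#' @rdname fit_gene_or
#' @method tidy gene_or_fit
#' @export
tidy.gene_or_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(term = character(0), estimate = numeric(0),
                  std.error = numeric(0), statistic = numeric(0),
                  p.value = numeric(0)))
  }
  sm <- summary(x$fit)$coefficients
  tibble(
    term = sub("^x$", paste0("carrier_", x$gene), rownames(sm)),
    estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]), p.value = unname(sm[, 4])
  )
}

#' Per-gene association across the whole panel
#'
#' Fits [fit_gene_or()] for each gene and returns one row per gene, sorted
#' by likelihood-ratio p-value with non-estimable genes last. No
#' multiple-testing correction is applied (raw p-values against a 0.05
#' threshold).
#'
#' @inheritParams fit_gene_or
#' @param genes Genes to fit (default: the matrix's gene columns).
#' @return A `panel_or_tbl` tibble of odds-ratio results.
#' @export
run_panel_association <- function(data, genes = NULL, adjust = "full",
                                  include_multigene = FALSE) {
  genes <- carrier_genes(data, genes)
  res <- map(genes, function(g) {
    glance(fit_gene_or(data, g, adjust = adjust,
                       include_multigene = include_multigene))
  }) %>%
    bind_rows() %>%
    arrange(desc(.data$estimable), .data$p)
  class(res) <- c("panel_or_tbl", class(res))
  res
}

#' Oestrogen-receptor subtype association
#'
#' Treats ER-positive and ER-negative breast cancer as separate diseases:
#' cases are restricted to the requested subtype (cases with unknown ER
#' status are dropped), all controls are retained, and the per-gene model of
#' [fit_gene_or()] is fitted on the restricted table.
#'
#' @inheritParams run_panel_association
#' @param subtype `"er_pos"` or `"er_neg"`.
#' @return A `panel_or_tbl` with a `subtype` column.
#' @export
run_subtype_association <- function(data, genes = NULL,
                                    subtype = c("er_pos", "er_neg"),
                                    adjust = "full",
                                    include_multigene = FALSE) {
  subtype <- match.arg(subtype)
  want <- if (subtype == "er_pos") "positive" else "negative"
  genes <- carrier_genes(data, genes)
  d <- as_tibble(data) %>%
    filter(.data$case_status == "control" |
             (!is.na(.data$er_status) & .data$er_status == want))
  if (!any(d$case_status == "case")) {
    abort(paste0("No cases of subtype ", subtype,
                 "; subtype association is not estimable"))
  }
  attr(d, "genes") <- genes
  res <- run_panel_association(d, genes = genes, adjust = adjust,
                               include_multigene = include_multigene)
  res$subtype <- subtype
  res
}

#' Split one recurrent variant from the rest of a gene's pathogenic variants
#'
#' Partitions carriers of a gene into carriers of one designated variant
#' (e.g. CHEK2 c.1100delC) versus carriers of any other pathogenic variant
#' in the gene (carriers of both fall in the designated stratum), fits a
#' logistic model with the two exposure indicators, and tests equality of
#' the two carrier coefficients by a likelihood-ratio test against the model
#' with a single common carrier coefficient.
#'
#' @inheritParams fit_gene_or
#' @param split_key Variant key designating the recurrent variant.
#' @return A two-row tibble (stratum `"split_variant"` / `"other_variants"`)
#'   with per-stratum OR, Wald CI, carrier counts and estimability, plus the
#'   shared equality-test p-value in `p_equal` (`NA` when a stratum is
#'   empty, in which case the fit reduces to [fit_gene_or()]).
#' @export
run_variant_split <- function(data, gene, split_key, adjust = "full",
                              include_multigene = FALSE, conf_level = 0.95) {
  covs <- adjustment_covariates(adjust)
  d <- as_tibble(data)
  if (!include_multigene && ".multi_gene" %in% names(d)) {
    d <- filter(d, !.data$.multi_gene)
  }
  if (!".pathogenic" %in% names(d)) {
    abort("run_variant_split() needs the .pathogenic list-column of a carrier_matrix")
  }
  has_split <- map_lgl(d$.pathogenic, function(pv) {
    any(pv$gene == gene & pv$key == split_key)
  })
  carrier <- d[[gene]]
  x1 <- as.integer(carrier & has_split)       # designated variant stratum
  x2 <- as.integer(carrier & !has_split)      # all other pathogenic variants

  df <- tibble(y = as.integer(d$case_status == "case"), x1 = x1, x2 = x2)
  for (cv in covs) df[[cv]] <- d[[cv]]
  df <- df[complete.cases(df), , drop = FALSE]

  stratum_counts <- function(x) {
    c(case = sum(x == 1 & df$y == 1), control = sum(x == 1 & df$y == 0))
  }
  c1 <- stratum_counts(df$x1)
  c2 <- stratum_counts(df$x2)

  empty1 <- sum(df$x1) == 0
  empty2 <- sum(df$x2) == 0
  if (empty1 || empty2) {
    # one stratum absent: reduces to the single-exposure gene fit
    single <- glance(fit_gene_or(data, gene, adjust = adjust,
                                 include_multigene = include_multigene,
                                 conf_level = conf_level))
    out <- bind_rows(
      tibble(gene = gene, stratum = "split_variant",
             or = if (empty1) NA_real_ else single$or,
             ci_low = if (empty1) NA_real_ else single$ci_low,
             ci_high = if (empty1) NA_real_ else single$ci_high,
             p = if (empty1) NA_real_ else single$p,
             n_case_carriers = c1[["case"]],
             n_control_carriers = c1[["control"]],
             estimable = !empty1 && single$estimable),
      tibble(gene = gene, stratum = "other_variants",
             or = if (empty2) NA_real_ else single$or,
             ci_low = if (empty2) NA_real_ else single$ci_low,
             ci_high = if (empty2) NA_real_ else single$ci_high,
             p = if (empty2) NA_real_ else single$p,
             n_case_carriers = c2[["case"]],
             n_control_carriers = c2[["control"]],
             estimable = !empty2 && single$estimable)
    )
    out$p_equal <- NA_real_
    return(out)
  }

  fits <- fit_logistic_pair(df, c("x1", "x2"), covs)
  common <- suppressWarnings(glm(
    as.formula(paste(c("y ~ I(x1 + x2)", covs), collapse = " + ")),
    data = df, family = binomial()))
  p_equal <- pchisq(common$deviance - fits$fit$deviance, df = 1,
                    lower.tail = FALSE)

  stratum_row <- function(term, lab, cnt) {
    beta <- coef(fits$fit)[[term]]
    se <- sqrt(vcov(fits$fit)[term, term])
    estimable <- cnt[["case"]] >= 1 && cnt[["control"]] >= 1
    ci <- wald_ci(beta, se, conf_level)
    p <- pchisq(
      suppressWarnings(glm(
        as.formula(paste(c(paste("y ~", setdiff(c("x1", "x2"), term)), covs),
                         collapse = " + ")),
        data = df, family = binomial()))$deviance - fits$fit$deviance,
      df = 1, lower.tail = FALSE)
    tibble(gene = gene, stratum = lab,
           or = if (estimable) exp(beta) else NA_real_,
           ci_low = if (estimable) ci[1] else NA_real_,
           ci_high = if (estimable) ci[2] else NA_real_,
           p = if (estimable) p else NA_real_,
           n_case_carriers = cnt[["case"]],
           n_control_carriers = cnt[["control"]],
           estimable = estimable)
  }
  out <- bind_rows(
    stratum_row("x1", "split_variant", c1),
    stratum_row("x2", "other_variants", c2)
  )
  out$p_equal <- p_equal
  out
}

#' Sensitivity analyses for the panel association
#'
#' `"exclude_aspree"` refits the panel on the age-matched case-control arms
#' only (all ASPREE subjects dropped), probing the age adjustment against
#' the elderly super-control design. `"include_multigene"` re-admits
#' subjects carrying pathogenic variants in two or more genes, each counting
#' as a carrier for every gene they carry.
#'
#' @inheritParams run_panel_association
#' @param mode `"exclude_aspree"` or `"include_multigene"`.
#' @return A `panel_or_tbl` with a `mode` column.
#' @export
run_sensitivity <- function(data, mode = c("exclude_aspree",
                                           "include_multigene"),
                            genes = NULL, adjust = "full") {
  mode <- match.arg(mode)
  genes <- carrier_genes(data, genes)
  res <- if (mode == "exclude_aspree") {
    d <- as_tibble(data) %>% filter(.data$study != "ASPREE")
    attr(d, "genes") <- genes
    run_panel_association(d, genes = genes, adjust = adjust)
  } else {
    run_panel_association(data, genes = genes, adjust = adjust,
                          include_multigene = TRUE)
  }
  res$mode <- mode
  res
}
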