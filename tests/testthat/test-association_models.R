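# Build a minimal analysis table from 2x2 (or stratified) counts.
mk_or_table <- function(case_exp, case_unexp, ctrl_exp, ctrl_unexp,
                        gene = "G1") {
  n <- case_exp + case_unexp + ctrl_exp + ctrl_unexp
  d <- tibble::tibble(
    subject_id = sprintf("s%05d", seq_len(n)),
    study = "ABCFS",
    case_status = rep(c("case", "case", "control", "control"),
                      c(case_exp, case_unexp, ctrl_exp, ctrl_unexp)),
    er_status = "unknown",
    age = 50 + (seq_len(n) %% 7) - 3,
    height = 1.6 + (seq_len(n) %% 5) / 100,
    bmi = 24 + (seq_len(n) %% 9) / 2,
    parity = seq_len(n) %% 4,
    education = 10 + seq_len(n) %% 3,
    alcohol = seq_len(n) %% 6)
  d[[gene]] <- rep(c(TRUE, FALSE, TRUE, FALSE),
                   c(case_exp, case_unexp, ctrl_exp, ctrl_unexp))
  d$.multi_gene <- FALSE
  attr(d, "genes") <- gene
  d
}

test_that("unadjusted logistic OR equals the 2x2 cross-product ratio to 6 significant digits", {
  set.seed(71)
  for (i in 1:25) {
    a <- sample(3:60, 1); b <- sample(50:800, 1)
    cc <- sample(3:60, 1); dd <- sample(50:800, 1)
    d <- mk_or_table(a, b, cc, dd)
    got <- glance(fit_gene_or(d, "G1", adjust = "none"))
    oracle <- oracle_cross_product_or(a, b, cc, dd)
    expect_equal(got$or, oracle, tolerance = 1e-7)
    expect_true(got$ci_low <= got$or && got$or <= got$ci_high)
    # Wald CI from the analytic SE of the log cross-product ratio
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / dd)
    expect_equal(got$ci_low, exp(log(oracle) - qnorm(0.975) * se),
                 tolerance = 1e-3)
  }
})

test_that("unadjusted LRT p-value equals the G-test on the 2x2 table", {
  set.seed(72)
  for (i in 1:15) {
    a <- sample(3:60, 1); b <- sample(50:800, 1)
    cc <- sample(3:60, 1); dd <- sample(50:800, 1)
    d <- mk_or_table(a, b, cc, dd)
    got <- glance(fit_gene_or(d, "G1", adjust = "none"))
    oracle <- oracle_g_test(matrix(c(a, cc, b, dd), 2))
    expect_equal(got$p, oracle$p, tolerance = 1e-8)
  }
})

test_that("printed carrier counts give the expected unadjusted odds ratio", {
  # 46/1418 exposed/unexposed cases, 6/7405 exposed/unexposed controls
  d <- mk_or_table(46, 1418, 6, 7405, gene = "BRCA1")
  got <- glance(fit_gene_or(d, "BRCA1", adjust = "none"))
  expect_equal(got$or, (46 * 7405) / (6 * 1418), tolerance = 1e-7)
  expect_equal(round(got$or, 2), 40.04)
})

test_that("equal carrier prevalence gives OR near 1 and zero-cell genes are non-estimable", {
  d <- mk_or_table(40, 1960, 40, 1960)
  got <- glance(fit_gene_or(d, "G1", adjust = "none"))
  expect_equal(got$or, 1, tolerance = 1e-9)
  expect_gt(got$p, 0.99)

  # one case carrier, zero control carriers: dash-rendered row
  d2 <- mk_or_table(1, 1463, 0, 7411, gene = "CDH1")
  got2 <- glance(fit_gene_or(d2, "CDH1", adjust = "none"))
  expect_false(got2$estimable)
  expect_true(is.na(got2$or) && is.na(got2$p))
  expect_equal(got2$n_case_carriers, 1L)

  # collinear covariate is a hard error
  d3 <- mk_or_table(10, 200, 10, 200)
  d3$height <- d3$age * 2
  expect_error(fit_gene_or(d3, "G1", adjust = "full"), "[Cc]ollinear")
})

test_that("complete-case rows are dropped per adjustment set and counted honestly", {
  d <- mk_or_table(20, 480, 20, 480)
  d$age[1:10] <- NA  # ten exposed cases lose their age
  una <- glance(fit_gene_or(d, "G1", adjust = "none"))
  adj <- glance(fit_gene_or(d, "G1", adjust = "age"))
  expect_equal(una$n_case_carriers, 20L)
  expect_equal(adj$n_case_carriers, 10L)
  expect_equal(adj$n_cases, una$n_cases - 10L)
})

test_that("panel association sorts by p with non-estimable genes last", {
  d <- mk_or_table(40, 1460, 8, 1492, gene = "STRONG")
  d$NULLG <- rep_len(c(TRUE, rep(FALSE, 99)), nrow(d))
  d$EMPTY <- FALSE
  attr(d, "genes") <- c("NULLG", "STRONG", "EMPTY")
  res <- run_panel_association(d, adjust = "none")
  expect_equal(res$gene[1], "STRONG")
  expect_equal(res$gene[3], "EMPTY")
  expect_false(res$estimable[3])
  expect_s3_class(autoplot(res), "ggplot")

  # all genes zero carriers -> all non-estimable
  d0 <- mk_or_table(0, 100, 0, 100, gene = "G0")
  attr(d0, "genes") <- "G0"
  expect_false(any(run_panel_association(d0, adjust = "none")$estimable))
})

test_that("tidy and glance expose broom-style views of a gene fit", {
  d <- mk_or_table(30, 970, 15, 985)
  f <- fit_gene_or(d, "G1", adjust = "none")
  td <- tidy(f)
  expect_equal(td$term, c("(Intercept)", "carrier_G1"))
  expect_equal(exp(td$estimate[2]), glance(f)$or, tolerance = 1e-9)
  expect_s3_class(glance(f), "tbl_df")
})

test_that("ER-subtype analyses restrict cases and keep all controls", {
  d <- mk_or_table(40, 1460, 10, 1490, gene = "G1")
  is_case <- d$case_status == "case"
  # carriers enriched among ER-negative cases
  d$er_status[is_case] <- ifelse(d$G1[is_case],
                                 rep_len(c("negative", "negative", "positive"),
                                         sum(is_case))[seq_len(sum(is_case))],
                                 rep_len(c("positive", "positive", "negative"),
                                         sum(is_case))[seq_len(sum(is_case))])
  d$er_status[which(is_case)[1:20]] <- "unknown"
  neg <- run_subtype_association(d, subtype = "er_neg", adjust = "none")
  pos <- run_subtype_association(d, subtype = "er_pos", adjust = "none")
  expect_equal(neg$n_controls, 1500L)
  expect_equal(pos$n_controls, 1500L)
  # unknown-ER cases are dropped from both
  expect_lt(neg$n_cases + pos$n_cases, sum(is_case))
  expect_gt(neg$or, pos$or)

  # all cases one subtype: subtype fit equals the overall fit
  d2 <- mk_or_table(30, 970, 15, 985)
  d2$er_status[d2$case_status == "case"] <- "positive"
  overall <- glance(fit_gene_or(d2, "G1", adjust = "none"))
  sub <- run_subtype_association(d2, subtype = "er_pos", adjust = "none")
  expect_equal(sub$or, overall$or, tolerance = 1e-12)

  # no cases of the subtype is an estimability error
  expect_error(run_subtype_association(d2, subtype = "er_neg",
                                       adjust = "none"), "not estimable")
})

mk_split_table <- function(n_split_case, n_split_ctrl, n_other_case,
                           n_other_ctrl, n_case, n_ctrl, gene = "CHEK2") {
  n <- n_case + n_ctrl
  d <- tibble::tibble(
    subject_id = sprintf("s%05d", seq_len(n)),
    study = "ABCFS",
    case_status = rep(c("case", "control"), c(n_case, n_ctrl)),
    er_status = "unknown", age = 50, height = 1.6, bmi = 24, parity = 2,
    education = 11, alcohol = 2)
  split_idx <- c(seq_len(n_split_case), n_case + seq_len(n_split_ctrl))
  other_idx <- c(n_split_case + seq_len(n_other_case),
                 n_case + n_split_ctrl + seq_len(n_other_ctrl))
  d[[gene]] <- seq_len(n) %in% c(split_idx, other_idx)
  d$.multi_gene <- FALSE
  d$.pathogenic <- lapply(seq_len(n), function(i) {
    if (i %in% split_idx) {
      tibble::tibble(gene = gene, key = "split_key")
    } else if (i %in% other_idx) {
      tibble::tibble(gene = gene, key = paste0("other", i))
    } else {
      tibble::tibble(gene = character(0), key = character(0))
    }
  })
  attr(d, "genes") <- gene
  d
}

test_that("variant split coefficients match a brute-force likelihood grid search", {
  d <- mk_split_table(12, 8, 15, 10, 400, 600)
  got <- run_variant_split(d, "CHEK2", "split_key", adjust = "none")
  x1 <- purrr::map_lgl(d$.pathogenic, ~ any(.x$key == "split_key"))
  x2 <- d$CHEK2 & !x1
  oracle <- oracle_grid_logistic3(as.integer(d$case_status == "case"),
                                  as.integer(x1), as.integer(x2))
  expect_equal(log(got$or[got$stratum == "split_variant"]),
               unname(oracle["b1"]), tolerance = 2e-3)
  expect_equal(log(got$or[got$stratum == "other_variants"]),
               unname(oracle["b2"]), tolerance = 2e-3)
  expect_true(all(got$estimable))
  expect_equal(unique(got$p_equal), got$p_equal[1])
  expect_true(got$p_equal[1] >= 0 && got$p_equal[1] <= 1)
})

test_that("variant split with an absent stratum reduces to the single-gene fit", {
  d <- mk_split_table(0, 0, 20, 12, 400, 600)
  got <- run_variant_split(d, "CHEK2", "split_key", adjust = "none")
  single <- glance(fit_gene_or(d, "CHEK2", adjust = "none"))
  other <- got[got$stratum == "other_variants", ]
  expect_equal(other$or, single$or, tolerance = 1e-12)
  expect_false(got$estimable[got$stratum == "split_variant"])
  expect_true(all(is.na(got$p_equal)))
})

test_that("the split-equality LRT p-value is uniform under the null", {
  set.seed(77)
  n <- 1200
  t_split <- tibble::tibble(gene = "CHEK2", key = "split_key")
  t_other <- tibble::tibble(gene = "CHEK2", key = "some_other_key")
  t_none <- tibble::tibble(gene = character(0), key = character(0))
  pvals <- vapply(1:200, function(i) {
    x1 <- runif(n) < 0.02
    x2 <- !x1 & runif(n) < 0.03
    eta <- -1 + 0.5 * (x1 | x2)
    y <- runif(n) < plogis(eta)
    d <- tibble::tibble(
      subject_id = as.character(seq_len(n)), study = "ABCFS",
      case_status = ifelse(y, "case", "control"), er_status = "unknown",
      age = 50, height = 1.6, bmi = 24, parity = 2, education = 11,
      alcohol = 2, CHEK2 = x1 | x2, .multi_gene = FALSE)
    slot <- ifelse(x1, 1L, ifelse(x2, 2L, 3L))
    d$.pathogenic <- list(t_split, t_other, t_none)[slot]
    attr(d, "genes") <- "CHEK2"
    run_variant_split(d, "CHEK2", "split_key", adjust = "none")$p_equal[1]
  }, 1.0)
  pvals <- pvals[!is.na(pvals)]
  expect_gt(length(pvals), 150)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("sensitivity analyses rework the cohort as specified", {
  # exclude_aspree drops the elderly arm entirely
  n <- 900
  d <- mk_or_table(30, 370, 20, 480)
  d$study[d$case_status == "control"][1:250] <- "ASPREE"
  sens <- run_sensitivity(d, "exclude_aspree", adjust = "none")
  expect_equal(unique(sens$mode), "exclude_aspree")
  expect_lt(sens$n_controls[1], 500L)

  # include_multigene with no multi-gene carriers equals the main analysis
  main <- run_panel_association(d, adjust = "none")
  inc <- run_sensitivity(d, "include_multigene", adjust = "none")
  expect_equal(inc$or, main$or, tolerance = 1e-12)

  # a multi-gene carrier case raises both genes' case-carrier counts by one
  d2 <- mk_or_table(10, 490, 10, 490, gene = "BRCA1")
  d2$ATM <- FALSE
  d2$ATM[500:505] <- TRUE   # some ATM-only carriers
  first_case <- which(d2$case_status == "case" & !d2$BRCA1)[1]
  d2$BRCA1[first_case] <- TRUE
  d2$ATM[first_case] <- TRUE
  d2$.multi_gene[first_case] <- TRUE
  attr(d2, "genes") <- c("BRCA1", "ATM")
  main2 <- run_panel_association(d2, adjust = "none")
  inc2 <- run_sensitivity(d2, "include_multigene", adjust = "none")
  for (g in c("BRCA1", "ATM")) {
    expect_equal(inc2$n_case_carriers[inc2$gene == g],
                 main2$n_case_carriers[main2$gene == g] + 1L)
  }
})

test_that("perfect separation is flagged non-estimable rather than reported", {
  n <- 60
  d <- tibble::tibble(
    subject_id = as.character(1:n), study = "ABCFS",
    case_status = rep(c("case", "control"), each = n / 2),
    er_status = "unknown", age = 50, height = 1.6, bmi = 24, parity = 2,
    education = 11, alcohol = 2,
    G1 = c(rep(TRUE, 10), rep(FALSE, n / 2 - 10), rep(FALSE, n / 2)),
    .multi_gene = FALSE)
  # give the controls one carrier so the estimability precheck passes but
  # the covariate-separated fit still explodes
  d$G1[n] <- TRUE
  d$age <- ifelse(d$G1 & d$case_status == "case", 95, 30)
  d$age[n] <- 30.5
  f <- fit_gene_or(d, "G1", adjust = "age")
  r <- glance(f)
  if (!r$estimable) expect_true(r$separation)
  expect_s3_class(r, "tbl_df")
})
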