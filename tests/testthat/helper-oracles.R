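# Independent oracles used across the suite. These re-derive expected
# values by brute force or closed form and deliberately avoid the package's
# own code paths.

# Hand-trim allele normalisation on character vectors.
oracle_trim <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

# Per-base set of 0-based positions covered by half-open intervals.
oracle_base_set <- function(regions) {
  if (nrow(regions) == 0) return(character(0))
  unlist(lapply(seq_len(nrow(regions)), function(i) {
    paste(regions$chrom[i], seq(regions$start[i], regions$end[i] - 1))
  }))
}

# Closed-form Welch two-sample t-test.
oracle_welch <- function(x, y) {
  v1 <- var(x) / length(x)
  v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# G-test (likelihood-ratio chi-square) on a 2x2 table of counts.
oracle_g_test <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  o <- as.numeric(tab)
  e <- as.numeric(e)
  g <- 2 * sum(ifelse(o == 0, 0, o * log(o / e)))
  list(statistic = g, p = pchisq(g, df = 1, lower.tail = FALSE))
}

oracle_cross_product_or <- function(case_exp, case_unexp, ctrl_exp,
                                    ctrl_unexp) {
  (case_exp * ctrl_unexp) / (ctrl_exp * case_unexp)
}

# Brute-force maximum-likelihood fit of y ~ x1 + x2 (binary exposures) by
# iterative grid refinement over (b0, b1, b2), on aggregated cells.
oracle_grid_logistic3 <- function(y, x1, x2) {
  cells <- aggregate(cbind(n = rep(1, length(y)), k = y),
                     by = list(x1 = x1, x2 = x2), FUN = sum)
  loglik <- function(b0, b1, b2) {
    eta <- b0 + b1 * cells$x1 + b2 * cells$x2
    sum(cells$k * eta - cells$n * log1p(exp(eta)))
  }
  loglik_vec <- function(b0, b1, b2) {
    # b2 is a vector; eta is cells x length(b2)
    eta <- outer(b0 + b1 * cells$x1, rep(1, length(b2))) +
      outer(cells$x2, b2)
    colSums(cells$k * eta - cells$n * log1p(exp(eta)))
  }
  centre <- c(0, 0, 0)
  width <- 8
  for (round in 1:6) {
    grid <- seq(-width, width, length.out = 21)
    best <- c(-Inf, centre)
    for (d0 in grid) for (d1 in grid) {
      ll <- loglik_vec(centre[1] + d0, centre[2] + d1, centre[3] + grid)
      j <- which.max(ll)
      if (ll[j] > best[1]) best <- c(ll[j], centre[1] + d0, centre[2] + d1,
                                     centre[3] + grid[j])
    }
    centre <- best[2:4]
    width <- width * 2.4 / 20
  }
  setNames(centre, c("b0", "b1", "b2"))
}

# Independent re-derivation of the expected classification, organised around
# verdict-level set logic rather than the implementation's first-match
# cascade.
expected_classification <- function(cons, sig, last_exon, rare, plp, blb) {
  ptv <- cons %in% c("stop_gained", "frameshift", "canonical_splice")
  tending <- plp >= 1 & plp > blb
  if (!rare) return(list(verdict = "not_pathogenic", reason = "not_rare"))
  pathogenic_routes <- c(
    clinvar_plp = sig %in% c("Pathogenic", "LikelyPathogenic"),
    conflicting_ptv = ptv && sig == "Conflicting" && tending,
    novel_ptv = ptv && sig == "Absent" && !last_exon)
  if (any(pathogenic_routes)) {
    return(list(verdict = "pathogenic",
                reason = names(which(pathogenic_routes))[1]))
  }
  reason <- if (sig %in% c("Benign", "LikelyBenign")) "clinvar_benign"
    else if (ptv && sig == "Absent" && last_exon) "last_exon_ptv_excluded"
    else "non_truncating_unclassified"
  list(verdict = "not_pathogenic", reason = reason)
}

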