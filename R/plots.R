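#' Forest plot of per-gene odds ratios
#'
#' Genes sorted by p-value (non-estimable genes omitted), point estimates
#' with 95% Wald intervals on a log scale.
#'
#' @param object A `panel_or_tbl` from [run_panel_association()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot panel_or_tbl
#' @export
autoplot.panel_or_tbl <- function(object, ...) {
  d <- as_tibble(object) %>%
    filter(.data$estimable) %>%
    arrange(.data$p) %>%
    mutate(gene = factor(.data$gene, levels = rev(.data$gene)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$gene)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2.4) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI, log scale)", y = NULL,
                  title = "Per-gene association with case status",
                  subtitle = "Sorted by likelihood-ratio p-value") +
    ggplot2::theme_minimal()
}

#' Carrier prevalence by study arm
#'
#' @param object A `cohort_summary` from [summarize_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_summary
#' @export
autoplot.cohort_summary <- function(object, ...) {
  d <- object$carriers %>%
    filter(!.data$gene %in% c("any_gene", "non_brca12"), .data$n_carriers > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$pct,
                                  fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Carriers (% of arm)", fill = NULL,
                  title = "Pathogenic-variant carrier prevalence by arm") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Per-step attrition of the QC harmonisation pipeline
#'
#' @param harmonised A `harmonised_calls` object.
#' @return A ggplot object.
#' @export
plot_attrition <- function(harmonised) {
  d <- harmonised$attrition %>%
    mutate(step = factor(.data$step, levels = .data$step))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "Calls surviving",
                  title = "Call-set attrition by harmonisation step") +
    ggplot2::theme_minimal()
}
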