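#  ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Kaplan-Meier curve
#'
#' @param object A `km_fit`.
#' @param ... Unused.
#' @return A ggplot step curve with censoring marks.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  d <- tidy(object)
  d <- dplyr::bind_rows(tibble::tibble(time = 0, n_risk = object$n,
                                       n_event = 0L, n_censor = 0L,
                                       estimate = 1, std_error = 0), d)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = d[d$n_censor > 0, ], shape = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Days from first treatment",
                  y = "Overall survival probability") +
    ggplot2::theme_minimal()
}

#' Expression-cluster evidence plot
#'
#' Per-cluster mean z-score of each panel gene — the evidence behind the
#' R/S labeling (R: high DNMT3B, low CDA/P15/CTCF).
#'
#' @param object An `expr_clusters`.
#' @param ... Unused.
#' @return A ggplot tile plot.
#' @method autoplot expr_clusters
#' @export
autoplot.expr_clusters <- function(object, ...) {
  ggplot2::ggplot(object$gene_means,
                  ggplot2::aes(x = .data$gene, y = .data$cluster,
                               fill = .data$mean_z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = "Expression cluster",
                  fill = "mean z") +
    ggplot2::theme_minimal()
}

#' Methylation-cluster summary plot
#'
#' Mean CGI methylation per cluster, labeled normal-like / intermediate /
#' CIMP-like.
#'
#' @param object A `meth_clusters`.
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @method autoplot meth_clusters
#' @export
autoplot.meth_clusters <- function(object, ...) {
  d <- tibble::tibble(label = object$labels,
                      cgi_mean = object$cgi_mean,
                      n = as.integer(table(object$assignment$cluster)))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$label,
                                                     .data$cgi_mean),
                                  y = .data$cgi_mean)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("n=", .data$n)),
                       vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "Mean CGI methylation") +
    ggplot2::theme_minimal()
}

#' Forest plot of a model report
#'
#' @param object A `surv_model`.
#' @param ... Unused.
#' @return A ggplot forest plot of hazard or odds ratios with 95% CIs.
#' @method autoplot surv_model
#' @export
autoplot.surv_model <- function(object, ...) {
  d <- object$report[!object$report$non_estimable, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = ifelse(object$effect == "hazard_ratio",
                             "Hazard ratio (95% CI)",
                             "Odds ratio (95% CI)"),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' z4 waterfall plot
#'
#' Patients ordered by z4 score, colored by response; the dashed line at
#' the threshold separates predicted-resistant (left) from
#' predicted-sensitive.
#'
#' @param z4_table Tibble with `patient_id`, `z4` and optionally `response`.
#' @param threshold Decision threshold (default 0).
#' @return A ggplot bar chart.
#' @export
plot_z4_waterfall <- function(z4_table, threshold = 0) {
  d <- z4_table[!is.na(z4_table$z4), , drop = FALSE]
  d <- d[order(d$z4), , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  aes <- if ("response" %in% names(d)) {
    ggplot2::aes(x = .data$rank, y = .data$z4,
                 fill = .data$response %in% c("CR", "CRp", "CRi"))
  } else {
    ggplot2::aes(x = .data$rank, y = .data$z4)
  }
  p <- ggplot2::ggplot(d, aes) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "Patients (ordered)", y = "z4 score",
                  fill = "CRc") +
    ggplot2::theme_minimal()
  p
}

#' Volcano-style plot of permutation DMC results
#'
#' @param dmc A [permutation_dmc()] tibble.
#' @param alpha Significance line.
#' @return A ggplot scatter of effect size vs -log10 empirical p.
#' @export
plot_dmc <- function(dmc, alpha = 0.05) {
  ggplot2::ggplot(dmc, ggplot2::aes(x = .data$observed,
                                    y = -log10(.data$p))) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "|mean methylation difference|",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
}
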