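#' Plot MSEA results as an enrichment dot chart
#'
#' Shows `-log10(q)` per gene set, faceted by tissue (and cohort when
#' several are present), with the FDR threshold drawn as a dashed line.
#'
#' @param object A `msea_result` or `msea_meta` tibble.
#' @param fdr_alpha Threshold line (default 0.05).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.msea_result <- function(object, fdr_alpha = 0.05, ...) {
  df <- as_tibble(object) %>%
    mutate(neglog_q = -log10(pmax(.data$q, 1e-300)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$neglog_q,
                                        y = stats::reorder(.data$set_id,
                                                           .data$neglog_q),
                                        colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = -log10(fdr_alpha), linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10](q)), y = NULL,
                  colour = "FDR significant") +
    ggplot2::theme_minimal()
  if ("cohort" %in% names(df) && n_distinct(df$cohort) > 1L) {
    p + ggplot2::facet_grid(ggplot2::vars(.data$tissue),
                            ggplot2::vars(.data$cohort))
  } else {
    p + ggplot2::facet_wrap(ggplot2::vars(.data$tissue))
  }
}

#' @rdname autoplot.msea_result
#' @export
autoplot.msea_meta <- function(object, fdr_alpha = 0.05, ...) {
  autoplot.msea_result(object, fdr_alpha = fdr_alpha, ...)
}

#' Plot key-driver results
#'
#' Lollipop chart of the enrichment z-score of the top-ranked key drivers per
#' superset and network.
#'
#' @param object A `kda_result` tibble.
#' @param top_k Drivers shown per (superset, tissue, network) (default 5).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.kda_result <- function(object, top_k = 5L, ...) {
  df <- as_tibble(object) %>%
    group_by(.data$set_id, .data$tissue, .data$network) %>%
    arrange(.data$p, desc(.data$x), .by_group = TRUE) %>%
    slice_head(n = top_k) %>%
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z,
                                   y = stats::reorder(.data$node, .data$z),
                                   colour = .data$significant)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$node)) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(ggplot2::vars(.data$set_id),
                        ggplot2::vars(.data$tissue, .data$network),
                        scales = "free_y") +
    ggplot2::labs(x = "neighborhood enrichment z", y = NULL,
                  colour = "FDR significant") +
    ggplot2::theme_minimal()
}

#' Forest plot of the EMR paired screen
#'
#' Mean pre-to-post C-peptide difference per drug with its two-sided 95%
#' confidence interval, faceted by window length.
#'
#' @param object An `emr_screen` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.emr_screen <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_diff, y = .data$drug,
                                   colour = .data$flagged)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$window_days)) +
    ggplot2::labs(x = "mean C-peptide difference (nmol/l), post - pre",
                  y = NULL, colour = "flagged") +
    ggplot2::theme_minimal()
}
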