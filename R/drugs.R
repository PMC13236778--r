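#' Filter connectivity-map style drug signatures by tau score
#'
#' Keeps (drug, tissue group) records whose `|median_tau|` meets the threshold
#' (the sign carries direction information that is deliberately not used, as
#' the direction of the drug effect is not inferred), then aggregates per drug
#' across its retained groups. Candidates are sorted by descending score, ties
#' by drug id.
#'
#' @param records Tibble with columns `drug`, `tissue_group`, `median_tau`
#'   (tau in `[-100, 100]`).
#' @param tau_min Threshold on `|median_tau|` (default 90).
#' @param aggregate `"mean_abs"` (default): mean of `|median_tau|` over
#'   retained groups; `"abs_mean"`: absolute value of the mean tau.
#' @return Tibble with columns `drug`, `score`, `n_groups`, `groups_hit`.
#' @export
filter_lincs <- function(records, tau_min = 90,
                         aggregate = c("mean_abs", "abs_mean")) {
  assert_cols(records, c("drug", "tissue_group", "median_tau"), "records")
  aggregate <- match.arg(aggregate)
  if (any(abs(records$median_tau) > 100)) {
    abort("`median_tau` must lie in [-100, 100]")
  }
  records %>%
    filter(abs(.data$median_tau) >= tau_min) %>%
    group_by(.data$drug) %>%
    summarise(
      score = if (aggregate == "mean_abs") mean(abs(.data$median_tau))
              else abs(mean(.data$median_tau)),
      n_groups = n_distinct(.data$tissue_group),
      groups_hit = paste(sort(unique(.data$tissue_group)), collapse = ","),
      .groups = "drop") %>%
    arrange(desc(.data$score), .data$drug)
}

#' Filter recurrence-style drug signatures by significance, rank and spread
#'
#' Per tissue keeps drugs that are significant (`p < p_max`, strict) and
#' within the top `top_n` ranks, then keeps drugs that survive in at least
#' `min_appearances` tissues. Candidates are sorted by descending appearance
#' count, ties by drug id.
#'
#' @param records Tibble with columns `drug`, `tissue`, `p`, `rank`; one row
#'   per (drug, tissue).
#' @param p_max Significance threshold (strict; default 0.05).
#' @param top_n Per-tissue rank cutoff (default 100).
#' @param min_appearances Minimum number of surviving tissues (default 5).
#' @return Tibble with columns `drug`, `n_tissues`, `tissues_hit`.
#' @export
filter_pharmomics <- function(records, p_max = 0.05, top_n = 100L,
                              min_appearances = 5L) {
  assert_cols(records, c("drug", "tissue", "p", "rank"), "records")
  if (anyDuplicated(records[, c("drug", "tissue")])) {
    abort("duplicate (drug, tissue) rows in `records`")
  }
  records %>%
    filter(.data$p < p_max, .data$rank <= top_n) %>%
    group_by(.data$drug) %>%
    summarise(n_tissues = n_distinct(.data$tissue),
              tissues_hit = paste(sort(unique(.data$tissue)), collapse = ","),
              .groups = "drop") %>%
    filter(.data$n_tissues >= min_appearances) %>%
    arrange(desc(.data$n_tissues), .data$drug)
}
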