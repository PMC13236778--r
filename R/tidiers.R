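#' Glance at an MSEA run
#'
#' @param x A `msea_result`.
#' @param ... Ignored.
#' @return One-row tibble with set counts and the run configuration summary.
#' @export
glance.msea_result <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_sets = nrow(x),
    n_significant = sum(x$significant),
    min_q = if (nrow(x)) min(x$q) else NA_real_,
    n_perm = cfg$n_perm %||% NA_integer_,
    fdr_alpha = cfg$fdr_alpha %||% NA_real_
  )
}

#' Glance at a key-driver run
#'
#' @param x A `kda_result`.
#' @param ... Ignored.
#' @return One-row tibble with candidate and driver counts.
#' @export
glance.kda_result <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_nodes = n_distinct(x$node),
    n_supersets = n_distinct(x$set_id),
    n_significant = sum(x$significant)
  )
}

#' Glance at an EMR screen
#'
#' @param x An `emr_screen`.
#' @param ... Ignored.
#' @return One-row tibble with drug/window/flag counts.
#' @export
glance.emr_screen <- function(x, ...) {
  tibble(
    n_drugs = n_distinct(x$drug),
    n_windows = n_distinct(x$window_days),
    n_testable = sum(x$testable),
    n_flagged = sum(x$flagged)
  )
}
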