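#' Prune GWAS markers by linkage disequilibrium
#'
#' Greedy LD pruning: markers are processed in ascending GWAS p-value (ties
#' broken by lexicographic marker id) and a marker is removed when it is in LD
#' (`r2 > r2_max`, strict) with an already-retained marker. Among retained
#' markers no pair exceeds the threshold, and the most significant marker of
#' every LD-redundant group is kept.
#'
#' @param markers Tibble with columns `marker_id`, `pvalue` (one cohort;
#'   marker ids must be unique).
#' @param ld Tibble with columns `marker_a`, `marker_b`, `r2`; pairs that
#'   reference markers absent from `markers` are skipped with a warning.
#' @param r2_max LD threshold in `[0, 1]`; pairs with `r2 > r2_max` are
#'   redundant. Default 0.7.
#' @return The rows of `markers` that survive pruning, in input order.
#' @examples
#' m <- tibble::tibble(marker_id = c("a", "b"), pvalue = c(1e-8, 1e-3))
#' ld <- tibble::tibble(marker_a = "a", marker_b = "b", r2 = 0.8)
#' prune_ld(m, ld)
#' @export
prune_ld <- function(markers, ld, r2_max = 0.7) {
  assert_cols(markers, c("marker_id", "pvalue"), "markers")
  assert_cols(ld, c("marker_a", "marker_b", "r2"), "ld")
  assert_fraction(r2_max, "r2_max")
  if (anyDuplicated(markers$marker_id)) {
    abort(paste("duplicate marker ids in `markers`;",
                "prune each cohort separately"))
  }
  if (any(markers$pvalue <= 0 | markers$pvalue > 1)) {
    abort("marker p-values must lie in (0, 1]")
  }
  if (any(ld$r2 < 0 | ld$r2 > 1)) abort("LD r2 must lie in [0, 1]")

  ids <- markers$marker_id
  ld <- ld[ld$r2 > r2_max, , drop = FALSE]
  known <- ld$marker_a %in% ids & ld$marker_b %in% ids
  if (any(!known)) {
    warn(sprintf("prune_ld: skipping %d LD pair(s) referencing unknown markers",
                 sum(!known)))
    ld <- ld[known, , drop = FALSE]
  }
  n <- length(ids)
  idx <- seq_len(n)
  a <- match(ld$marker_a, ids)
  b <- match(ld$marker_b, ids)
  adj <- split(c(b, a), c(a, b))  # symmetric adjacency over threshold pairs

  retained <- logical(n)
  for (i in idx[order(markers$pvalue, ids)]) {
    nb <- adj[[as.character(i)]]
    if (is.null(nb) || !any(retained[nb])) retained[i] <- TRUE
  }
  markers[retained, , drop = FALSE]
}

#' Map retained markers to genes through tissue-specific eQTLs
#'
#' Joins an LD-pruned marker table against one tissue's eQTL records. The
#' marker universe of the resulting map is the number of retained markers with
#' at least one eQTL gene in that tissue; markers without any eQTL are outside
#' the universe, so downstream enrichment expectations are computed over
#' mappable markers only.
#'
#' @param markers Retained markers (output of [prune_ld()]), needing at least
#'   a `marker_id` column.
#' @param eqtls Tibble with columns `marker_id`, `gene_id`, `tissue`.
#' @param tissue Tissue label to map through; must be present in `eqtls`.
#' @return A tibble of distinct (`marker_id`, `gene_id`) rows with attributes
#'   `tissue` and `n_universe`, of class `marker_gene_map`.
#' @export
map_markers_to_genes <- function(markers, eqtls, tissue) {
  assert_cols(markers, "marker_id", "markers")
  assert_cols(eqtls, c("marker_id", "gene_id", "tissue"), "eqtls")
  if (!tissue %in% eqtls$tissue) {
    abort(sprintf("tissue '%s' not present in the eQTL table", tissue))
  }
  rows <- eqtls %>%
    filter(.data$tissue == !!tissue,
           .data$marker_id %in% markers$marker_id) %>%
    distinct(.data$marker_id, .data$gene_id) %>%
    arrange(.data$marker_id, .data$gene_id)
  if (nrow(rows) == 0L) {
    warn(sprintf("no retained marker maps to any gene in tissue '%s'", tissue))
  }
  structure(rows,
            tissue = tissue,
            n_universe = n_distinct(rows$marker_id),
            class = c("marker_gene_map", class(rows)))
}
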