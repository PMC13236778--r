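#' Merge overlapping gene sets into independent supersets
#'
#' Iterative agglomeration of redundant gene sets. At every step all current
#' pairs are scored by overlap ratio `rho(A, B) = |A n B| / min(|A|, |B|)` and
#' a one-sided Fisher (hypergeometric upper-tail) p-value over a fixed gene
#' universe. A pair qualifies when `rho >= overlap_ratio_min` and
#' `p < pair_p_max / n_pairs_tested` (Bonferroni over the pairs scored in that
#' iteration). The qualifying pair with the largest `rho` (ties broken by the
#' lexicographically smallest set-id pair) is merged into the union of its
#' genes, and the procedure repeats until no pair qualifies. Unmerged sets
#' pass through as singleton supersets. The procedure is deterministic and
#' terminates after at most n - 1 merges.
#'
#' @param catalog Long gene-set tibble with columns `set_id`, `gene`.
#' @param universe Gene-id universe for the Fisher test; defaults to the union
#'   of all catalog genes.
#' @param overlap_ratio_min Minimum overlap ratio, in (0, 1]. Default 0.33.
#' @param pair_p_max Per-family Fisher significance level before the Bonferroni
#'   correction. Default 0.05.
#' @return A tibble with columns `set_id` (superset id `SSxx`), `label`
#'   (concatenated member ids) and `gene`, carrying a `"provenance"` attribute
#'   (tibble `superset_id`, `member_set_id`); class `superset_catalog`.
#' @export
merge_gene_sets <- function(catalog, universe = NULL,
                            overlap_ratio_min = 0.33, pair_p_max = 0.05) {
  assert_cols(catalog, c("set_id", "gene"), "catalog")
  assert_fraction(overlap_ratio_min, "overlap_ratio_min")
  if (overlap_ratio_min <= 0) abort("`overlap_ratio_min` must be in (0, 1]")
  assert_fraction(pair_p_max, "pair_p_max")
  if (nrow(catalog) == 0L) {
    warn("merge_gene_sets: empty catalog")
    out <- tibble(set_id = character(), label = character(), gene = character())
    attr(out, "provenance") <- tibble(superset_id = character(),
                                      member_set_id = character())
    class(out) <- c("superset_catalog", class(out))
    return(out)
  }
  sets <- purrr::map(split(catalog$gene, catalog$set_id), unique)
  if (is.null(universe)) universe <- unique(catalog$gene)
  if (!all(catalog$gene %in% universe)) {
    abort("`universe` must contain every catalog gene")
  }
  n_universe <- length(universe)
  members <- purrr::map(names(sets), identity)  # provenance per current set
  names(members) <- names(sets)

  repeat {
    ids <- names(sets)
    n <- length(ids)
    if (n < 2L) break
    pairs <- utils::combn(n, 2L)
    n_pairs <- ncol(pairs)
    sizes <- lengths(sets)
    stats <- purrr::map_dfr(seq_len(n_pairs), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      k <- length(intersect(sets[[i1]], sets[[i2]]))
      tibble(i1 = i1, i2 = i2, k = k,
             rho = k / min(sizes[i1], sizes[i2]),
             log_p = phyper(k - 1, sizes[i1], n_universe - sizes[i1],
                            sizes[i2], lower.tail = FALSE, log.p = TRUE))
    })
    qualifies <- stats$rho >= overlap_ratio_min &
      stats$log_p < log(pair_p_max / n_pairs)
    if (!any(qualifies)) break
    cand <- stats[qualifies, , drop = FALSE]
    key_a <- pmin(ids[cand$i1], ids[cand$i2])
    key_b <- pmax(ids[cand$i1], ids[cand$i2])
    pick <- order(-cand$rho, key_a, key_b)[1]
    i1 <- cand$i1[pick]; i2 <- cand$i2[pick]
    merged_genes <- union(sets[[i1]], sets[[i2]])
    merged_members <- sort(union(members[[ids[i1]]], members[[ids[i2]]]))
    new_id <- min(ids[i1], ids[i2])
    sets[[ids[i1]]] <- NULL
    sets[[ids[i2]]] <- NULL
    members[[ids[i1]]] <- NULL
    members[[ids[i2]]] <- NULL
    sets[[new_id]] <- merged_genes
    members[[new_id]] <- merged_members
  }

  ord <- order(names(sets))
  sets <- sets[ord]
  members <- members[ord]
  ss_ids <- sprintf("SS%02d", seq_along(sets))
  out <- purrr::map_dfr(seq_along(sets), function(i) {
    tibble(set_id = ss_ids[i],
           label = paste(members[[i]], collapse = "+"),
           gene = sort(sets[[i]]))
  })
  attr(out, "provenance") <- purrr::map_dfr(seq_along(sets), function(i) {
    tibble(superset_id = ss_ids[i], member_set_id = members[[i]])
  })
  class(out) <- c("superset_catalog", class(out))
  out
}

#' Provenance of a merged superset catalog
#'
#' @param supersets A [merge_gene_sets()] result.
#' @return Tibble with columns `superset_id`, `member_set_id`.
#' @export
superset_provenance <- function(supersets) {
  attr(supersets, "provenance") %||%
    abort("`supersets` carries no provenance attribute")
}

#' Confirm supersets with a second cross-cohort enrichment round
#'
#' Re-runs MSEA on the superset catalog for every (tissue, cohort) pair and
#' combines cohorts by [meta_msea()], mirroring the confirmation round run on
#' the combined cohorts after merging. Supersets that fail the FDR threshold
#' are flagged (`significant = FALSE`), not dropped.
#'
#' @param supersets Superset catalog (tibble with `set_id`, `gene`).
#' @param maps Either a named list of [map_markers_to_genes()] results (one
#'   per tissue, shared by all cohorts) or a nested list keyed by cohort and
#'   then tissue when pruning was cohort-specific.
#' @param gwas Association tibble covering all cohorts (column `cohort`).
#' @param cfg An [msea_config()].
#' @return A `msea_meta` tibble over all tissues.
#' @export
confirm_supersets <- function(supersets, maps, gwas, cfg = msea_config()) {
  assert_cols(supersets, c("set_id", "gene"), "supersets")
  if (nrow(supersets) == 0L) abort("`supersets` is empty")
  assert_cols(gwas, c("marker_id", "pvalue", "cohort"), "gwas")
  cohorts <- sort(unique(gwas$cohort))
  if (length(cohorts) < 2L) {
    abort("confirmation requires at least two cohorts")
  }
  nested <- !is.data.frame(maps[[1]])
  per_run <- purrr::map_dfr(cohorts, function(co) {
    tissue_maps <- if (nested) maps[[co]] else maps
    purrr::map_dfr(tissue_maps, function(map) {
      msea(map, gwas[gwas$cohort == co, , drop = FALSE], supersets, cfg)
    })
  })
  meta_msea(per_run, fdr_alpha = cfg$fdr_alpha)
}
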