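#' Configuration for marker-set enrichment analysis
#'
#' @param quantiles Strictly increasing vector of fractions in (0, 1); the
#'   statistic sums standardized exceedances over these universe score
#'   quantiles. Default `c(0.50, 0.75, 0.90, 0.95, 0.99)`.
#' @param kappa Non-negative stabilizing constant added to the expected count
#'   in the denominator of each quantile term. Default 1.
#' @param n_perm Number of gene-label permutations for the null (minimum 100).
#' @param min_genes,max_genes Sets with a mapped-gene count outside
#'   `[min_genes, max_genes]` are excluded before testing.
#' @param fdr_alpha FDR threshold for the significance flag.
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `msea_config`.
#' @export
msea_config <- function(quantiles = c(0.50, 0.75, 0.90, 0.95, 0.99),
                        kappa = 1, n_perm = 2000L, min_genes = 10L,
                        max_genes = 500L, fdr_alpha = 0.05, seed = 1L) {
  if (any(quantiles <= 0) || any(quantiles >= 1) ||
      any(diff(quantiles) <= 0)) {
    abort("`quantiles` must be strictly increasing fractions in (0, 1)")
  }
  if (!is.numeric(kappa) || kappa < 0) abort("`kappa` must be non-negative")
  n_perm <- assert_count(n_perm, "n_perm", min = 100L)
  min_genes <- assert_count(min_genes, "min_genes")
  max_genes <- assert_count(max_genes, "max_genes", min = min_genes)
  assert_fraction(fdr_alpha, "fdr_alpha")
  seed <- assert_count(seed, "seed", min = 0L)
  structure(list(quantiles = quantiles, kappa = kappa, n_perm = n_perm,
                 min_genes = min_genes, max_genes = max_genes,
                 fdr_alpha = fdr_alpha, seed = seed),
            class = "msea_config")
}

#' Multi-quantile chi-square-like enrichment statistic
#'
#' For each quantile `q` of the universe score distribution, counts how many
#' member markers score at or above that quantile (`O_q`), compares with the
#' expected count `E_q = n_member * (1 - q)`, and sums the stabilized
#' standardized differences: `X = sum_q (O_q - E_q) / sqrt(E_q + kappa)`.
#' Scores are association strengths on the `-log10(p)` scale; member markers
#' are counted once even when mapped through several member genes (the caller
#' passes deduplicated scores).
#'
#' @param member_scores Scores of the (deduplicated) member markers.
#' @param universe_scores Scores of all markers in the mappable universe.
#' @param quantiles,kappa See [msea_config()].
#' @return The statistic X (a single number).
#' @examples
#' # universe 1..100, members are the top 10 scores, single quantile 0.9
#' msea_statistic(91:100, 1:100, quantiles = 0.9, kappa = 1)
#' @export
msea_statistic <- function(member_scores, universe_scores,
                           quantiles = c(0.50, 0.75, 0.90, 0.95, 0.99),
                           kappa = 1) {
  if (length(member_scores) == 0L) {
    abort("the statistic is undefined for an empty member set")
  }
  if (length(universe_scores) < length(member_scores)) {
    abort("the universe cannot be smaller than the member set")
  }
  tau <- quantile(universe_scores, quantiles, names = FALSE, type = 7)
  o <- vapply(tau, function(t) sum(member_scores >= t), numeric(1))
  e <- length(member_scores) * (1 - quantiles)
  sum((o - e) / sqrt(e + kappa))
}

# fast inner statistic: `lv` holds, per member marker, how many of the K
# increasing thresholds it reaches; O_k follows by reverse cumulation
x_from_levels <- function(lv, k, e, kappa) {
  o <- rev(cumsum(rev(tabulate(lv, nbins = k))))
  sum((o - e) / sqrt(e + kappa))
}

#' Marker-set enrichment analysis for one (tissue, cohort) run
#'
#' Scores every gene set in a catalog for enrichment of strong GWAS signal
#' among its eQTL-mapped markers. The observed statistic (see
#' [msea_statistic()]) is compared against a permutation null built by
#' reassigning set membership uniformly over the mappable genes, keeping each
#' gene's marker list intact - this preserves the markers-per-gene structure
#' that inflates naive marker-permutation nulls. The permutation moments give
#' a z-score and a Gaussian upper-tail p-value (needed to resolve p well below
#' 1/n_perm); the empirical permutation p-value is reported alongside for
#' diagnostics. Benjamini-Hochberg FDR is computed across the sets of the run.
#'
#' @param map A [map_markers_to_genes()] result (or any tibble with
#'   `marker_id`, `gene_id` columns).
#' @param gwas Single-cohort association tibble with columns `marker_id`,
#'   `pvalue` (and optionally `cohort`).
#' @param catalog Long gene-set tibble with columns `set_id`, `gene`.
#' @param cfg An [msea_config()].
#' @return A tibble of class `msea_result` with one row per tested set:
#'   `set_id`, `tissue`, `cohort`, `n_genes`, `n_markers`, `x`, `z`, `p`,
#'   `p_emp`, `q`, `significant`.
#' @export
msea <- function(map, gwas, catalog, cfg = msea_config()) {
  assert_cols(map, c("marker_id", "gene_id"), "map")
  assert_cols(gwas, c("marker_id", "pvalue"), "gwas")
  assert_cols(catalog, c("set_id", "gene"), "catalog")
  stopifnot(inherits(cfg, "msea_config"))
  tissue <- attr(map, "tissue") %||% NA_character_
  cohort <- if ("cohort" %in% names(gwas)) unique(gwas$cohort) else NA_character_
  if (length(cohort) > 1L) {
    abort("`gwas` contains several cohorts; run msea() per cohort")
  }

  uni <- sort(unique(map$marker_id))
  pv <- gwas$pvalue[match(uni, gwas$marker_id)]
  if (anyNA(pv)) {
    warn(sprintf("msea: dropping %d mapped marker(s) missing from the GWAS table",
                 sum(is.na(pv))))
    uni <- uni[!is.na(pv)]
    pv <- pv[!is.na(pv)]
  }
  if (!length(uni)) abort("empty marker universe after matching map and GWAS")
  score <- -log10(pv)
  tau <- quantile(score, cfg$quantiles, names = FALSE, type = 7)
  level <- findInterval(score, tau)        # thresholds reached per marker
  k <- length(tau)

  gene_markers <- split(match(map$marker_id, uni), map$gene_id)
  gene_markers <- purrr::map(gene_markers, function(ix) unique(ix[!is.na(ix)]))
  gene_markers <- gene_markers[lengths(gene_markers) > 0L]
  all_genes <- names(gene_markers)

  sets <- split(catalog$gene, catalog$set_id)
  sets <- purrr::map(sets, function(g) intersect(unique(g), all_genes))
  n_mapped <- lengths(sets)
  keep <- n_mapped >= cfg$min_genes & n_mapped <= cfg$max_genes
  if (any(!keep)) {
    inform(sprintf(
      "msea: excluded %d set(s) outside the [%d, %d] mapped-gene range",
      sum(!keep), cfg$min_genes, cfg$max_genes))
  }
  sets <- sets[keep]
  if (!length(sets)) {
    warn("msea: no set passes the size filter; returning an empty result")
    return(empty_msea_result(tissue, cohort, cfg))
  }

  n_pool <- length(all_genes)
  res <- withr::with_seed(cfg$seed, {
    purrr::map_dfr(names(sets), function(sid) {
      genes <- sets[[sid]]
      member <- unique(unlist(gene_markers[genes], use.names = FALSE))
      n_mem <- length(member)
      e <- n_mem * (1 - cfg$quantiles)
      x <- x_from_levels(level[member], k, e, cfg$kappa)
      n_g <- length(genes)
      xb <- vapply(seq_len(cfg$n_perm), function(b) {
        gs <- sample.int(n_pool, n_g)
        mem_b <- unique(unlist(gene_markers[gs], use.names = FALSE))
        eb <- length(mem_b) * (1 - cfg$quantiles)
        x_from_levels(level[mem_b], k, eb, cfg$kappa)
      }, numeric(1))
      s <- sd(xb)
      if (!is.finite(s) || s == 0) {
        warn(sprintf("msea: degenerate permutation null for set '%s'; p set to 1",
                     sid))
        z <- 0
        p <- 1
      } else {
        z <- (x - mean(xb)) / s
        p <- pnorm(z, lower.tail = FALSE)
      }
      tibble(set_id = sid, tissue = tissue, cohort = cohort,
             n_genes = n_g, n_markers = n_mem, x = x, z = z, p = p,
             p_emp = (1 + sum(xb >= x)) / (cfg$n_perm + 1))
    })
  })
  res$q <- bh_fdr(res$p)
  res$significant <- res$q < cfg$fdr_alpha
  structure(res, config = cfg, class = c("msea_result", class(res)))
}

empty_msea_result <- function(tissue, cohort, cfg) {
  structure(
    tibble(set_id = character(), tissue = character(), cohort = character(),
           n_genes = integer(), n_markers = integer(), x = numeric(),
           z = numeric(), p = numeric(), p_emp = numeric(), q = numeric(),
           significant = logical()),
    config = cfg, class = c("msea_result", "tbl_df", "tbl", "data.frame"))
}

#' Cross-cohort meta-analysis of MSEA results
#'
#' Combines per-cohort MSEA z-scores for the same tissue and catalog with an
#' unweighted Stouffer sum, `z_meta = sum_c(z_c) / sqrt(n_cohorts)`, followed
#' by a Gaussian upper-tail p-value and Benjamini-Hochberg FDR across sets
#' (within tissue). Sets absent from one or more cohorts are excluded with a
#' warning.
#'
#' @param results MSEA results for two or more cohorts, row-bound (columns
#'   `set_id`, `cohort`, `z`, optionally `tissue`).
#' @param fdr_alpha FDR threshold for the significance flag.
#' @return A tibble of class `msea_meta` with columns `set_id`, `tissue`,
#'   `n_cohorts`, `z_meta`, `p`, `q`, `significant`.
#' @export
meta_msea <- function(results, fdr_alpha = 0.05) {
  assert_cols(results, c("set_id", "cohort", "z"), "results")
  if (!"tissue" %in% names(results)) results$tissue <- NA_character_
  n_coh <- n_distinct(results$cohort)
  if (n_coh < 2L) abort("meta_msea needs results from at least two cohorts")
  meta <- results %>%
    group_by(.data$tissue, .data$set_id) %>%
    summarise(n_cohorts = n_distinct(.data$cohort),
              z_meta = sum(.data$z) / sqrt(n_distinct(.data$cohort)),
              .groups = "drop")
  incomplete <- meta$n_cohorts < n_coh
  if (any(incomplete)) {
    warn(sprintf("meta_msea: excluded %d set(s) absent from some cohort",
                 sum(incomplete)))
    meta <- meta[!incomplete, , drop = FALSE]
  }
  meta$p <- pnorm(meta$z_meta, lower.tail = FALSE)
  meta <- meta %>%
    group_by(.data$tissue) %>%
    mutate(q = bh_fdr(.data$p)) %>%
    ungroup() %>%
    mutate(significant = .data$q < fdr_alpha) %>%
    arrange(.data$tissue, .data$set_id)
  structure(meta, class = c("msea_meta", class(meta)))
}

#' Gene sets significant in at least one mapping set
#'
#' Implements the discovery rule "significant if FDR below the threshold in at
#' least one SNP-gene mapping set": returns the distinct set ids whose q-value
#' beats `fdr_alpha` in any (tissue, cohort) run present in `results`.
#'
#' @param results One or more row-bound MSEA (or meta-MSEA) result tibbles.
#' @param fdr_alpha FDR threshold.
#' @return Character vector of significant set ids, sorted.
#' @export
significant_sets <- function(results, fdr_alpha = 0.05) {
  assert_cols(results, c("set_id", "q"), "results")
  sort(unique(results$set_id[results$q < fdr_alpha]))
}
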