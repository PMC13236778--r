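#' Read a gene-set catalog from a GMT file
#'
#' Parses the standard tab-separated GMT format (one gene set per line:
#' identifier, description, then one or more gene ids) into a long tibble with
#' one row per (set, gene). Duplicate gene ids within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_id`, `description`, `gene`.
#' @seealso [write_gmt()], [exclude_genes()]
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warn(sprintf("GMT file '%s' is empty; returning an empty catalog", path))
    return(tibble(set_id = character(), description = character(),
                  gene = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    abort(sprintf(
      "malformed GMT line(s) %s in '%s': expected >= 3 tab-separated fields",
      paste(bad, collapse = ", "), path))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(sprintf("duplicate set_id in '%s': %s", path,
                  paste(dup, collapse = ", ")))
  }
  purrr::map2_dfr(fields, ids, function(f, id) {
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    tibble(set_id = id, description = f[[2]], gene = genes)
  })
}

#' Write a gene-set catalog to a GMT file
#'
#' @param catalog A tibble with columns `set_id`, `gene` and optionally
#'   `description`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  assert_cols(catalog, c("set_id", "gene"), "catalog")
  desc <- if ("description" %in% names(catalog)) catalog$description else ""
  catalog <- mutate(catalog, .desc = desc)
  lines <- catalog %>%
    group_by(.data$set_id) %>%
    summarise(line = paste(c(.data$set_id[1], .data$.desc[1],
                             unique(.data$gene)), collapse = "\t"),
              .groups = "drop") %>%
    arrange(.data$set_id)
  writeLines(lines$line, path)
  invisible(path)
}

#' Remove blocklisted genes from a catalog
#'
#' Removes genes matching an explicit blocklist and/or one of a vector of id
#' prefixes (by default ids beginning `"HLA-"`, the usual convention for the
#' human MHC class I/II genes). Sets emptied by the exclusion are dropped and
#' their number reported.
#'
#' @param catalog Long gene-set tibble with columns `set_id`, `gene`.
#' @param blocklist Character vector of exact gene ids to remove.
#' @param prefixes Character vector of id prefixes to remove (case-sensitive);
#'   set to `character(0)` to disable prefix matching.
#' @return The filtered catalog.
#' @export
exclude_genes <- function(catalog, blocklist = character(0),
                          prefixes = "HLA-") {
  assert_cols(catalog, c("set_id", "gene"), "catalog")
  hit <- catalog$gene %in% blocklist
  for (pref in prefixes) {
    hit <- hit | startsWith(catalog$gene, pref)
  }
  out <- catalog[!hit, , drop = FALSE]
  dropped <- setdiff(unique(catalog$set_id), unique(out$set_id))
  if (length(dropped)) {
    inform(sprintf("exclude_genes: dropped %d set(s) emptied by exclusion",
                   length(dropped)))
  }
  out
}

#' Cross-catalog overlap enrichment
#'
#' Fold enrichment and one-sided Fisher (hypergeometric upper-tail) p-value for
#' the overlap between two subsets of a common universe, e.g. the gene sets
#' found significant in each of two independent GWAS cohorts. The fold is the
#' observed overlap divided by its expectation under independence,
#' `k / (n1 * n2 / N)`; the p-value is `P[X >= k]` for
#' `X ~ Hypergeometric(N, n1, n2)`, computed in the log domain so that
#' extremely small values do not underflow.
#'
#' @param universe_n Size of the common universe (total sets tested).
#' @param n1,n2 Sizes of the two subsets.
#' @param k_overlap Observed overlap.
#' @return A one-row tibble with columns `universe_n`, `n1`, `n2`, `k_overlap`,
#'   `expected`, `fold`, `fisher_p`, `log10_fisher_p`.
#' @examples
#' overlap_enrichment(1827, 187, 143, 121)
#' @export
overlap_enrichment <- function(universe_n, n1, n2, k_overlap) {
  universe_n <- assert_count(universe_n, "universe_n")
  n1 <- assert_count(n1, "n1", min = 0L)
  n2 <- assert_count(n2, "n2", min = 0L)
  k_overlap <- assert_count(k_overlap, "k_overlap", min = 0L)
  if (n1 * n2 == 0L) abort("fold is undefined when n1 * n2 == 0")
  if (k_overlap > min(n1, n2) || max(n1, n2) > universe_n) {
    abort("need k_overlap <= min(n1, n2) <= universe_n")
  }
  expected <- n1 * n2 / universe_n
  log_p <- phyper(k_overlap - 1L, n1, universe_n - n1, n2,
                  lower.tail = FALSE, log.p = TRUE)
  out <- tibble(
    universe_n = universe_n, n1 = n1, n2 = n2, k_overlap = k_overlap,
    expected = expected,
    fold = k_overlap / expected,
    fisher_p = exp(log_p),
    log10_fisher_p = log_p / log(10)
  )
  class(out) <- c("overlap_enrichment", class(out))
  out
}
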