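#' Strain-contrast t-tests on expression or protein levels
#'
#' Classic (equal-variance) Student's two-sample t-test between two strains,
#' applied per gene/protein (and per assay and sex group when those columns
#' are present), with the direction of the contrast reported separately as the
#' sign of `mean(strain_a) - mean(strain_b)`. The test is two-sided; Welch's
#' unequal-variance form is available via `welch = TRUE`.
#'
#' @param expr Long tibble with columns `id`, `strain`, `value` and optionally
#'   `assay` and `sex`.
#' @param ids Optional subset of ids to test (default: all).
#' @param strain_a,strain_b Strains to contrast (defaults NOD vs B6).
#' @param welch Use Welch's unequal-variance test instead of the pooled form.
#' @param by_sex Stratify by sex when a `sex` column is present (default
#'   `TRUE`); set `FALSE` to pool sexes.
#' @return Tibble with one row per tested group: `id`, (`assay`, `sex`,)
#'   `n_a`, `n_b`, `mean_a`, `mean_b`, `t`, `p`, `direction`.
#' @export
strain_ttest <- function(expr, ids = NULL, strain_a = "NOD", strain_b = "B6",
                         welch = FALSE, by_sex = TRUE) {
  assert_cols(expr, c("id", "strain", "value"), "expr")
  if (!is.null(ids)) expr <- filter(expr, .data$id %in% ids)
  expr <- filter(expr, .data$strain %in% c(strain_a, strain_b))
  group_cols <- intersect(c("id", "assay", if (by_sex) "sex"), names(expr))
  expr %>%
    group_by(dplyr::across(dplyr::all_of(group_cols))) %>%
    summarise(
      n_a = sum(.data$strain == strain_a),
      n_b = sum(.data$strain == strain_b),
      mean_a = mean(.data$value[.data$strain == strain_a]),
      mean_b = mean(.data$value[.data$strain == strain_b]),
      test = list(two_sample_t(.data$value[.data$strain == strain_a],
                               .data$value[.data$strain == strain_b],
                               welch = welch)),
      .groups = "drop") %>%
    tidyr::unnest_wider("test") %>%
    mutate(direction = sign(.data$mean_a - .data$mean_b))
}

# pooled/Welch two-sample t with explicit handling of zero-variance groups
two_sample_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("strain_ttest needs >= 2 replicates per strain group")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  fit <- t.test(a, b, var.equal = !welch)
  list(t = unname(fit$statistic), p = fit$p.value)
}

#' Overlap of key drivers (and their neighbors) with an external DEG list
#'
#' Exact id intersection, case-folded, of a key-driver list with a list of
#' differentially expressed genes, plus the per-driver overlap of direct
#' network neighbors. Case folding harmonizes human (upper-case) and mouse
#' (title-case) symbol conventions; no orthology mapping is attempted.
#'
#' @param kds Character vector of key-driver gene ids.
#' @param degs Character vector of DEG ids.
#' @param neighbors Optional named list: per key driver, the ids of its direct
#'   network neighbors.
#' @return A list of class `deg_overlap` with elements `kd_overlap` (tibble
#'   `kd`, `matched_deg`) and `neighbor_overlap` (tibble `kd`, `neighbor`,
#'   `matched_deg`).
#' @examples
#' deg_overlap(c("CBL", "SOS1", "FYN"), c("Cbl", "Sos1"))
#' @export
deg_overlap <- function(kds, degs, neighbors = NULL) {
  if (!length(degs)) warn("deg_overlap: empty DEG list")
  key <- toupper(degs)
  match_ids <- function(x) {
    hit <- match(toupper(x), key)
    tibble(id = x[!is.na(hit)], matched_deg = degs[hit[!is.na(hit)]])
  }
  kd_hit <- match_ids(unique(kds))
  nb_hit <- if (is.null(neighbors)) {
    tibble(kd = character(), neighbor = character(), matched_deg = character())
  } else {
    purrr::imap_dfr(neighbors, function(nb, kd) {
      m <- match_ids(unique(nb))
      if (nrow(m) == 0L) return(NULL)
      tibble(kd = kd, neighbor = m$id, matched_deg = m$matched_deg)
    })
  }
  structure(list(
    kd_overlap = rename(kd_hit, kd = "id"),
    neighbor_overlap = nb_hit
  ), class = "deg_overlap")
}

#' @export
tidy.deg_overlap <- function(x, ...) {
  bind_rows(
    mutate(x$kd_overlap, role = "key_driver", neighbor = NA_character_),
    mutate(x$neighbor_overlap, role = "neighbor")
  ) %>%
    select("role", "kd", "neighbor", "matched_deg")
}

#' @export
print.deg_overlap <- function(x, ...) {
  cat(sprintf("DEG overlap: %d key driver(s), %d neighbor hit(s)\n",
              nrow(x$kd_overlap), nrow(x$neighbor_overlap)))
  if (nrow(x$kd_overlap)) print(x$kd_overlap)
  invisible(x)
}
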