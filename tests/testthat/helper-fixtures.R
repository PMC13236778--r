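# small, fast study configurations used across the suite
small_cfg <- function(seed = 1L, n_drugs = 10L,
                      true_drug_ids = c("DRUG01", "DRUG02"),
                      n_patients = 60L, n_exposed = 15L, ...) {
  sim_config(
    seed = seed,
    n_markers = 600L, n_genes = 150L, n_ld_blocks = 200L,
    tissues = c("blood", "islet"),
    n_sets = 15L, set_size_range = c(15L, 25L),
    network_nodes = 150L,
    n_drugs = n_drugs, true_drug_ids = true_drug_ids,
    n_patients = n_patients, n_exposed = n_exposed,
    ...
  )
}

fast_msea_cfg <- function(seed = 1L, ...) {
  msea_config(n_perm = 200L, seed = seed, ...)
}

fast_kda_cfg <- function(seed = 1L, ...) {
  kda_config(n_perm = 200L, seed = seed, ...)
}

# long-format catalog from a named list of gene vectors
catalog_of <- function(sets) {
  dplyr::bind_rows(lapply(names(sets), function(id) {
    tibble::tibble(set_id = id, gene = sets[[id]])
  }))
}

# exhaustive-merge oracle: applies every qualifying merge order and returns
# the distinct final partitions of original set ids (as canonical strings)
all_merge_partitions <- function(sets, universe_n,
                                 rho_min = 0.33, p_max = 0.05) {
  partition_key <- function(members) {
    paste(sort(vapply(members, function(m) paste(sort(m), collapse = "+"),
                      character(1))), collapse = "|")
  }
  results <- new.env()
  recurse <- function(sets, members) {
    ids <- names(sets)
    n <- length(ids)
    qual <- NULL
    if (n >= 2L) {
      pairs <- utils::combn(n, 2L)
      np <- ncol(pairs)
      sz <- lengths(sets)
      for (j in seq_len(np)) {
        i1 <- pairs[1, j]; i2 <- pairs[2, j]
        k <- length(intersect(sets[[i1]], sets[[i2]]))
        rho <- k / min(sz[i1], sz[i2])
        lp <- phyper(k - 1, sz[i1], universe_n - sz[i1], sz[i2],
                     lower.tail = FALSE, log.p = TRUE)
        if (rho >= rho_min && lp < log(p_max / np)) qual <- rbind(qual, c(i1, i2))
      }
    }
    if (is.null(qual)) {
      assign(partition_key(members), TRUE, envir = results)
      return(invisible())
    }
    for (r in seq_len(nrow(qual))) {
      i1 <- qual[r, 1]; i2 <- qual[r, 2]
      s2 <- sets; m2 <- members
      nid <- min(ids[c(i1, i2)])
      new_genes <- union(sets[[i1]], sets[[i2]])
      new_members <- sort(union(members[[i1]], members[[i2]]))
      s2[[ids[i1]]] <- NULL; s2[[ids[i2]]] <- NULL
      m2[[ids[i1]]] <- NULL; m2[[ids[i2]]] <- NULL
      s2[[nid]] <- new_genes; m2[[nid]] <- new_members
      recurse(s2, m2)
    }
  }
  recurse(sets, setNames(lapply(names(sets), identity), names(sets)))
  ls(results)
}

merge_partition_key <- function(supersets) {
  prov <- superset_provenance(supersets)
  paste(sort(tapply(prov$member_set_id, prov$superset_id,
                    function(x) paste(sort(x), collapse = "+"))),
        collapse = "|")
}
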