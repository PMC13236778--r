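pipeline_stages <- c("simulate", "map", "msea", "meta", "merge", "kda",
                     "drugs", "emr", "validate")

write_stage <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  path
}

#' Run the full synthetic-data analysis chain
#'
#' Orchestrates the nine pipeline stages from one configuration: simulate all
#' inputs; LD-prune markers and map them to genes per tissue and cohort; run
#' MSEA per (tissue, cohort); meta-analyze cohorts per tissue; merge the
#' significant sets into supersets and confirm them on the combined cohorts;
#' run key-driver analysis on every simulated network; apply both drug
#' repositioning filters; screen candidate drugs in the EMR tables; and
#' validate designated key-driver genes against the strain expression panel.
#' Every stage writes its outputs as TSV under `out_dir` and is recorded in a
#' `manifest.json` with input hashes, a config echo and the seed; a rerun with
#' the same configuration reproduces byte-identical result files.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created; must be empty unless
#'   `overwrite = TRUE`).
#' @param msea_cfg,kda_cfg Stage configurations; seeds default to `cfg$seed`.
#' @param overlap_ratio_min,pair_p_max Superset merging thresholds.
#' @param tau_min,p_max,top_n,min_appearances Drug filter thresholds.
#' @param windows,min_duration_days,min_patients,alpha EMR screen settings.
#' @param overwrite Allow writing into a non-empty directory.
#' @return The path to `out_dir`, invisibly; side effect: stage TSVs and
#'   `manifest.json`.
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir,
                         msea_cfg = msea_config(seed = cfg$seed),
                         kda_cfg = kda_config(seed = cfg$seed),
                         overlap_ratio_min = 0.33, pair_p_max = 0.05,
                         tau_min = 90, p_max = 0.05, top_n = 100L,
                         min_appearances = 5L,
                         windows = c(183L, 365L, 730L),
                         min_duration_days = 30L, min_patients = 5L,
                         alpha = 0.05, overwrite = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite) {
    abort(sprintf("output directory '%s' is not empty (use overwrite = TRUE)",
                  out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("netmsea")),
                   config = cfg[setdiff(names(cfg), "planted_hubs")],
                   stages = list())
  files <- character(0)
  note <- function(stage, paths) {
    manifest$stages[[stage]] <<- purrr::map(paths, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)),
           bytes = file.size(p))
    })
    files <<- c(files, paths)
  }

  # -- stage 1: simulate -----------------------------------------------------
  sim <- sim_all(cfg)
  net_tissues <- unique(sim$networks$tissue)
  missing_net <- setdiff(cfg$tissues, net_tissues)
  if (length(missing_net)) {
    abort(sprintf("tissue label(s) present in eQTL config but absent from networks: %s",
                  paste(missing_net, collapse = ", ")))
  }
  paths <- c(
    write_stage(sim$gwas$associations, out_dir, "gwas_associations.tsv"),
    write_stage(sim$gwas$ld, out_dir, "ld_pairs.tsv"),
    write_stage(sim$eqtl, out_dir, "eqtl.tsv"),
    write_stage(sim$sets, out_dir, "gene_sets.tsv"),
    write_stage(sim$networks, out_dir, "networks.tsv"),
    write_stage(sim$drugs$lincs, out_dir, "drug_lincs.tsv"),
    write_stage(sim$drugs$pharmomics, out_dir, "drug_pharmomics.tsv"),
    write_stage(sim$emr$patients, out_dir, "emr_patients.tsv"),
    write_stage(sim$emr$prescriptions, out_dir, "emr_prescriptions.tsv"),
    write_stage(sim$emr$labs, out_dir, "emr_labs.tsv"),
    write_stage(sim$strain, out_dir, "strain_expression.tsv")
  )
  note("simulate", paths)

  # -- stage 2: prune + map --------------------------------------------------
  cohorts <- sort(unique(sim$gwas$associations$cohort))
  pruned <- purrr::map(setNames(cohorts, cohorts), function(co) {
    prune_ld(filter(sim$gwas$associations, .data$cohort == co), sim$gwas$ld)
  })
  maps <- purrr::map(setNames(cohorts, cohorts), function(co) {
    purrr::map(setNames(cfg$tissues, cfg$tissues), function(ts) {
      map_markers_to_genes(pruned[[co]], sim$eqtl, ts)
    })
  })
  map_tbl <- purrr::map_dfr(cohorts, function(co) {
    purrr::map_dfr(cfg$tissues, function(ts) {
      mutate(as_tibble(maps[[co]][[ts]]), tissue = ts, cohort = co)
    })
  })
  note("map", write_stage(map_tbl, out_dir, "marker_gene_maps.tsv"))

  # -- stage 3: msea ---------------------------------------------------------
  msea_res <- purrr::map_dfr(cohorts, function(co) {
    gw <- filter(sim$gwas$associations, .data$cohort == co)
    purrr::map_dfr(cfg$tissues, function(ts) {
      msea(maps[[co]][[ts]], gw, sim$sets, msea_cfg)
    })
  })
  note("msea", write_stage(msea_res, out_dir, "msea_results.tsv"))

  # -- stage 4: meta ---------------------------------------------------------
  meta_res <- if (length(cohorts) >= 2L) meta_msea(msea_res, msea_cfg$fdr_alpha)
              else mutate(msea_res, z_meta = .data$z)
  note("meta", write_stage(meta_res, out_dir, "meta_results.tsv"))

  # -- stage 5: merge + confirm ----------------------------------------------
  sig_ids <- significant_sets(meta_res, msea_cfg$fdr_alpha)
  sig_catalog <- filter(sim$sets, .data$set_id %in% sig_ids)
  if (nrow(sig_catalog)) {
    supersets <- merge_gene_sets(sig_catalog,
                                 universe = unique(sim$sets$gene),
                                 overlap_ratio_min = overlap_ratio_min,
                                 pair_p_max = pair_p_max)
    confirmation <- if (length(cohorts) >= 2L) {
      confirm_supersets(supersets, maps, sim$gwas$associations, msea_cfg)
    } else tibble()
  } else {
    warn("run_pipeline: no significant set; supersets are empty")
    supersets <- merge_gene_sets(tibble(set_id = character(),
                                        gene = character()))
    confirmation <- tibble()
  }
  prov <- superset_provenance(supersets)
  note("merge", c(
    write_stage(supersets, out_dir, "supersets.tsv"),
    write_stage(prov, out_dir, "superset_provenance.tsv"),
    write_stage(confirmation, out_dir, "superset_confirmation.tsv")
  ))

  # -- stage 6: kda ----------------------------------------------------------
  net_keys <- distinct(sim$networks, .data$tissue, .data$network,
                       .data$directed)
  kda_res <- if (nrow(supersets)) {
    purrr::map_dfr(seq_len(nrow(net_keys)), function(i) {
      ed <- filter(sim$networks, .data$tissue == net_keys$tissue[i],
                   .data$network == net_keys$network[i])
      run_kda(ed, supersets, kda_cfg, tissue = net_keys$tissue[i],
              network = net_keys$network[i],
              directed = net_keys$directed[i])
    })
  } else empty_kda_result()
  kda_top <- select_top_kds(kda_res, kda_cfg$fdr_alpha,
                            kda_cfg$top_k_per_superset)
  kda_shared <- if (nrow(kda_top)) {
    cross_network_overlap(filter(kda_top, .data$network == "grn"),
                          filter(kda_top, .data$network == "ppi"))
  } else tibble(tissue = character(), node = character())
  note("kda", c(
    write_stage(kda_res, out_dir, "kda_results.tsv"),
    write_stage(kda_top, out_dir, "kda_top.tsv"),
    write_stage(kda_shared, out_dir, "kda_cross_network.tsv")
  ))

  # -- stage 7: drugs --------------------------------------------------------
  lincs_hits <- filter_lincs(sim$drugs$lincs, tau_min = tau_min)
  pharm_hits <- filter_pharmomics(sim$drugs$pharmomics, p_max = p_max,
                                  top_n = top_n,
                                  min_appearances = min_appearances)
  note("drugs", c(
    write_stage(lincs_hits, out_dir, "drug_candidates_lincs.tsv"),
    write_stage(pharm_hits, out_dir, "drug_candidates_pharmomics.tsv")
  ))

  # -- stage 8: emr ----------------------------------------------------------
  candidates <- union(lincs_hits$drug, pharm_hits$drug)
  emr_res <- emr_screen(sim$emr$prescriptions, sim$emr$labs,
                        drugs = candidates, windows = windows,
                        min_duration_days = min_duration_days,
                        alpha = alpha, min_patients = min_patients)
  note("emr", write_stage(emr_res, out_dir, "emr_screen.tsv"))

  # -- stage 9: strain validation --------------------------------------------
  kd_genes <- attr(sim$strain, "kd_genes")
  strain_res <- strain_ttest(sim$strain, ids = kd_genes)
  note("validate", write_stage(strain_res, out_dir, "strain_validation.tsv"))

  manifest$planted <- list(
    causal_set_ids = cfg$causal_set_ids,
    true_drug_ids = cfg$true_drug_ids,
    responder_drug_ids = cfg$responder_drug_ids,
    planted_hubs = as.list(attr(sim$networks, "planted_hubs")),
    kd_genes = kd_genes
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Summarize a pipeline run directory
#'
#' Reads the stage outputs of a [run_pipeline()] run and tabulates per-tissue
#' significant set counts, the cross-cohort overlap enrichment of significant
#' sets (via [overlap_enrichment()]), superset and key-driver counts, drug
#' candidates and EMR-flagged drugs, together with a recovered-truth section
#' comparing each stage against the planted ground truth in the manifest.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param overlap_counts Optional list with elements `universe_n`, `n1`, `n2`,
#'   `k_overlap` to report an externally tabulated cohort overlap instead of
#'   the one computed from the run.
#' @return A list of class `pipeline_report` with elements `summary` (tibble
#'   metric/value), `overlap` (an [overlap_enrichment()] row or `NULL`) and
#'   `recovered` (tibble of planted-vs-recovered checks).
#' @export
pipeline_report <- function(run_dir, overlap_counts = NULL) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(sprintf("no manifest.json under '%s'", run_dir))
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  rd <- function(name) {
    p <- file.path(run_dir, name)
    if (!file.exists(p)) abort(sprintf("missing stage output '%s'", name))
    out <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    # empty stage outputs parse as all-character; restore key column types
    for (col in intersect(c("significant", "flagged", "testable"), names(out))) {
      out[[col]] <- as.logical(out[[col]])
    }
    for (col in intersect(c("q", "p", "z", "z_meta"), names(out))) {
      out[[col]] <- as.numeric(out[[col]])
    }
    out
  }
  msea_res <- rd("msea_results.tsv")
  meta_res <- rd("meta_results.tsv")
  supersets <- rd("supersets.tsv")
  kda_top <- rd("kda_top.tsv")
  lincs_hits <- rd("drug_candidates_lincs.tsv")
  pharm_hits <- rd("drug_candidates_pharmomics.tsv")
  emr_res <- rd("emr_screen.tsv")

  per_tissue <- msea_res %>%
    filter(.data$significant) %>%
    count(.data$tissue, .data$cohort, name = "n_significant")

  overlap <- if (!is.null(overlap_counts)) {
    overlap_enrichment(overlap_counts$universe_n, overlap_counts$n1,
                       overlap_counts$n2, overlap_counts$k_overlap)
  } else if (nrow(msea_res)) {
    cohorts <- sort(unique(msea_res$cohort))
    if (length(cohorts) >= 2L) {
      sig <- purrr::map(cohorts[1:2], function(co) {
        significant_sets(filter(msea_res, .data$cohort == co))
      })
      n1 <- length(sig[[1]]); n2 <- length(sig[[2]])
      if (n1 * n2 > 0) {
        overlap_enrichment(n_distinct(msea_res$set_id), n1, n2,
                           length(intersect(sig[[1]], sig[[2]])))
      } else NULL
    } else NULL
  } else NULL

  flagged <- emr_res %>% filter(.data$flagged) %>% pull(.data$drug) %>% unique()
  summary <- tibble(
    metric = c("stages_completed", "tissues", "cohorts",
               "significant_sets_meta", "supersets", "top_key_drivers",
               "lincs_candidates", "pharmomics_candidates",
               "emr_flagged_drugs"),
    value = c(length(manifest$stages), n_distinct(msea_res$tissue),
              n_distinct(msea_res$cohort),
              length(significant_sets(meta_res)),
              n_distinct(supersets$set_id), nrow(kda_top),
              nrow(lincs_hits), nrow(pharm_hits), length(flagged))
  )

  pl <- manifest$planted
  n_causal_sig <- length(intersect(pl$causal_set_ids,
                                   significant_sets(meta_res)))
  n_drug_rec <- length(intersect(pl$true_drug_ids,
                                 union(lincs_hits$drug, pharm_hits$drug)))
  n_resp_flag <- length(intersect(pl$responder_drug_ids, flagged))
  recovered <- tibble(
    check = c("causal_sets_significant", "true_drugs_recovered",
              "responder_drugs_flagged"),
    planted = c(length(pl$causal_set_ids), length(pl$true_drug_ids),
                length(pl$responder_drug_ids)),
    recovered = c(n_causal_sig, n_drug_rec, n_resp_flag)
  )
  structure(list(summary = summary, per_tissue = per_tissue,
                 overlap = overlap, recovered = recovered, seed = manifest$seed),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %s)\n", x$seed))
  print(x$summary, n = Inf)
  if (!is.null(x$overlap)) {
    cat(sprintf("\nCohort overlap: %d / expected %.2f -> fold %.2f (p = %.3g)\n",
                x$overlap$k_overlap, x$overlap$expected, x$overlap$fold,
                x$overlap$fisher_p))
  }
  cat("\nRecovered planted truth:\n")
  print(x$recovered, n = Inf)
  invisible(x)
}
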