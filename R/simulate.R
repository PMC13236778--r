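#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the synthetic-data module into one validated list.
#' The defaults define a desk-scale study in which two independent GWAS
#' cohorts share a planted causal gene set, markers sit in LD blocks, each
#' tissue has its own marker-to-gene eQTL map, networks are scale-free with
#' planted hub neighborhoods, drug-signature tables contain designated true
#' drugs that pass both repositioning filters, and EMR records contain a
#' responder drug that raises post-exposure C-peptide.
#'
#' @param seed Integer seed; fixing it makes every generator byte-identical
#'   across runs.
#' @param n_markers Number of GWAS markers.
#' @param n_genes Number of genes.
#' @param n_ld_blocks Number of LD blocks markers are partitioned into.
#' @param block_r2 Pairwise r-squared assigned to every within-block marker
#'   pair, in `[0, 1]`.
#' @param tissues Character vector of tissue labels.
#' @param n_sets Number of gene sets in the catalog.
#' @param set_size_range Length-2 integer vector, inclusive bounds on set size.
#' @param causal_set_ids Ids (among the generated `SET%03d` ids) whose member
#'   genes carry planted association signal.
#' @param effect_mu Non-negative mean shift of the association z-scores of
#'   markers mapped to causal-set genes; 0 gives fully null data.
#' @param n_cohorts Number of independent GWAS cohorts sharing the same causal
#'   sets.
#' @param network_nodes Nodes per simulated network (must not exceed
#'   `n_genes`).
#' @param planted_hubs Optional tibble with columns `node`, `set_id` naming
#'   hub genes to plant for given sets; `NULL` plants one hub per causal set,
#'   chosen automatically.
#' @param n_drugs Number of drugs in the signature tables.
#' @param true_drug_ids Drug ids (among the generated `DRUG%02d` ids) built to
#'   pass both repositioning filters; all others are decoys that pass neither.
#' @param n_patients Number of EMR patients.
#' @param n_exposed Patients exposed to each drug in the EMR tables.
#' @param responder_drug_ids Drugs whose exposure shifts post-window C-peptide.
#' @param responder_drug_effect Shift (nmol/l) added to post-exposure
#'   C-peptide for responder drugs.
#' @param max_markers_per_gene Upper bound on eQTL markers per gene per tissue.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_markers = 3000L,
                       n_genes = 600L,
                       n_ld_blocks = 1000L,
                       block_r2 = 0.9,
                       tissues = c("blood", "islet", "pancreas"),
                       n_sets = 50L,
                       set_size_range = c(20L, 40L),
                       causal_set_ids = "SET001",
                       effect_mu = 3,
                       n_cohorts = 2L,
                       network_nodes = 500L,
                       planted_hubs = NULL,
                       n_drugs = 30L,
                       true_drug_ids = c("DRUG01", "DRUG02", "DRUG03"),
                       n_patients = 150L,
                       n_exposed = 30L,
                       responder_drug_ids = "DRUG01",
                       responder_drug_effect = 0.3,
                       max_markers_per_gene = 6L) {
  seed <- assert_count(seed, "seed", min = 0L)
  n_markers <- assert_count(n_markers, "n_markers")
  n_genes <- assert_count(n_genes, "n_genes")
  n_ld_blocks <- assert_count(n_ld_blocks, "n_ld_blocks")
  assert_fraction(block_r2, "block_r2")
  n_sets <- assert_count(n_sets, "n_sets")
  n_cohorts <- assert_count(n_cohorts, "n_cohorts")
  network_nodes <- assert_count(network_nodes, "network_nodes")
  n_drugs <- assert_count(n_drugs, "n_drugs")
  n_patients <- assert_count(n_patients, "n_patients")
  n_exposed <- assert_count(n_exposed, "n_exposed")
  max_markers_per_gene <- assert_count(max_markers_per_gene,
                                       "max_markers_per_gene")
  if (length(set_size_range) != 2L || set_size_range[1] > set_size_range[2] ||
      set_size_range[1] < 1L) {
    abort("`set_size_range` must be c(min, max) with 1 <= min <= max")
  }
  if (set_size_range[2] > n_genes) {
    abort("`set_size_range` upper bound exceeds n_genes")
  }
  if (!is.numeric(effect_mu) || effect_mu < 0) {
    abort("`effect_mu` must be non-negative")
  }
  if (network_nodes > n_genes) {
    abort("`network_nodes` must not exceed `n_genes`")
  }
  if (n_genes > n_markers * max_markers_per_gene) {
    abort("`n_genes` exceeds n_markers * max_markers_per_gene")
  }
  set_ids <- sprintf("SET%03d", seq_len(n_sets))
  if (!all(causal_set_ids %in% set_ids)) {
    abort("`causal_set_ids` must be a subset of the generated set ids")
  }
  drug_ids <- sprintf("DRUG%02d", seq_len(n_drugs))
  if (!all(true_drug_ids %in% drug_ids)) {
    abort("`true_drug_ids` must be a subset of the generated drug ids")
  }
  if (!all(responder_drug_ids %in% drug_ids)) {
    abort("`responder_drug_ids` must be a subset of the generated drug ids")
  }
  if (!is.null(planted_hubs)) {
    assert_cols(planted_hubs, c("node", "set_id"), "planted_hubs")
  }
  if (length(tissues) < 1L) abort("need at least one tissue label")
  structure(list(
    seed = seed, n_markers = n_markers, n_genes = n_genes,
    n_ld_blocks = n_ld_blocks, block_r2 = block_r2, tissues = tissues,
    n_sets = n_sets, set_size_range = as.integer(set_size_range),
    causal_set_ids = causal_set_ids, effect_mu = effect_mu,
    n_cohorts = n_cohorts, network_nodes = network_nodes,
    planted_hubs = planted_hubs, n_drugs = n_drugs,
    true_drug_ids = true_drug_ids, n_patients = n_patients,
    n_exposed = n_exposed, responder_drug_ids = responder_drug_ids,
    responder_drug_effect = responder_drug_effect,
    max_markers_per_gene = max_markers_per_gene
  ), class = "sim_config")
}

sim_marker_ids <- function(cfg) sprintf("M%05d", seq_len(cfg$n_markers))
sim_gene_ids <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))
sim_drug_ids <- function(cfg) sprintf("DRUG%02d", seq_len(cfg$n_drugs))

#' Simulate a gene-set catalog
#'
#' Draws `n_sets` gene sets with sizes uniform on `set_size_range`, sampled
#' without replacement within each set from the gene pool. Causal sets (those
#' in `cfg$causal_set_ids`) are ordinary sets; their special role is only that
#' [sim_gwas()] plants association signal on the markers mapped to their
#' genes.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `set_id`, `description`, `source`, `gene`.
#' @export
sim_gene_sets <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- sim_gene_ids(cfg)
  withr::with_seed(cfg$seed + 101L, {
    sizes <- sample(seq(cfg$set_size_range[1], cfg$set_size_range[2]),
                    cfg$n_sets, replace = TRUE)
    purrr::map_dfr(seq_len(cfg$n_sets), function(i) {
      id <- sprintf("SET%03d", i)
      tibble(
        set_id = id,
        description = if (id %in% cfg$causal_set_ids) "causal" else "null",
        source = "pathway",
        gene = sample(genes, sizes[i])
      )
    })
  })
}

#' Simulate per-tissue eQTL maps
#'
#' Each tissue draws its own marker pool (70% of all markers, so tissue pools
#' overlap partially), then assigns each gene between 1 and
#' `max_markers_per_gene` markers from that pool. Every gene receives at least
#' one marker in every tissue unless a restricted `gene_panels` list is given.
#'
#' @param cfg A [sim_config()].
#' @param gene_panels Optional named list (tissue -> character vector of gene
#'   ids) restricting which genes a tissue maps; tissues absent from the list
#'   map all genes.
#' @return A tibble with columns `marker_id`, `gene_id`, `tissue`.
#' @export
sim_eqtl <- function(cfg, gene_panels = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  markers <- sim_marker_ids(cfg)
  genes <- sim_gene_ids(cfg)
  pool_size <- max(cfg$max_markers_per_gene, ceiling(0.7 * cfg$n_markers))
  withr::with_seed(cfg$seed + 202L, {
    purrr::map_dfr(cfg$tissues, function(ts) {
      pool <- sample(markers, pool_size)
      panel <- if (!is.null(gene_panels) && ts %in% names(gene_panels)) {
        intersect(genes, gene_panels[[ts]])
      } else genes
      k <- sample(cfg$max_markers_per_gene, length(panel), replace = TRUE)
      purrr::map_dfr(seq_along(panel), function(i) {
        tibble(marker_id = sample(pool, k[i]), gene_id = panel[i], tissue = ts)
      })
    })
  })
}

#' Simulate GWAS summary statistics for one or more cohorts
#'
#' Markers are partitioned into LD blocks; every within-block pair carries
#' `r2 = block_r2` in the LD table. Association z-scores are standard normal
#' except for markers that any tissue's eQTL map links to a causal-set gene,
#' which are drawn `Normal(effect_mu, 1)`; two-sided p-values are reported.
#' The same causal sets (and hence the same causal markers) are planted in
#' every cohort, with independent noise per cohort.
#'
#' @param cfg A [sim_config()].
#' @param eqtl eQTL table from [sim_eqtl()]; regenerated from `cfg` if `NULL`.
#' @param sets Gene-set catalog from [sim_gene_sets()]; regenerated if `NULL`.
#' @return A list with elements `associations` (tibble `marker_id`, `chrom`,
#'   `pos`, `pvalue`, `cohort`), `ld` (tibble `marker_a`, `marker_b`, `r2`)
#'   and `causal_markers` (character vector).
#' @export
sim_gwas <- function(cfg, eqtl = NULL, sets = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(eqtl)) eqtl <- sim_eqtl(cfg)
  if (is.null(sets)) sets <- sim_gene_sets(cfg)
  markers <- sim_marker_ids(cfg)
  block <- rep(seq_len(cfg$n_ld_blocks),
               each = ceiling(cfg$n_markers / cfg$n_ld_blocks))[
                 seq_len(cfg$n_markers)]
  causal_genes <- sets$gene[sets$set_id %in% cfg$causal_set_ids]
  causal_markers <- sort(unique(
    eqtl$marker_id[eqtl$gene_id %in% causal_genes]))
  is_causal <- markers %in% causal_markers

  ld <- purrr::map_dfr(split(markers, block), function(ms) {
    if (length(ms) < 2L) return(NULL)
    idx <- utils::combn(length(ms), 2L)
    tibble(marker_a = ms[idx[1, ]], marker_b = ms[idx[2, ]], r2 = cfg$block_r2)
  })

  assoc <- withr::with_seed(cfg$seed + 303L, {
    purrr::map_dfr(seq_len(cfg$n_cohorts), function(co) {
      mu <- ifelse(is_causal, cfg$effect_mu, 0)
      z <- rnorm(cfg$n_markers, mean = mu, sd = 1)
      tibble(
        marker_id = markers,
        chrom = as.character(((block - 1L) %% 22L) + 1L),
        pos = seq_len(cfg$n_markers) * 1000L,
        pvalue = pmax(2 * pnorm(-abs(z)), .Machine$double.xmin),
        cohort = sprintf("cohort%d", co)
      )
    })
  })
  list(associations = assoc, ld = ld, causal_markers = causal_markers)
}

# place a hub for each planted (node, set) pair and relabel its neighborhood
# so that >= `share` of direct neighbors carry member-gene labels; label swaps
# preserve the simple-graph topology
plant_hub <- function(graph, hub_label, set_genes, protected, share = 0.8) {
  labels <- igraph::V(graph)$name
  deg <- igraph::degree(graph, mode = "all")
  max_deg <- floor(length(set_genes) / share)
  ok <- deg >= 5L & deg <= max_deg & !(labels %in% set_genes) &
    !(labels %in% protected)
  if (!any(ok)) {
    abort("no eligible hub vertex (degree in [5, |set|/share]) to plant")
  }
  # highest-degree eligible vertex; ties broken by label for determinism
  cand <- which(ok)
  cand <- cand[order(-deg[cand], labels[cand])]
  v <- cand[1]
  # move the requested hub label onto vertex v (swap if it exists elsewhere)
  if (labels[v] != hub_label) {
    j <- match(hub_label, labels)
    if (!is.na(j)) labels[j] <- labels[v]
    labels[v] <- hub_label
  }
  nb <- as.integer(igraph::neighbors(graph, v, mode = "all"))
  need <- ceiling(share * length(nb))
  in_set <- labels[nb] %in% set_genes
  to_convert <- nb[!in_set & !(labels[nb] %in% protected)]
  avail <- setdiff(set_genes, c(labels[nb], labels[v]))
  n_conv <- max(0L, need - sum(in_set))
  if (n_conv > length(to_convert) || n_conv > length(avail)) {
    abort("cannot plant hub: not enough convertible neighbors or spare member genes")
  }
  for (i in seq_len(n_conv)) {
    w <- to_convert[i]
    g <- avail[i]
    j <- match(g, labels)
    if (!is.na(j)) labels[j] <- labels[w]
    labels[w] <- g
  }
  igraph::V(graph)$name <- labels
  list(graph = graph, hub = hub_label,
       protected = c(protected, labels[c(v, nb)]))
}

#' Simulate scale-free tissue networks with planted hubs
#'
#' One network per (tissue, kind) is grown by seeded preferential attachment
#' (`igraph::sample_pa`, m = 2), vertices are labeled with gene ids, and for
#' each planted (hub, set) pair the hub's direct neighborhood is relabeled so
#' that at least 80% of neighbors are member genes of the set. With
#' `cfg$planted_hubs = NULL` one hub per causal set is planted and named
#' automatically.
#'
#' @param cfg A [sim_config()].
#' @param sets Gene-set catalog; regenerated from `cfg` if `NULL`.
#' @param kinds Network kinds to generate, subset of `c("grn", "ppi")`; `grn`
#'   edges are directed, `ppi` undirected.
#' @return A tibble with columns `tissue`, `network`, `from`, `to`,
#'   `directed`, with attribute `"planted_hubs"` (tibble `tissue`, `network`,
#'   `node`, `set_id`).
#' @export
sim_networks <- function(cfg, sets = NULL, kinds = c("grn", "ppi")) {
  stopifnot(inherits(cfg, "sim_config"))
  kinds <- match.arg(kinds, c("grn", "ppi"), several.ok = TRUE)
  if (is.null(sets)) sets <- sim_gene_sets(cfg)
  genes <- sim_gene_ids(cfg)
  set_list <- split(sets$gene, sets$set_id)

  withr::with_seed(cfg$seed + 404L, {
    planted_all <- list()
    edges <- purrr::map_dfr(cfg$tissues, function(ts) {
      purrr::map_dfr(kinds, function(kind) {
        g <- igraph::sample_pa(cfg$network_nodes, power = 1, m = 2,
                               directed = FALSE)
        igraph::V(g)$name <- sample(genes, cfg$network_nodes)
        g <- igraph::simplify(g)

        plants <- cfg$planted_hubs
        if (is.null(plants)) {
          plants <- tibble(node = NA_character_, set_id = cfg$causal_set_ids)
        }
        protected <- character(0)
        planted_rows <- purrr::map_dfr(seq_len(nrow(plants)), function(i) {
          sid <- plants$set_id[i]
          set_genes <- set_list[[sid]]
          if (is.null(set_genes)) abort(sprintf("unknown planted set '%s'", sid))
          hub_label <- plants$node[i]
          if (is.na(hub_label)) {
            # auto mode: the hub keeps whatever label the chosen vertex has,
            # communicated back through the return value
            hub_label <- "<auto>"
          }
          if (hub_label == "<auto>") {
            # choose eligible vertex first, then use its own label as hub id
            labels <- igraph::V(g)$name
            deg <- igraph::degree(g)
            ok <- deg >= 5L & deg <= floor(length(set_genes) / 0.8) &
              !(labels %in% set_genes) & !(labels %in% protected)
            if (!any(ok)) abort("no eligible hub vertex for auto planting")
            cand <- which(ok)
            cand <- cand[order(-deg[cand], labels[cand])]
            hub_label <- labels[cand[1]]
          }
          res <- plant_hub(g, hub_label, set_genes, protected)
          g <<- res$graph
          protected <<- res$protected
          tibble(tissue = ts, network = kind, node = res$hub, set_id = sid)
        })
        # post-condition audit: planting must actually hold
        for (i in seq_len(nrow(planted_rows))) {
          nb <- names(igraph::neighbors(g, planted_rows$node[i]))
          share <- mean(nb %in% set_list[[planted_rows$set_id[i]]])
          if (length(nb) < 5L || share < 0.8) {
            abort("planted hub failed its neighborhood share audit")
          }
        }
        planted_all[[paste(ts, kind)]] <<- planted_rows
        el <- igraph::as_edgelist(g)
        tibble(tissue = ts, network = kind, from = el[, 1], to = el[, 2],
               directed = kind == "grn")
      })
    })
    attr(edges, "planted_hubs") <- bind_rows(planted_all)
    edges
  })
}

#' Simulate drug-signature tables
#'
#' Generates a connectivity-map style table (drug x tissue group with a median
#' tau score in `[-100, 100]`) and a recurrence-style table (drug x tissue
#' with a p-value and within-tissue rank). Designated true drugs exceed
#' `|median tau| >= 90` in all five tau tissue groups and are significant
#' (p < 0.05) with rank <= 100 in at least five recurrence tissues; decoys
#' satisfy neither filter.
#'
#' @param cfg A [sim_config()].
#' @return A list with tibbles `lincs` (`drug`, `tissue_group`, `median_tau`)
#'   and `pharmomics` (`drug`, `tissue`, `p`, `rank`).
#' @export
sim_drug_signatures <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  drugs <- sim_drug_ids(cfg)
  is_true <- drugs %in% cfg$true_drug_ids
  tau_groups <- c("blood", "lymphocyte", "pancreas", "islet", "non_hla")
  rec_tissues <- c("islet", "adipose", "blood", "lymphocyte", "macrophage",
                   "monocyte", "pancreas")
  withr::with_seed(cfg$seed + 505L, {
    lincs <- purrr::map_dfr(seq_along(drugs), function(i) {
      tau <- if (is_true[i]) {
        sample(c(-1, 1), length(tau_groups), replace = TRUE) *
          runif(length(tau_groups), 90.5, 99.5)
      } else {
        runif(length(tau_groups), -85, 85)
      }
      tibble(drug = drugs[i], tissue_group = tau_groups, median_tau = tau)
    })
    pharm <- purrr::map_dfr(seq_along(drugs), function(i) {
      n_hit <- if (is_true[i]) 5L else sample(0:2, 1)
      hit <- rec_tissues %in% sample(rec_tissues, n_hit)
      p <- ifelse(hit, runif(length(rec_tissues), 0.001, 0.04),
                  runif(length(rec_tissues), 0.06, 0.95))
      tibble(drug = drugs[i], tissue = rec_tissues, p = p)
    })
    pharm <- pharm %>%
      group_by(.data$tissue) %>%
      mutate(rank = rank(.data$p, ties.method = "first")) %>%
      ungroup()
    list(lincs = lincs, pharmomics = pharm)
  })
}

#' Simulate an EMR cohort (patients, prescriptions, C-peptide labs)
#'
#' Every drug is prescribed to `n_exposed` patients as two prescription rows
#' spanning a merged episode of at least 60 days. Each exposure contributes
#' three C-peptide measurements in the year before the earliest start and
#' three in the year after the latest end; responder-drug post-window values
#' are shifted up by `responder_drug_effect` nmol/l, other drugs by 0.
#' Patients carry an individual baseline so pre and post values are paired.
#'
#' @param cfg A [sim_config()].
#' @return A list with tibbles `patients` (`patient_id`, `birth_year`, `sex`),
#'   `prescriptions` (`patient_id`, `drug`, `start_date`, `end_date`) and
#'   `labs` (`patient_id`, `date`, `analyte`, `value`, `unit`).
#' @export
sim_emr <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_patients < 5L) {
    abort("n_patients < 5: no drug could ever be testable in the screen")
  }
  if (cfg$n_exposed > cfg$n_patients) {
    abort("`n_exposed` cannot exceed `n_patients`")
  }
  ids <- sprintf("P%04d", seq_len(cfg$n_patients))
  drugs <- sim_drug_ids(cfg)
  lab_sd <- 0.15
  withr::with_seed(cfg$seed + 606L, {
    patients <- tibble(
      patient_id = ids,
      birth_year = sample(1950:2005, cfg$n_patients, replace = TRUE),
      sex = sample(c("F", "M"), cfg$n_patients, replace = TRUE)
    )
    baseline <- setNames(pmax(rnorm(cfg$n_patients, 0.5, 0.15), 0.05), ids)
    origin <- as.Date("2019-01-01")
    rx <- list()
    labs <- list()
    for (d in drugs) {
      exposed <- sample(ids, cfg$n_exposed)
      eff <- if (d %in% cfg$responder_drug_ids) cfg$responder_drug_effect else 0
      for (p in exposed) {
        s <- origin + sample(0:730, 1)
        dur <- sample(60:200, 1)
        e <- s + dur
        rx[[length(rx) + 1L]] <- tibble(
          patient_id = p, drug = d,
          start_date = c(s, s + 30L), end_date = c(s + 20L, e)
        )
        pre_dates <- s - sample(10:330, 3)
        post_dates <- e + sample(10:330, 3)
        labs[[length(labs) + 1L]] <- tibble(
          patient_id = p,
          date = c(pre_dates, post_dates),
          analyte = "C-peptide",
          value = pmax(baseline[[p]] +
                         rnorm(6, 0, lab_sd) + c(0, 0, 0, eff, eff, eff),
                       0.001),
          unit = "nmol/l"
        )
      }
    }
    list(patients = patients,
         prescriptions = bind_rows(rx),
         labs = bind_rows(labs) %>% arrange(.data$patient_id, .data$date))
  })
}

#' Simulate strain-by-gene expression and protein matrices
#'
#' Emulates an inbred-strain islet profiling panel: eight mouse strains
#' including the autoimmune-diabetic NOD, the obesity/type-2-like NZO and the
#' non-diabetic B6, both sexes, five replicates per (gene, strain, sex) group.
#' Designated key-driver genes are shifted up by two within-group standard
#' deviations in NOD animals only; all other genes are null everywhere.
#'
#' @param cfg A [sim_config()].
#' @param sets Gene-set catalog; regenerated from `cfg` if `NULL`.
#' @param kd_genes Designated up-in-NOD genes; defaults to the first five
#'   genes of the first causal set.
#' @param n_background Number of additional null genes to include.
#' @param n_rep Replicates per (gene, strain, sex) group.
#' @return A tibble with columns `id`, `assay` (rna/protein), `strain`, `sex`,
#'   `replicate`, `value`, with attribute `"kd_genes"`.
#' @export
sim_strain_expression <- function(cfg, sets = NULL, kd_genes = NULL,
                                  n_background = 10L, n_rep = 5L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(sets)) sets <- sim_gene_sets(cfg)
  if (is.null(kd_genes)) {
    first_causal <- sets$gene[sets$set_id == cfg$causal_set_ids[1]]
    kd_genes <- head(sort(first_causal), 5L)
  }
  strains <- c("NOD", "NZO", "B6", "AJ", "129", "CAST", "PWK", "WSB")
  background <- head(setdiff(sim_gene_ids(cfg), kd_genes), n_background)
  panel <- c(kd_genes, background)
  grid <- tidyr::expand_grid(
    id = panel, assay = c("rna", "protein"), strain = strains,
    sex = c("F", "M"), replicate = seq_len(n_rep)
  )
  withr::with_seed(cfg$seed + 707L, {
    base_mean <- setNames(rnorm(2L * length(panel), 10, 2),
                          paste(rep(panel, each = 2L), c("rna", "protein")))
    grid %>%
      mutate(
        shift = ifelse(.data$id %in% kd_genes & .data$strain == "NOD", 2, 0),
        value = base_mean[paste(.data$id, .data$assay)] + .data$shift +
          rnorm(nrow(grid), 0, 1)
      ) %>%
      select(-"shift") %>%
      structure(kd_genes = kd_genes)
  })
}

#' Simulate every pipeline input at once
#'
#' Convenience wrapper producing a coherent bundle: one gene-set catalog and
#' eQTL map shared by the GWAS generator, networks planted against the causal
#' sets, drug signatures, EMR tables and strain expression matrices.
#'
#' @param cfg A [sim_config()].
#' @return A named list with elements `config`, `sets`, `eqtl`, `gwas`,
#'   `networks`, `drugs`, `emr`, `strain`.
#' @export
sim_all <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  sets <- sim_gene_sets(cfg)
  eqtl <- sim_eqtl(cfg)
  list(
    config = cfg,
    sets = sets,
    eqtl = eqtl,
    gwas = sim_gwas(cfg, eqtl = eqtl, sets = sets),
    networks = sim_networks(cfg, sets = sets),
    drugs = sim_drug_signatures(cfg),
    emr = sim_emr(cfg),
    strain = sim_strain_expression(cfg, sets = sets)
  )
}
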