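test_that("sim_config rejects invalid study conditions", {
  expect_error(sim_config(n_markers = 0), "n_markers")
  expect_error(sim_config(effect_mu = -1), "non-negative")
  expect_error(sim_config(causal_set_ids = "SET999"), "subset")
  expect_error(sim_config(true_drug_ids = "DRUG99"), "subset")
  expect_error(sim_config(network_nodes = 10000), "network_nodes")
  expect_error(sim_config(set_size_range = c(30, 10)), "set_size_range")
  expect_error(sim_config(n_genes = 5000, n_markers = 100,
                          max_markers_per_gene = 2, network_nodes = 100),
               "max_markers_per_gene")
})

test_that("all generators are byte-identical under a fixed seed", {
  a <- sim_all(small_cfg(seed = 7))
  b <- sim_all(small_cfg(seed = 7))
  expect_identical(a$sets, b$sets)
  expect_identical(a$eqtl, b$eqtl)
  expect_identical(a$gwas, b$gwas)
  expect_identical(a$networks, b$networks)
  expect_identical(a$drugs, b$drugs)
  expect_identical(a$emr, b$emr)
  expect_identical(a$strain, b$strain)
})

test_that("null GWAS generator is calibrated at the causal markers", {
  cfg <- small_cfg(seed = 3, effect_mu = 0)
  sim <- sim_all(cfg)
  causal <- sim$gwas$causal_markers
  expect_gt(length(causal), 20)
  assoc <- dplyr::filter(sim$gwas$associations, cohort == "cohort1",
                         marker_id %in% causal)
  frac <- mean(assoc$pvalue < 0.05)
  mc_sd <- sqrt(0.05 * 0.95 / nrow(assoc))
  expect_lt(abs(frac - 0.05), 3 * mc_sd)
})

test_that("planted effect stochastically dominates the null markers", {
  cfg <- small_cfg(seed = 4, effect_mu = 3)
  sim <- sim_all(cfg)
  assoc <- dplyr::filter(sim$gwas$associations, cohort == "cohort1")
  causal <- assoc$marker_id %in% sim$gwas$causal_markers
  expect_lt(median(assoc$pvalue[causal]), median(assoc$pvalue[!causal]))
  # p-values remain valid probabilities
  expect_true(all(assoc$pvalue > 0 & assoc$pvalue <= 1))
})

test_that("eQTL maps stay inside the gene universe and honor gene panels", {
  cfg <- small_cfg(seed = 5)
  eq <- sim_eqtl(cfg)
  expect_true(all(eq$gene_id %in% sprintf("G%04d", 1:cfg$n_genes)))
  expect_true(all(eq$tissue %in% cfg$tissues))
  # every gene mapped in every tissue by default
  counts <- dplyr::count(eq, tissue, gene_id)
  expect_equal(nrow(counts), length(cfg$tissues) * cfg$n_genes)
  # disjoint panels give no shared (marker, gene) rows across the two tissues
  genes <- sprintf("G%04d", 1:cfg$n_genes)
  eq2 <- sim_eqtl(cfg, gene_panels = list(blood = genes[1:40],
                                          islet = genes[41:80]))
  shared <- dplyr::inner_join(
    dplyr::filter(eq2, tissue == "blood")[, c("marker_id", "gene_id")],
    dplyr::filter(eq2, tissue == "islet")[, c("marker_id", "gene_id")],
    by = c("marker_id", "gene_id"))
  expect_equal(nrow(shared), 0)
  expect_identical(sim_eqtl(cfg), eq)
})

test_that("simulated networks are simple, heavy-tailed and carry planted hubs", {
  cfg <- sim_config(seed = 6)  # default size: network_nodes = 500
  sets <- sim_gene_sets(cfg)
  nets <- sim_networks(cfg, sets = sets)
  expect_true(all(nets$from != nets$to))
  ppi <- dplyr::filter(nets, network == "ppi", tissue == "blood")
  canon <- paste(pmin(ppi$from, ppi$to), pmax(ppi$from, ppi$to))
  expect_false(anyDuplicated(canon) > 0)
  g <- as_network(ppi, directed = FALSE)
  deg <- igraph::degree(g)
  expect_gte(max(deg), 5 * median(deg))
  planted <- attr(nets, "planted_hubs")
  expect_true(nrow(planted) >= length(cfg$tissues))
  set_list <- split(sets$gene, sets$set_id)
  for (i in seq_len(nrow(planted))) {
    ed <- dplyr::filter(nets, tissue == planted$tissue[i],
                        network == planted$network[i])
    gi <- as_network(ed, directed = planted$network[i] == "grn")
    nb <- neighborhood_nodes(gi, planted$node[i])
    expect_gte(length(nb), 5)
    expect_gte(mean(nb %in% set_list[[planted$set_id[i]]]), 0.8)
  }
})

test_that("drug signature tables separate true drugs from decoys by design", {
  cfg <- small_cfg(seed = 8)
  sig <- sim_drug_signatures(cfg)
  expect_identical(sim_drug_signatures(cfg), sig)
  expect_equal(dplyr::n_distinct(sig$lincs$drug), cfg$n_drugs)
  decoys <- setdiff(unique(sig$lincs$drug), cfg$true_drug_ids)
  expect_length(decoys, cfg$n_drugs - length(cfg$true_drug_ids))
  # decoys never reach the tau threshold; true drugs do so in >= 5 groups
  by_drug <- dplyr::summarise(
    dplyr::group_by(sig$lincs, drug),
    n_hit = sum(abs(median_tau) >= 90), .groups = "drop")
  expect_true(all(by_drug$n_hit[by_drug$drug %in% cfg$true_drug_ids] >= 5))
  expect_true(all(by_drug$n_hit[!by_drug$drug %in% cfg$true_drug_ids] == 0))
})

test_that("EMR tables are well-formed", {
  cfg <- small_cfg(seed = 9)
  emr <- sim_emr(cfg)
  expect_s3_class(emr$labs$date, "Date")
  expect_true(all(emr$labs$value >= 0))
  expect_true(all(emr$labs$unit == "nmol/l"))
  expect_true(all(emr$prescriptions$end_date >= emr$prescriptions$start_date))
  expect_identical(sim_emr(cfg), emr)
  expect_error(sim_emr(small_cfg(n_patients = 4L, n_exposed = 2L)), "testable")
})

test_that("strain panel plants an up-in-NOD shift on designated genes only", {
  cfg <- small_cfg(seed = 10)
  expr <- sim_strain_expression(cfg)
  expect_identical(sim_strain_expression(cfg), expr)
  kd <- attr(expr, "kd_genes")
  expect_length(kd, 5)
  expect_setequal(unique(expr$strain),
                  c("NOD", "NZO", "B6", "AJ", "129", "CAST", "PWK", "WSB"))
  expect_setequal(unique(expr$sex), c("F", "M"))
  # designated genes recovered in >= 90% of seeded replicates (sexes pooled)
  hits <- vapply(1:10, function(s) {
    e <- sim_strain_expression(small_cfg(seed = 100 + s))
    g <- attr(e, "kd_genes")[1]
    res <- strain_ttest(e, ids = g, by_sex = FALSE)
    res <- res[res$assay == "rna", ]
    res$p < 0.05 && res$direction > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # a non-designated gene shows no systematic NOD shift
  bg <- setdiff(unique(expr$id), kd)[1]
  res_bg <- strain_ttest(expr, ids = bg, by_sex = FALSE)
  expect_true(all(abs(res_bg$t) < 3))
})
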