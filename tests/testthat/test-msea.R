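test_that("the multi-quantile statistic matches hand evaluation", {
  # universe 1..100, members are the top 10 scores, single quantile 0.9:
  # threshold 90.1, O = 10, E = 1, X = 9 / sqrt(2)
  expect_equal(msea_statistic(91:100, 1:100, quantiles = 0.9, kappa = 1),
               9 / sqrt(2))
  # balanced member sample has O = E at the median threshold: X = 0
  expect_equal(msea_statistic(c(1:10, 91:100), 1:100, quantiles = 0.5),
               0)
  expect_error(msea_statistic(numeric(0), 1:10), "empty")
})

test_that("the statistic is invariant to monotone rescaling of scores", {
  set.seed(42)
  for (i in 1:10) {
    uni <- runif(200, 0, 10)
    mem <- sample(uni, 25)
    x1 <- msea_statistic(mem, uni)
    x2 <- msea_statistic(exp(mem), exp(uni))
    x3 <- msea_statistic(mem^3, uni^3)
    expect_equal(x1, x2)
    expect_equal(x1, x3)
  }
})

test_that("adding a low-scoring member marker decreases the statistic", {
  set.seed(7)
  for (i in 1:10) {
    uni <- sort(runif(100, 1, 10))
    mem <- sample(uni[uni > 5], 10)
    x_before <- msea_statistic(mem, uni)
    x_after <- msea_statistic(c(mem, uni[1]), uni)
    expect_lt(x_after, x_before)
  }
})

test_that("bh_fdr implements the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(1), 1)
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("msea is reproducible, filters by size, and dedupes shared markers", {
  cfg <- small_cfg(seed = 2)
  sim <- sim_all(cfg)
  g1 <- dplyr::filter(sim$gwas$associations, cohort == "cohort1")
  pr <- prune_ld(g1, sim$gwas$ld)
  map <- map_markers_to_genes(pr, sim$eqtl, "blood")
  mcfg <- fast_msea_cfg(seed = 5)
  res1 <- suppressMessages(msea(map, g1, sim$sets, mcfg))
  res2 <- suppressMessages(msea(map, g1, sim$sets, mcfg))
  expect_identical(as.data.frame(res1), as.data.frame(res2))
  expect_true(all(res1$p >= 0 & res1$p <= 1))
  expect_true(all(res1$q >= 0 & res1$q <= 1))

  # member markers are counted once even when shared by several member genes
  map2 <- tibble::tibble(
    marker_id = c("m1", "m1", "m2", "m3", "m4", "m5"),
    gene_id   = c("gA", "gB", "gA", "gC", "gD", "gE"))
  gw2 <- tibble::tibble(marker_id = sprintf("m%d", 1:5),
                        pvalue = c(1e-6, 1e-5, 0.5, 0.6, 0.7))
  res3 <- msea(map2, gw2, catalog_of(list(S = c("gA", "gB"))),
               msea_config(min_genes = 1, n_perm = 100, seed = 1,
                           quantiles = 0.5))
  expect_equal(res3$n_markers, 2)  # m1 deduplicated, not 3

  # a set below min_genes is excluded with a message
  small_set <- catalog_of(list(TINY = unique(map$gene_id)[1:5]))
  expect_message(
    expect_warning(msea(map, g1, small_set, fast_msea_cfg()), "no set"),
    "excluded")
})

test_that("a degenerate permutation null yields p = 1 with a warning", {
  map <- tibble::tibble(marker_id = rep("m1", 4),
                        gene_id = c("g1", "g2", "g3", "g4"))
  gw <- tibble::tibble(marker_id = "m1", pvalue = 0.01)
  expect_warning(
    res <- msea(map, gw, catalog_of(list(S = "g1")),
                msea_config(min_genes = 1, n_perm = 100, seed = 1)),
    "degenerate")
  expect_equal(res$p, 1)
})

test_that("the planted causal set dominates a seeded MSEA run", {
  cfg <- sim_config(seed = 21, effect_mu = 3)
  sets <- sim_gene_sets(cfg)
  eqtl <- sim_eqtl(cfg)
  gwas <- sim_gwas(cfg, eqtl = eqtl, sets = sets)
  g1 <- dplyr::filter(gwas$associations, cohort == "cohort1")
  pr <- prune_ld(g1, gwas$ld)
  map <- map_markers_to_genes(pr, eqtl, "blood")
  res <- suppressMessages(msea(map, g1, sets, fast_msea_cfg(seed = 3)))
  expect_equal(res$set_id[which.max(res$z)], cfg$causal_set_ids)
})

test_that("meta-analysis follows the unweighted Stouffer rule", {
  res <- tibble::tibble(set_id = "S", cohort = c("c1", "c2"), z = c(2, 2))
  meta <- meta_msea(res)
  expect_equal(meta$z_meta, 2 * sqrt(2))
  # cancellation
  meta2 <- meta_msea(tibble::tibble(set_id = "S", cohort = c("c1", "c2"),
                                    z = c(3, -3)))
  expect_equal(meta2$z_meta, 0)
  expect_equal(meta2$p, 0.5)
  # three cohorts
  meta3 <- meta_msea(tibble::tibble(set_id = "S", cohort = c("c1", "c2", "c3"),
                                    z = c(1, 2, 3)))
  expect_equal(meta3$z_meta, 6 / sqrt(3))
  # sets present in only some cohorts are excluded with a warning
  res4 <- tibble::tibble(set_id = c("S", "S", "T"),
                         cohort = c("c1", "c2", "c1"), z = c(1, 1, 5))
  expect_warning(meta4 <- meta_msea(res4), "absent")
  expect_equal(meta4$set_id, "S")
  expect_error(meta_msea(res4[c(1, 3), ]), "two cohorts")
})

test_that("significant_sets implements the at-least-one-mapping-set rule", {
  res <- tibble::tibble(
    set_id = c("A", "A", "B", "C"),
    tissue = c("blood", "islet", "blood", "islet"),
    q = c(0.5, 0.01, 0.2, 0.04))
  expect_equal(significant_sets(res), c("A", "C"))
})
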