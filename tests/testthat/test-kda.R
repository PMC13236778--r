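path_graph <- function() {
  as_network(tibble::tibble(from = c("a", "b"), to = c("b", "c")),
             directed = FALSE)
}

test_that("neighborhoods expand monotonically with depth", {
  g <- path_graph()
  expect_setequal(neighborhood_nodes(g, "b", 1), c("a", "c"))
  expect_setequal(neighborhood_nodes(g, "a", 2), c("b", "c"))
  expect_error(neighborhood_nodes(g, "zz"), "not in the network")
  set.seed(1)
  er <- igraph::sample_gnp(30, 0.1)
  igraph::V(er)$name <- sprintf("n%02d", 1:30)
  for (v in sprintf("n%02d", 1:10)) {
    expect_true(all(neighborhood_nodes(er, v, 1) %in%
                      neighborhood_nodes(er, v, 2)))
  }
})

test_that("the neighborhood statistic matches hand evaluation", {
  expect_equal(kda_statistic(5, 5, 10, 100), 4.5 / sqrt(1.5))
  expect_equal(kda_statistic(0, 5, 10, 100), -0.5 / sqrt(1.5))
  # O equal to E gives 0
  expect_equal(kda_statistic(2, 10, 20, 100), 0)
  # X strictly increases with the overlap at fixed neighborhood
  xs <- kda_statistic(0:5, 5, 10, 100)
  expect_true(all(diff(xs) > 0))
  expect_error(kda_statistic(0, 0, 10, 100), "empty")
})

test_that("edge lists are canonicalized", {
  ed <- tibble::tibble(from = c("a", "b", "a", "a"),
                       to = c("b", "a", "a", "c"))
  g <- as_network(ed, directed = FALSE)
  expect_equal(igraph::ecount(g), 2)  # dup + self-loop removed
})

test_that("run_kda is seeded-reproducible and degenerates safely on saturation", {
  cfg <- small_cfg(seed = 41)
  sim <- sim_all(cfg)
  ed <- dplyr::filter(sim$networks, tissue == "blood", network == "ppi")
  ss <- dplyr::filter(sim$sets, set_id == "SET001")
  k1 <- suppressWarnings(run_kda(ed, ss, fast_kda_cfg(seed = 2)))
  k2 <- suppressWarnings(run_kda(ed, ss, fast_kda_cfg(seed = 2)))
  expect_identical(as.data.frame(k1), as.data.frame(k2))
  # superset covering every node leaves no contrast: nothing significant
  all_nodes <- tibble::tibble(set_id = "ALL", gene = unique(c(ed$from, ed$to)))
  sat <- suppressWarnings(run_kda(ed, all_nodes, fast_kda_cfg(seed = 2)))
  expect_false(any(sat$significant))
})

test_that("Monte-Carlo p agrees with the exact hypergeometric oracle", {
  set.seed(3)
  er <- igraph::sample_gnp(18, 0.25)
  igraph::V(er)$name <- sprintf("n%02d", 1:18)
  ed <- igraph::as_edgelist(er)
  edges <- tibble::tibble(from = ed[, 1], to = ed[, 2])
  members <- sprintf("n%02d", sample(1:18, 6))
  ss <- tibble::tibble(set_id = "S", gene = members)
  b <- 4000L
  res <- run_kda(edges, ss, kda_config(n_perm = b, seed = 9, min_degree = 2))
  n_nodes <- igraph::vcount(er)
  for (i in seq_len(nrow(res))) {
    p_exact <- phyper(res$overlap[i] - 1, 6, n_nodes - 6,
                      res$neighborhood_size[i], lower.tail = FALSE)
    tol <- 3 * sqrt(p_exact * (1 - p_exact) / b) + 2 / b
    expect_lt(abs(res$p_emp[i] - p_exact), tol)
  }
})

test_that("planted hubs are recovered at FDR < 5%", {
  hits <- vapply(1:10, function(s) {
    cfg <- small_cfg(seed = 200 + s)
    sets <- sim_gene_sets(cfg)
    nets <- sim_networks(cfg, sets = sets, kinds = "ppi")
    planted <- attr(nets, "planted_hubs")
    planted <- planted[planted$tissue == "blood", ]
    ed <- dplyr::filter(nets, tissue == "blood")
    ss <- dplyr::filter(sets, set_id == planted$set_id[1])
    res <- run_kda(ed, ss, fast_kda_cfg(seed = s))
    planted$node[1] %in% res$node[res$significant]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("top key drivers are selected by the published ranking rule", {
  res <- tibble::tibble(
    node = sprintf("n%d", 1:8),
    set_id = "S", tissue = "islet", network = "ppi",
    p = c(1e-6, 1e-5, 1e-4, 1e-3, 1e-3, 1e-2, 0.2, 0.5),
    x = c(9, 8, 7, 5, 6, 4, 3, 2),
    q = c(rep(0.01, 7), 0.5))
  top <- select_top_kds(res, fdr_alpha = 0.05, top_k = 5)
  expect_equal(nrow(top), 5)
  # equal p resolved by larger statistic first
  expect_equal(top$node[4], "n5")
  expect_equal(top$rank, 1:5)
  # fewer than top_k significant drivers: all kept
  top3 <- select_top_kds(res[c(1, 2, 8), ], top_k = 5)
  expect_equal(nrow(top3), 2)
})

test_that("cross-network overlap intersects on node id", {
  a <- tibble::tibble(node = c("FYN", "LCK"), tissue = "islet",
                      network = "grn", set_id = "S1")
  b <- tibble::tibble(node = c("LCK", "WAS"), tissue = "islet",
                      network = "ppi", set_id = "S1")
  shared <- cross_network_overlap(a, b)
  expect_equal(shared$node, "LCK")
  expect_equal(nrow(cross_network_overlap(a, b[2, ])), 0)
  expect_equal(nrow(cross_network_overlap(a, a)), 2)
})
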