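#' Configuration for key-driver analysis
#'
#' @param depth Neighborhood depth in hops (default 1).
#' @param min_degree Minimum degree for a node to be a key-driver candidate;
#'   excludes leaves (default 3).
#' @param kappa Stabilizing constant in the statistic denominator (default 1).
#' @param n_perm Monte-Carlo draws from the membership-relabeling null
#'   (minimum 100; default 2000).
#' @param fdr_alpha FDR threshold for calling key drivers.
#' @param top_k_per_superset Key drivers kept per (superset, tissue, network)
#'   by [select_top_kds()] (default 5).
#' @param respect_direction If `TRUE` and the network is directed, the
#'   neighborhood follows outgoing edges only; by default direction is
#'   ignored.
#' @param seed Integer seed for the null draws.
#' @return A list of class `kda_config`.
#' @export
kda_config <- function(depth = 1L, min_degree = 3L, kappa = 1,
                       n_perm = 2000L, fdr_alpha = 0.05,
                       top_k_per_superset = 5L, respect_direction = FALSE,
                       seed = 1L) {
  depth <- assert_count(depth, "depth")
  min_degree <- assert_count(min_degree, "min_degree", min = 0L)
  if (!is.numeric(kappa) || kappa < 0) abort("`kappa` must be non-negative")
  n_perm <- assert_count(n_perm, "n_perm", min = 100L)
  assert_fraction(fdr_alpha, "fdr_alpha")
  top_k_per_superset <- assert_count(top_k_per_superset, "top_k_per_superset")
  seed <- assert_count(seed, "seed", min = 0L)
  structure(list(depth = depth, min_degree = min_degree, kappa = kappa,
                 n_perm = n_perm, fdr_alpha = fdr_alpha,
                 top_k_per_superset = top_k_per_superset,
                 respect_direction = isTRUE(respect_direction), seed = seed),
            class = "kda_config")
}

#' Build an igraph network from an edge list
#'
#' Canonicalizes an edge-list tibble: self-loops and duplicate edges are
#' removed (undirected edges are treated as unordered pairs).
#'
#' @param edges Tibble with columns `from`, `to` (a `weight` column is carried
#'   along but unused).
#' @param directed Whether edges are directed.
#' @return An `igraph` graph.
#' @export
as_network <- function(edges, directed = FALSE) {
  assert_cols(edges, c("from", "to"), "edges")
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = directed)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Network neighborhood of a node
#'
#' All nodes within `depth` hops of `node`, excluding the node itself.
#' Direction is ignored unless `mode` says otherwise, matching how hub
#' detection treats regulatory networks as local-connectivity structures.
#'
#' @param graph An `igraph` graph.
#' @param node Node name.
#' @param depth Number of hops (default 1).
#' @param mode Edge direction to follow: `"all"` (default) or `"out"`.
#' @return Character vector of neighbor node names.
#' @export
neighborhood_nodes <- function(graph, node, depth = 1L, mode = "all") {
  if (!node %in% igraph::V(graph)$name) {
    abort(sprintf("node '%s' is not in the network", node))
  }
  nb <- igraph::ego(graph, order = depth, nodes = node, mode = mode)[[1]]
  setdiff(names(nb), node)
}

#' Key-driver enrichment statistic
#'
#' The chi-square-like statistic used for neighborhood enrichment:
#' `X = (O - E) / sqrt(E + kappa)` with `O` the observed overlap between the
#' neighborhood and the gene set (restricted to network nodes) and
#' `E = n_neighborhood * n_set_in_network / n_nodes` its expectation under
#' uniform membership.
#'
#' @param overlap Observed overlap count `O`.
#' @param n_neighborhood Neighborhood size.
#' @param n_set_in_network Number of set genes present in the network.
#' @param n_nodes Total network nodes.
#' @param kappa Stabilizing constant.
#' @return The statistic X.
#' @examples
#' kda_statistic(5, 5, 10, 100)  # a neighborhood of 5 fully inside the set
#' @export
kda_statistic <- function(overlap, n_neighborhood, n_set_in_network, n_nodes,
                          kappa = 1) {
  if (any(n_neighborhood <= 0)) {
    abort("the statistic is undefined for an empty neighborhood")
  }
  e <- n_neighborhood * n_set_in_network / n_nodes
  (overlap - e) / sqrt(e + kappa)
}

#' Key-driver analysis of a network against supersets
#'
#' For every candidate node (degree at least `min_degree`) and every superset,
#' compares the overlap of the node's neighborhood with the superset against a
#' null in which superset membership is relabeled uniformly at random over the
#' network nodes (`n_perm` Monte-Carlo draws of the overlap, which under this
#' null is hypergeometric). The null moments give a z-score and Gaussian
#' upper-tail p-value; the empirical Monte-Carlo p-value is reported alongside.
#' FDR is controlled by Benjamini-Hochberg across candidates within each
#' superset.
#'
#' @param edges Edge-list tibble (`from`, `to`).
#' @param supersets Long gene-set tibble (`set_id`, `gene`).
#' @param cfg A [kda_config()].
#' @param tissue,network Labels carried into the result.
#' @param directed Whether `edges` are directed.
#' @return A tibble of class `kda_result`: `node`, `set_id`, `tissue`,
#'   `network`, `neighborhood_size`, `overlap`, `x`, `z`, `p`, `p_emp`, `q`,
#'   `significant`, `rank`.
#' @export
run_kda <- function(edges, supersets, cfg = kda_config(),
                    tissue = NA_character_, network = NA_character_,
                    directed = FALSE) {
  assert_cols(supersets, c("set_id", "gene"), "supersets")
  stopifnot(inherits(cfg, "kda_config"))
  g <- as_network(edges, directed = directed)
  nodes <- igraph::V(g)$name
  n_nodes <- length(nodes)
  mode <- if (cfg$respect_direction && directed) "out" else "all"
  deg <- igraph::degree(g, mode = "all")
  candidates <- sort(nodes[deg >= cfg$min_degree])
  if (!length(candidates)) {
    warn("run_kda: no candidate reaches min_degree")
    return(empty_kda_result())
  }
  nbhd <- purrr::map(candidates, function(v) {
    neighborhood_nodes(g, v, depth = cfg$depth, mode = mode)
  })
  names(nbhd) <- candidates
  nb_sizes <- lengths(nbhd)
  ok <- nb_sizes > 0L
  candidates <- candidates[ok]
  nbhd <- nbhd[ok]
  nb_sizes <- nb_sizes[ok]

  set_list <- purrr::map(split(supersets$gene, supersets$set_id),
                         function(gn) intersect(unique(gn), nodes))
  res <- withr::with_seed(cfg$seed, {
    purrr::map_dfr(names(set_list), function(sid) {
      s_nodes <- set_list[[sid]]
      s <- length(s_nodes)
      if (s == 0L) {
        warn(sprintf("run_kda: superset '%s' has no gene in the network; skipped",
                     sid))
        return(NULL)
      }
      rows <- purrr::map_dfr(seq_along(candidates), function(i) {
        n_h <- nb_sizes[[i]]
        o <- sum(nbhd[[i]] %in% s_nodes)
        x <- kda_statistic(o, n_h, s, n_nodes, cfg$kappa)
        # uniform membership relabeling: the neighborhood overlap is a
        # hypergeometric draw of size n_h from s member labels among n_nodes
        ob <- rhyper(cfg$n_perm, s, n_nodes - s, n_h)
        xb <- kda_statistic(ob, n_h, s, n_nodes, cfg$kappa)
        sdev <- sd(xb)
        if (!is.finite(sdev) || sdev == 0) {
          warn(sprintf("run_kda: degenerate null for node '%s'; p set to 1",
                       candidates[i]))
          z <- 0; p <- 1
        } else {
          z <- (x - mean(xb)) / sdev
          p <- pnorm(z, lower.tail = FALSE)
        }
        tibble(node = candidates[i], set_id = sid, tissue = tissue,
               network = network, neighborhood_size = n_h, overlap = o,
               x = x, z = z, p = p,
               p_emp = (1 + sum(xb >= x)) / (cfg$n_perm + 1))
      })
      rows$q <- bh_fdr(rows$p)
      rows$significant <- rows$q < cfg$fdr_alpha
      rows %>%
        arrange(.data$p, desc(.data$x), .data$node) %>%
        mutate(rank = row_number())
    })
  })
  structure(res, config = cfg, class = c("kda_result", class(res)))
}

empty_kda_result <- function() {
  structure(
    tibble(node = character(), set_id = character(), tissue = character(),
           network = character(), neighborhood_size = integer(),
           overlap = integer(), x = numeric(), z = numeric(), p = numeric(),
           p_emp = numeric(), q = numeric(), significant = logical(),
           rank = integer()),
    class = c("kda_result", "tbl_df", "tbl", "data.frame"))
}

#' Select the top-ranked key drivers per superset
#'
#' Within each (superset, tissue, network) keeps nodes with `q < fdr_alpha`,
#' ordered by ascending p, then descending statistic, then node name, and
#' returns the first `top_k`.
#'
#' @param results A [run_kda()] result (or several row-bound).
#' @param fdr_alpha FDR threshold (default 0.05).
#' @param top_k Key drivers to keep per group (default 5).
#' @return The filtered, re-ranked tibble.
#' @export
select_top_kds <- function(results, fdr_alpha = 0.05, top_k = 5L) {
  assert_cols(results, c("node", "set_id", "p", "x", "q"), "results")
  top_k <- assert_count(top_k, "top_k")
  if (!"tissue" %in% names(results)) results$tissue <- NA_character_
  if (!"network" %in% names(results)) results$network <- NA_character_
  results %>%
    filter(.data$q < fdr_alpha) %>%
    group_by(.data$set_id, .data$tissue, .data$network) %>%
    arrange(.data$p, desc(.data$x), .data$node, .by_group = TRUE) %>%
    mutate(rank = row_number()) %>%
    slice_head(n = top_k) %>%
    ungroup()
}

#' Key drivers shared between two networks
#'
#' Intersects two key-driver tables on node id (within tissue when both carry
#' a tissue label), annotating each shared driver with the networks and
#' supersets that support it on either side.
#'
#' @param a,b Key-driver tibbles (at least a `node` column).
#' @return A tibble with one row per shared (tissue, node).
#' @export
cross_network_overlap <- function(a, b) {
  assert_cols(a, "node", "a")
  assert_cols(b, "node", "b")
  prep <- function(x, suffix) {
    if (!"tissue" %in% names(x)) x$tissue <- NA_character_
    if (!"network" %in% names(x)) x$network <- NA_character_
    if (!"set_id" %in% names(x)) x$set_id <- NA_character_
    x %>%
      group_by(.data$tissue, .data$node) %>%
      summarise(networks = paste(sort(unique(.data$network)), collapse = ","),
                set_ids = paste(sort(unique(.data$set_id)), collapse = ","),
                .groups = "drop") %>%
      rename(!!paste0("networks_", suffix) := "networks",
             !!paste0("set_ids_", suffix) := "set_ids")
  }
  inner_join(prep(a, "a"), prep(b, "b"), by = c("tissue", "node")) %>%
    arrange(.data$tissue, .data$node)
}
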