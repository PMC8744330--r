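ring_graph <- function(names) {
  g <- igraph::make_ring(length(names))
  igraph::V(g)$name <- names
  g
}

test_that("tissue subnetworks equal the brute-force induced subgraph", {
  set.seed(61)
  e <- random_ranked_edges(20, seed = 3)
  keep <- senescape:::.pmfg_select_cpp(matrix(as.integer(e), ncol = 2), 20L)
  g <- igraph::graph_from_edgelist(e[keep, , drop = FALSE], directed = FALSE)
  igraph::V(g)$name <- sprintf("g%02d", 1:20)
  pfn <- list(graph = g, nodes = igraph::V(g)$name, tissue = "t1",
              edges = NULL, is_planar = TRUE)
  class(pfn) <- "pfn"
  fl <- tibble::tibble(tissue = "t1", module_id = "M1.1",
                       members = list(sprintf("g%02d", 1:8)))
  sub <- tissue_subnetworks(list(t1 = pfn), fl)[["t1"]]
  el <- igraph::as_edgelist(g)
  manual <- el[el[, 1] %in% sprintf("g%02d", 1:8) &
               el[, 2] %in% sprintf("g%02d", 1:8), , drop = FALSE]
  got <- igraph::as_edgelist(sub)
  expect_setequal(paste(pmin(got[, 1], got[, 2]), pmax(got[, 1], got[, 2])),
                  paste(pmin(manual[, 1], manual[, 2]), pmax(manual[, 1], manual[, 2])))
  # whole-network module: subgraph = PFN
  fl2 <- tibble::tibble(tissue = "t1", module_id = "M1",
                        members = list(igraph::V(g)$name))
  sub2 <- tissue_subnetworks(list(t1 = pfn), fl2)[["t1"]]
  expect_equal(igraph::ecount(sub2), igraph::ecount(g))
  # tissue with no flagged modules is absent
  expect_message(out <- tissue_subnetworks(list(t1 = pfn),
                                           fl[fl$tissue == "zz", ]), "skipped")
  expect_length(out, 0)
})

test_that("aggregation weights equal brute-force frequency counts", {
  # 10 synthetic tissues with known gene rosters
  genes_for <- function(i) sprintf("g%02d", 1:(4 + i))  # nested rosters
  nets <- lapply(1:10, function(i) ring_graph(genes_for(i)))
  names(nets) <- paste0("t", 1:10)
  agg <- aggregate_networks(nets, min_node_weight = 1)
  # gene g05 appears in all 10, g14 only in the largest ring
  expect_equal(agg$nodes$weight[agg$nodes$gene == "g05"], 10)
  expect_equal(agg$nodes$weight[agg$nodes$gene == "g14"], 1)
  # brute-force node counts
  manual <- table(unlist(lapply(nets, function(g) igraph::V(g)$name)))
  for (g in agg$nodes$gene) {
    expect_equal(agg$nodes$weight[agg$nodes$gene == g], unname(manual[g]))
  }
  # threshold semantics: weight < 5 removed at min_node_weight = 5
  agg5 <- aggregate_networks(nets, min_node_weight = 5)
  w <- setNames(agg$nodes$weight, agg$nodes$gene)
  expect_setequal(agg5$nodes$gene, names(w)[w >= 5])
  # gene in exactly 4 tissues is excluded at threshold 5
  expect_equal(sum(w == 4), sum(!names(w)[w == 4] %in% agg5$nodes$gene))
  # monotonicity + endpoint closure
  expect_lte(nrow(agg5$nodes), nrow(agg$nodes))
  expect_true(all(agg5$edges$gene_a %in% agg5$nodes$gene))
  expect_true(all(agg5$edges$gene_b %in% agg5$nodes$gene))
  # permutation invariance in tissue order
  agg_rev <- aggregate_networks(rev(nets), min_node_weight = 5)
  expect_equal(dplyr::arrange(agg5$nodes[, c("gene", "weight")], gene),
               dplyr::arrange(agg_rev$nodes[, c("gene", "weight")], gene))
})

test_that("neighborhood equals breadth-first search", {
  # path a-b-c-d-e: 3 layers from a reach {a,b,c,d}
  g <- igraph::make_graph(~ a - b, b - c, c - d, d - e)
  nb <- neighborhood(g, "a", layers = 3)
  expect_setequal(nb$genes, c("a", "b", "c", "d"))
  # isolated seed
  g2 <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices("x", "y")
  nb2 <- neighborhood(g2, "x")
  expect_identical(nb2$genes, "x")
  expect_equal(igraph::ecount(nb2$graph), 0)
  # absent seed warns and returns empty
  expect_warning(nb3 <- neighborhood(g, "zz"), "not in the network")
  expect_length(nb3$genes, 0)
  # random planar graph vs BFS oracle
  e <- random_ranked_edges(25, seed = 8)
  keep <- senescape:::.pmfg_select_cpp(matrix(as.integer(e), ncol = 2), 25L)
  gg <- igraph::graph_from_edgelist(e[keep, , drop = FALSE], directed = FALSE)
  igraph::V(gg)$name <- sprintf("v%02d", 1:25)
  for (seed_gene in c("v01", "v13")) {
    nb4 <- neighborhood(gg, seed_gene, layers = 2)
    d <- igraph::distances(gg, v = seed_gene)
    expect_setequal(nb4$genes, colnames(d)[d[1, ] <= 2])
  }
})

test_that("consensus neighborhood keeps the seed and counts support", {
  nets <- lapply(1:7, function(i) {
    g <- igraph::make_graph(~ seed - a, a - b)
    if (i <= 4) g <- igraph::add_vertices(g, 1, name = "rare")
    g
  })
  names(nets) <- paste0("t", 1:7)
  cn <- consensus_neighborhood(nets, "seed", min_node_weight = 5)
  expect_true("seed" %in% cn$nodes$gene)
  expect_equal(cn$nodes$weight[cn$nodes$gene == "a"], 7)
  expect_false("rare" %in% cn$nodes$gene)  # 4 < 5 excluded
  # seed survives even when its own support is below threshold
  nets2 <- nets[1:3]
  cn2 <- consensus_neighborhood(nets2, "seed", min_node_weight = 5)
  expect_identical(cn2$nodes$gene[cn2$nodes$gene == "seed"], "seed")
  expect_equal(nrow(cn2$nodes), 1)
})

test_that("planted cross-tissue genes receive node weight equal to tissue count", {
  b <- small_bulk(seed = 17, n_samples = 30)
  truth <- b$cohort$truth
  # build truth-based subnetworks directly (module membership is the truth)
  nets <- lapply(split(truth$membership, truth$membership$tissue), function(df) {
    genes <- df$gene[df$module == df$planted_sng_module[1]]
    ring_graph(sort(genes))
  })
  agg <- aggregate_networks(nets, min_node_weight = 1)
  planted_counts <- table(truth$membership$gene[
    truth$membership$module == truth$membership$planted_sng_module])
  for (g in sample(names(planted_counts), 20)) {
    expect_equal(agg$nodes$weight[agg$nodes$gene == g],
                 unname(planted_counts[g]))
  }
})
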