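test_that("pairwise correlations match the covariance formula and t-transform", {
  set.seed(41)
  expr <- matrix(rnorm(10 * 15), 10, 15,
                 dimnames = list(sprintf("g%02d", 1:10), NULL))
  expr["g02", ] <- expr["g01", ]           # exact copy
  expr["g03", ] <- -expr["g01", ]          # negation
  cands <- pairwise_pcc(expr)
  expect_equal(nrow(cands), choose(10, 2))
  r12 <- cands$r[cands$gene_a == "g01" & cands$gene_b == "g02"]
  r13 <- cands$r[cands$gene_a == "g01" & cands$gene_b == "g03"]
  expect_equal(r12, 1)
  expect_equal(r13, -1)
  # brute-force covariance formula oracle
  for (i in sample(nrow(cands), 20)) {
    a <- expr[cands$gene_a[i], ]; b <- expr[cands$gene_b[i], ]
    manual <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(cands$r[i], manual, tolerance = 1e-12)
    m <- length(a)
    tt <- abs(manual) * sqrt((m - 2) / (1 - manual^2))
    if (abs(manual) < 1) {
      expect_equal(cands$p[i], 2 * pt(tt, m - 2, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
  # zero-variance genes are excluded with a message
  expr["g04", ] <- 5
  expect_message(out <- pairwise_pcc(expr), "zero-variance")
  expect_false(any(out$gene_a == "g04" | out$gene_b == "g04"))
})

test_that("FDR edge filter matches the BH step-up oracle and unsigned ranking", {
  set.seed(42)
  n <- 100
  cands <- tibble::tibble(
    gene_a = sprintf("a%03d", 1:n), gene_b = sprintf("b%03d", 1:n),
    r = runif(n, -1, 1), p = runif(n)^2
  )
  kept <- fdr_filter_edges(cands, alpha = 0.05)
  q_all <- bh_oracle(cands$p)
  expect_setequal(paste(kept$gene_a, kept$gene_b),
                  paste(cands$gene_a, cands$gene_b)[q_all <= 0.05])
  expect_true(all(diff(abs(kept$r)) <= 1e-15))
  expect_equal(kept$rank, seq_len(nrow(kept)))
  # degenerate cases
  expect_equal(nrow(fdr_filter_edges(dplyr::mutate(cands, p = 1))), 0)
  one <- fdr_filter_edges(tibble::tibble(gene_a = "a", gene_b = "b",
                                         r = .5, p = 0.01))
  expect_equal(nrow(one), 1)
})

test_that("PMFG keeps K4, prunes K5, and matches the independent greedy oracle", {
  # K4: all 6 edges planar
  e4 <- t(combn(4, 2))
  k4 <- senescape:::.pmfg_select_cpp(matrix(as.integer(e4), ncol = 2), 4L)
  expect_true(all(k4))
  # K5: exactly 9 = 3*5-6 edges kept, the last-ranked closing edge dropped
  e5 <- t(combn(5, 2))
  k5 <- senescape:::.pmfg_select_cpp(matrix(as.integer(e5), ncol = 2), 5L)
  expect_equal(sum(k5), 9)
  expect_false(k5[10])
  # random fixtures: planar by networkx, edge bound, identical to the
  # from-scratch networkx greedy oracle
  fixtures <- lapply(1:4, function(i) {
    n <- c(18, 25, 30, 30)[i]
    list(n = n, edges = random_ranked_edges(n, seed = 100 + i), mode = "pmfg")
  })
  oracle <- nx_oracle(fixtures)
  for (i in seq_along(fixtures)) {
    fx <- fixtures[[i]]
    keep <- senescape:::.pmfg_select_cpp(
      matrix(as.integer(fx$edges), ncol = 2), as.integer(fx$n))
    expect_equal(as.logical(keep), as.logical(oracle[[i]]))
    acc <- fx$edges[keep, , drop = FALSE]
    expect_lte(nrow(acc), 3 * fx$n - 6)
    expect_true(is_planar(acc, fx$n))
    expect_true(nx_is_planar(acc, fx$n))
  }
})

test_that("build_pfn returns a planar igraph with ordered edge metadata", {
  set.seed(43)
  expr <- matrix(rnorm(30 * 40), 30, 40,
                 dimnames = list(sprintf("g%02d", 1:30), NULL))
  # plant one correlated block so some edges certainly pass the FDR screen
  expr[1:8, ] <- matrix(rep(expr[1, ], 8), nrow = 8, byrow = TRUE) +
    0.4 * matrix(rnorm(8 * 40), 8)
  edges <- fdr_filter_edges(pairwise_pcc(expr), alpha = 0.2)
  pfn <- build_pfn(edges, nodes = rownames(expr), tissue = "toy")
  expect_s3_class(pfn, "pfn")
  expect_true(is_planar(pfn$graph))
  expect_lte(nrow(pfn$edges), 3 * 30 - 6)
  expect_identical(glance(pfn)$tissue, "toy")
  expect_identical(tidy(pfn), pfn$edges)
  # unsigned contract: negating one gene leaves the PFN edge set unchanged
  expr_neg <- expr
  expr_neg["g05", ] <- -expr_neg["g05", ]
  pfn2 <- build_pfn(fdr_filter_edges(pairwise_pcc(expr_neg), alpha = 0.2),
                    nodes = rownames(expr_neg))
  expect_identical(pfn$edges[, c("gene_a", "gene_b")],
                   pfn2$edges[, c("gene_a", "gene_b")])
})

test_that("module detection recovers planted blocks and resists null graphs", {
  set.seed(44)
  # two 25-cliques joined by one bridge: exact recovery at depth 1
  g <- igraph::disjoint_union(igraph::make_full_graph(25),
                              igraph::make_full_graph(25))
  g <- igraph::add_edges(g, c(1, 26))
  igraph::V(g)$name <- sprintf("n%02d", 1:50)
  h <- detect_modules(g, seed = 3)
  d1 <- h[h$depth == 1, ]
  expect_equal(nrow(d1), 2)
  lab <- setNames(rep(NA_character_, 50), igraph::V(g)$name)
  for (i in 1:2) lab[d1$members[[i]]] <- d1$module_id[i]
  truth <- rep(c("A", "B"), each = 25)
  expect_equal(ari(lab, truth), 1)
  # small clique-like component: no accepted split
  g2 <- igraph::make_full_graph(10)
  igraph::V(g2)$name <- sprintf("m%02d", 1:10)
  h2 <- detect_modules(g2, seed = 3)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$depth, 0)
  # rewire-null calibration: ER graphs with no structure rarely split
  splits <- vapply(1:20, function(sd) {
    set.seed(sd)
    ger <- igraph::sample_gnm(40, 80)
    igraph::V(ger)$name <- sprintf("r%02d", 1:40)
    hh <- detect_modules(ger, seed = sd)
    any(hh$depth > 0)
  }, logical(1))
  expect_lte(mean(splits), 0.05)
})

test_that("hub flags equal the mean + 2SD recomputation", {
  # star: only the center is a hub
  star <- igraph::make_star(12, mode = "undirected")
  igraph::V(star)$name <- c("hub", sprintf("leaf%02d", 1:11))
  h <- tibble::tibble(module_id = "M1", parent_id = NA_character_, depth = 0,
                      members = list(igraph::V(star)$name), n_genes = 12)
  hubs <- detect_hubs(star, h)
  expect_identical(hubs$gene[hubs$is_hub], "hub")
  # ring: zero SD, no hubs
  ring <- igraph::make_ring(10)
  igraph::V(ring)$name <- sprintf("r%02d", 1:10)
  h2 <- tibble::tibble(module_id = "M1", parent_id = NA_character_, depth = 0,
                       members = list(igraph::V(ring)$name), n_genes = 10)
  expect_false(any(detect_hubs(ring, h2)$is_hub))
  # random planar module: direct recomputation
  set.seed(45)
  e <- random_ranked_edges(20, seed = 9)
  keep <- senescape:::.pmfg_select_cpp(matrix(as.integer(e), ncol = 2), 20L)
  g <- igraph::graph_from_edgelist(e[keep, , drop = FALSE], directed = FALSE)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(igraph::vcount(g)))
  h3 <- tibble::tibble(module_id = "M1", parent_id = NA_character_, depth = 0,
                       members = list(igraph::V(g)$name),
                       n_genes = igraph::vcount(g))
  hubs3 <- detect_hubs(g, h3)
  deg <- igraph::degree(g)[hubs3$gene]
  expect_identical(hubs3$is_hub, unname(deg > mean(deg) + 2 * sd(deg)))
})
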