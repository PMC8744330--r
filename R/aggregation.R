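#' Tissue subnetworks induced by flagged-module genes
#'
#' For each tissue with flagged modules, the subgraph of its planar network
#' induced by the union of flagged-module member genes: those genes, plus the
#' network edges with both endpoints among them.
#'
#' @param pfns Named list `tissue -> pfn` (from [build_pfn()]).
#' @param flagged_modules Tibble from [flag_sng_modules()].
#' @return Named list `tissue -> igraph`; tissues without flagged modules are
#'   absent (with a message).
#' @export
tissue_subnetworks <- function(pfns, flagged_modules) {
  out <- list()
  for (tn in names(pfns)) {
    fl <- dplyr::filter(flagged_modules, .data$tissue == tn)
    if (nrow(fl) == 0) {
      message("tissue ", tn, " has no flagged modules; skipped")
      next
    }
    genes <- unique(unlist(fl$members))
    g <- pfns[[tn]]$graph
    out[[tn]] <- igraph::induced_subgraph(g, intersect(genes, igraph::V(g)$name))
  }
  out
}

# shared counting core for aggregate()/consensus_neighborhood()
aggregate_graphs <- function(graphs, min_node_weight, min_edge_weight,
                             always_keep = character()) {
  stopifnot(length(graphs) >= 1)
  node_tabs <- purrr::imap_dfr(graphs, function(g, tn)
    tibble::tibble(tissue = tn, gene = igraph::V(g)$name))
  edge_tabs <- purrr::imap_dfr(graphs, function(g, tn) {
    if (igraph::ecount(g) == 0) return(tibble::tibble())
    el <- igraph::as_edgelist(g)
    tibble::tibble(tissue = tn, gene_a = pmin(el[, 1], el[, 2]),
                   gene_b = pmax(el[, 1], el[, 2]))
  })
  nodes <- node_tabs |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(weight = dplyr::n(),
                     tissues = list(sort(unique(.data$tissue))), .groups = "drop")
  edges <- if (nrow(edge_tabs)) {
    edge_tabs |>
      dplyr::group_by(.data$gene_a, .data$gene_b) |>
      dplyr::summarise(weight = dplyr::n(),
                       tissues = list(sort(unique(.data$tissue))), .groups = "drop")
  } else {
    tibble::tibble(gene_a = character(), gene_b = character(),
                   weight = integer(), tissues = list())
  }
  keep_nodes <- nodes$weight >= min_node_weight | nodes$gene %in% always_keep
  nodes <- nodes[keep_nodes, , drop = FALSE]
  edges <- dplyr::filter(edges, .data$gene_a %in% nodes$gene,
                         .data$gene_b %in% nodes$gene,
                         .data$weight >= min_edge_weight)
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = nodes$gene)
  )
  if (igraph::ecount(g) > 0) igraph::E(g)$weight <- edges$weight
  igraph::V(g)$weight <- nodes$weight
  structure(list(nodes = dplyr::arrange(nodes, dplyr::desc(.data$weight), .data$gene),
                 edges = edges, graph = g,
                 n_networks = length(graphs),
                 min_node_weight = min_node_weight,
                 min_edge_weight = min_edge_weight),
            class = "weighted_aggregate")
}

#' Conservation-weighted network aggregation
#'
#' Merges tissue subnetworks: the node conservation weight counts the tissues
#' whose subnetwork contains the gene, the edge conservation weight counts
#' the subnetworks containing the link. Nodes with weight below
#' `min_node_weight` (default 5, i.e. "weights < 5" filtered) are dropped,
#' then edges with a dropped endpoint. No edge-weight threshold is applied by
#' default (`min_edge_weight = 1`).
#'
#' @param subnetworks Named list `tissue -> igraph` (from
#'   [tissue_subnetworks()]).
#' @param min_node_weight Minimum node conservation weight (default 5).
#' @param min_edge_weight Minimum edge conservation weight (default 1).
#' @return Object of class `weighted_aggregate`: `nodes` and `edges` tibbles
#'   (with integer weights and supporting-tissue lists) and `graph` (igraph).
#' @export
aggregate_networks <- function(subnetworks, min_node_weight = 5,
                               min_edge_weight = 1) {
  aggregate_graphs(subnetworks, min_node_weight, min_edge_weight)
}

#' @export
tidy.weighted_aggregate <- function(x, ...) x$edges

#' @export
glance.weighted_aggregate <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 n_networks = x$n_networks,
                 min_node_weight = x$min_node_weight,
                 max_node_weight = if (nrow(x$nodes)) max(x$nodes$weight) else NA_integer_)
}

#' @export
print.weighted_aggregate <- function(x, ...) {
  cat("Conservation-weighted aggregate:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges from", x$n_networks, "networks",
      sprintf("(node weight >= %d)\n", x$min_node_weight))
  invisible(x)
}

#' Multi-layer neighborhood of a seed gene
#'
#' Breadth-first expansion to graph distance `layers` around the seed (seed
#' at distance 0), with the induced subgraph on that gene set.
#'
#' @param pfn A [build_pfn()] result or igraph graph.
#' @param seed_gene Gene symbol.
#' @param layers Neighborhood radius in edges (default 3).
#' @return List with `genes` (character, sorted, seed included) and `graph`
#'   (igraph). A seed absent from the network yields an empty result with a
#'   warning.
#' @export
neighborhood <- function(pfn, seed_gene, layers = 3) {
  g <- if (inherits(pfn, "pfn")) pfn$graph else pfn
  if (!seed_gene %in% igraph::V(g)$name) {
    warning("seed gene ", seed_gene, " not in the network")
    return(list(genes = character(), graph = igraph::make_empty_graph(0, directed = FALSE)))
  }
  vs <- igraph::ego(g, order = layers, nodes = seed_gene)[[1]]
  genes <- sort(vs$name)
  list(genes = genes, graph = igraph::induced_subgraph(g, genes))
}

#' Consensus neighborhood across tissues
#'
#' Aggregates per-tissue neighborhood subgraphs of one seed gene with
#' conservation weights (as [aggregate_networks()]); the seed gene itself is
#' always retained regardless of the node-weight threshold so the consensus
#' stays anchored.
#'
#' @param per_tissue_neighborhoods Named list `tissue -> neighborhood()`
#'   result (or igraph).
#' @param seed_gene The seed gene (kept unconditionally).
#' @param min_node_weight Minimum node conservation weight (default 5).
#' @param min_edge_weight Minimum edge conservation weight (default 1).
#' @return A `weighted_aggregate`.
#' @export
consensus_neighborhood <- function(per_tissue_neighborhoods, seed_gene,
                                   min_node_weight = 5, min_edge_weight = 1) {
  graphs <- lapply(per_tissue_neighborhoods, function(x) {
    if (inherits(x, "igraph")) x else x$graph
  })
  graphs <- graphs[vapply(graphs, igraph::vcount, numeric(1)) > 0]
  aggregate_graphs(graphs, min_node_weight, min_edge_weight,
                   always_keep = seed_gene)
}
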