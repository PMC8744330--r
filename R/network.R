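#' All-pairs Pearson correlations with p-values
#'
#' Computes the Pearson correlation for every gene pair and a two-sided
#' p-value from the t transform `t = r * sqrt((m - 2) / (1 - r^2))` with
#' `m - 2` degrees of freedom (`m` samples). Zero-variance genes are
#' excluded (their correlations are undefined) with a message.
#'
#' @param expr Gene x sample matrix of (residualized) expression.
#' @return Tibble with `gene_a`, `gene_b` (`gene_a < gene_b`
#'   lexicographically), `r`, `p`.
#' @export
pairwise_pcc <- function(expr) {
  m <- ncol(expr)
  if (m < 3) stop("need at least 3 samples for correlation p-values")
  v <- apply(expr, 1, var)
  if (any(v == 0)) {
    message("excluding ", sum(v == 0), " zero-variance gene(s) from correlation")
    expr <- expr[v > 0, , drop = FALSE]
  }
  genes <- rownames(expr)
  ord <- order(genes)
  expr <- expr[ord, , drop = FALSE]
  genes <- genes[ord]
  cm <- cor(t(expr))
  iu <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[iu]
  r <- pmin(1, pmax(-1, r))
  tt <- abs(r) * sqrt((m - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(tt, df = m - 2, lower.tail = FALSE)
  p[abs(r) == 1] <- 0
  tibble::tibble(gene_a = genes[iu[, 1]], gene_b = genes[iu[, 2]], r = r, p = p)
}

#' FDR-screen and rank candidate edges
#'
#' Benjamini-Hochberg adjusts the correlation p-values over all tested pairs,
#' keeps pairs with `q <= alpha`, and ranks them by decreasing `|r|` (the
#' network is unsigned), ties broken lexicographically on
#' `(gene_a, gene_b)`.
#'
#' @param cands Tibble from [pairwise_pcc()].
#' @param alpha FDR cutoff (default 0.05).
#' @return Tibble `gene_a`, `gene_b`, `r`, `p`, `q`, `rank` (1 = strongest).
#' @export
fdr_filter_edges <- function(cands, alpha = 0.05) {
  stopifnot(all(cands$p >= 0 & cands$p <= 1))
  out <- dplyr::mutate(cands, q = p.adjust(.data$p, method = "BH"))
  out <- dplyr::filter(out, .data$q <= alpha)
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$r)), .data$gene_a, .data$gene_b)
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' Exact planarity test
#'
#' Demoucron-Malgrange-Pertuiset edge embedding per biconnected component; an
#' exact combinatorial answer, not a heuristic.
#'
#' @param edges Two-column matrix/data frame of vertex ids (integer) or an
#'   igraph graph.
#' @param n_nodes Number of vertices (ids are `1..n_nodes`). Ignored for
#'   igraph input.
#' @return Logical.
#' @export
is_planar <- function(edges, n_nodes = NULL) {
  if (inherits(edges, "igraph")) {
    n_nodes <- igraph::vcount(edges)
    edges <- igraph::as_edgelist(edges, names = FALSE)
  }
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  if (nrow(edges) == 0) return(TRUE)
  .is_planar_cpp(edges, as.integer(n_nodes))
}

#' Grow a planar filtered network (PMFG)
#'
#' Inserts the ranked candidate edges strongest-first, keeping each edge iff
#' the graph remains planar (exact test), and stops when all candidates are
#' processed or the planar edge bound `3|V| - 6` is reached.
#'
#' @param ranked_edges Tibble from [fdr_filter_edges()] (must carry `rank`).
#' @param nodes Character vector of node names (defaults to the genes on the
#'   candidate edges).
#' @param tissue Optional tissue label stored on the network.
#' @return Object of class `pfn`: list with `graph` (igraph, edge attributes
#'   `r`, `weight = |r|`, `rank`), `edges` (tibble of kept edges), `nodes`,
#'   `tissue`, `is_planar = TRUE`.
#' @export
build_pfn <- function(ranked_edges, nodes = NULL, tissue = NA_character_) {
  if (is.null(nodes)) {
    nodes <- sort(unique(c(ranked_edges$gene_a, ranked_edges$gene_b)))
  }
  stopifnot(!is.unsorted(ranked_edges$rank))
  idx <- cbind(match(ranked_edges$gene_a, nodes), match(ranked_edges$gene_b, nodes))
  storage.mode(idx) <- "integer"
  keep <- if (nrow(idx)) .pmfg_select_cpp(idx, length(nodes)) else logical(0)
  kept <- ranked_edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    kept[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  igraph::E(g)$r <- kept$r
  igraph::E(g)$weight <- abs(kept$r)
  igraph::E(g)$rank <- kept$rank
  structure(list(graph = g, edges = kept, nodes = nodes, tissue = tissue,
                 is_planar = TRUE),
            class = "pfn")
}

#' @export
tidy.pfn <- function(x, ...) x$edges

#' @export
glance.pfn <- function(x, ...) {
  tibble::tibble(
    tissue = x$tissue, n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    edge_bound = max(3 * length(x$nodes) - 6, 0),
    is_planar = x$is_planar
  )
}

#' @export
print.pfn <- function(x, ...) {
  cat("Planar filtered network", if (!is.na(x$tissue)) paste0("(", x$tissue, ")"),
      "-", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Multiscale module detection on a planar network
#'
#' Recursive modularity splitting: at each level Louvain communities are
#' computed on the (sub)graph and the split is accepted only if its
#' modularity exceeds the mean + 2 SD of modularities from `n_rewires`
#' degree-preserving edge rewires of that subgraph. Children smaller than
#' `min_module_size` stay merged in their parent; depth is capped. Each
#' connected component of the network is a separate root. This is a
#' documented functional stand-in producing a multiscale hierarchy (id,
#' parent, depth, members); the method tag is recorded on the result.
#'
#' @param pfn A [build_pfn()] result (or igraph graph).
#' @param min_module_size Minimum module size (default 10).
#' @param max_depth Maximum split depth below a root (default 4).
#' @param n_rewires Degree-preserving rewires for the null (default 100).
#' @param resolution_ladder Louvain resolution per depth (depth 1 uses the
#'   first entry, and so on; the last entry is reused below). Coarse at the
#'   top, finer deeper — the "scales of compactness" of the hierarchy.
#' @param seed Integer seed for Louvain and the rewires.
#' @return Object of class `module_hierarchy`: tibble with `module_id`,
#'   `parent_id`, `depth`, `members` (list-column), `n_genes`; attribute
#'   `method = "recursive-louvain-rewire-null"`.
#' @export
detect_modules <- function(pfn, min_module_size = 10, max_depth = 4,
                           n_rewires = 100,
                           resolution_ladder = c(0.1, 0.5, 1, 2),
                           seed = 1L) {
  g <- if (inherits(pfn, "pfn")) pfn$graph else pfn
  set.seed(seed)
  rows <- list()
  add_row <- function(id, parent, depth, members) {
    n <- length(members)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      module_id = id, parent_id = parent, depth = depth,
      members = list(sort(members)), n_genes = n
    )
  }
  accept_split <- function(sub, depth) {
    gamma <- resolution_ladder[min(depth + 1, length(resolution_ladder))]
    cl <- igraph::cluster_louvain(sub, resolution = gamma)
    if (length(unique(igraph::membership(cl))) < 2) return(NULL)
    q_obs <- igraph::modularity(sub, igraph::membership(cl), resolution = gamma)
    q_null <- vapply(seq_len(n_rewires), function(i) {
      rw <- igraph::rewire(sub, igraph::keeping_degseq(niter = max(igraph::ecount(sub) * 10, 1)))
      igraph::modularity(rw, igraph::membership(igraph::cluster_louvain(rw, resolution = gamma)),
                         resolution = gamma)
    }, numeric(1))
    if (q_obs > mean(q_null) + 2 * sd(q_null)) cl else NULL
  }
  recurse <- function(sub, id, parent, depth) {
    members <- igraph::V(sub)$name
    add_row(id, parent, depth, members)
    if (depth >= max_depth || length(members) < 2 * min_module_size ||
        igraph::ecount(sub) < 2) {
      return(invisible())
    }
    cl <- accept_split(sub, depth)
    if (is.null(cl)) return(invisible())
    mem <- igraph::membership(cl)
    sizes <- table(mem)
    big <- as.integer(names(sizes)[sizes >= min_module_size])
    if (length(big) < 1 || (length(big) == 1 && sizes[as.character(big)] == length(members))) {
      return(invisible())
    }
    child_i <- 0
    for (b in big) {
      child_i <- child_i + 1
      child_members <- names(mem)[mem == b]
      child <- igraph::induced_subgraph(sub, child_members)
      recurse(child, paste0(id, ".", child_i), id, depth + 1)
    }
    invisible()
  }
  comps <- igraph::components(g)
  root_i <- 0
  for (ci in seq_len(comps$no)) {
    vs <- names(comps$membership)[comps$membership == ci]
    if (length(vs) < min_module_size) next
    root_i <- root_i + 1
    recurse(igraph::induced_subgraph(g, vs), paste0("M", root_i), NA_character_, 0)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(module_id = character(), parent_id = character(),
                   depth = integer(), members = list(), n_genes = integer())
  }
  structure(out, method = "recursive-louvain-rewire-null",
            class = c("module_hierarchy", class(out)))
}

#' Flag hub genes within each module
#'
#' Within each module, a gene is a hub if its within-module degree strictly
#' exceeds the mean + 2 SD of within-module degrees; with zero spread the
#' threshold sits at the common degree, so regular modules have no hubs.
#' Modules with fewer than 3 genes get none.
#'
#' @param pfn A [build_pfn()] result (or igraph graph).
#' @param hierarchy A [detect_modules()] result.
#' @return Tibble `module_id`, `gene`, `degree`, `is_hub`.
#' @export
detect_hubs <- function(pfn, hierarchy) {
  g <- if (inherits(pfn, "pfn")) pfn$graph else pfn
  purrr::map_dfr(seq_len(nrow(hierarchy)), function(i) {
    members <- hierarchy$members[[i]]
    if (length(members) < 3) {
      return(tibble::tibble(module_id = character(), gene = character(),
                            degree = integer(), is_hub = logical()))
    }
    sub <- igraph::induced_subgraph(g, members)
    deg <- igraph::degree(sub)
    thr <- mean(deg) + 2 * sd(deg)
    tibble::tibble(module_id = hierarchy$module_id[i], gene = names(deg),
                   degree = as.integer(unname(deg)), is_hub = unname(deg > thr))
  })
}
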