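#' Log-normalize single-cell counts
#'
#' Global-scaling normalization: each cell's counts are divided by the cell
#' total, multiplied by `scale` (10,000 by default) and natural-log
#' transformed with a pseudocount of 1: `ln(1 + count / total * scale)`.
#'
#' @param counts Gene x cell count matrix.
#' @param scale Scale factor (default 10000).
#' @return Gene x cell matrix of normalized values (zeros stay zero).
#' @export
sc_lognormalize <- function(counts, scale = 10000) {
  tot <- colSums(counts)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0] %||% which(tot == 0)
    stop("cell(s) with zero total counts: ", paste(head(bad, 5), collapse = ", "))
  }
  log1p(sweep(counts, 2, tot, "/") * scale)
}

#' Cluster cells by PCA, KNN graph and Louvain
#'
#' Top variable genes are selected by the variance of the normalized values,
#' z-scaled, reduced by PCA, and cells are linked to their `knn_k` nearest
#' neighbors (Euclidean distance over the top `knn_pcs` principal
#' components); Louvain modularity optimization at the given resolution
#' yields the cluster labels.
#'
#' @param normalized Gene x cell matrix from [sc_lognormalize()].
#' @param n_var_genes Variable genes to keep (default 2000; all genes with a
#'   warning when fewer exist).
#' @param n_pcs Principal components to compute (default 30).
#' @param knn_pcs PCs used for the KNN graph (default 10).
#' @param knn_k Neighbors per cell (default 20).
#' @param resolution Louvain resolution (default 0.05, coarse clusters).
#' @param seed Integer seed.
#' @return Named factor of cluster labels (`c1`, `c2`, ...), one per cell.
#' @export
cluster_cells <- function(normalized, n_var_genes = 2000, n_pcs = 30,
                          knn_pcs = 10, knn_k = 20, resolution = 0.05,
                          seed = 1L) {
  n_cells <- ncol(normalized)
  if (n_cells <= knn_k) stop("need more cells than knn_k")
  if (nrow(normalized) < n_var_genes) {
    warning("fewer genes (", nrow(normalized), ") than n_var_genes; using all")
    n_var_genes <- nrow(normalized)
  }
  set.seed(seed)
  gv <- apply(normalized, 1, var)
  vg <- names(sort(gv, decreasing = TRUE))[seq_len(n_var_genes)]
  x <- normalized[vg, , drop = FALSE]
  sds <- apply(x, 1, sd)
  x <- (x - rowMeans(x)) / pmax(sds, 1e-12)
  n_pcs <- min(n_pcs, n_cells - 1, nrow(x))
  pc <- prcomp(t(x), center = FALSE, scale. = FALSE, rank. = n_pcs)
  emb <- pc$x[, seq_len(min(knn_pcs, ncol(pc$x))), drop = FALSE]
  d <- as.matrix(dist(emb))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(knn_k)]))
  el <- cbind(rep(seq_len(n_cells), each = knn_k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  labs <- igraph::membership(cl)
  setNames(factor(paste0("c", labs)), colnames(normalized))
}

#' Detect cell-type marker genes
#'
#' One-vs-rest Wilcoxon rank-sum tests on the normalized values per cell
#' type. The log fold change is on the natural-log scale,
#' `ln(mean(expm1(in)) + 1) - ln(mean(expm1(out)) + 1)`; the expressing
#' fraction is the share of in-type cells with value > 0. BH correction is
#' applied across all genes x types; only upregulated genes passing
#' `q < q_max`, `lfc >= lfc_min` and `frac_in >= min_frac` are retained.
#'
#' @param normalized Gene x cell matrix from [sc_lognormalize()].
#' @param labels Cell labels aligned with the columns.
#' @param lfc_min Minimum natural-log fold change (default 0.25).
#' @param min_frac Minimum in-type expressing fraction (default 0.25).
#' @param q_max FDR threshold (default 0.05).
#' @return Tibble `gene`, `cell_type`, `log_fold_change`, `frac_in`,
#'   `frac_out`, `p`, `q`, sorted by type then q.
#' @export
find_markers <- function(normalized, labels, lfc_min = 0.25, min_frac = 0.25,
                         q_max = 0.05) {
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(normalized))
  types <- sort(unique(labels))
  if (length(types) < 2) stop("need at least 2 cell types")
  rows <- list()
  for (tp in types) {
    idx <- labels == tp
    if (sum(idx) < 3) {
      warning("cell type ", tp, " has fewer than 3 cells; skipped")
      next
    }
    x_in <- normalized[, idx, drop = FALSE]
    x_out <- normalized[, !idx, drop = FALSE]
    lfc <- log(rowMeans(expm1(x_in)) + 1) - log(rowMeans(expm1(x_out)) + 1)
    frac_in <- rowMeans(x_in > 0)
    frac_out <- rowMeans(x_out > 0)
    p <- vapply(seq_len(nrow(normalized)), function(i) {
      a <- x_in[i, ]
      b <- x_out[i, ]
      if (all(a == a[1]) && all(b == a[1])) return(1)
      suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    }, numeric(1))
    rows[[tp]] <- tibble::tibble(
      gene = rownames(normalized), cell_type = tp, log_fold_change = lfc,
      frac_in = frac_in, frac_out = frac_out, p = p
    )
  }
  tab <- dplyr::bind_rows(rows)
  tab$q <- bh_adjust(tab$p)
  tab |>
    dplyr::filter(.data$q < q_max, .data$log_fold_change >= lfc_min,
                  .data$frac_in >= min_frac) |>
    dplyr::arrange(.data$cell_type, .data$q, dplyr::desc(.data$log_fold_change))
}

#' Per-cell gene-set enrichment by permutation GSEA
#'
#' For each cell, genes are ranked by normalized expression (descending, ties
#' broken by symbol) and the weighted-KS running-sum enrichment score of the
#' gene set is computed ([gsea_score()]); significance comes from gene-label
#' permutations. A cell is called enriched at `p < p_enriched`.
#'
#' @param normalized Gene x cell matrix from [sc_lognormalize()].
#' @param gene_set Character vector (e.g. inducer SnGs).
#' @param n_perm Permutations per cell (default 1000).
#' @param min_overlap Minimum set overlap with the matrix genes (default 5).
#' @param p_enriched Enrichment call threshold (default 0.01).
#' @param seed Integer seed.
#' @return Tibble `cell_id`, `es`, `p`, `enriched`.
#' @export
cell_gsea <- function(normalized, gene_set, n_perm = 1000, min_overlap = 5,
                      p_enriched = 0.01, seed = 1L) {
  set.seed(seed)
  purrr::map_dfr(seq_len(ncol(normalized)), function(ci) {
    sc <- gsea_score(normalized[, ci], gene_set, n_perm = n_perm,
                     min_overlap = min_overlap)
    tibble::tibble(cell_id = colnames(normalized)[ci], es = sc$es, p = sc$p,
                   enriched = !is.na(sc$p) & sc$p < p_enriched)
  })
}

#' Per-type summary of enriched cells
#'
#' Counts enriched cells per cell type and reports both framings: the
#' fraction of the type that is enriched, and the type's share of all
#' enriched cells.
#'
#' @param scores Tibble from [cell_gsea()].
#' @param labels Cell labels aligned with `scores$cell_id`.
#' @return Tibble `cell_type`, `n_cells`, `n_enriched`, `frac_of_type`,
#'   `share_of_enriched`.
#' @export
sng_cell_fractions <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(scores))
  total_enriched <- sum(scores$enriched, na.rm = TRUE)
  tibble::tibble(cell_type = labels, enriched = scores$enriched) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_enriched = sum(.data$enriched, na.rm = TRUE), .groups = "drop"
    ) |>
    dplyr::mutate(
      frac_of_type = .data$n_enriched / .data$n_cells,
      share_of_enriched = if (total_enriched > 0)
        .data$n_enriched / total_enriched else 0
    )
}
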