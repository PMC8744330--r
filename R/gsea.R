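#' Weighted-KS enrichment score over a ranked gene list
#'
#' Running-sum enrichment score: walking down the ranking, the sum rises by
#' the gene's weight (normalized so hit weights sum to 1) at gene-set hits
#' and falls by `1/(N - |S|)` at misses; the score is the maximum deviation
#' from zero (signed). Used identically for per-cell and per-voxel scoring.
#'
#' @param values Named numeric vector of expression values (names = genes).
#'   Ranking is by decreasing value, ties broken by gene symbol.
#' @param gene_set Character vector.
#' @param n_perm Gene-label permutations for the p-value (0 = score only).
#' @param min_overlap Minimum `|gene_set / ranked genes|` (default 5).
#' @return One-row tibble `es`, `p`, `n_hits`, `n_genes` (`es`/`p` are `NA`
#'   when the overlap is too small; `p` is `NA` when `n_perm = 0`).
#' @export
gsea_score <- function(values, gene_set, n_perm = 1000, min_overlap = 5) {
  ord <- order(-values, names(values))
  vals <- values[ord]
  hits <- which(names(vals) %in% gene_set)
  n <- length(vals)
  if (length(hits) < min_overlap || length(hits) >= n) {
    return(tibble::tibble(es = NA_real_, p = NA_real_,
                          n_hits = length(hits), n_genes = n))
  }
  w <- pmax(as.numeric(vals), 0)
  if (n_perm > 0) {
    res <- .gsea_es_perm_cpp(w, as.integer(hits), as.integer(n_perm))
    p <- (1 + res$n_ge) / (1 + n_perm)
    tibble::tibble(es = res$es, p = p, n_hits = length(hits), n_genes = n)
  } else {
    tibble::tibble(es = .gsea_es_cpp(w, as.integer(hits)), p = NA_real_,
                   n_hits = length(hits), n_genes = n)
  }
}
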