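#' Coexistence proportion of two genes
#'
#' Fraction of cells in which both genes have normalized expression above
#' zero — a dropout-robust co-expression proxy for single cells. Symmetric in
#' the two genes.
#'
#' @param normalized Gene x cell matrix from [sc_lognormalize()].
#' @param gene_a,gene_b Gene symbols (must be present).
#' @param cells Optional cell-id/index subset (default: all cells).
#' @param cell_type Optional label carried into the record.
#' @return One-row tibble `gene_a`, `gene_b`, `cell_type`, `n_cells`,
#'   `n_both`, `proportion`.
#' @export
coexistence_proportion <- function(normalized, gene_a, gene_b, cells = NULL,
                                   cell_type = NA_character_) {
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(normalized)) stop("gene not in matrix: ", g)
  }
  m <- if (is.null(cells)) normalized else normalized[, cells, drop = FALSE]
  if (ncol(m) < 1) stop("empty cell subset")
  both <- sum(m[gene_a, ] > 0 & m[gene_b, ] > 0)
  tibble::tibble(gene_a = gene_a, gene_b = gene_b, cell_type = cell_type,
                 n_cells = ncol(m), n_both = both,
                 proportion = both / ncol(m))
}

# vectorized: coexistence proportions of many genes with one marker
coexist_props <- function(normalized, marker, genes, cells) {
  m <- normalized[, cells, drop = FALSE]
  mk <- m[marker, ] > 0
  as.numeric((m[genes, , drop = FALSE] > 0) %*% mk) / ncol(m)
}

#' Coexistence test of query genes vs random background
#'
#' Per cell type, compares the coexistence proportions of a senescence marker
#' with each query gene against its proportions with `n_background` genes
#' sampled (without replacement) from the matrix genes excluding the marker
#' and the query set, by a two-sided Wilcoxon (Mann-Whitney) rank-sum test.
#'
#' @param normalized Gene x cell matrix.
#' @param marker_gene Senescence marker symbol.
#' @param query_genes Character vector (e.g. aggregated-network genes).
#' @param labels Cell labels aligned with the columns.
#' @param n_background Background genes to sample (default 1000, capped at
#'   the pool size).
#' @param seed Integer seed.
#' @return Tibble per cell type: `cell_type`, `n_cells`, `n_query`,
#'   `n_background`, `median_query`, `median_background`, `p`.
#' @export
coexistence_test <- function(normalized, marker_gene, query_genes, labels,
                             n_background = 1000, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(normalized))
  query_genes <- intersect(query_genes, rownames(normalized))
  if (!length(query_genes)) stop("no query genes present in the matrix")
  pool <- setdiff(rownames(normalized), c(marker_gene, query_genes))
  if (!length(pool)) stop("empty background universe")
  set.seed(seed)
  bg <- sample(pool, min(n_background, length(pool)))
  purrr::map_dfr(sort(unique(labels)), function(tp) {
    cells <- which(labels == tp)
    if (length(cells) == 0) return(tibble::tibble())
    pq <- coexist_props(normalized, marker_gene, query_genes, cells)
    pb <- coexist_props(normalized, marker_gene, bg, cells)
    p <- if (length(unique(c(pq, pb))) == 1 || identical(sort(pq), sort(pb))) 1 else
      suppressWarnings(wilcox.test(pq, pb, exact = FALSE)$p.value)
    tibble::tibble(cell_type = tp, n_cells = length(cells),
                   n_query = length(pq), n_background = length(pb),
                   median_query = median(pq), median_background = median(pb),
                   p = p)
  })
}

#' Ligand-receptor communication permutation test
#'
#' For each ordered (source, target) cell-type pair, counts the
#' ligand-receptor pairs whose ligand is a source marker and receptor a
#' target marker, and compares that count with a null in which both marker
#' sets are replaced by uniform draws (without replacement, matching sizes)
#' from the expressed genes. `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param markers Marker tibble from [find_markers()] (columns `gene`,
#'   `cell_type`).
#' @param lr_db Tibble with columns `ligand`, `receptor`.
#' @param expressed_genes Character vector: the permutation pool.
#' @param n_perm Permutations (default 10000).
#' @param alpha Significance threshold (default 0.05).
#' @param seed Integer seed.
#' @return Tibble per ordered pair: `source_type`, `target_type`,
#'   `observed_pairs`, `pairs` (list of matched ligand-receptor rows), `p`,
#'   `significant`.
#' @export
lr_communication <- function(markers, lr_db, expressed_genes, n_perm = 10000,
                             alpha = 0.05, seed = 1L) {
  if (nrow(lr_db) == 0) stop("empty ligand-receptor table")
  types <- sort(unique(markers$cell_type))
  msets <- lapply(setNames(types, types), function(tp)
    unique(markers$gene[markers$cell_type == tp]))
  gid <- setNames(seq_along(expressed_genes), expressed_genes)
  lig <- unname(gid[lr_db$ligand])
  rec <- unname(gid[lr_db$receptor])
  usable <- !is.na(lig) & !is.na(rec)
  set.seed(seed)
  out <- list()
  for (src in types) {
    for (tgt in types) {
      if (src == tgt) next
      sm <- intersect(msets[[src]], expressed_genes)
      tm <- intersect(msets[[tgt]], expressed_genes)
      hit <- lr_db$ligand %in% sm & lr_db$receptor %in% tm
      obs <- sum(hit)
      if (length(sm) == 0 || length(tm) == 0) {
        out[[paste(src, tgt)]] <- tibble::tibble(
          source_type = src, target_type = tgt, observed_pairs = 0L,
          pairs = list(lr_db[0, ]), p = 1, significant = FALSE,
          empty_markers = TRUE)
        next
      }
      nG <- length(expressed_genes)
      null_counts <- .lr_null_counts_cpp(lig[usable], rec[usable],
                                         length(sm), length(tm), nG,
                                         as.integer(n_perm))
      p <- (1 + sum(null_counts >= obs)) / (1 + n_perm)
      out[[paste(src, tgt)]] <- tibble::tibble(
        source_type = src, target_type = tgt, observed_pairs = as.integer(obs),
        pairs = list(lr_db[hit, , drop = FALSE]), p = p,
        significant = p < alpha, empty_markers = FALSE)
    }
  }
  dplyr::bind_rows(out)
}
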