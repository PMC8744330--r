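#' Normalize and scale voxel expression for ranking
#'
#' Log-normalizes voxel counts (as [sc_lognormalize()], voxels as columns)
#' and z-scales each gene across voxels, the scale on which per-voxel
#' rankings are built.
#'
#' @param counts Gene x voxel count matrix.
#' @param scale Scale factor (default 10000).
#' @return Gene x voxel matrix of z-scaled normalized expression.
#' @export
spatial_normalize <- function(counts, scale = 10000) {
  ln <- sc_lognormalize(counts, scale = scale)
  sds <- apply(ln, 1, sd)
  z <- (ln - rowMeans(ln)) / pmax(sds, 1e-12)
  z[sds == 0, ] <- 0
  z
}

#' Ranked gene list of one voxel
#'
#' Genes with value above zero, ranked by decreasing value, ties broken by
#' symbol. Voxels with fewer than `min_expressed` positive genes are skipped
#' (`NULL` with a message).
#'
#' @param voxel_values Named numeric vector (one voxel's scaled values).
#' @param min_expressed Minimum positive genes (default 50).
#' @return Named numeric vector in rank order, or `NULL`.
#' @export
rank_voxel_genes <- function(voxel_values, min_expressed = 50) {
  pos <- voxel_values[voxel_values > 0]
  if (length(pos) < min_expressed) {
    message("voxel skipped: only ", length(pos), " expressed genes")
    return(NULL)
  }
  pos[order(-pos, names(pos))]
}

#' Per-voxel module enrichment by permutation GSEA
#'
#' For each voxel, the module's weighted-KS running-sum enrichment score is
#' computed over the voxel's ranked expressed genes ([gsea_score()], the same
#' scoring core as [cell_gsea()]), with gene-label permutation p-values;
#' voxels are called enriched at `p < p_enriched`.
#'
#' @param scaled Gene x voxel matrix from [spatial_normalize()].
#' @param module_genes Character vector.
#' @param coordinates Optional tibble `voxel_id`, `row`, `col` joined onto
#'   the result.
#' @param n_perm Permutations (default 1000).
#' @param min_expressed Minimum expressed genes per voxel (default 50).
#' @param min_overlap Minimum module overlap with the ranking (default 5).
#' @param p_enriched Call threshold (default 0.01).
#' @param seed Integer seed.
#' @return Object of class `voxel_scores`: tibble `voxel_id`, `es`, `p`,
#'   `enriched` (plus coordinates when given).
#' @export
voxel_gsea <- function(scaled, module_genes, coordinates = NULL,
                       n_perm = 1000, min_expressed = 50, min_overlap = 5,
                       p_enriched = 0.01, seed = 1L) {
  set.seed(seed)
  out <- purrr::map_dfr(seq_len(ncol(scaled)), function(vi) {
    ranked <- suppressMessages(rank_voxel_genes(scaled[, vi], min_expressed))
    if (is.null(ranked)) {
      return(tibble::tibble(voxel_id = colnames(scaled)[vi], es = NA_real_,
                            p = NA_real_, enriched = NA))
    }
    sc <- gsea_score(ranked, module_genes, n_perm = n_perm,
                     min_overlap = min_overlap)
    tibble::tibble(voxel_id = colnames(scaled)[vi], es = sc$es, p = sc$p,
                   enriched = !is.na(sc$p) & sc$p < p_enriched)
  })
  if (!is.null(coordinates)) {
    out <- dplyr::left_join(out, coordinates, by = "voxel_id")
  }
  structure(out, class = c("voxel_scores", class(out)))
}

#' @export
autoplot.voxel_scores <- function(object, ...) {
  stopifnot(all(c("row", "col") %in% colnames(object)))
  ggplot(as_tibble(object), aes(x = .data$col, y = .data$row,
                                fill = .data$es)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         name = "ES") +
    geom_point(data = dplyr::filter(as_tibble(object), .data$enriched),
               shape = 21, size = 0.8, stroke = 0.3, fill = NA) +
    coord_equal() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Compare voxel cell-type compositions between enriched and other voxels
#'
#' Per cell type, a two-sided Wilcoxon (Mann-Whitney) test of the composition
#' weights in enriched vs non-enriched voxels.
#'
#' @param voxel_scores Tibble from [voxel_gsea()].
#' @param compositions Voxel x type matrix of simplex weights (rownames =
#'   voxel ids).
#' @return Tibble `cell_type`, `median_enriched`, `median_other`, `p`
#'   (`NA` with a warning if either group is empty).
#' @export
compare_compositions <- function(voxel_scores, compositions) {
  sc <- dplyr::filter(as_tibble(voxel_scores), !is.na(.data$enriched))
  enr <- sc$voxel_id[sc$enriched]
  oth <- sc$voxel_id[!sc$enriched]
  purrr::map_dfr(colnames(compositions), function(tp) {
    if (length(enr) == 0 || length(oth) == 0) {
      warning("one voxel group is empty; composition comparison is NA")
      return(tibble::tibble(cell_type = tp, median_enriched = NA_real_,
                            median_other = NA_real_, p = NA_real_))
    }
    a <- compositions[enr, tp]
    b <- compositions[oth, tp]
    p <- if (length(unique(c(a, b))) == 1 || identical(sort(a), sort(b))) 1 else
      suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    tibble::tibble(cell_type = tp, median_enriched = median(a),
                   median_other = median(b), p = p)
  })
}
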