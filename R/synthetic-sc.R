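#' Specify a synthetic single-cell cohort
#'
#' Cell types with planted marker genes (elevated by a natural-log fold
#' change), optional SnG elevation in chosen types, and independent Bernoulli
#' dropout applied per gene x cell entry after Poisson sampling.
#'
#' @param n_cells Total cells.
#' @param n_genes Genes in the universe (symbols shared with the bulk
#'   generator convention if `genes` is supplied).
#' @param genes Optional character vector of gene symbols (length `n_genes`).
#' @param cell_types List of lists with fields `name`, `proportion`,
#'   `n_marker_genes`, `marker_lfc` (natural-log fold change of the marker
#'   block in that type). Proportions must sum to 1.
#' @param base_mean Mean count per gene per cell before type effects.
#' @param dropout_rate Probability an entry is zeroed, independent of level.
#' @param planted_sng_celltypes Named list `type -> character vector` of SnG
#'   symbols elevated in that type (by `planted_lfc`).
#' @param planted_lfc Natural-log fold change for planted SnGs.
#' @param seed Integer seed.
#' @return An object of class `sc_cohort_spec`.
#' @export
sc_cohort_spec <- function(n_cells = 800L,
                           n_genes = 1000L,
                           genes = NULL,
                           cell_types = list(
                             list(name = "typeA", proportion = 0.5, n_marker_genes = 40, marker_lfc = 2),
                             list(name = "typeB", proportion = 0.3, n_marker_genes = 40, marker_lfc = 2),
                             list(name = "typeC", proportion = 0.2, n_marker_genes = 40, marker_lfc = 2)
                           ),
                           base_mean = 0.3,
                           dropout_rate = 0.2,
                           planted_sng_celltypes = list(),
                           planted_lfc = 2,
                           seed = 1L) {
  props <- vapply(cell_types, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-8) stop("cell-type proportions must sum to 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (!is.null(genes) && length(genes) != n_genes) {
    stop("genes must have length n_genes")
  }
  structure(list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    genes = genes, cell_types = cell_types, base_mean = base_mean,
    dropout_rate = dropout_rate, planted_sng_celltypes = planted_sng_celltypes,
    planted_lfc = planted_lfc, seed = as.integer(seed)
  ), class = "sc_cohort_spec")
}

#' Generate a synthetic single-cell dataset
#'
#' @param spec An [sc_cohort_spec()].
#' @return List with `counts` (gene x cell integer matrix), `labels` (named
#'   character vector of true cell types) and `truth` (tibble of planted
#'   markers per type, plus planted SnG elevations).
#' @details Counts are Poisson draws from a gene baseline (lognormal across
#'   genes around `base_mean`) times `exp(lfc)` for marker genes in their own
#'   type; dropout then zeroes each entry independently with probability
#'   `dropout_rate`. Marker blocks are disjoint across types and exclude any
#'   planted SnGs.
#' @export
gen_scrna <- function(spec) {
  stopifnot(inherits(spec, "sc_cohort_spec"))
  set.seed(spec$seed)
  genes <- spec$genes %||% sprintf("g%04d", seq_len(spec$n_genes))
  cells <- sprintf("cell%04d", seq_len(spec$n_cells))
  props <- vapply(spec$cell_types, `[[`, numeric(1), "proportion")
  type_names <- vapply(spec$cell_types, `[[`, character(1), "name")
  n_per <- diff(round(cumsum(c(0, props)) * spec$n_cells))
  labels <- setNames(rep(type_names, n_per), cells)

  sng_all <- unique(unlist(spec$planted_sng_celltypes))
  marker_pool <- setdiff(genes, sng_all)
  need <- sum(vapply(spec$cell_types, `[[`, numeric(1), "n_marker_genes"))
  if (need > length(marker_pool)) stop("not enough genes for the marker blocks")
  marker_sets <- list()
  off <- 0
  for (ct in spec$cell_types) {
    k <- ct$n_marker_genes
    marker_sets[[ct$name]] <- marker_pool[(off + 1):(off + k)]
    off <- off + k
  }

  base <- spec$base_mean * exp(rnorm(spec$n_genes, 0, 0.5))
  names(base) <- genes
  lam <- matrix(rep(base, spec$n_cells), nrow = spec$n_genes,
                dimnames = list(genes, cells))
  for (ct in spec$cell_types) {
    idx <- labels == ct$name
    lam[marker_sets[[ct$name]], idx] <- lam[marker_sets[[ct$name]], idx] * exp(ct$marker_lfc)
  }
  for (tn in names(spec$planted_sng_celltypes)) {
    gs <- intersect(spec$planted_sng_celltypes[[tn]], genes)
    idx <- labels == tn
    lam[gs, idx] <- lam[gs, idx] * exp(spec$planted_lfc)
  }
  counts <- matrix(rpois(length(lam), lam), nrow = spec$n_genes,
                   dimnames = dimnames(lam))
  if (spec$dropout_rate > 0) {
    keep <- matrix(rbinom(length(counts), 1L, 1 - spec$dropout_rate),
                   nrow = spec$n_genes)
    counts <- counts * keep
  }
  truth_markers <- dplyr::bind_rows(lapply(spec$cell_types, function(ct) {
    tibble::tibble(cell_type = ct$name, gene = marker_sets[[ct$name]],
                   lfc = ct$marker_lfc)
  }))
  list(counts = counts, labels = labels,
       truth = list(markers = truth_markers,
                    planted_sng = spec$planted_sng_celltypes))
}

#' Specify and generate a ligand-receptor table
#'
#' A stand-in for a curated ligand-receptor database: planted pairs whose
#' ligand is a marker of a source type and receptor a marker of a target
#' type, plus decoy pairs drawn from a non-marker gene pool.
#'
#' @param planted_pairs Tibble/data.frame with columns `ligand`, `receptor`.
#' @param n_decoys Number of decoy pairs.
#' @param decoy_pool Character vector of genes decoys are drawn from.
#' @param seed Integer seed.
#' @return Tibble with columns `ligand`, `receptor`, `planted` (logical).
#' @export
gen_lr_db <- function(planted_pairs, n_decoys = 0L, decoy_pool = character(),
                      seed = 1L) {
  planted_pairs <- tibble::as_tibble(planted_pairs)
  if (nrow(planted_pairs) && any(planted_pairs$ligand == planted_pairs$receptor)) {
    stop("ligand must differ from receptor within a pair")
  }
  set.seed(seed)
  out <- dplyr::mutate(planted_pairs[, c("ligand", "receptor")], planted = TRUE)
  if (n_decoys > 0) {
    if (length(decoy_pool) < 2) stop("decoy_pool too small for decoys")
    lig <- sample(decoy_pool, n_decoys, replace = TRUE)
    rec <- vapply(lig, function(l) sample(setdiff(decoy_pool, l), 1), character(1))
    out <- dplyr::bind_rows(out, tibble::tibble(ligand = lig, receptor = unname(rec),
                                                planted = FALSE))
  }
  out
}
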