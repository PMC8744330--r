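#' Specify a synthetic spatial transcriptomic slide
#'
#' Voxels sit on a rectangular grid; each voxel's expression is a
#' composition-weighted mixture of cell-type mean profiles, with a designated
#' module's genes elevated inside a planted enriched region.
#'
#' @param n_voxels Number of voxels (laid out on a near-square grid).
#' @param n_genes Genes in the universe.
#' @param genes Optional gene symbols (length `n_genes`).
#' @param n_cell_types Number of cell types mixed per voxel.
#' @param markers_per_type Marker genes per cell type (elevated `marker_lfc`
#'   in that type's mean profile).
#' @param marker_lfc Natural-log elevation of type markers in the profile.
#' @param module_genes Character vector: the gene set elevated inside the
#'   enriched region (defaults to the markers of type 1).
#' @param region_fraction Fraction of the grid (a corner block) forming the
#'   enriched region; those voxels are also skewed toward cell type 1.
#' @param enriched_offset Natural-log elevation of `module_genes` in region
#'   voxels.
#' @param base_mean Baseline mean count per gene per voxel.
#' @param noise_sd Lognormal noise SD on the voxel lambda (0 = noise-free
#'   mixture).
#' @param count_model `"poisson"` for integer counts, `"none"` to return the
#'   continuous mixture itself (useful for exact mixture checks).
#' @param seed Integer seed.
#' @return An object of class `spatial_spec`.
#' @export
spatial_spec <- function(n_voxels = 400L,
                         n_genes = 600L,
                         genes = NULL,
                         n_cell_types = 4L,
                         markers_per_type = 50L,
                         marker_lfc = 2,
                         module_genes = NULL,
                         region_fraction = 0.2,
                         enriched_offset = 1.5,
                         base_mean = 0.5,
                         noise_sd = 0.2,
                         count_model = c("poisson", "none"),
                         seed = 1L) {
  count_model <- match.arg(count_model)
  if (!is.null(genes) && length(genes) != n_genes) stop("genes must match n_genes")
  structure(list(
    n_voxels = as.integer(n_voxels), n_genes = as.integer(n_genes),
    genes = genes, n_cell_types = as.integer(n_cell_types),
    markers_per_type = as.integer(markers_per_type), marker_lfc = marker_lfc,
    module_genes = module_genes, region_fraction = region_fraction,
    enriched_offset = enriched_offset, base_mean = base_mean,
    noise_sd = noise_sd, count_model = count_model, seed = as.integer(seed)
  ), class = "spatial_spec")
}

#' Generate a synthetic spatial slide
#'
#' @param spec A [spatial_spec()].
#' @param compositions Optional voxel x type matrix of simplex weights
#'   overriding the generated compositions (rows must sum to 1).
#' @return List with `counts` (gene x voxel matrix), `coordinates` (tibble
#'   `voxel_id, row, col`), `compositions` (voxel x type matrix), `truth`
#'   (region voxel ids, module genes, type profiles).
#' @export
gen_spatial <- function(spec, compositions = NULL) {
  stopifnot(inherits(spec, "spatial_spec"))
  set.seed(spec$seed)
  genes <- spec$genes %||% sprintf("g%04d", seq_len(spec$n_genes))
  nv <- spec$n_voxels
  nr <- ceiling(sqrt(nv))
  coords <- tibble::tibble(
    voxel_id = sprintf("vox%04d", seq_len(nv)),
    row = ((seq_len(nv) - 1) %/% nr) + 1,
    col = ((seq_len(nv) - 1) %% nr) + 1
  )
  nt <- spec$n_cell_types
  # type mean profiles: shared baseline, markers elevated per type
  base <- spec$base_mean * exp(rnorm(spec$n_genes, 0, 0.3))
  profiles <- matrix(rep(base, nt), nrow = spec$n_genes,
                     dimnames = list(genes, paste0("type", seq_len(nt))))
  need <- nt * spec$markers_per_type
  if (need > spec$n_genes) stop("not enough genes for type marker blocks")
  for (t in seq_len(nt)) {
    idx <- ((t - 1) * spec$markers_per_type + 1):(t * spec$markers_per_type)
    profiles[idx, t] <- profiles[idx, t] * exp(spec$marker_lfc)
  }
  module_genes <- spec$module_genes %||% genes[seq_len(spec$markers_per_type)]

  # enriched region: top-left grid block covering ~region_fraction of voxels
  side <- ceiling(sqrt(spec$region_fraction) * nr)
  in_region <- coords$row <= side & coords$col <= side
  region_ids <- coords$voxel_id[in_region]

  if (is.null(compositions)) {
    a <- matrix(stats::rgamma(nv * nt, shape = 1), nrow = nv)
    a[in_region, 1] <- a[in_region, 1] + 4  # region skews toward type 1
    compositions <- a / rowSums(a)
    dimnames(compositions) <- list(coords$voxel_id, colnames(profiles))
  } else {
    stopifnot(nrow(compositions) == nv, ncol(compositions) == nt)
    if (any(abs(rowSums(compositions) - 1) > 1e-8) || any(compositions < 0)) {
      stop("compositions must be nonnegative simplex weights per voxel")
    }
  }

  lam <- profiles %*% t(compositions)  # gene x voxel mixture
  lam[module_genes, in_region] <- lam[module_genes, in_region] * exp(spec$enriched_offset)
  if (spec$noise_sd > 0) {
    lam <- lam * exp(matrix(rnorm(length(lam), 0, spec$noise_sd), nrow(lam)))
  }
  counts <- if (spec$count_model == "poisson") {
    matrix(rpois(length(lam), lam), nrow = nrow(lam), dimnames = dimnames(lam))
  } else {
    lam
  }
  colnames(counts) <- coords$voxel_id
  list(counts = counts, coordinates = coords, compositions = compositions,
       truth = list(region = region_ids, module_genes = module_genes,
                    profiles = profiles))
}
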