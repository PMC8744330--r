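#' Pipeline configuration
#'
#' Flat key-value configuration for a full landscape run, with the
#' method-default thresholds: edge FDR 0.05; module enrichment q 0.05;
#' consensus k-means k = 4 with 100 runs; minimum conservation weight 5;
#' 3-layer neighborhoods; single-cell scale factor 10,000; marker thresholds
#' FDR 0.05 / lfc 0.25 / fraction 0.25; 1,000 GSEA permutations; 10,000
#' ligand-receptor permutations; voxel call p < 0.01. Unknown keys are
#' errors. One master `seed` deterministically derives per-stage seeds
#' (stage offsets 1..9), so any stage is reproducible in isolation.
#'
#' @param ... Overrides of the defaults listed above (see the function
#'   definition for the full key set, e.g. `n_tissues`, `n_genes`,
#'   `n_samples`, `module_size`, `module_rho`, `n_sng`, `edge_fdr`,
#'   `module_q`, `kmeans_k`, `kmeans_runs`, `min_node_weight`,
#'   `neighborhood_layers`, `sc_n_cells`, `sc_scale`, `marker_q`,
#'   `marker_lfc`, `marker_frac`, `gsea_nperm`, `lr_nperm`, `voxel_p`,
#'   `n_voxels`, `seed`).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # synthetic cohort
    n_tissues = 3L, n_genes = 300L, n_samples = 40L,
    n_modules = 2L, module_size = 50L, module_rho = 0.7,
    n_sng = 60L, sng_planted_per_tissue = 30L,
    # bulk preprocessing / networks
    include_age = FALSE, edge_fdr = 0.05,
    min_module_size = 10L, max_depth = 4L, n_rewires = 100L,
    # enrichment / landscape
    module_q = 0.05, kmeans_k = 4L, kmeans_runs = 100L,
    min_tissue_fraction = 0.5,
    # aggregation
    min_node_weight = 5L, min_edge_weight = 1L, neighborhood_layers = 3L,
    neighborhood_seed_gene = NULL,
    # single cell
    sc_n_cells = 800L, sc_scale = 10000, sc_resolution = 0.05,
    marker_q = 0.05, marker_lfc = 0.25, marker_frac = 0.25,
    gsea_nperm = 1000L, gsea_p = 0.01,
    # interactions
    n_background = 1000L, lr_nperm = 10000L, lr_n_decoys = 40L,
    # spatial
    n_voxels = 400L, voxel_p = 0.01,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file of overrides.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_stage_tsv <- function(x, out_dir, name) {
  p <- file.path(out_dir, paste0(name, ".tsv"))
  df <- as.data.frame(x)
  df <- df[!vapply(df, is.list, logical(1))]
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

#' Run the full senescence-landscape pipeline on a synthetic cohort
#'
#' Generates every input from the configuration (bulk cohort with planted SnG
#' modules, SnG annotation, single-cell cohort with the SnG inducers elevated
#' in one type, ligand-receptor table, spatial slide with an enriched
#' region), then runs preprocessing, per-tissue planar networks and modules,
#' SnG enrichment, presence-matrix consensus clustering, conservation
#' aggregation and seed-gene neighborhoods, single-cell markers and per-cell
#' GSEA, coexistence and ligand-receptor tests, and per-voxel GSEA with
#' composition comparison. All stage outputs are written as TSV under
#' `out_dir` with a JSON manifest carrying the config, the per-stage seeds
#' and the md5 checksum of every file; identical config implies identical
#' checksums.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible list of all in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("senescape_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- setNames(vapply(1:9, function(i) derive_seed(config$seed, i), numeric(1)),
                    c("synth", "network", "flagging", "landscape", "aggregate",
                      "single_cell", "interactions", "spatial", "extra"))
  files <- character()

  # --- stage 1: synthetic inputs -------------------------------------------
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  sng <- gen_sng_annotation(genes, config$n_sng, seed = seeds[["synth"]])
  mods <- replicate(config$n_modules,
                    c(config$module_size, config$module_rho), simplify = FALSE)
  bspec <- bulk_cohort_spec(
    n_tissues = config$n_tissues, n_genes = config$n_genes,
    n_samples_per_tissue = config$n_samples, modules_per_tissue = mods,
    sng_genes = head(sng$gene, config$sng_planted_per_tissue),
    age_effect_modules = 1L, seed = seeds[["synth"]]
  )
  bulk <- gen_bulk_cohort(bspec)
  inducers <- sng$gene[sng$role == "inducer"]
  scspec <- sc_cohort_spec(
    n_cells = config$sc_n_cells, n_genes = config$n_genes, genes = genes,
    planted_sng_celltypes = list(typeA = intersect(inducers, bspec$sng_genes)),
    seed = seeds[["synth"]]
  )
  sc <- gen_scrna(scspec)
  mk_truth <- sc$truth$markers
  planted_lr <- tibble::tibble(
    ligand = head(mk_truth$gene[mk_truth$cell_type == "typeA"], 10),
    receptor = head(mk_truth$gene[mk_truth$cell_type == "typeB"], 10)
  )
  lr_db <- gen_lr_db(planted_lr, n_decoys = config$lr_n_decoys,
                     decoy_pool = setdiff(genes, mk_truth$gene),
                     seed = seeds[["synth"]])

  # --- stage 2-3: preprocess + networks ------------------------------------
  pfns <- list()
  hierarchies <- list()
  resid <- list()
  for (tn in names(bulk$tissues)) {
    tt <- bulk$tissues[[tn]]
    resid[[tn]] <- preprocess_tissue(tt$counts, tt$covariates,
                                     include_age = config$include_age)
    edges <- fdr_filter_edges(pairwise_pcc(resid[[tn]]), alpha = config$edge_fdr)
    pfns[[tn]] <- build_pfn(edges, nodes = rownames(resid[[tn]]), tissue = tn)
    hierarchies[[tn]] <- detect_modules(
      pfns[[tn]], min_module_size = config$min_module_size,
      max_depth = config$max_depth, n_rewires = config$n_rewires,
      seed = derive_seed(seeds[["network"]], match(tn, names(bulk$tissues)))
    )
  }
  files["networks"] <- write_stage_tsv(
    purrr::imap_dfr(pfns, function(p, tn) dplyr::mutate(tidy(p), tissue = tn)),
    out_dir, "network_edges")

  # --- stage 4: SnG enrichment ----------------------------------------------
  universes <- lapply(resid, rownames)
  flagged <- flag_sng_modules(hierarchies, sng$gene, universes = universes,
                              alpha_q = config$module_q)
  files["flagged"] <- write_stage_tsv(flagged, out_dir, "flagged_modules")

  # --- stage 5: presence matrix + consensus clustering ----------------------
  presence <- suppressMessages(build_presence_matrix(flagged, sng$gene))
  k_eff <- min(config$kmeans_k, nrow(presence) - 1)
  rowcl <- consensus_kmeans(presence, k = k_eff, runs = config$kmeans_runs,
                            axis = "rows", seed = seeds[["landscape"]])
  colcl <- consensus_kmeans(presence, k = min(k_eff, ncol(presence)),
                            runs = config$kmeans_runs, axis = "cols",
                            seed = seeds[["landscape"]])
  conserved <- select_conserved_sngs(
    rowcl, presence, min_tissue_fraction = config$min_tissue_fraction)
  files["presence"] <- write_stage_tsv(
    data.frame(gene = rownames(presence), presence, check.names = FALSE),
    out_dir, "presence_matrix")
  files["row_clusters"] <- write_stage_tsv(tidy(rowcl), out_dir, "sng_clusters")

  # --- stage 6: aggregation + neighborhoods ---------------------------------
  subnets <- suppressMessages(tissue_subnetworks(pfns, flagged))
  agg <- aggregate_networks(subnets,
                            min_node_weight = min(config$min_node_weight, length(subnets)),
                            min_edge_weight = config$min_edge_weight)
  seed_gene <- config$neighborhood_seed_gene %||% bspec$sng_genes[1]
  neighs <- lapply(pfns, neighborhood, seed_gene = seed_gene,
                   layers = config$neighborhood_layers)
  cons_neigh <- consensus_neighborhood(
    neighs, seed_gene,
    min_node_weight = min(config$min_node_weight, length(pfns)))
  files["aggregate_nodes"] <- write_stage_tsv(agg$nodes, out_dir, "aggregate_nodes")
  files["aggregate_edges"] <- write_stage_tsv(agg$edges, out_dir, "aggregate_edges")

  # --- stage 7: single cell -------------------------------------------------
  norm <- sc_lognormalize(sc$counts, scale = config$sc_scale)
  clusters <- cluster_cells(norm, resolution = config$sc_resolution,
                            seed = seeds[["single_cell"]])
  markers <- find_markers(norm, sc$labels, lfc_min = config$marker_lfc,
                          min_frac = config$marker_frac, q_max = config$marker_q)
  gsea_set <- intersect(inducers, rownames(norm))
  cells <- cell_gsea(norm, gsea_set, n_perm = config$gsea_nperm,
                     p_enriched = config$gsea_p, seed = seeds[["single_cell"]])
  fractions <- sng_cell_fractions(cells, sc$labels)
  files["markers"] <- write_stage_tsv(markers, out_dir, "marker_table")
  files["cell_scores"] <- write_stage_tsv(cells, out_dir, "cell_gsea")
  files["cell_fractions"] <- write_stage_tsv(fractions, out_dir, "cell_fractions")

  # --- stage 8: interactions ------------------------------------------------
  marker_sng <- intersect(scspec$planted_sng_celltypes$typeA, rownames(norm))[1]
  coexist <- coexistence_test(
    norm, marker_sng, intersect(agg$nodes$gene, rownames(norm)),
    sc$labels, n_background = config$n_background,
    seed = seeds[["interactions"]])
  expressed <- rownames(norm)[rowMeans(norm > 0) >= 0.01]
  lr <- lr_communication(markers, lr_db, expressed, n_perm = config$lr_nperm,
                         seed = seeds[["interactions"]])
  files["coexistence"] <- write_stage_tsv(coexist, out_dir, "coexistence")
  files["lr"] <- write_stage_tsv(lr, out_dir, "lr_communication")

  # --- stage 9: spatial -----------------------------------------------------
  planted_module_genes <- bulk$truth$membership |>
    dplyr::filter(.data$tissue == names(bulk$tissues)[1],
                  .data$module == bulk$truth$planted_module[1]) |>
    dplyr::pull(.data$gene)
  sspec <- spatial_spec(n_voxels = config$n_voxels, n_genes = config$n_genes,
                        genes = genes, module_genes = planted_module_genes,
                        seed = seeds[["spatial"]])
  spatial <- gen_spatial(sspec)
  scaled <- spatial_normalize(spatial$counts)
  vox <- voxel_gsea(scaled, planted_module_genes,
                    coordinates = spatial$coordinates,
                    n_perm = config$gsea_nperm, p_enriched = config$voxel_p,
                    seed = seeds[["spatial"]])
  comp <- compare_compositions(vox, spatial$compositions)
  files["voxel_scores"] <- write_stage_tsv(vox, out_dir, "voxel_gsea")
  files["compositions"] <- write_stage_tsv(comp, out_dir, "voxel_compositions")

  manifest <- list(
    package_version = as.character(utils::packageVersion("senescape")),
    method_tags = list(modules = "recursive-louvain-rewire-null",
                       gsea = "weighted-ks-gene-label-permutation"),
    config = unclass(config),
    seeds = as.list(seeds),
    files = as.list(setNames(basename(unname(files)), names(files))),
    checksums = as.list(tools::md5sum(unname(files)))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(
    bulk = bulk, sng = sng, resid = resid, pfns = pfns,
    hierarchies = hierarchies, flagged = flagged, presence = presence,
    row_clusters = rowcl, col_clusters = colcl, conserved = conserved,
    aggregate = agg, consensus_neighborhood = cons_neigh, sc = sc,
    markers = markers, cell_scores = cells, cell_fractions = fractions,
    coexistence = coexist, lr = lr, spatial = spatial, voxel_scores = vox,
    composition_comparison = comp, manifest = manifest,
    manifest_path = manifest_path, out_dir = out_dir
  ))
}
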