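test_that("bulk generator is deterministic and respects module structure", {
  spec <- bulk_cohort_spec(n_tissues = 2, n_genes = 120,
                           n_samples_per_tissue = 30,
                           modules_per_tissue = list(c(30, 0.7)),
                           seed = 7)
  a <- gen_bulk_cohort(spec)
  b <- gen_bulk_cohort(spec)
  expect_identical(a, b)
  counts <- a$tissues[[1]]$counts
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  expect_equal(dim(counts), c(120, 30))
  expect_setequal(unique(a$tissues[[1]]$covariates$age), seq(25, 75, 10)[
    seq(25, 75, 10) %in% a$tissues[[1]]$covariates$age])
})

test_that("planted within-module correlation is recovered (brute-force pairwise r)", {
  spec <- bulk_cohort_spec(n_tissues = 1, n_genes = 100,
                           n_samples_per_tissue = 100,
                           modules_per_tissue = list(c(50, 0.7)),
                           covariate_effects = numeric(), seed = 3)
  cohort <- gen_bulk_cohort(spec)
  counts <- cohort$tissues[[1]]$counts
  le <- log2(sweep(counts, 2, colSums(counts), "/") * 1e6 + 1)
  mem <- cohort$truth$membership$gene[cohort$truth$membership$module == 1]
  cm <- cor(t(le[mem, ]))
  mean_abs_r <- mean(abs(cm[upper.tri(cm)]))
  expect_gt(mean_abs_r, 0.6)
  expect_lt(mean_abs_r, 0.8)
  # off-module pairs stay near zero
  off <- setdiff(rownames(le), mem)
  cm0 <- cor(t(le[off[1:30], ]))
  expect_lt(mean(abs(cm0[upper.tri(cm0)])), 0.2)
})

test_that("SnG annotation has requested size, labels and determinism", {
  genes <- sprintf("g%04d", 1:500)
  s <- gen_sng_annotation(genes, 279, seed = 1)
  expect_equal(nrow(s), 279)
  expect_equal(anyDuplicated(s$gene), 0)
  expect_setequal(unique(s$role), c("inducer", "inhibitor"))
  expect_equal(sum(s$role == "inducer"), 153)
  expect_identical(s, gen_sng_annotation(genes, 279, seed = 1))
  expect_equal(nrow(gen_sng_annotation(genes, 0, seed = 1)), 0)
  expect_error(gen_sng_annotation(genes, 501, seed = 1), "exceeds")
})

test_that("single-cell generator plants markers and applies dropout", {
  spec0 <- sc_cohort_spec(n_cells = 200, n_genes = 150, dropout_rate = 0,
                          cell_types = list(list(name = "only", proportion = 1,
                                                 n_marker_genes = 0, marker_lfc = 0)),
                          seed = 2)
  one <- gen_scrna(spec0)
  expect_equal(as.vector(table(one$labels)), 200)
  # marker elevation across seeds (Monte-Carlo): planted LFC 3 marker mean
  # higher in its own type in >= 95% of seeds
  hits <- vapply(1:20, function(sd) {
    sp <- sc_cohort_spec(
      n_cells = 150, n_genes = 80, dropout_rate = 0.1,
      cell_types = list(
        list(name = "A", proportion = 0.5, n_marker_genes = 5, marker_lfc = 3),
        list(name = "B", proportion = 0.5, n_marker_genes = 5, marker_lfc = 3)),
      seed = sd)
    d <- gen_scrna(sp)
    mk <- d$truth$markers$gene[d$truth$markers$cell_type == "A"][1]
    mean(d$counts[mk, d$labels == "A"]) > mean(d$counts[mk, d$labels == "B"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # dropout: zero fraction rises accordingly (direct count)
  spA <- sc_cohort_spec(n_cells = 300, n_genes = 200, dropout_rate = 0, seed = 4)
  spB <- sc_cohort_spec(n_cells = 300, n_genes = 200, dropout_rate = 0.9, seed = 4)
  a <- gen_scrna(spA)$counts
  b <- gen_scrna(spB)$counts
  kept_nonzero <- sum(b > 0) / sum(a > 0)
  expect_lt(kept_nonzero, 0.12) # ~10% of pre-dropout nonzeros survive
  expect_identical(b, gen_scrna(spB)$counts)
})

test_that("LR generator returns planted pairs exactly when decoy-free", {
  planted <- tibble::tibble(ligand = c("g1", "g2"), receptor = c("g3", "g4"))
  db <- gen_lr_db(planted, n_decoys = 0)
  expect_equal(db$ligand, planted$ligand)
  expect_equal(db$receptor, planted$receptor)
  expect_error(gen_lr_db(tibble::tibble(ligand = "g1", receptor = "g1")),
               "differ")
  db2 <- gen_lr_db(planted, n_decoys = 10, decoy_pool = sprintf("d%02d", 1:20),
                   seed = 3)
  expect_equal(nrow(db2), 12)
  expect_true(all(db2$ligand != db2$receptor))
})

test_that("spatial voxels are exact composition mixtures at zero noise", {
  sp <- spatial_spec(n_voxels = 25, n_genes = 60, n_cell_types = 3,
                     markers_per_type = 10, region_fraction = 0,
                     enriched_offset = 0, noise_sd = 0, count_model = "none",
                     seed = 6)
  # pure type-1 voxels
  comp <- matrix(0, 25, 3)
  comp[, 1] <- 1
  d <- gen_spatial(sp, compositions = comp)
  expect_equal(unname(d$counts[, 1]), unname(d$truth$profiles[, 1]))
  # random compositions: brute-force mixing oracle
  set.seed(9)
  a <- matrix(rgamma(25 * 3, 1), 25, 3)
  comp2 <- a / rowSums(a)
  d2 <- gen_spatial(sp, compositions = comp2)
  for (v in c(1, 7, 25)) {
    manual <- d2$truth$profiles %*% comp2[v, ]
    expect_equal(unname(d2$counts[, v]), unname(manual[, 1]), tolerance = 1e-12)
  }
})

test_that("written fixtures round-trip: GMT, TSV, MTX, LR table", {
  td <- withr::local_tempdir()
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9"))
  read_back <- read_gmt(write_gmt(sets, file.path(td, "sets.gmt")))
  expect_identical(read_back, sets)
  m <- matrix(rpois(20, 5), 4, 5,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  expect_identical(read_counts_tsv(write_counts_tsv(m, file.path(td, "m.tsv"))),
                   m)
  m2 <- read_counts_mtx(write_counts_mtx(m, file.path(td, "sc")))
  expect_equal(m2, m, ignore_attr = FALSE)
  lr <- tibble::tibble(ligand = c("g1", "g2"), receptor = c("g3", "g4"))
  expect_equal(read_lr_tsv(write_lr_tsv(lr, file.path(td, "lr.tsv"))), lr)
})
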