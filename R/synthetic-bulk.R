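#' Specify a synthetic bulk expression cohort
#'
#' Describes a multi-tissue bulk RNA-seq cohort with blockwise-correlated gene
#' modules, planted senescence genes (SnGs), sample covariates and optional
#' linear age trends. The generated data have the statistical structure the
#' downstream network pipeline assumes: within a module, latent log-expression
#' follows a single-factor model whose pairwise Pearson correlation equals
#' `within_correlation`; counts are lognormal-Poisson (overdispersed);
#' covariate and age effects act additively on the latent log scale.
#'
#' @param n_tissues Number of tissues.
#' @param n_genes Genes in the universe (symbols `g0001`, ...).
#' @param n_samples_per_tissue Samples per tissue (donor cohorts in the
#'   emulated resource range from 20 to 663; default 60).
#' @param modules_per_tissue List of `c(size, rho)` pairs: module sizes and
#'   within-module correlations in (0, 1). Module m occupies a fixed slice of
#'   the gene universe, shared across tissues so cross-tissue conservation is
#'   a controlled truth.
#' @param sng_genes Character vector of SnG symbols (subset of the universe).
#' @param sng_planting Named integer vector `tissue -> module index`; in that
#'   tissue the SnGs are added to the module's factor block.
#' @param covariate_effects Named numeric vector, latent log-expression units
#'   per covariate SD (numeric covariates) or per level contrast
#'   (`site`, `sex`).
#' @param age_effect_modules Integer vector of module indices receiving a
#'   linear age trend.
#' @param age_slope Latent log-expression units per decade of age.
#' @param base_log_mean,base_log_sd Gene baseline abundance: log-mean counts
#'   are drawn from N(`base_log_mean`, `base_log_sd`).
#' @param noise_sd Gene-level latent noise SD (log scale).
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return An object of class `bulk_cohort_spec`.
#' @export
bulk_cohort_spec <- function(n_tissues = 3L,
                             n_genes = 300L,
                             n_samples_per_tissue = 60L,
                             modules_per_tissue = list(c(50, 0.7), c(50, 0.7)),
                             sng_genes = character(),
                             sng_planting = NULL,
                             covariate_effects = c(rin = 0.4, ischemic_time = 0.2),
                             age_effect_modules = integer(),
                             age_slope = 0.15,
                             base_log_mean = log(100),
                             base_log_sd = 0.4,
                             noise_sd = 0.5,
                             seed = 1L) {
  sizes <- vapply(modules_per_tissue, `[`, numeric(1), 1)
  rhos <- vapply(modules_per_tissue, `[`, numeric(1), 2)
  if (sum(sizes) > n_genes) {
    stop("module sizes (", sum(sizes), ") exceed n_genes (", n_genes, ")")
  }
  if (any(rhos <= 0 | rhos >= 1)) {
    stop("within_correlation must lie strictly in (0, 1)")
  }
  if (is.null(sng_planting)) {
    sng_planting <- setNames(rep(1L, n_tissues), paste0("tissue", seq_len(n_tissues)))
  }
  structure(list(
    n_tissues = as.integer(n_tissues), n_genes = as.integer(n_genes),
    n_samples_per_tissue = as.integer(n_samples_per_tissue),
    modules_per_tissue = modules_per_tissue, sng_genes = sng_genes,
    sng_planting = sng_planting, covariate_effects = covariate_effects,
    age_effect_modules = as.integer(age_effect_modules), age_slope = age_slope,
    base_log_mean = base_log_mean, base_log_sd = base_log_sd,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "bulk_cohort_spec")
}

#' Generate a synthetic multi-tissue bulk cohort
#'
#' @param spec A [bulk_cohort_spec()].
#' @return A list with `tissues` (named list; each has `counts`, a gene x
#'   sample integer matrix, and `covariates`, a tibble with one row per
#'   sample) and `truth` (module membership tibble, planted SnG module per
#'   tissue, ages).
#' @details Donor age is recorded as decade-bin midpoints (25, 35, ..., 75),
#'   mirroring cohorts whose donor ages are released as ten-year ranges, so
#'   age correlation analyses run on the mean value of the range.
#' @export
gen_bulk_cohort <- function(spec) {
  stopifnot(inherits(spec, "bulk_cohort_spec"))
  set.seed(spec$seed)
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  sng <- spec$sng_genes
  if (length(sng) && !all(sng %in% genes)) {
    stop("sng_genes must be drawn from the gene universe")
  }
  sizes <- vapply(spec$modules_per_tissue, `[`, numeric(1), 1)
  rhos <- vapply(spec$modules_per_tissue, `[`, numeric(1), 2)
  n_mod <- length(sizes)
  # fixed, non-SnG module slices shared across tissues
  pool <- setdiff(genes, sng)
  if (sum(sizes) > length(pool)) stop("module sizes exceed non-SnG gene pool")
  offs <- cumsum(c(0, sizes))
  slices <- lapply(seq_len(n_mod), function(m) pool[(offs[m] + 1):offs[m + 1]])
  base_mu <- rnorm(spec$n_genes, spec$base_log_mean, spec$base_log_sd)
  names(base_mu) <- genes

  tissues <- list()
  truth_rows <- list()
  tissue_names <- names(spec$sng_planting)
  if (length(tissue_names) != spec$n_tissues) {
    tissue_names <- paste0("tissue", seq_len(spec$n_tissues))
  }
  ns <- spec$n_samples_per_tissue
  for (ti in seq_len(spec$n_tissues)) {
    tn <- tissue_names[ti]
    covars <- tibble::tibble(
      sample_id = sprintf("%s_s%03d", tn, seq_len(ns)),
      site = sample(c("siteA", "siteB", "siteC"), ns, replace = TRUE),
      rin = rnorm(ns, 7, 1),
      ischemic_time = rnorm(ns, 400, 150),
      exonic_rate = rnorm(ns, 0.8, 0.04),
      rrna_rate = rnorm(ns, 0.02, 0.008),
      intergenic_rate = rnorm(ns, 0.05, 0.015),
      sex = sample(c("M", "F"), ns, replace = TRUE),
      age = sample(seq(25, 75, by = 10), ns, replace = TRUE)
    )
    membership <- slices
    planted <- spec$sng_planting[[tn]] %||% spec$sng_planting[[ti]]
    if (length(sng)) {
      membership[[planted]] <- c(membership[[planted]], sng)
    }
    x <- matrix(rep(base_mu, ns), nrow = spec$n_genes,
                dimnames = list(genes, covars$sample_id))
    # latent gene noise
    x <- x + matrix(rnorm(spec$n_genes * ns, 0, spec$noise_sd), spec$n_genes)
    # module factors: loading magnitude b gives pairwise latent |r| = rho;
    # random loading signs keep the block library-size neutral (the network
    # is unsigned, so sign-balanced modules are equivalent)
    signs <- lapply(membership, function(g) sample(c(-1, 1), length(g), replace = TRUE))
    for (m in seq_len(n_mod)) {
      b <- spec$noise_sd * sqrt(rhos[m] / (1 - rhos[m]))
      f <- rnorm(ns)
      if (m %in% spec$age_effect_modules) {
        # the module factor itself trends with age, so the module eigengene
        # carries the age signal
        f <- f + spec$age_slope * (covars$age - 50) / 10
      }
      x[membership[[m]], ] <- x[membership[[m]], ] + signs[[m]] %o% (b * f)
    }
    # covariate effects: one shared shift per sample (what residualization removes)
    shift <- numeric(ns)
    for (cv in names(spec$covariate_effects)) {
      eff <- spec$covariate_effects[[cv]]
      z <- switch(cv,
        site = as.numeric(factor(covars$site)) - 2,
        sex = ifelse(covars$sex == "M", 0.5, -0.5),
        {
          v <- covars[[cv]]
          (v - mean(v)) / stats::sd(v)
        }
      )
      shift <- shift + eff * z
    }
    x <- x + matrix(rep(shift, each = spec$n_genes), nrow = spec$n_genes)
    counts <- matrix(rpois(length(x), exp(x)), nrow = spec$n_genes,
                     dimnames = dimnames(x))
    tissues[[tn]] <- list(counts = counts, covariates = covars)
    truth_rows[[tn]] <- tibble::tibble(
      tissue = tn,
      module = rep(seq_len(n_mod), lengths(membership)),
      gene = unlist(membership),
      loading_sign = unlist(signs),
      planted_sng_module = planted
    )
  }
  list(
    tissues = tissues,
    truth = list(
      membership = dplyr::bind_rows(truth_rows),
      planted_module = vapply(tissue_names, function(tn)
        spec$sng_planting[[tn]] %||% 1L, numeric(1)),
      sng_genes = sng,
      genes = genes
    )
  )
}

#' Generate a stand-in senescence-gene annotation
#'
#' Draws `n_total` unique symbols from the gene universe and labels each as a
#' senescence inducer or inhibitor, emulating a curated SnG catalogue (the
#' reference catalogue holds 279 experimentally validated genes, of which 153
#' are inducers).
#'
#' @param universe Character vector of candidate symbols.
#' @param n_total Number of SnGs to draw (must not exceed the universe).
#' @param inducer_fraction Fraction labelled `"inducer"`; the rest are
#'   `"inhibitor"`. Default 153/279.
#' @param seed Integer seed.
#' @return Tibble with columns `gene` and `role`.
#' @export
gen_sng_annotation <- function(universe, n_total, inducer_fraction = 153 / 279,
                               seed = 1L) {
  if (n_total > length(universe)) {
    stop("n_total (", n_total, ") exceeds the universe size (", length(universe), ")")
  }
  set.seed(seed)
  if (n_total == 0) {
    return(tibble::tibble(gene = character(), role = character()))
  }
  g <- sample(universe, n_total)
  n_ind <- round(inducer_fraction * n_total)
  tibble::tibble(
    gene = g,
    role = c(rep("inducer", n_ind), rep("inhibitor", n_total - n_ind))
  )
}
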