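#' Fisher's exact enrichment of a module against a gene set
#'
#' One-tailed hypergeometric enrichment p-value (probability of an overlap at
#' least as large, given the margins) plus fold enrichment
#' `FE = (overlap / module) / (set / universe)`. The universe defaults to the
#' genes of the tissue's network (post-filter), which must contain both sets.
#'
#' @param module_genes Character vector.
#' @param gene_set Character vector.
#' @param universe Character vector containing both.
#' @param module_id,set_name Optional labels carried into the result.
#' @return One-row tibble: `module_id`, `set_name`, `overlap`, `module_size`,
#'   `set_size`, `universe_size`, `fold_enrichment`, `p`.
#' @export
fisher_enrichment <- function(module_genes, gene_set, universe,
                              module_id = NA_character_,
                              set_name = NA_character_) {
  module_genes <- unique(module_genes)
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!all(module_genes %in% universe) || !all(gene_set %in% universe)) {
    stop("module_genes and gene_set must be subsets of the universe")
  }
  nm <- length(module_genes)
  ns <- length(gene_set)
  nu <- length(universe)
  ov <- length(intersect(module_genes, gene_set))
  if (nm == 0 || ns == 0) {
    return(tibble::tibble(module_id = module_id, set_name = set_name,
                          overlap = 0L, module_size = nm, set_size = ns,
                          universe_size = nu, fold_enrichment = NA_real_,
                          p = 1))
  }
  p <- phyper(ov - 1, ns, nu - ns, nm, lower.tail = FALSE)
  fe <- (ov / nm) / (ns / nu)
  tibble::tibble(module_id = module_id, set_name = set_name, overlap = ov,
                 module_size = nm, set_size = ns, universe_size = nu,
                 fold_enrichment = fe, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, `q_(i) = min_{j >= i} p_(j) * n / j`, preserving
#' input order.
#'
#' @param pvals Numeric vector in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "BH")
}

#' Module eigengene
#'
#' First principal component of the module's gene x sample submatrix: genes
#' are z-scored, the first right-singular vector gives the per-sample score,
#' and the sign is flipped if the score correlates negatively with the mean
#' standardized module profile (so the eigengene tracks overall module
#' expression).
#'
#' @param expr Gene x sample matrix.
#' @param module_genes Character vector (>= 2 genes present in `expr`).
#' @param module_id Optional label.
#' @return Object of class `eigengene`: list with `module_id`, `score`
#'   (named per-sample vector), `variance_explained`, `n_genes`.
#' @export
module_eigengene <- function(expr, module_genes, module_id = NA_character_) {
  sub <- expr[intersect(module_genes, rownames(expr)), , drop = FALSE]
  if (nrow(sub) < 2) stop("module needs at least 2 genes present in expr")
  if (ncol(sub) < 3) stop("need at least 3 samples")
  v <- apply(sub, 1, sd)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance gene(s) from the module")
    sub <- sub[v > 0, , drop = FALSE]
    v <- v[v > 0]
    if (nrow(sub) < 2) stop("too few non-constant genes")
  }
  z <- (sub - rowMeans(sub)) / v
  sv <- svd(z)
  score <- sv$v[, 1]
  ve <- sv$d[1]^2 / sum(sv$d^2)
  mean_profile <- colMeans(z)
  if (cor(score, mean_profile) < 0) score <- -score
  structure(list(module_id = module_id,
                 score = setNames(score, colnames(sub)),
                 variance_explained = ve, n_genes = nrow(sub)),
            class = "eigengene")
}

#' @export
tidy.eigengene <- function(x, ...) {
  tibble::tibble(module_id = x$module_id, sample = names(x$score),
                 score = unname(x$score))
}

#' @export
glance.eigengene <- function(x, ...) {
  tibble::tibble(module_id = x$module_id, n_genes = x$n_genes,
                 variance_explained = x$variance_explained)
}

#' Spearman correlation of a module eigengene with donor age
#'
#' Midrank-tie Spearman rho (ages are decade midpoints and heavily tied) with
#' a two-sided p-value from the t approximation.
#'
#' @param eigengene An [module_eigengene()] result or a numeric score vector.
#' @param ages Numeric vector of ages, aligned with the scores.
#' @return One-row tibble `module_id`, `rho`, `p`.
#' @export
age_correlation <- function(eigengene, ages) {
  score <- if (inherits(eigengene, "eigengene")) eigengene$score else eigengene
  mid <- if (inherits(eigengene, "eigengene")) eigengene$module_id else NA_character_
  if (length(score) < 5) stop("need at least 5 samples")
  if (sd(score) == 0 || sd(ages) == 0) {
    return(tibble::tibble(module_id = mid, rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(cor.test(score, ages, method = "spearman", exact = FALSE))
  tibble::tibble(module_id = mid, rho = unname(ct$estimate), p = ct$p.value)
}

#' Enrichment of every module in every tissue against one gene set
#'
#' Runs [fisher_enrichment()] for each module with the tissue's network genes
#' as the universe, BH-adjusts within the chosen scope, and flags modules
#' with `q <= alpha_q` (non-strict, so `alpha_q = 1` returns every module
#' with a nonzero overlap).
#'
#' @param hierarchies Named list `tissue -> module_hierarchy` (from
#'   [detect_modules()]).
#' @param sng_set Character vector of SnG symbols.
#' @param universes Named list `tissue -> character vector` (network genes);
#'   defaults to the union of module members per tissue.
#' @param alpha_q FDR threshold on the adjusted p (default 0.05).
#' @param scope BH scope: `"per_tissue"` (default) or `"global"`.
#' @param include_roots Score root modules too? Default `FALSE` (roots span
#'   whole components and are not candidate senescence modules).
#' @return Tibble of flagged modules: `tissue`, `module_id`, `members`,
#'   `module_size`, `overlap`, `fold_enrichment`, `p`, `q`; the unfiltered
#'   table is attached as attribute `"all"`, and `scope` is recorded.
#' @export
flag_sng_modules <- function(hierarchies, sng_set, universes = NULL,
                             alpha_q = 0.05, scope = c("per_tissue", "global"),
                             include_roots = FALSE) {
  scope <- match.arg(scope)
  tabs <- purrr::imap_dfr(hierarchies, function(h, tn) {
    hh <- as_tibble(h)
    if (!include_roots && any(!is.na(hh$parent_id))) {
      hh <- dplyr::filter(hh, !is.na(.data$parent_id))
    }
    if (nrow(hh) == 0) return(tibble::tibble())
    uni <- if (!is.null(universes)) universes[[tn]] else {
      unique(unlist(as_tibble(h)$members))
    }
    sset <- intersect(sng_set, uni)
    purrr::map_dfr(seq_len(nrow(hh)), function(i) {
      dplyr::mutate(
        fisher_enrichment(hh$members[[i]], sset, uni,
                          module_id = hh$module_id[i], set_name = "SnG"),
        tissue = tn, members = list(hh$members[[i]]), .before = 1
      )
    })
  })
  if (nrow(tabs) == 0) stop("no modules to score; run detect_modules first")
  tabs <- if (scope == "per_tissue") {
    dplyr::mutate(dplyr::group_by(tabs, .data$tissue), q = bh_adjust(.data$p)) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(tabs, q = bh_adjust(.data$p))
  }
  flagged <- dplyr::filter(tabs, .data$q <= alpha_q, .data$overlap >= 1)
  structure(flagged, all = tabs, scope = scope, alpha_q = alpha_q)
}
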