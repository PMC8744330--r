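#' Binary SnG x module presence matrix
#'
#' Rows are SnGs found in at least one flagged module, columns are
#' tissue-qualified flagged modules; entry 1 marks presence of the SnG in the
#' module, 0 absence. All-zero rows/columns are dropped with a message.
#'
#' @param flagged_modules Tibble from [flag_sng_modules()] (needs `tissue`,
#'   `module_id`, `members`).
#' @param sng_set Character vector of SnG symbols.
#' @return Binary matrix with SnG rownames and `tissue:module` colnames.
#' @export
build_presence_matrix <- function(flagged_modules, sng_set) {
  if (nrow(flagged_modules) == 0) stop("no flagged modules")
  cols <- paste(flagged_modules$tissue, flagged_modules$module_id, sep = ":")
  m <- vapply(seq_len(nrow(flagged_modules)), function(i) {
    as.integer(sng_set %in% flagged_modules$members[[i]])
  }, integer(length(sng_set)))
  dim(m) <- c(length(sng_set), nrow(flagged_modules))
  dimnames(m) <- list(sng_set, cols)
  rz <- rowSums(m) == 0
  cz <- colSums(m) == 0
  if (any(rz)) message("dropping ", sum(rz), " SnG row(s) absent from all modules")
  if (any(cz)) message("dropping ", sum(cz), " module column(s) with no SnGs")
  m[!rz, !cz, drop = FALSE]
}

# k-means++ seeding: iterative D^2 sampling
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  ci <- sample.int(n, 1)
  centers[1, ] <- x[ci, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    ci <- sample.int(n, 1, prob = probs)
    centers[j + 1, ] <- x[ci, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j + 1, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' Consensus k-means clustering of a presence matrix axis
#'
#' Runs Euclidean k-means (k-means++ initialization, distinct sub-seeds)
#' `runs` times on the rows (or columns), builds the co-assignment matrix
#' (fraction of runs placing two items together), and cuts an
#' average-linkage hierarchical clustering of `1 - co_assignment` into `k`
#' consensus groups.
#'
#' @param mat Numeric matrix (e.g. from [build_presence_matrix()]).
#' @param k Number of clusters (default 4).
#' @param runs Number of k-means runs (default 100).
#' @param axis `"rows"` or `"cols"`.
#' @param seed Integer seed.
#' @return Object of class `consensus_clusters`: list with `labels` (named
#'   integer vector), `co_assignment`, `k`, `runs`, `axis`.
#' @export
consensus_kmeans <- function(mat, k = 4, runs = 100, axis = c("rows", "cols"),
                             seed = 1L) {
  axis <- match.arg(axis)
  x <- if (axis == "rows") mat else t(mat)
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds the number of items (", n, ")")
  if (k > nrow(unique(as.data.frame(x)))) {
    stop("fewer distinct items than k")
  }
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max, runs)
  co <- matrix(0, n, n)
  for (rr in seq_len(runs)) {
    set.seed(subseeds[rr])
    if (k == n) {
      cl <- seq_len(n)
    } else {
      centers <- kmeanspp_centers(x, k)
      centers <- centers + matrix(rnorm(length(centers), 0, 1e-9), k) # break exact duplicates
      cl <- kmeans(x, centers = centers, iter.max = 50,
                   algorithm = "Lloyd")$cluster
    }
    same <- outer(cl, cl, "==")
    co <- co + same
  }
  co <- co / runs
  dimnames(co) <- list(rownames(x), rownames(x))
  labels <- if (k == n) setNames(seq_len(n), rownames(x)) else {
    hc <- hclust(as.dist(1 - co), method = "average")
    cutree(hc, k = k)
  }
  structure(list(labels = labels, co_assignment = co, k = k, runs = runs,
                 axis = axis),
            class = "consensus_clusters")
}

#' @export
tidy.consensus_clusters <- function(x, ...) {
  tibble::tibble(item = names(x$labels), cluster = unname(x$labels))
}

#' @export
glance.consensus_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, runs = x$runs, axis = x$axis,
                 n_items = length(x$labels),
                 mean_co_assignment = mean(x$co_assignment[lower.tri(x$co_assignment)]))
}

#' @export
autoplot.consensus_clusters <- function(object, ...) {
  ord <- order(object$labels)
  co <- object$co_assignment[ord, ord]
  df <- tibble::tibble(
    a = factor(rep(rownames(co), times = ncol(co)), levels = rownames(co)),
    b = factor(rep(colnames(co), each = nrow(co)), levels = colnames(co)),
    co = as.vector(co)
  )
  ggplot(df, aes(x = .data$a, y = .data$b, fill = .data$co)) +
    geom_tile() +
    scale_fill_viridis_c(name = "co-assignment", limits = c(0, 1)) +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Select conserved SnG clusters by tissue breadth
#'
#' For each row (SnG) cluster, the tissue breadth is the number of distinct
#' tissues whose flagged modules contain at least one cluster member;
#' clusters whose breadth exceeds `min_tissue_fraction * n_tissues_surveyed`
#' contribute all their member genes to the conserved list.
#'
#' @param clusters A [consensus_kmeans()] result over rows (SnGs).
#' @param presence The presence matrix the clustering used.
#' @param tissue_of Named character vector `module column -> tissue` (default
#'   parses the `tissue:module` column names).
#' @param min_tissue_fraction Breadth threshold as a fraction (default 0.5:
#'   "more than half of the surveyed tissues").
#' @param n_tissues_surveyed Denominator; default = number of distinct
#'   tissues among the presence-matrix columns.
#' @return List with `conserved` (character vector) and `summary` (tibble
#'   `cluster`, `n_genes`, `tissue_breadth`, `selected`).
#' @export
select_conserved_sngs <- function(clusters, presence, tissue_of = NULL,
                                  min_tissue_fraction = 0.5,
                                  n_tissues_surveyed = NULL) {
  stopifnot(inherits(clusters, "consensus_clusters"))
  if (is.null(tissue_of)) {
    tissue_of <- setNames(sub(":.*$", "", colnames(presence)), colnames(presence))
  }
  if (is.null(n_tissues_surveyed)) {
    n_tissues_surveyed <- length(unique(tissue_of[colnames(presence)]))
  }
  labs <- clusters$labels
  summ <- purrr::map_dfr(sort(unique(labs)), function(cl) {
    genes <- names(labs)[labs == cl]
    sub <- presence[genes, , drop = FALSE]
    hit_cols <- colnames(presence)[colSums(sub) > 0]
    breadth <- length(unique(tissue_of[hit_cols]))
    tibble::tibble(cluster = cl, n_genes = length(genes),
                   tissue_breadth = breadth,
                   selected = breadth > min_tissue_fraction * n_tissues_surveyed)
  })
  conserved <- sort(names(labs)[labs %in% summ$cluster[summ$selected]])
  list(conserved = conserved, summary = summ)
}
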